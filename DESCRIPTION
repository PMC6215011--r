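Package: wingscan
Title: Genome Scans for Morph-Associated Outlier Loci in Wing-Dimorphic Insects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, filtering and genome-scan tools for detecting loci
    associated with a discrete morphotype in an otherwise panmictic
    population, modelled on genotyping-by-sequencing (GBS) SNP studies of
    wing reduction in alpine stoneflies. Provides a GENEPOP reader/writer
    and locus filters (call rate, minor allele frequency, one SNP per tag),
    per-locus heterozygosity summaries, population-structure diagnostics
    (VanRaden genomic relatedness, neighbor-joining relatedness trees,
    principal components, BIC-based cluster-number selection), a Bayesian
    logistic-FST outlier model fitted by reversible-jump MCMC with
    posterior-probability q-values, a principal-component Mahalanobis
    outlier scan with genomic-inflation correction, Weir-Cockerham FST,
    and a replication framework of balanced split-half scans, randomized
    null scans and hypergeometric overlap statistics. A synthetic-data
    generator with known ground truth makes every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
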