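#!/usr/bin/env Rscript

# Stage 2 -- locus filtering and per-locus summaries.
#
# Applies the GBS post-genotyping filters (call rate >= 0.5, minor allele
# frequency >= 0.05, one SNP per tag) and writes the filtered GENEPOP
# plus per-locus call rate, MAF and observed/expected heterozygosity.

library(wingscan)

out <- "results"
gm <- read_genepop("results/data/genotypes.genepop")
message(sprintf("input: %d individuals x %d loci", nrow(gm$calls), ncol(gm$calls)))

gmf <- filter_loci(gm, min_call_rate = 0.5, min_maf = 0.05, one_per_tag = TRUE)
message(sprintf("retained %d loci after filtering", ncol(gmf$calls)))

write_genepop(gmf, file.path(out, "genotypes_filtered.genepop"))
st <- locus_summary(gmf)
write.table(st, file.path(out, "locus_stats.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf(
  "observed heterozygosity mean %.3f (sd %.3f); expected %.3f (sd %.3f)",
  mean(st$ho), sd(st$ho), mean(st$he), sd(st$he)
))
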