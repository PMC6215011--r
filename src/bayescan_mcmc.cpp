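#include <Rcpp.h>
using namespace Rcpp;

// Logistic decomposition of locus-group FST:
//   logit(FST_ij) = delta_i * alpha_i + beta_j
// with allele counts a_ij ~ BetaBinomial(n_ij, theta_ij p_i, theta_ij (1-p_i)),
// theta_ij = 1/FST_ij - 1 = exp(-logit(FST_ij)).
// The locus effect alpha_i is toggled by a reversible-jump move whose prior
// inclusion probability is 1/(1 + prior_odds).

static const double X_CLAMP = 15.0;  // bound on logit(FST); theta in [3e-7, 3e6]
static const double P_EPS = 1e-6;

// log beta-binomial likelihood for one locus-group cell, up to the
// data-only constant choose(n, a)
static inline double cell_loglik(double a, double n, double p, double x) {
  if (n <= 0.0) return 0.0;
  if (x > X_CLAMP) x = X_CLAMP;
  if (x < -X_CLAMP) x = -X_CLAMP;
  double theta = std::exp(-x);
  double tp = theta * p, tq = theta * (1.0 - p);
  return R::lgammafn(theta) - R::lgammafn(tp) - R::lgammafn(tq)
       + R::lgammafn(a + tp) + R::lgammafn(n - a + tq)
       - R::lgammafn(n + theta);
}

static inline double reflect01(double x) {
  // reflect a random-walk proposal back into (P_EPS, 1 - P_EPS)
  while (x < P_EPS || x > 1.0 - P_EPS) {
    if (x < P_EPS) x = 2.0 * P_EPS - x;
    if (x > 1.0 - P_EPS) x = 2.0 * (1.0 - P_EPS) - x;
  }
  return x;
}

struct Tuner {
  double width;
  int acc, att;
  Tuner(double w) : width(w), acc(0), att(0) {}
  void adapt(double lo, double hi, double wmin, double wmax) {
    if (att < 10) { acc = 0; att = 0; return; }
    double rate = (double)acc / att;
    if (rate > hi) width *= 1.5;
    else if (rate < lo) width /= 1.5;
    if (width > wmax) width = wmax;
    if (width < wmin) width = wmin;
    acc = 0; att = 0;
  }
};

// [[Rcpp::export]]
List bayescan_mcmc(IntegerMatrix acount, IntegerMatrix ncount,
                   int n_output, int thinning, int burn_in,
                   int n_pilot, int pilot_length, double prior_odds) {
  const int L = acount.nrow();
  const int J = acount.ncol();
  if (ncount.nrow() != L || ncount.ncol() != J)
    stop("allele-count and sample-size matrices disagree");
  if (n_output < 1 || thinning < 1 || burn_in < 0 || n_pilot < 0 ||
      pilot_length < 0 || prior_odds <= 0.0)
    stop("invalid MCMC configuration");

  const double log_prior_incl = -std::log(prior_odds); // log pi1/pi0

  // state
  std::vector<double> p(L), alpha(L, 0.0);
  std::vector<int> delta(L, 0);
  std::vector<double> beta(J, -1.0);
  for (int i = 0; i < L; ++i) {
    double atot = 0.0, ntot = 0.0;
    for (int j = 0; j < J; ++j) { atot += acount(i, j); ntot += ncount(i, j); }
    p[i] = (atot + 1.0) / (ntot + 2.0);
  }

  // cached log-likelihood per cell
  std::vector<double> ll(L * J);
  auto xval = [&](int i, int j) { return (delta[i] ? alpha[i] : 0.0) + beta[j]; };
  for (int i = 0; i < L; ++i)
    for (int j = 0; j < J; ++j)
      ll[i * J + j] = cell_loglik(acount(i, j), ncount(i, j), p[i], xval(i, j));

  // proposal tuners: per-locus p and alpha widths, per-group beta widths
  std::vector<Tuner> tune_p(L, Tuner(0.2)), tune_a(L, Tuner(1.0));
  std::vector<Tuner> tune_b(J, Tuner(0.25));
  int rj_acc = 0, rj_att = 0;

  // posterior accumulators
  std::vector<double> sum_delta(L, 0.0), sum_alpha(L, 0.0), sum_fst(L * J, 0.0);
  std::vector<int> n_incl(L, 0);
  std::vector<double> sum_beta(J, 0.0);
  int n_kept = 0;
  std::vector<double> diag_iter, diag_logpost, diag_nincl;
  std::vector<double> lbuf(J);

  const int total_iter = n_pilot * pilot_length + burn_in + n_output * thinning;
  const int sample_start = n_pilot * pilot_length + burn_in;

  RNGScope scope;
  for (int it = 0; it < total_iter; ++it) {
    // p_i updates (uniform prior; symmetric reflected walk)
    for (int i = 0; i < L; ++i) {
      double pprop = reflect01(p[i] + R::runif(-tune_p[i].width, tune_p[i].width));
      double lnew0 = cell_loglik(acount(i, 0), ncount(i, 0), pprop, xval(i, 0));
      double logr = lnew0 - ll[i * J];
      double lnew1 = 0.0;
      if (J > 1) {
        lnew1 = cell_loglik(acount(i, 1), ncount(i, 1), pprop, xval(i, 1));
        logr += lnew1 - ll[i * J + 1];
      }
      tune_p[i].att++;
      if (std::log(R::runif(0, 1)) < logr) {
        p[i] = pprop;
        ll[i * J] = lnew0;
        if (J > 1) ll[i * J + 1] = lnew1;
        tune_p[i].acc++;
      }
    }

    // alpha_i updates for included loci (N(0,1) prior)
    for (int i = 0; i < L; ++i) {
      if (!delta[i]) continue;
      double aprop = alpha[i] + R::norm_rand() * tune_a[i].width;
      double logr = R::dnorm(aprop, 0.0, 1.0, 1) - R::dnorm(alpha[i], 0.0, 1.0, 1);
      double* lnew = lbuf.data();
      for (int j = 0; j < J; ++j) {
        lnew[j] = cell_loglik(acount(i, j), ncount(i, j), p[i], aprop + beta[j]);
        logr += lnew[j] - ll[i * J + j];
      }
      tune_a[i].att++;
      if (std::log(R::runif(0, 1)) < logr) {
        alpha[i] = aprop;
        for (int j = 0; j < J; ++j) ll[i * J + j] = lnew[j];
        tune_a[i].acc++;
      }
    }

    // beta_j updates (N(-1,1) prior); recompute the whole column
    for (int j = 0; j < J; ++j) {
      double bprop = beta[j] + R::norm_rand() * tune_b[j].width;
      double logr = R::dnorm(bprop, -1.0, 1.0, 1) - R::dnorm(beta[j], -1.0, 1.0, 1);
      std::vector<double> lnew(L);
      for (int i = 0; i < L; ++i) {
        lnew[i] = cell_loglik(acount(i, j), ncount(i, j), p[i],
                              (delta[i] ? alpha[i] : 0.0) + bprop);
        logr += lnew[i] - ll[i * J + j];
      }
      tune_b[j].att++;
      if (std::log(R::runif(0, 1)) < logr) {
        beta[j] = bprop;
        for (int i = 0; i < L; ++i) ll[i * J + j] = lnew[i];
        tune_b[j].acc++;
      }
    }

    // reversible-jump toggle of delta_i; birth proposal alpha* ~ N(0, s_i)
    for (int i = 0; i < L; ++i) {
      rj_att++;
      double s = tune_a[i].width;
      if (!delta[i]) {
        double astar = R::norm_rand() * s;
        double logr = log_prior_incl
          + R::dnorm(astar, 0.0, 1.0, 1) - R::dnorm(astar, 0.0, s, 1);
        double* lnew = lbuf.data();
        for (int j = 0; j < J; ++j) {
          lnew[j] = cell_loglik(acount(i, j), ncount(i, j), p[i], astar + beta[j]);
          logr += lnew[j] - ll[i * J + j];
        }
        if (std::log(R::runif(0, 1)) < logr) {
          delta[i] = 1;
          alpha[i] = astar;
          for (int j = 0; j < J; ++j) ll[i * J + j] = lnew[j];
          rj_acc++;
        }
      } else {
        double logr = -log_prior_incl
          + R::dnorm(alpha[i], 0.0, s, 1) - R::dnorm(alpha[i], 0.0, 1.0, 1);
        double* lnew = lbuf.data();
        for (int j = 0; j < J; ++j) {
          lnew[j] = cell_loglik(acount(i, j), ncount(i, j), p[i], beta[j]);
          logr += lnew[j] - ll[i * J + j];
        }
        if (std::log(R::runif(0, 1)) < logr) {
          delta[i] = 0;
          for (int j = 0; j < J; ++j) ll[i * J + j] = lnew[j];
          rj_acc++;
        }
      }
    }

    // end-of-pilot adaptation
    if (n_pilot > 0 && it < n_pilot * pilot_length &&
        (it + 1) % pilot_length == 0) {
      for (int i = 0; i < L; ++i) {
        tune_p[i].adapt(0.25, 0.45, 1e-3, 0.49);
        tune_a[i].adapt(0.25, 0.45, 0.05, 6.0);
      }
      for (int j = 0; j < J; ++j) tune_b[j].adapt(0.25, 0.45, 1e-3, 3.0);
    }

    // retain samples
    if (it >= sample_start && (it - sample_start + 1) % thinning == 0) {
      ++n_kept;
      int nincl = 0;
      double logpost = 0.0;
      for (int i = 0; i < L; ++i) {
        sum_delta[i] += delta[i];
        if (delta[i]) {
          sum_alpha[i] += alpha[i];
          n_incl[i]++;
          nincl++;
          logpost += R::dnorm(alpha[i], 0.0, 1.0, 1) + log_prior_incl;
        }
        for (int j = 0; j < J; ++j) {
          double x = xval(i, j);
          if (x > X_CLAMP) x = X_CLAMP;
          if (x < -X_CLAMP) x = -X_CLAMP;
          sum_fst[i * J + j] += 1.0 / (1.0 + std::exp(-x));
          logpost += ll[i * J + j];
        }
      }
      for (int j = 0; j < J; ++j) {
        sum_beta[j] += beta[j];
        logpost += R::dnorm(beta[j], -1.0, 1.0, 1);
      }
      diag_iter.push_back(it + 1);
      diag_logpost.push_back(logpost);
      diag_nincl.push_back(nincl);
    }

    if ((it & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector post_prob(L), alpha_mean(L);
  NumericMatrix fst(L, J);
  for (int i = 0; i < L; ++i) {
    post_prob[i] = sum_delta[i] / n_kept;
    alpha_mean[i] = n_incl[i] > 0 ? sum_alpha[i] / n_incl[i] : NA_REAL;
    for (int j = 0; j < J; ++j) fst(i, j) = sum_fst[i * J + j] / n_kept;
  }
  NumericVector beta_mean(J);
  for (int j = 0; j < J; ++j) beta_mean[j] = sum_beta[j] / n_kept;

  return List::create(
    _["post_prob"] = post_prob,
    _["alpha_mean"] = alpha_mean,
    _["fst"] = fst,
    _["beta_mean"] = beta_mean,
    _["diagnostics"] = DataFrame::create(
      _["iteration"] = diag_iter,
      _["log_posterior"] = diag_logpost,
      _["n_included"] = diag_nincl),
    _["rj_accept_rate"] = rj_att > 0 ? (double)rj_acc / rj_att : NA_REAL,
    _["n_retained"] = n_kept);
}
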