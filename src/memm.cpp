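// Inner computations of the spatially explicit mixed-effect mating
// model MCMC: kernel weight matrices, per-seed local mating sums, and
// the Metropolis sweep over per-male fecundities (which dominates the
// cost of an iteration and is maintained incrementally).

#include <Rcpp.h>
using namespace Rcpp;

// exp() results below the normal floating-point range are flushed to
// zero: subnormal kernel weights are meaningless here and extremely
// slow on common hardware
static inline double safe_exp(double x) {
  return (x < -700.0) ? 0.0 : std::exp(x);
}

// power-exponential kernel value at the mother x male distances,
// parameterised by mean distance delta and shape b
// [[Rcpp::export]]
NumericMatrix memm_kernel(NumericMatrix D, double delta, double b) {
  double a = delta * R::gammafn(2.0 / b) / R::gammafn(3.0 / b);
  int nm = D.nrow(), nj = D.ncol();
  NumericMatrix K(nm, nj);
  for (int j = 0; j < nj; ++j)
    for (int i = 0; i < nm; ++i)
      K(i, j) = safe_exp(-std::pow(D(i, j) / a, b));
  return K;
}

// mating sums given kernel and fecundities:
//   W_m = sum_j f_j K(m, j)           (per mother)
//   T_i = sum_j f_j K(mom_i, j) R_ij  (per seed)
// R_ij is the seed x male genotype likelihood ratio against the
// outside-pollen model; mom is the 0-based mother index per seed
// [[Rcpp::export]]
List memm_sums(NumericMatrix R, IntegerVector mom, NumericMatrix K,
               NumericVector f) {
  int n = R.nrow(), nj = R.ncol(), nm = K.nrow();
  NumericVector W(nm), T(n);
  for (int j = 0; j < nj; ++j) {
    double fj = f[j];
    for (int m = 0; m < nm; ++m) W[m] += fj * K(m, j);
    for (int i = 0; i < n; ++i) T[i] += fj * K(mom[i], j) * R(i, j);
  }
  return List::create(_["W"] = W, _["T"] = T);
}

// conditional log-likelihood core:
//   sum_i log(m g_i + (1 - m) T_i / W_mom_i)
// where g_i is the outside-pollen likelihood of seed i on the shared
// per-seed normalisation scale (1 when normalising by it)
// [[Rcpp::export]]
double memm_llcore(NumericVector T, NumericVector W, IntegerVector mom,
                   double m, NumericVector g) {
  double ll = 0.0, prod = 1.0;
  int n = T.size(), chunk = 0;
  for (int i = 0; i < n; ++i) {
    prod *= m * g[i] + (1.0 - m) * T[i] / W[mom[i]];
    if (++chunk == 16 || i == n - 1) {
      ll += std::log(prod);
      prod = 1.0;
      chunk = 0;
    }
  }
  return ll;
}

// one Metropolis sweep over the per-male fecundities (random walk on
// log f_j). prior_type 0: gamma with shape alpha and mean mu_j;
// prior_type 1: log-normal with variance parameter sig2 and mean mu_j.
// T and W are updated in place on acceptance; the likelihood-ratio
// term accumulates per-seed ratios in chunked products to avoid one
// log() per seed. When prior_only is true the likelihood is dropped.
// [[Rcpp::export]]
List memm_fec_sweep(NumericMatrix R, IntegerVector mom, NumericMatrix K,
                    NumericVector f, NumericVector T, NumericVector W,
                    NumericVector g, double m, double step,
                    int prior_type, double par, NumericVector mu,
                    bool prior_only) {
  int n = R.nrow(), nj = R.ncol(), nmo = K.nrow();
  std::vector<double> Tn(n), Wn(nmo), invWn(nmo), invW(nmo);
  int accept = 0;
  double c1 = 1.0 - m;
  for (int j = 0; j < nj; ++j) {
    double fj = f[j];
    double fp = fj * std::exp(step * norm_rand());
    double dprior, ljac = std::log(fp / fj);
    if (prior_type == 0) {
      double alpha = par;
      dprior = R::dgamma(fp, alpha, mu[j] / alpha, 1) -
               R::dgamma(fj, alpha, mu[j] / alpha, 1);
    } else {
      double sig = std::sqrt(par);
      double ml = std::log(mu[j]) - par / 2.0;
      dprior = R::dlnorm(fp, ml, sig, 1) - R::dlnorm(fj, ml, sig, 1);
    }
    double dll = 0.0;
    if (!prior_only) {
      double df = fp - fj;
      for (int mm = 0; mm < nmo; ++mm) {
        Wn[mm] = W[mm] + df * K(mm, j);
        invWn[mm] = 1.0 / Wn[mm];
        invW[mm] = 1.0 / W[mm];
      }
      double prod = 1.0;
      int chunk = 0;
      for (int i = 0; i < n; ++i) {
        double Ti = T[i] + df * K(mom[i], j) * R(i, j);
        Tn[i] = Ti;
        double lnew = m * g[i] + c1 * Ti * invWn[mom[i]];
        double lold = m * g[i] + c1 * T[i] * invW[mom[i]];
        prod *= lnew / lold;
        if (++chunk == 32 || i == n - 1) {
          dll += std::log(prod);
          prod = 1.0;
          chunk = 0;
        }
      }
    }
    if (std::log(unif_rand()) < dll + dprior + ljac) {
      f[j] = fp;
      if (!prior_only) {
        for (int mm = 0; mm < nmo; ++mm) W[mm] = Wn[mm];
        for (int i = 0; i < n; ++i) T[i] = Tn[i];
      }
      ++accept;
    }
  }
  return List::create(_["f"] = f, _["T"] = T, _["W"] = W,
                      _["accept"] = accept);
}
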