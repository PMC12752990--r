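// Per-CpG binomial logistic regression likelihood-ratio tests.
//
// Fits, for every CpG site, a binomial GLM of per-sample methylated
// counts on a shared design matrix, with and without the group column,
// and returns the likelihood-ratio chi-square p-value for the group
// term. Written in C++ because the permutation-null filter re-runs the
// genome-wide scan for each label permutation; the reduced
// (covariate-only) model does not depend on the permuted labels, so its
// per-site log-likelihood can be computed once and passed back in.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double PMIN = 1e-10;

// binomial log-likelihood (up to the constant binomial coefficient,
// which cancels in the LRT)
static double binom_ll(const arma::vec& succ, const arma::vec& tot,
                       const arma::vec& p) {
  double ll = 0.0;
  for (arma::uword i = 0; i < succ.n_elem; ++i) {
    double pc = std::min(std::max(p(i), PMIN), 1.0 - PMIN);
    ll += succ(i) * std::log(pc) + (tot(i) - succ(i)) * std::log(1.0 - pc);
  }
  return ll;
}

// IRLS fit; returns log-likelihood, sets converged flag
static double fit_logistic(const arma::mat& X, const arma::vec& succ,
                           const arma::vec& tot, bool& converged) {
  const arma::uword k = X.n_cols;
  arma::vec beta(k, arma::fill::zeros);
  double mu0 = arma::sum(succ) / arma::sum(tot);
  mu0 = std::min(std::max(mu0, PMIN), 1.0 - PMIN);
  beta(0) = std::log(mu0 / (1.0 - mu0));  // column 0 is the intercept
  double ll_old = -1e300;
  converged = false;
  arma::vec eta, p, w, z, b, beta_new;
  arma::mat A;
  for (int it = 0; it < 30; ++it) {
    eta = X * beta;
    p = 1.0 / (1.0 + arma::exp(-eta));
    p = arma::clamp(p, PMIN, 1.0 - PMIN);
    w = tot % p % (1.0 - p);
    z = eta + (succ - tot % p) / w;
    A = X.t() * (X.each_col() % w);
    b = X.t() * (w % z);
    bool ok = arma::solve(beta_new, A, b,
                          arma::solve_opts::likely_sympd +
                          arma::solve_opts::no_approx);
    if (!ok) {
      beta_new = arma::pinv(A) * b;
      if (!beta_new.is_finite()) return binom_ll(succ, tot, p);
    }
    // cap runaway coefficients (quasi-separation); likelihood plateaus
    beta_new = arma::clamp(beta_new, -30.0, 30.0);
    beta = beta_new;
    p = 1.0 / (1.0 + arma::exp(-(X * beta)));
    double ll = binom_ll(succ, tot, p);
    if (std::fabs(ll - ll_old) < 1e-8 * (std::fabs(ll_old) + 1.0)) {
      converged = true;
      return ll;
    }
    ll_old = ll;
  }
  return ll_old;
}

// [[Rcpp::export]]
NumericMatrix dmc_lrt_cpp(const IntegerMatrix& meth,
                          const IntegerMatrix& total,
                          const arma::mat& Xfull,
                          const int group_col,
                          Nullable<NumericVector> ll_reduced_cache =
                              R_NilValue) {
  const int n_sites = meth.nrow();
  const int n = meth.ncol();
  if (Xfull.n_rows != (arma::uword)n)
    stop("design matrix rows != sample count");
  if (group_col < 0 || group_col >= (int)Xfull.n_cols)
    stop("bad group column index");
  arma::uvec keep_cols(Xfull.n_cols - 1);
  {
    arma::uword j = 0;
    for (arma::uword c = 0; c < Xfull.n_cols; ++c)
      if ((int)c != group_col) keep_cols(j++) = c;
  }
  arma::mat Xred = Xfull.cols(keep_cols);
  bool have_cache = ll_reduced_cache.isNotNull();
  NumericVector cache;
  if (have_cache) {
    cache = ll_reduced_cache.get();
    if (cache.size() != n_sites) stop("ll_reduced cache length mismatch");
  }
  // p, lrt stat, converged (0/1), reduced-model ll (cacheable)
  NumericMatrix out(n_sites, 4);
  colnames(out) = CharacterVector::create("p", "stat", "converged",
                                          "ll_reduced");
  arma::vec succ(n), tot(n);
  for (int i = 0; i < n_sites; ++i) {
    arma::uvec use(n);
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (total(i, j) > 0) {
        succ(m) = meth(i, j);
        tot(m) = total(i, j);
        use(m) = j;
        ++m;
      }
    }
    if (m < (int)Xfull.n_cols + 1) {  // not enough observations
      out(i, 0) = 1.0; out(i, 1) = 0.0; out(i, 2) = 0.0;
      out(i, 3) = NA_REAL;
      continue;
    }
    bool cf = false, cr = true;
    double llf, llr;
    if (m == n) {
      llf = fit_logistic(Xfull, succ, tot, cf);
      if (have_cache && R_finite(cache[i])) llr = cache[i];
      else llr = fit_logistic(Xred, succ, tot, cr);
    } else {
      arma::vec s = succ.head(m), t = tot.head(m);
      arma::uvec rows = use.head(m);
      llf = fit_logistic(Xfull.rows(rows), s, t, cf);
      llr = fit_logistic(Xred.rows(rows), s, t, cr);
    }
    double stat = 2.0 * (llf - llr);
    if (!std::isfinite(stat) || stat < 0.0) stat = 0.0;
    bool degenerate = !std::isfinite(llf) || !std::isfinite(llr);
    out(i, 0) = degenerate ? 1.0 : R::pchisq(stat, 1.0, 0, 0);
    out(i, 1) = stat;
    out(i, 2) = (cf && cr && !degenerate) ? 1.0 : 0.0;
    out(i, 3) = llr;
  }
  return out;
}
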