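// Elementary imputation draws and the chained-equations cycler.
// All randomness comes from R's RNG (RNGScope), so set.seed() on the R side
// fully determines every draw.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int kBootMaxTries = 10;

// Solve A x = b for a symmetric positive (semi)definite A, escalating a ridge
// on the diagonal until the Cholesky succeeds.
static arma::vec solve_spd_ridge(arma::mat A, const arma::vec& b) {
  double base = arma::trace(A) / A.n_rows;
  if (!(base > 0)) base = 1.0;
  double lambda = 0.0;
  for (int attempt = 0; attempt < 12; ++attempt) {
    arma::mat Ar = A;
    if (lambda > 0) Ar.diag() += lambda;
    arma::mat R;
    if (arma::chol(R, Ar)) {
      arma::vec z = arma::solve(arma::trimatl(R.t()), b);
      return arma::solve(arma::trimatu(R), z);
    }
    lambda = (lambda == 0.0) ? 1e-8 * base : lambda * 100.0;
  }
  return arma::pinv(A) * b; // last resort
}

// Cholesky with ridge escalation; returns upper-triangular R with R'R = A (+ridge).
static arma::mat chol_ridge(arma::mat A) {
  double base = arma::trace(A) / A.n_rows;
  if (!(base > 0)) base = 1.0;
  double lambda = 0.0;
  for (int attempt = 0; attempt < 12; ++attempt) {
    arma::mat Ar = A;
    if (lambda > 0) Ar.diag() += lambda;
    arma::mat R;
    if (arma::chol(R, Ar)) return R;
    lambda = (lambda == 0.0) ? 1e-8 * base : lambda * 100.0;
  }
  stop("Cholesky factorization failed even with ridge regularization");
}

static inline double inv_logit(double x) {
  if (x > 30.0) return 1.0 - 1e-13;
  if (x < -30.0) return 1e-13;
  return 1.0 / (1.0 + std::exp(-x));
}

// Linear regression draw via the bootstrap: resample observed cases, fit least
// squares on the resample, impute with the resampled coefficients plus noise at
// the resample residual SD. Singular resampled designs are redrawn a bounded
// number of times, then fitted with a ridge.
static arma::vec linear_boot_draw(const arma::mat& X, const arma::vec& y,
                                  const arma::mat& Xmiss) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  arma::vec beta(p);
  double sigma = 0.0;
  bool ok = false;
  for (int attempt = 0; attempt < kBootMaxTries && !ok; ++attempt) {
    arma::uvec idx(n);
    for (arma::uword i = 0; i < n; ++i)
      idx[i] = (arma::uword)(unif_rand() * n);
    arma::mat Xb = X.rows(idx);
    arma::vec yb = y.elem(idx);
    arma::mat XtX = Xb.t() * Xb;
    arma::mat R;
    if (!arma::chol(R, XtX)) continue; // singular resample: redraw
    arma::vec z = arma::solve(arma::trimatl(R.t()), Xb.t() * yb);
    beta = arma::solve(arma::trimatu(R), z);
    arma::vec resid = yb - Xb * beta;
    double df = (double)n - (double)p;
    double s2 = (df > 0) ? arma::dot(resid, resid) / df : 0.0;
    sigma = (s2 > 0) ? std::sqrt(s2) : 0.0;
    ok = true;
  }
  if (!ok) {
    // ridge fallback on a final resample
    arma::uvec idx(n);
    for (arma::uword i = 0; i < n; ++i)
      idx[i] = (arma::uword)(unif_rand() * n);
    arma::mat Xb = X.rows(idx);
    arma::vec yb = y.elem(idx);
    beta = solve_spd_ridge(Xb.t() * Xb, Xb.t() * yb);
    arma::vec resid = yb - Xb * beta;
    double df = std::max(1.0, (double)n - (double)p);
    double s2 = arma::dot(resid, resid) / df;
    sigma = (s2 > 0) ? std::sqrt(s2) : 0.0;
  }
  arma::vec out = Xmiss * beta;
  if (sigma > 0)
    for (arma::uword i = 0; i < out.n_elem; ++i) out[i] += norm_rand() * sigma;
  return out;
}

// Bayesian linear regression draw: sigma*^2 from the scaled inverse-chi^2
// posterior, beta* ~ N(betahat, sigma*^2 (X'X)^-1), then predictive noise.
static arma::vec linear_bayes_draw(const arma::mat& X, const arma::vec& y,
                                   const arma::mat& Xmiss) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  arma::mat XtX = X.t() * X;
  arma::mat R = chol_ridge(XtX);
  arma::vec z = arma::solve(arma::trimatl(R.t()), X.t() * y);
  arma::vec betahat = arma::solve(arma::trimatu(R), z);
  arma::vec resid = y - X * betahat;
  double df = std::max(1.0, (double)n - (double)p);
  double rss = arma::dot(resid, resid);
  double chi2 = ::Rf_rchisq(df);
  if (chi2 <= 0) chi2 = df;
  double s2 = rss / chi2;
  if (!(s2 > 0)) s2 = 0.0;
  double sigma = std::sqrt(s2);
  arma::vec zn(p);
  for (arma::uword j = 0; j < p; ++j) zn[j] = norm_rand();
  // cov(beta*) = s2 (X'X)^-1 = s2 R^-1 R^-T: beta* = betahat + sigma R^-1 z
  arma::vec beta = betahat + sigma * arma::solve(arma::trimatu(R), zn);
  arma::vec out = Xmiss * beta;
  if (sigma > 0)
    for (arma::uword i = 0; i < out.n_elem; ++i) out[i] += norm_rand() * sigma;
  return out;
}

// IRLS logistic fit with optional ridge penalty and optional warm start.
// Returns convergence flag.
static bool logistic_irls(const arma::mat& X, const arma::vec& y, double lambda,
                          arma::vec& beta, arma::mat& XtWX,
                          const arma::vec* init = nullptr) {
  const arma::uword p = X.n_cols;
  if (init != nullptr && init->n_elem == p && init->is_finite()) {
    beta = *init;
  } else {
    beta.zeros(p);
  }
  bool converged = false;
  for (int it = 0; it < 30; ++it) {
    arma::vec eta = X * beta;
    arma::vec mu(eta.n_elem), w(eta.n_elem);
    for (arma::uword i = 0; i < eta.n_elem; ++i) {
      mu[i] = inv_logit(eta[i]);
      w[i] = std::max(mu[i] * (1.0 - mu[i]), 1e-10);
    }
    XtWX = X.t() * (X.each_col() % w);
    if (lambda > 0) XtWX.diag() += lambda;
    arma::vec grad = X.t() * (y - mu);
    if (lambda > 0) grad -= lambda * beta;
    arma::vec step = solve_spd_ridge(XtWX, grad);
    beta += step;
    if (!beta.is_finite()) return false;
    if (arma::abs(step).max() < 1e-6) { converged = true; break; }
  }
  return converged && beta.is_finite() && arma::abs(beta).max() < 1e3;
}

// [[Rcpp::export]]
arma::vec cpp_logistic_fit(const arma::mat& X, const arma::vec& y,
                           double lambda) {
  arma::vec beta;
  arma::mat XtWX;
  if (!logistic_irls(X, y, lambda, beta, XtWX)) {
    double lam = (lambda > 0) ? lambda * 100.0 : 1.0;
    if (!logistic_irls(X, y, lam, beta, XtWX))
      logistic_irls(X, y, lam * 100.0, beta, XtWX);
  }
  return beta;
}

// Approximate-Bayesian logistic draw: beta* ~ N(betahat, (X'WX)^-1), then
// Bernoulli at the shifted probabilities. Separation falls back to a weak
// ridge penalty.
static arma::vec logistic_abayes_draw(const arma::mat& X, const arma::vec& y,
                                      const arma::mat& Xmiss,
                                      arma::vec* warm = nullptr) {
  // degenerate single-class input: impute the constant class
  double ybar = arma::mean(y);
  if (ybar <= 0.0 || ybar >= 1.0)
    return arma::vec(Xmiss.n_rows, arma::fill::value(ybar <= 0.0 ? 0.0 : 1.0));
  arma::vec beta;
  arma::mat XtWX;
  if (!logistic_irls(X, y, 0.0, beta, XtWX, warm)) {
    if (!logistic_irls(X, y, 0.1, beta, XtWX))
      logistic_irls(X, y, 10.0, beta, XtWX);
  }
  if (warm != nullptr) *warm = beta;
  arma::mat R = chol_ridge(XtWX); // R'R = X'WX
  arma::vec zn(beta.n_elem);
  for (arma::uword j = 0; j < beta.n_elem; ++j) zn[j] = norm_rand();
  arma::vec bstar = beta + arma::solve(arma::trimatu(R), zn);
  arma::vec eta = Xmiss * bstar;
  arma::vec out(eta.n_elem);
  for (arma::uword i = 0; i < eta.n_elem; ++i)
    out[i] = (unif_rand() < inv_logit(eta[i])) ? 1.0 : 0.0;
  return out;
}

// [[Rcpp::export]]
arma::vec cpp_draw_linear_boot(const arma::mat& X, const arma::vec& y,
                               const arma::mat& Xmiss) {
  RNGScope scope;
  return linear_boot_draw(X, y, Xmiss);
}

// [[Rcpp::export]]
arma::vec cpp_draw_linear_bayes(const arma::mat& X, const arma::vec& y,
                                const arma::mat& Xmiss) {
  RNGScope scope;
  return linear_bayes_draw(X, y, Xmiss);
}

// [[Rcpp::export]]
arma::vec cpp_draw_logistic_abayes(const arma::mat& X, const arma::vec& y,
                                   const arma::mat& Xmiss) {
  RNGScope scope;
  return logistic_abayes_draw(X, y, Xmiss);
}

// Bootstrap draw gathering the resampled design directly from the working
// matrix (one gather instead of two) — the chained cycler's hot path.
static arma::vec linear_boot_draw_direct(const arma::mat& dat,
                                         const arma::uvec& orows,
                                         const arma::uvec& pc,
                                         arma::uword col,
                                         const arma::mat& Xmiss) {
  const arma::uword n = orows.n_elem, p = pc.n_elem + 1;
  arma::mat Xb(n, p);
  arma::vec yb(n);
  arma::vec beta(p);
  double sigma = 0.0;
  bool ok = false;
  for (int attempt = 0; attempt < kBootMaxTries && !ok; ++attempt) {
    arma::uvec idx(n);
    for (arma::uword i = 0; i < n; ++i)
      idx[i] = orows[(arma::uword)(unif_rand() * n)];
    Xb.col(0).ones();
    for (arma::uword j = 0; j < pc.n_elem; ++j) {
      const double* src = dat.colptr(pc[j]);
      double* dst = Xb.colptr(j + 1);
      for (arma::uword i = 0; i < n; ++i) dst[i] = src[idx[i]];
    }
    const double* ysrc = dat.colptr(col);
    for (arma::uword i = 0; i < n; ++i) yb[i] = ysrc[idx[i]];
    arma::mat XtX = Xb.t() * Xb;
    arma::mat R;
    if (!arma::chol(R, XtX)) continue;
    arma::vec z = arma::solve(arma::trimatl(R.t()), Xb.t() * yb);
    beta = arma::solve(arma::trimatu(R), z);
    arma::vec resid = yb - Xb * beta;
    double df = (double)n - (double)p;
    double s2 = (df > 0) ? arma::dot(resid, resid) / df : 0.0;
    sigma = (s2 > 0) ? std::sqrt(s2) : 0.0;
    ok = true;
  }
  if (!ok) {
    beta = solve_spd_ridge(Xb.t() * Xb, Xb.t() * yb);
    arma::vec resid = yb - Xb * beta;
    double df = std::max(1.0, (double)n - (double)p);
    sigma = std::sqrt(arma::dot(resid, resid) / df);
  }
  arma::vec out = Xmiss * beta;
  if (sigma > 0)
    for (arma::uword i = 0; i < out.n_elem; ++i) out[i] += norm_rand() * sigma;
  return out;
}

// Chained-equations cycler over the flattened variable-by-time layout.
//
// dat:        n x C data matrix (targets + always-observed predictors),
//             modified copy is returned; missing target cells may hold NA.
// target_col: 0-based column indices of variables to impute (those with
//             missing cells), in visit order.
// miss_rows:  list of 0-based row indices of missing cells per target.
// pred_cols:  list of 0-based predictor column indices per target.
// method:     per target: 0 linear bootstrap, 1 Bayesian linear,
//             2 approximate-Bayesian logistic.
// iterations: number of full cycles after the initial random fill.
// [[Rcpp::export]]
arma::mat cpp_impute_chained(arma::mat dat, const IntegerVector& target_col,
                             const List& miss_rows, const List& pred_cols,
                             const IntegerVector& method, int iterations,
                             bool do_init = true) {
  RNGScope scope;
  const int K = target_col.size();

  // initial fill: sample observed values of the same column
  std::vector<arma::uvec> mrows(K), pcols(K), orows(K);
  for (int k = 0; k < K; ++k) {
    mrows[k] = as<arma::uvec>(miss_rows[k]);
    pcols[k] = as<arma::uvec>(pred_cols[k]);
    arma::uword col = (arma::uword)target_col[k];
    // observed rows = complement of missing rows
    std::vector<char> is_miss(dat.n_rows, 0);
    for (arma::uword i = 0; i < mrows[k].n_elem; ++i) is_miss[mrows[k][i]] = 1;
    arma::uvec obs(dat.n_rows - mrows[k].n_elem);
    arma::uword j = 0;
    for (arma::uword i = 0; i < dat.n_rows; ++i)
      if (!is_miss[i]) obs[j++] = i;
    orows[k] = obs;
    if (obs.n_elem == 0) stop("variable to impute has no observed cells");
    if (do_init) {
      for (arma::uword i = 0; i < mrows[k].n_elem; ++i) {
        arma::uword pick = obs[(arma::uword)(unif_rand() * obs.n_elem)];
        dat(mrows[k][i], col) = dat(pick, col);
      }
    }
  }

  std::vector<arma::vec> warm(K); // IRLS warm starts across cycles
  for (int it = 0; it < iterations; ++it) {
    for (int k = 0; k < K; ++k) {
      if (mrows[k].n_elem == 0) continue;
      arma::uword col = (arma::uword)target_col[k];
      const arma::uvec& pc = pcols[k];
      arma::mat Xm(mrows[k].n_elem, pc.n_elem + 1);
      Xm.col(0).ones();
      for (arma::uword j = 0; j < pc.n_elem; ++j) {
        const double* src = dat.colptr(pc[j]);
        double* dst = Xm.colptr(j + 1);
        for (arma::uword i = 0; i < mrows[k].n_elem; ++i)
          dst[i] = src[mrows[k][i]];
      }
      arma::vec imp;
      if (method[k] == 0) {
        imp = linear_boot_draw_direct(dat, orows[k], pc, col, Xm);
      } else {
        arma::mat X(orows[k].n_elem, pc.n_elem + 1);
        X.col(0).ones();
        for (arma::uword j = 0; j < pc.n_elem; ++j) {
          const double* src = dat.colptr(pc[j]);
          double* dst = X.colptr(j + 1);
          for (arma::uword i = 0; i < orows[k].n_elem; ++i)
            dst[i] = src[orows[k][i]];
        }
        arma::vec y(orows[k].n_elem);
        const double* ysrc = dat.colptr(col);
        for (arma::uword i = 0; i < orows[k].n_elem; ++i)
          y[i] = ysrc[orows[k][i]];
        switch (method[k]) {
          case 1: imp = linear_bayes_draw(X, y, Xm); break;
          case 2: imp = logistic_abayes_draw(X, y, Xm, &warm[k]); break;
          default: stop("unknown elementary method code");
        }
      }
      for (arma::uword i = 0; i < mrows[k].n_elem; ++i)
        dat(mrows[k][i], col) = imp[i];
    }
  }
  return dat;
}
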