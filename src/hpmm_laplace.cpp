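// Laplace-approximated marginal likelihood for the hierarchical Poisson
// mixed model
//
//   y_ij ~ Pois( exp(mu + X_ij beta + C_ij gamma + b_i + eps_ij) * K_ij )
//
// with b_i ~ N(0, var_b) shared within subject and eps_ij ~ N(0, var_eps)
// independent per observation.  Because observations of different subjects
// share no random effects, the marginal likelihood factorises by subject;
// each factor is a (1 + m_i)-dimensional integral (m_i = observations of
// subject i) approximated by Laplace's method at the joint mode of the
// integrand.  The negative Hessian at the mode is an arrowhead matrix
// (b couples to every eps_ij, the eps_ij do not couple to each other), so
// the Newton solve and the log-determinant are O(m_i) per subject.

#include <RcppArmadillo.h>
using namespace Rcpp;

static const int    MAX_NEWTON  = 100;
static const double GRAD_TOL    = 1e-10;
static const double ETA_CLAMP   = 40.0;   // exp(40) ~ 2.4e17, still finite

static inline double safe_exp(double x) {
  return std::exp(x > ETA_CLAMP ? ETA_CLAMP : x);
}

// Log joint density (Poisson terms + Gaussian priors, constants included)
// for one subject; c = linear predictor without random effects (offset
// log K folded in), b scalar, e vector (may be empty when var_eps == 0).
static double subject_logjoint(const arma::vec& y, const arma::vec& c,
                               double b, const arma::vec& e,
                               double var_b, double var_eps, bool has_b,
                               bool has_eps) {
  const int m = y.n_elem;
  double g = 0.0;
  for (int j = 0; j < m; ++j) {
    double eta = c[j] + (has_b ? b : 0.0) + (has_eps ? e[j] : 0.0);
    g += y[j] * eta - safe_exp(eta) - std::lgamma(y[j] + 1.0);
  }
  if (has_b)
    g += -0.5 * b * b / var_b - 0.5 * std::log(2.0 * M_PI * var_b);
  if (has_eps)
    for (int j = 0; j < m; ++j)
      g += -0.5 * e[j] * e[j] / var_eps - 0.5 * std::log(2.0 * M_PI * var_eps);
  return g;
}

// Laplace-approximated log marginal likelihood contribution of one
// subject.  b0/e0 warm-start the Newton mode search (and receive the
// converged mode back) so that consecutive likelihood evaluations during
// the outer optimization start near the solution.
static double subject_laplace(const arma::vec& y, const arma::vec& c,
                              double var_b, double var_eps,
                              double& b0, arma::subview_col<double> e0) {
  const int m = y.n_elem;
  const bool has_b = var_b > 0.0, has_eps = var_eps > 0.0;

  // No random effects: plain Poisson log likelihood.
  if (!has_b && !has_eps) {
    double ll = 0.0;
    for (int j = 0; j < m; ++j)
      ll += y[j] * c[j] - safe_exp(c[j]) - std::lgamma(y[j] + 1.0);
    return ll;
  }

  double b = has_b ? b0 : 0.0;
  arma::vec e(m);
  for (int j = 0; j < m; ++j) e[j] = has_eps ? e0[j] : 0.0;
  double g = subject_logjoint(y, c, b, e, var_b, var_eps, has_b, has_eps);

  for (int iter = 0; iter < MAX_NEWTON; ++iter) {
    // Gradient and arrowhead (negative) Hessian.
    arma::vec lam(m), ge(m);
    double gb = 0.0;
    for (int j = 0; j < m; ++j) {
      double eta = c[j] + (has_b ? b : 0.0) + (has_eps ? e[j] : 0.0);
      lam[j] = safe_exp(eta);
      if (has_eps) ge[j] = y[j] - lam[j] - e[j] / var_eps;
      gb += y[j] - lam[j];
    }
    if (has_b) gb -= b / var_b;

    double gmax = has_b ? std::fabs(gb) : 0.0;
    if (has_eps) gmax = std::max(gmax, arma::abs(ge).max());
    if (gmax < GRAD_TOL) break;

    // Newton direction via the Schur complement of the arrowhead.
    double db = 0.0;
    arma::vec de(m, arma::fill::zeros);
    if (has_b && has_eps) {
      double schur = 1.0 / var_b, rhs = gb;
      for (int j = 0; j < m; ++j) {
        double dj = lam[j] + 1.0 / var_eps;
        schur += lam[j] - lam[j] * lam[j] / dj;
        rhs -= lam[j] * ge[j] / dj;
      }
      db = rhs / schur;
      for (int j = 0; j < m; ++j)
        de[j] = (ge[j] - lam[j] * db) / (lam[j] + 1.0 / var_eps);
    } else if (has_b) {
      double h = 1.0 / var_b;
      for (int j = 0; j < m; ++j) h += lam[j];
      db = gb / h;
    } else {
      for (int j = 0; j < m; ++j) de[j] = ge[j] / (lam[j] + 1.0 / var_eps);
    }

    // Backtracking line search (g is strictly concave).
    double step = 1.0, gnew;
    for (int ls = 0; ls < 40; ++ls) {
      double bn = b + step * db;
      arma::vec en = e + step * de;
      gnew = subject_logjoint(y, c, bn, en, var_b, var_eps, has_b, has_eps);
      if (gnew >= g - 1e-12) { b = bn; e = en; break; }
      step *= 0.5;
    }
    if (std::fabs(gnew - g) < 1e-13 && gmax < 1e-6) { g = gnew; break; }
    g = gnew;
  }

  // log det of the negative Hessian at the mode, via the Schur complement.
  arma::vec lam(m);
  for (int j = 0; j < m; ++j)
    lam[j] = safe_exp(c[j] + (has_b ? b : 0.0) + (has_eps ? e[j] : 0.0));

  int dim = (has_b ? 1 : 0) + (has_eps ? m : 0);
  double logdet;
  if (has_b && has_eps) {
    double schur = 1.0 / var_b;
    logdet = 0.0;
    for (int j = 0; j < m; ++j) {
      double dj = lam[j] + 1.0 / var_eps;
      schur += lam[j] - lam[j] * lam[j] / dj;
      logdet += std::log(dj);
    }
    logdet += std::log(schur);
  } else if (has_b) {
    double h = 1.0 / var_b;
    for (int j = 0; j < m; ++j) h += lam[j];
    logdet = std::log(h);
  } else {
    logdet = 0.0;
    for (int j = 0; j < m; ++j) logdet += std::log(lam[j] + 1.0 / var_eps);
  }

  double gmode = subject_logjoint(y, c, b, e, var_b, var_eps, has_b, has_eps);
  if (has_b) b0 = b;
  if (has_eps) for (int j = 0; j < m; ++j) e0[j] = e[j];
  return gmode + 0.5 * dim * std::log(2.0 * M_PI) - 0.5 * logdet;
}

//' Negative Laplace log likelihood of the HPMM (internal)
//'
//' @param coef fixed-effect coefficients, conformable with \code{Xf}
//' @param var_b,var_eps variance components; a value of exactly 0 removes
//'   that random effect from the model
//' @param y observation counts
//' @param log_offset log K per observation
//' @param Xf fixed-effect design matrix (n_obs x p)
//' @param subj_start,subj_len 0-based start index and length of each
//'   subject's contiguous block of observations
//' @param warm numeric vector of length n_subjects + n_obs holding the
//'   random-effect modes (subject modes first, then observation modes);
//'   updated in place across calls to warm-start the inner Newton search
//' @return the negative log marginal likelihood (Laplace approximation)
//' @keywords internal
// [[Rcpp::export]]
double hpmm_nll_cpp(const arma::vec& coef, double var_b, double var_eps,
                    const arma::vec& y, const arma::vec& log_offset,
                    const arma::mat& Xf, const arma::ivec& subj_start,
                    const arma::ivec& subj_len, NumericVector warm) {
  arma::vec c_all = Xf * coef + log_offset;
  const int n_subj = subj_start.n_elem;
  arma::vec wmode(warm.begin(), warm.size(), false, true);  // no copy
  double ll = 0.0;
  for (int i = 0; i < n_subj; ++i) {
    int s = subj_start[i], m = subj_len[i];
    ll += subject_laplace(y.subvec(s, s + m - 1), c_all.subvec(s, s + m - 1),
                          var_b, var_eps, wmode[i],
                          wmode.subvec(n_subj + s, n_subj + s + m - 1));
  }
  if (!std::isfinite(ll)) return 1e10;
  return -ll;
}
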