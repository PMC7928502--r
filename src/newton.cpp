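#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Stable Bernoulli-logit log-likelihood: sum y*eta - log(1 + exp(eta)).
static double bernoulli_loglik(const arma::vec& y, const arma::vec& eta) {
  double ll = 0.0;
  for (arma::uword i = 0; i < eta.n_elem; ++i) {
    double e = eta[i];
    double lse = (e > 0.0) ? e + std::log1p(std::exp(-e)) : std::log1p(std::exp(e));
    ll += y[i] * e - lse;
  }
  return ll;
}

// Joint log-density log p(y | u) + log p(u) with independent Gaussian priors
// of precision prec[j] on each latent coordinate; all 2*pi constants kept so
// that prior-only blocks cancel exactly in Laplace marginal likelihoods.
static double joint_logdens(const arma::mat& W, const arma::vec& y,
                            const arma::vec& prec, const arma::vec& u,
                            const arma::vec& offset, double* loglik_out) {
  arma::vec eta = W * u + offset;
  double ll = bernoulli_loglik(y, eta);
  if (loglik_out) *loglik_out = ll;
  const double l2pi = std::log(2.0 * M_PI);
  double lp = 0.0;
  for (arma::uword j = 0; j < u.n_elem; ++j)
    lp += 0.5 * (std::log(prec[j]) - l2pi) - 0.5 * prec[j] * u[j] * u[j];
  return ll + lp;
}

//' Newton mode of a Bernoulli-logit model with diagonal Gaussian prior.
//'
//' Maximizes the joint log-density over the latent field u by damped Newton
//' iterations (step-halving line search). Returns the mode, the negative
//' Hessian of the joint log-density at the mode, its log-determinant and the
//' joint log-density value, so callers can form Laplace approximations.
// [[Rcpp::export(name = ".cpp_newton_mode")]]
List cpp_newton_mode(const arma::mat& W, const arma::vec& y,
                     const arma::vec& prec, const arma::vec& u0,
                     double tol, int maxit, const arma::vec& offset) {
  arma::vec u = u0;
  const arma::uword d = W.n_cols;
  double loglik = 0.0;
  double f = joint_logdens(W, y, prec, u, offset, &loglik);
  bool converged = false;
  int iter = 0;
  NumericVector trace(maxit > 0 ? maxit : 1);

  arma::mat H(d, d, arma::fill::zeros);
  for (iter = 0; iter < maxit; ++iter) {
    arma::vec eta = W * u + offset;
    arma::vec p = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec w = p % (1.0 - p);
    // keep curvature bounded away from 0 so H stays invertible
    w.transform([](double v) { return v < 1e-10 ? 1e-10 : v; });
    arma::vec grad = W.t() * (y - p) - prec % u;
    H = W.t() * (W.each_col() % w);
    H.diag() += prec;
    arma::vec step;
    bool ok = arma::solve(step, H, grad, arma::solve_opts::likely_sympd);
    if (!ok) { converged = false; break; }
    // trust-region style cap: near-separated directions have tiny local
    // curvature and produce huge Newton steps whose line search stalls at
    // machine precision; capped ascent on the concave objective converges
    double smax = arma::norm(step, "inf");
    if (smax > 10.0) step *= 10.0 / smax;
    double s = 1.0;
    double fnew = f;
    arma::vec unew = u;
    for (int h = 0; h < 40; ++h) {
      unew = u + s * step;
      fnew = joint_logdens(W, y, prec, unew, offset, &loglik);
      if (std::isfinite(fnew) && fnew >= f - 1e-14) break;
      s *= 0.5;
    }
    double improve = fnew - f;
    u = unew;
    f = fnew;
    trace[iter] = f;
    if (std::fabs(improve) < tol &&
        arma::norm(grad, "inf") < 1e-3 * std::max(1.0, std::fabs(f))) {
      converged = true;
      ++iter;
      break;
    }
  }
  // recompute H at the final iterate
  {
    arma::vec eta = W * u + offset;
    arma::vec p = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec w = p % (1.0 - p);
    w.transform([](double v) { return v < 1e-10 ? 1e-10 : v; });
    H = W.t() * (W.each_col() % w);
    H.diag() += prec;
  }
  f = joint_logdens(W, y, prec, u, offset, &loglik);
  double logdet_val, logdet_sign;
  arma::log_det(logdet_val, logdet_sign, H);

  return List::create(
    _["u"] = u, _["H"] = H, _["logdet"] = logdet_val,
    _["logjoint"] = f, _["loglik"] = loglik,
    _["converged"] = converged, _["niter"] = iter,
    _["trace"] = trace[Range(0, std::max(iter - 1, 0))]);
}

// Bernoulli deviance -2 * loglik at given latent values, probabilities
// clamped to [1e-12, 1 - 1e-12]; returns deviance and whether clamping fired.
// [[Rcpp::export(name = ".cpp_deviance")]]
List cpp_deviance(const arma::mat& W, const arma::vec& y, const arma::vec& u) {
  arma::vec eta = W * u;
  bool clamped = false;
  double ll = 0.0;
  for (arma::uword i = 0; i < eta.n_elem; ++i) {
    double p = 1.0 / (1.0 + std::exp(-eta[i]));
    if (p < 1e-12) { p = 1e-12; clamped = true; }
    if (p > 1.0 - 1e-12) { p = 1.0 - 1e-12; clamped = true; }
    ll += y[i] * std::log(p) + (1.0 - y[i]) * std::log1p(-p);
  }
  return List::create(_["deviance"] = -2.0 * ll, _["clamped"] = clamped);
}
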