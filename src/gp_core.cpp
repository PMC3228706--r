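// Core numerics for ARD squared-exponential Gaussian processes:
// exact regression, Laplace-approximate logistic classification, and
// approximate entropy. Kept in C++ so full-cohort fits stay interactive.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// squared-distance matrix along one column
static mat sqdist1(const vec& a, const vec& b) {
  mat D(a.n_elem, b.n_elem);
  for (uword j = 0; j < b.n_elem; ++j) D.col(j) = square(a - b(j));
  return D;
}

static mat kernel_se_ard(const mat& X1, const mat& X2,
                         const vec& ell, double sf2) {
  mat S(X1.n_rows, X2.n_rows, fill::zeros);
  for (uword j = 0; j < X1.n_cols; ++j)
    S += sqdist1(X1.col(j), X2.col(j)) / (ell(j) * ell(j));
  return sf2 * exp(-0.5 * S);
}

// [[Rcpp::export]]
arma::mat cpp_kernel_se_ard(const arma::mat& X1, const arma::mat& X2,
                            const arma::vec& log_ell, double log_sf2) {
  return kernel_se_ard(X1, X2, exp(log_ell), std::exp(log_sf2));
}

// Negative log marginal likelihood and gradient for exact GP regression.
// theta = c(log_ell[1..d], log_sf2, log_sn2).
// [[Rcpp::export]]
Rcpp::List cpp_gp_reg_nlml(const arma::mat& X, const arma::vec& y,
                           const arma::vec& theta, double jitter) {
  const uword n = X.n_rows, d = X.n_cols;
  vec ell = exp(theta.subvec(0, d - 1));
  double sf2 = std::exp(theta(d)), sn2 = std::exp(theta(d + 1));

  mat K = kernel_se_ard(X, X, ell, sf2);
  mat Ky = K;
  Ky.diag() += sn2 + jitter;

  mat L;
  if (!chol(L, Ky, "lower"))
    return Rcpp::List::create(Rcpp::Named("ok") = false);

  vec alpha = solve(trimatu(L.t()), solve(trimatl(L), y));
  double nlml = 0.5 * dot(y, alpha) + accu(log(L.diag()))
    + 0.5 * n * std::log(2.0 * M_PI);

  mat Linv = inv(trimatl(L));
  mat A = alpha * alpha.t() - Linv.t() * Linv;  // alpha alpha' - Ky^{-1}

  vec grad(d + 2);
  for (uword j = 0; j < d; ++j) {
    // dK/dlog ell_j = K o D_j / ell_j^2
    mat dK = K % sqdist1(X.col(j), X.col(j)) / (ell(j) * ell(j));
    grad(j) = -0.5 * accu(A % dK);
  }
  grad(d) = -0.5 * accu(A % K);          // dK/dlog sf2 = K
  grad(d + 1) = -0.5 * sn2 * trace(A);   // dK/dlog sn2 = sn2 I

  return Rcpp::List::create(
    Rcpp::Named("ok") = true,
    Rcpp::Named("nlml") = nlml,
    Rcpp::Named("grad") = grad);
}

static double loglik_logistic(const vec& f, const vec& t) {
  // sum_i log sigma(z_i), z = (2t-1) f, stable form
  vec z = (2.0 * t - 1.0) % f;
  vec out(z.n_elem);
  for (uword i = 0; i < z.n_elem; ++i)
    out(i) = z(i) > 0 ? -std::log1p(std::exp(-z(i)))
                      : z(i) - std::log1p(std::exp(z(i)));
  return accu(out);
}

// Laplace approximation for binary GP classification with logistic link.
// t in {0,1}; theta = c(log_ell[1..d], log_sf2). Newton iterations to the
// posterior mode, then the approximate marginal likelihood and its gradient.
// [[Rcpp::export]]
Rcpp::List cpp_gp_cls_nlml(const arma::mat& X, const arma::vec& t,
                           const arma::vec& theta, const arma::vec& f_init,
                           int maxit, double tol, double jitter,
                           bool want_grad) {
  const uword n = X.n_rows, d = X.n_cols;
  vec ell = exp(theta.subvec(0, d - 1));
  double sf2 = std::exp(theta(d));

  mat K = kernel_se_ard(X, X, ell, sf2);
  K.diag() += jitter;

  vec f = (f_init.n_elem == n) ? f_init : vec(n, fill::zeros);
  vec a(n, fill::zeros), pi_, W, sW, b;
  mat L, B;
  double psi_old = -datum::inf;
  bool ok = true;

  // psi(f) = -0.5 a'f + log p(t|f), with a = K^{-1} f maintained implicitly
  auto psi_of = [&](const vec& avec, const vec& fvec) {
    return -0.5 * dot(avec, fvec) + loglik_logistic(fvec, t);
  };

  int it = 0;
  for (; it < maxit; ++it) {
    pi_ = 1.0 / (1.0 + exp(-f));
    W = pi_ % (1.0 - pi_);
    sW = sqrt(W);
    B = sW * sW.t() % K;
    B.diag() += 1.0;
    if (!chol(L, B, "lower")) { ok = false; break; }
    b = W % f + (t - pi_);
    vec c = solve(trimatl(L), sW % (K * b));
    vec a_new = b - sW % solve(trimatu(L.t()), c);
    vec f_new = K * a_new;
    double psi_new = psi_of(a_new, f_new);
    // step-halving toward the previous iterate if Newton overshoots
    int half = 0;
    while (psi_new < psi_old && half < 20) {
      a_new = 0.5 * (a_new + a);
      f_new = K * a_new;
      psi_new = psi_of(a_new, f_new);
      ++half;
    }
    double delta = std::abs(psi_new - psi_old);
    a = a_new; f = f_new; psi_old = psi_new;
    if (delta < tol) { ++it; break; }
  }
  if (!ok) return Rcpp::List::create(Rcpp::Named("ok") = false);

  // final state at the mode
  pi_ = 1.0 / (1.0 + exp(-f));
  W = pi_ % (1.0 - pi_);
  sW = sqrt(W);
  B = sW * sW.t() % K;
  B.diag() += 1.0;
  if (!chol(L, B, "lower"))
    return Rcpp::List::create(Rcpp::Named("ok") = false);

  double nlml = 0.5 * dot(a, f) - loglik_logistic(f, t) + accu(log(L.diag()));

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("ok") = true,
    Rcpp::Named("nlml") = nlml,
    Rcpp::Named("f_hat") = f,
    Rcpp::Named("iterations") = it);
  if (!want_grad) return out;

  mat Linv = inv(trimatl(L));
  mat Binv = Linv.t() * Linv;
  mat R = (sW * sW.t()) % Binv;           // (K + W^{-1})^{-1}
  mat C = Linv * (K.each_col() % sW);
  vec d3 = pi_ % (1.0 - pi_) % (2.0 * pi_ - 1.0);  // third log-lik derivative
  vec s2 = 0.5 * (K.diag() - sum(C % C, 0).t()) % d3;
  vec grad_vec = t - pi_;

  vec grad(d + 1);
  for (uword j = 0; j <= d; ++j) {
    mat dK = (j < d) ? mat(K % sqdist1(X.col(j), X.col(j)) / (ell(j) * ell(j)))
                     : K;
    double s1 = 0.5 * dot(a, dK * a) - 0.5 * accu(R % dK);
    vec bv = dK * grad_vec;
    vec s3 = bv - K * (R * bv);
    grad(j) = -(s1 + dot(s2, s3));
  }
  out["grad"] = grad;
  return out;
}

// Approximate entropy (Pincus): phi(m) - phi(m+1) with self-inclusive
// neighbor counts under Chebyshev distance and absolute tolerance r.
// [[Rcpp::export]]
double cpp_apen(const arma::vec& x, int m, double r) {
  const int N = x.n_elem;
  auto phi = [&](int k) {
    const int M = N - k + 1;
    double acc = 0.0;
    for (int i = 0; i < M; ++i) {
      int cnt = 0;
      for (int j = 0; j < M; ++j) {
        bool close = true;
        for (int u = 0; u < k; ++u) {
          if (std::abs(x(i + u) - x(j + u)) > r) { close = false; break; }
        }
        if (close) ++cnt;
      }
      acc += std::log((double) cnt / M);
    }
    return acc / M;
  };
  return phi(m) - phi(m + 1);
}
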