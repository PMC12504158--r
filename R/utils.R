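# Internal numerical helpers. All mixture-weight arithmetic is done on the
# log scale with Cholesky-based log-determinants: at clinical scales the
# covariance entries are ~1e5 and raw determinants overflow double precision.

# Cholesky factor with an informative error naming the offending matrix.
chol_pd <- function(m, what = "matrix") {
  out <- tryCatch(chol(m), error = function(e) NULL)
  if (is.null(out)) {
    stop(sprintf("%s is not positive-definite (Cholesky failed)", what),
         call. = FALSE)
  }
  out
}

is_symmetric <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) &&
    max(abs(m - t(m))) <= tol * max(1, max(abs(m)))
}

# force exact symmetry (guards against drift from repeated solves)
symmetrize <- function(m) (m + t(m)) / 2

log_det_pd <- function(m) 2 * sum(log(diag(chol_pd(m))))

# log multivariate normal density via Cholesky
ldmvnorm <- function(x, mean, cov) {
  L <- chol_pd(cov, "covariance")
  z <- backsolve(L, x - mean, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(z * z)
}

# log multivariate gamma function Gamma_J(a), as a sum of univariate
# log-gamma terms
lmvgamma <- function(J, a) {
  (J * (J - 1) / 4) * log(pi) + sum(lgamma(a + (1 - seq_len(J)) / 2))
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# normalize a vector of log weights to probabilities
softmax <- function(lw) {
  w <- exp(lw - log_sum_exp(lw))
  w / sum(w)
}

# solve(A, b) for symmetric positive-definite A via Cholesky
pd_solve <- function(a, b = diag(nrow(a))) {
  L <- chol_pd(a)
  chol2inv(L) %*% b
}

# draw n iid N(mean, cov) rows
rmvnorm_chol <- function(n, mean, chol_cov) {
  d <- length(mean)
  z <- matrix(stats::rnorm(n * d), n, d) %*% chol_cov
  sweep(z, 2, mean, "+")
}

# inverse-Wishart draw, Gelman parameterization:
# Sigma ~ IW(Psi, nu)  <=>  Sigma^-1 ~ Wishart(Psi^-1, nu)
riwish <- function(scale, dof) {
  w <- matrix(stats::rWishart(1, dof, pd_solve(scale))[, , 1], nrow(scale))
  symmetrize(pd_solve(w))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
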