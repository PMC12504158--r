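# Shared fixtures: the two-visit worked example and random instances.

# informative component of the two-visit prior on the mean
we_sigma_inf <- matrix(c(1, 0.5, 0.5, 1), 2)
we_psi <- matrix(c(20, 10, 10, 20), 2)

we_prior_mvn <- function(weights = c(0.5, 0.5)) {
  inf <- mvn_params(c(5, 5), we_sigma_inf)
  mixture_prior(inf, vague_component(inf, 20), weights = weights)
}

we_prior_niw <- function(weights = c(0.5, 0.5)) {
  inf <- niw_params(c(5, 5), 20, we_psi, 2)
  mixture_prior(inf, vague_component(inf, 20), weights = weights)
}

we_prior_product <- function(weights = c(0.5, 0.5)) {
  inf <- product_params(mvn_params(c(5, 5), we_sigma_inf),
                        iw_params(we_psi, 2))
  mixture_prior(inf, vague_component(inf, 20), weights = weights)
}

we_data_full <- function() {
  summary_stats(c(6, 8), matrix(c(18, 5, 5, 22), 2), 30)
}

we_data_v1 <- function() {
  summary_stats(6, matrix(18, 1, 1), 30)
}

# random PD covariance of dimension d
rand_pd <- function(d) {
  a <- matrix(stats::rnorm(d * d), d)
  crossprod(a) + diag(d) * 0.5
}

# random mvn prior + summary data instance over d = J + K coordinates
rand_instance <- function(J, K) {
  d <- J + K
  list(
    prior = mvn_params(stats::rnorm(d, 0, 2), rand_pd(d)),
    data = summary_stats(stats::rnorm(J), rand_pd(J),
                         sample(5:50, 1)),
    data_cov = rand_pd(J)
  )
}

expect_matrix_equal <- function(object, expected, tol = 1e-8) {
  expect_lt(max(abs(object - expected)), tol)
}
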