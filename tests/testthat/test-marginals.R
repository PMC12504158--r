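we_post_mvn <- function() {
  posterior_mixture(we_prior_mvn(), we_data_full(),
                    data_cov = we_data_full()$cov)
}

test_that("normal-mixture marginals reproduce the worked example summaries", {
  post <- we_post_mvn()
  m1 <- marginal_mean(post, c(1, 0))
  expect_equal(round(mixture_mean(m1), 2), 5.88)
  expect_equal(round(credible_interval(m1), 2), c(4.54, 7.28))
  m2 <- marginal_mean(post, c(0, 1))
  expect_equal(round(mixture_mean(m2), 2), 7.28)
  expect_equal(round(credible_interval(m2), 2), c(5.63, 9.25))

  # partial-data mixture: the unobserved visit
  postp <- posterior_mixture(we_prior_mvn(), we_data_v1(),
                             data_cov = we_data_v1()$cov,
                             part = partition(1, 2))
  mp <- marginal_mean(postp, c(0, 1))
  expect_equal(round(mixture_mean(mp), 2), 5.36)
  expect_equal(round(credible_interval(mp), 2), c(0.32, 10.65))

  # single component: a plain normal marginal
  single <- mixture_prior(list(we_prior_mvn()$components[[1]]), weights = 1)
  ms <- marginal_mean(posterior_mixture(single, we_data_full(),
                                        data_cov = we_data_full()$cov),
                      c(1, 0))
  expect_length(ms$location, 1)
  expect_equal(ms$type, "normal")
})

test_that("t-mixture marginals reproduce the NIW worked example", {
  post <- posterior_mixture(we_prior_niw(), we_data_full())
  m1 <- marginal_mean(post, c(1, 0))
  expect_equal(m1$type, "t")
  expect_equal(m1$df, c(31, 31))
  expect_equal(round(mixture_mean(m1), 2), 5.75)
  expect_equal(round(credible_interval(m1), 2), c(4.38, 7.24))
  m2 <- marginal_mean(post, c(0, 1))
  expect_equal(round(mixture_mean(m2), 2), 7.26)
})

test_that("normal and t marginals agree in the large-dof limit", {
  nu <- 1e5
  lam <- 50
  niw <- niw_params(c(1, 2), lam, (nu - 2 + 1) * we_sigma_inf * lam, nu)
  pr_t <- mixture_prior(niw, vague_component(niw, 10),
                        weights = c(0.5, 0.5))
  m_t <- marginal_mean(structure(list(components = pr_t$components,
                                      weights = pr_t$weights, kind = "niw"),
                                 class = "mixture_posterior"), c(1, 0))
  # matched normal mixture: cov = scale / (lambda * (nu - J + 1))
  mvn1 <- mvn_params(c(1, 2), we_sigma_inf)
  mvn2 <- mvn_params(c(1, 2), 10 * we_sigma_inf)
  m_n <- marginal_mean(mixture_prior(mvn1, mvn2, weights = c(0.5, 0.5)),
                       c(1, 0))
  expect_equal(credible_interval(m_t), credible_interval(m_n),
               tolerance = 1e-3)
})

test_that("equal-tailed intervals invert the mixture CDF", {
  std <- mixture1d("normal", 1, 0, 1)
  expect_equal(round(credible_interval(std), 2), c(-1.96, 1.96))

  # endpoints bracket the requested mass, including Cauchy components
  m <- mixture1d("t", c(0.4, 0.6), c(-1, 2), c(1, 3), df = c(1, 4))
  for (lev in c(0.5, 0.9, 0.99)) {
    ci <- credible_interval(m, lev, tol = 1e-10)
    expect_equal(mixture_cdf(m, ci[1]), (1 - lev) / 2, tolerance = 1e-8)
    expect_equal(mixture_cdf(m, ci[2]), 1 - (1 - lev) / 2,
                 tolerance = 1e-8)
  }
  # CDF is monotone
  q <- seq(-20, 20, length.out = 101)
  expect_true(all(diff(mixture_cdf(m, q)) >= 0))
})

test_that("tail probabilities for treatment comparisons", {
  sym <- mixture1d("normal", c(0.5, 0.5), c(-2, 2), c(1, 1))
  expect_equal(prob_below(sym, 0), 0.5)
  d <- mixture1d("normal", 1, -100, 45)
  expect_equal(prob_below(d, 0), pnorm(100 / 45))
  expect_equal(prob_below(c(-1, -2, 3, -4), 0), 0.75)
})

test_that("mixture difference combines independent arms over component pairs", {
  x <- mixture1d("normal", c(0.3, 0.7), c(1, 2), c(0.5, 1))
  y <- mixture1d("normal", 1, 0.5, 2)
  d <- mixture_difference(x, y)
  expect_equal(d$weights, c(0.3, 0.7))
  expect_equal(d$location, c(0.5, 1.5))
  expect_equal(d$scale, sqrt(c(0.25, 1) + 4))
  expect_equal(mixture_mean(d), mixture_mean(x) - mixture_mean(y))
})

test_that("compositional partial-NIW sampling matches closed forms at K = 0", {
  prior <- we_prior_niw()$components[[1]]
  pp <- update_niw_partial(prior, we_data_full(), partition(2, 2))
  dr <- sample_partial_niw(pp, 4e4, seed = 31)
  expect_equal(ncol(dr$beta), 0)
  m <- marginal_mean(
    structure(list(components = list(update_niw_full(prior, we_data_full())),
                   weights = 1, kind = "niw"), class = "mixture_posterior"),
    c(1, 0))
  expect_equal(mean(dr$alpha[, 1]), m$location, tolerance = 0.01)
  ci <- credible_interval(dr$alpha[, 1])
  expect_equal(ci, credible_interval(m), tolerance = 0.05)
})

test_that("compositional sampler agrees with an importance-sampling oracle", {
  # small-n instance so that importance sampling from the prior is
  # efficient; this checks the whole factorization, including the
  # matrix-normal row/column orientation and the observed-block dof
  psi <- matrix(c(4, 1.5, 1.5, 3), 2)
  lam <- 3; nu <- 5
  pr <- niw_params(c(1, 2), lam, psi, nu)
  xv <- c(0.2, 1.5, 2.3, 0.8, 1.1, 2.9)
  n <- length(xv); xb <- mean(xv); ssd1 <- sum((xv - xb)^2)
  da <- summary_stats(xb, matrix(ssd1 / n, 1, 1), n,
                      sum_sq_dev = matrix(ssd1, 1, 1))
  pp <- update_niw_partial(pr, da, partition(1, 2))
  dr <- sample_partial_niw(pp, 3e5, seed = 9)

  set.seed(13)
  n_is <- 5e5
  w_arr <- stats::rWishart(n_is, nu, solve(psi))
  a <- w_arr[1, 1, ]; b <- w_arr[1, 2, ]; d <- w_arr[2, 2, ]
  dt <- a * d - b * b
  s11 <- d / dt; s12 <- -b / dt; s22 <- a / dt
  l11 <- sqrt(s11); l21 <- s12 / l11; l22 <- sqrt(s22 - l21^2)
  z1 <- stats::rnorm(n_is); z2 <- stats::rnorm(n_is)
  mu1 <- 1 + l11 * z1 / sqrt(lam)
  mu2 <- 2 + (l21 * z1 + l22 * z2) / sqrt(lam)
  ll <- -n / 2 * log(2 * pi * s11) - 0.5 * (ssd1 + n * (xb - mu1)^2) / s11
  w <- exp(ll - max(ll)); w <- w / sum(w)
  expect_gt(1 / sum(w^2), 1e4)  # effective IS sample size
  expect_equal(mean(dr$alpha), sum(w * mu1), tolerance = 0.01)
  expect_equal(mean(dr$beta), sum(w * mu2), tolerance = 0.03)
  expect_equal(mean(dr$beta < 2), sum(w * (mu2 < 2)), tolerance = 0.01)

  # looped (keep_cov) path draws from the same law
  dr2 <- sample_partial_niw(pp, 2e4, seed = 10, keep_cov = TRUE)
  expect_equal(mean(dr2$beta), mean(dr$beta), tolerance = 0.05)
  expect_equal(dim(dr2$A), c(1, 1, 2e4))
  expect_equal(dim(dr2$R), c(1, 1, 2e4))
})

test_that("interval endpoints of sampled marginals tighten at the MC rate", {
  prior <- we_prior_niw()$components[[1]]
  pp <- update_niw_partial(prior, we_data_v1(), partition(1, 2))
  spread <- vapply(c(2e3, 8e3, 32e3), function(n) {
    los <- vapply(1:8, function(s) {
      credible_interval(sample_partial_niw(pp, n, seed = s)$beta[, 1])[1]
    }, numeric(1))
    stats::sd(los)
  }, numeric(1))
  # doubling draws should halve the spread: slope of log(sd) on log(n)
  fit <- stats::lm(log(spread) ~ log(c(2e3, 8e3, 32e3)))
  expect_lt(stats::coef(fit)[2], -0.25)
  expect_gt(stats::coef(fit)[2], -0.85)
})
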