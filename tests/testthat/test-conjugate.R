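test_that("full-dimension normal update matches the worked example", {
  post <- update_mvn_full(we_prior_mvn()$components[[1]], we_data_full(),
                          we_data_full()$cov)
  expect_equal(round(post$mean, 2), c(5.77, 6.72))
  expect_equal(round(post$cov, 2), matrix(c(0.37, 0.14, 0.14, 0.41), 2))

  # empty data returns the prior
  prior <- we_prior_mvn()$components[[1]]
  d0 <- we_data_full(); d0$n <- 0L
  expect_equal(update_mvn_full(prior, d0, d0$cov), prior)

  # flat-prior limit: posterior tends to (xbar, Sigma/n)
  flat <- mvn_params(c(0, 0), 1e8 * diag(2))
  post_flat <- update_mvn_full(flat, we_data_full(), we_data_full()$cov)
  expect_equal(post_flat$mean, c(6, 8), tolerance = 1e-3)
  expect_matrix_equal(post_flat$cov, matrix(c(18, 5, 5, 22), 2) / 30, 1e-3)
})

test_that("posterior covariance shrinks below prior and data information", {
  set.seed(11)
  for (i in 1:5) {
    inst <- rand_instance(3, 0)
    post <- update_mvn_full(inst$prior, inst$data, inst$data_cov)
    eig1 <- eigen(inst$prior$cov - post$cov, symmetric = TRUE)$values
    eig2 <- eigen(inst$data_cov / inst$data$n - post$cov,
                  symmetric = TRUE)$values
    expect_gt(min(eig1), -1e-10)
    expect_gt(min(eig2), -1e-10)
  }
})

test_that("partial normal update matches the worked example and reduces at K = 0", {
  part <- partition(1, 2)
  post <- update_mvn_partial(we_prior_mvn()$components[[1]], we_data_v1(),
                             we_data_v1()$cov, part)
  # exact closed forms (printed as 5.63/5.31 and 0.38/0.19/0.84)
  expect_equal(post$mean, c(5.625, 5.3125), tolerance = 1e-10)
  expect_matrix_equal(post$cov,
                      matrix(c(0.375, 0.1875, 0.1875, 0.84375), 2), 1e-10)
  vag <- update_mvn_partial(we_prior_mvn()$components[[2]], we_data_v1(),
                            we_data_v1()$cov, part)
  expect_equal(round(vag$mean, 2), c(5.97, 5.49))
  expect_equal(round(vag$cov, 2), matrix(c(0.58, 0.29, 0.29, 15.15), 2))

  # K = 0 equals the full update to machine precision, across instances
  set.seed(21)
  for (i in 1:5) {
    inst <- rand_instance(3, 0)
    full <- update_mvn_full(inst$prior, inst$data, inst$data_cov)
    red <- update_mvn_partial(inst$prior, inst$data, inst$data_cov,
                              partition(3, 3))
    expect_matrix_equal(red$cov, full$cov, 1e-12)
    expect_equal(red$mean, full$mean, tolerance = 1e-12)
  }
})

test_that("zero-augmented precision gives the partitioned posterior for any padding", {
  set.seed(31)
  for (i in 1:4) {
    J <- 2; K <- 2
    inst <- rand_instance(J, K)
    part <- partition(J, J + K)
    post <- update_mvn_partial(inst$prior, inst$data, inst$data_cov, part)
    prec_aug <- matrix(0, J + K, J + K)
    prec_aug[1:J, 1:J] <- inst$data$n * solve(inst$data_cov)
    v <- solve(solve(inst$prior$cov) + prec_aug)
    for (pad in c(0, 1, 1e6)) {
      x_aug <- c(inst$data$xbar, rep(pad, K))
      m <- v %*% (solve(inst$prior$cov, inst$prior$mean) + prec_aug %*% x_aug)
      expect_equal(drop(m), post$mean, tolerance = 1e-6)
    }
    expect_matrix_equal(v, post$cov, 1e-6 * max(abs(v)))
  }
})

test_that("diagonal prior covariance leaves unobserved marginals at the prior", {
  prior <- mvn_params(c(5, 5), diag(c(1, 3)))
  post <- update_mvn_partial(prior, we_data_v1(), we_data_v1()$cov,
                             partition(1, 2))
  expect_equal(post$mean[2], 5)
  expect_equal(post$cov[2, 2], 3)
  expect_equal(post$cov[1, 2], 0)
})

test_that("full-dimension NIW update matches its closed form", {
  prior <- we_prior_niw()$components[[1]]
  post <- update_niw_full(prior, we_data_full())
  expect_equal(post$mean, c(5.60, 6.80))
  expect_equal(post$precision_scalar, 50)
  expect_equal(post$dof, 32)
  ssd <- 30 * matrix(c(18, 5, 5, 22), 2)
  expect_matrix_equal(
    post$scale,
    we_psi + ssd + (20 * 30 / 50) * tcrossprod(c(5, 5) - c(6, 8)))
  # marginal t scale matrix as printed (2 d.p.)
  expect_equal(round(post$scale / (50 * 31), 2),
               matrix(c(0.37, 0.13, 0.13, 0.51), 2))

  d0 <- we_data_full(); d0$n <- 0L
  expect_equal(update_niw_full(prior, d0), prior)

  # dogmatic-location limit
  heavy <- niw_params(c(5, 5), 1e12, we_psi, 2)
  expect_equal(update_niw_full(heavy, we_data_full())$mean, c(5, 5),
               tolerance = 1e-9)
})

test_that("partial NIW posterior keeps prior laws for the unobserved block", {
  prior <- we_prior_niw()$components[[1]]
  pp <- update_niw_partial(prior, we_data_v1(), partition(1, 2))
  expect_s3_class(pp, "partial_niw_posterior")
  expect_equal(pp$obs_niw$mean, 5.6)
  expect_equal(pp$obs_niw$precision_scalar, 50)
  # observed-block dof: (nu0 - K) + n
  expect_equal(pp$obs_niw$dof, 31)
  # unobserved block: untouched prior quantities
  expect_equal(pp$schur_prior$dof, 2)
  expect_equal(pp$schur_prior$scale, matrix(15, 1, 1))
  expect_equal(drop(pp$regression_prior), 0.5)
  expect_equal(pp$unobs_precision_scalar, 20)

  # K = 0: observed part equals the full update, unobserved part empty
  pp0 <- update_niw_partial(prior, we_data_full(), partition(2, 2))
  expect_equal(pp0$obs_niw, update_niw_full(prior, we_data_full()))
  expect_equal(length(pp0$unobs_base_mean), 0)

  # J = 0 is rejected: with no data the posterior is the prior
  expect_error(partition(0, 2), "J >= 1")
})

test_that("normal mixture weights match the worked example and the quadrature oracle", {
  w_full <- mixture_weights_mvn(we_prior_mvn(), we_data_full(),
                                we_data_full()$cov)
  expect_equal(round(w_full[1], 2), 0.52)
  w_part <- mixture_weights_mvn(we_prior_mvn(), we_data_v1(),
                                we_data_v1()$cov, partition(1, 2))
  expect_equal(round(w_part[1], 2), 0.73)

  # identical components: likelihood cancels, prior weights returned
  inf <- mvn_params(c(5, 5), we_sigma_inf)
  same <- mixture_prior(inf, inf, weights = c(0.3, 0.7))
  expect_equal(mixture_weights_mvn(same, we_data_full(),
                                   we_data_full()$cov),
               c(0.3, 0.7), tolerance = 1e-12)

  # quadrature oracle: w_c proportional to
  # w0_c * integral phi(xbar; mu, Sigma/n) phi(mu; alpha_c, A_c) dmu
  marg_quad_1d <- function(comp, data) {
    stats::integrate(function(mu) {
      stats::dnorm(data$xbar, mu, sqrt(data$cov[1] / data$n)) *
        stats::dnorm(mu, comp$mean, sqrt(comp$cov[1]))
    }, -Inf, Inf, rel.tol = 1e-10)$value
  }
  set.seed(41)
  for (i in 1:4) {
    inst <- rand_instance(1, 0)
    inf <- inst$prior
    vag <- vague_component(inf, 15)
    pr <- mixture_prior(inf, vag, weights = c(0.4, 0.6))
    w <- mixture_weights_mvn(pr, inst$data, inst$data$cov)
    m1 <- 0.4 * marg_quad_1d(inf, inst$data)
    m2 <- 0.6 * marg_quad_1d(vag, inst$data)
    expect_equal(w[1], m1 / (m1 + m2), tolerance = 1e-5)
  }
})

test_that("normal mixture weights match a 2-D quadrature oracle", {
  skip_if_not_installed("pracma")
  data <- we_data_full()
  marg_quad_2d <- function(comp) {
    s_lik <- data$cov / data$n
    f <- function(x, y) {
      vapply(seq_along(x), function(k) {
        mu <- c(x[k], y[k])
        exp(mvborrow:::ldmvnorm(data$xbar, mu, s_lik) +
              mvborrow:::ldmvnorm(mu, comp$mean, comp$cov))
      }, numeric(1))
    }
    # integrate over the region where the product density has its mass:
    # center and spread from the precision-weighted combination
    v_star <- solve(solve(comp$cov) + solve(s_lik))
    m_star <- v_star %*% (solve(comp$cov, comp$mean) +
                            solve(s_lik, data$xbar))
    hw <- 10 * sqrt(diag(v_star))
    pracma::integral2(Vectorize(function(x, y) f(x, y)),
                      m_star[1] - hw[1], m_star[1] + hw[1],
                      m_star[2] - hw[2], m_star[2] + hw[2],
                      reltol = 1e-11)$Q
  }
  pr <- we_prior_mvn()
  m1 <- 0.5 * marg_quad_2d(pr$components[[1]])
  m2 <- 0.5 * marg_quad_2d(pr$components[[2]])
  w <- mixture_weights_mvn(pr, data, data$cov)
  expect_equal(w[1], m1 / (m1 + m2), tolerance = 1e-5)
})

test_that("NIW mixture weights match the worked example and a Monte Carlo oracle", {
  w <- mixture_weights_niw(we_prior_niw(), we_data_full())
  expect_equal(round(w[1], 2), 0.58)

  inf <- niw_params(c(5, 5), 20, we_psi, 2)
  same <- mixture_prior(inf, inf, weights = c(0.25, 0.75))
  expect_equal(mixture_weights_niw(same, we_data_full()), c(0.25, 0.75),
               tolerance = 1e-12)

  expect_error(
    mixture_weights_niw(we_prior_niw(), we_data_v1(),
                        partition(1, 3)),
    "dimension|J \\+ K")

  # MC oracle, J = 1, K = 0, n = 5: marginal likelihood estimated by
  # averaging the likelihood over prior draws
  x <- c(4.1, 5.9, 5.4, 6.8, 5.0)
  n <- length(x)
  xb <- mean(x)
  ssd1 <- sum((x - xb)^2)
  data <- summary_stats(xb, matrix(ssd1 / n, 1, 1), n,
                        sum_sq_dev = matrix(ssd1, 1, 1))
  p_inf <- niw_params(5, 4, matrix(6, 1, 1), 3)
  p_vag <- vague_component(p_inf, 10)
  pr <- mixture_prior(p_inf, p_vag, weights = c(0.5, 0.5))
  w <- mixture_weights_niw(pr, data)

  mc_ml <- function(comp, n_mc = 1e6) {
    sig <- comp$scale[1] / stats::rchisq(n_mc, comp$dof)
    mu <- stats::rnorm(n_mc, comp$mean, sqrt(sig / comp$precision_scalar))
    ll <- -n / 2 * log(2 * pi * sig) -
      0.5 * (ssd1 + n * (xb - mu)^2) / sig
    lw <- ll - max(ll)
    list(est = mean(exp(lw)), lmax = max(ll),
         se = stats::sd(exp(lw)) / sqrt(n_mc))
  }
  set.seed(99)
  m1 <- mc_ml(p_inf)
  m2 <- mc_ml(p_vag)
  # ratio of marginal likelihoods on a common scale
  r_mc <- (m1$est * exp(m1$lmax)) / (m2$est * exp(m2$lmax))
  w_mc <- r_mc / (1 + r_mc)
  se_w <- w_mc * (1 - w_mc) * sqrt((m1$se / m1$est)^2 + (m2$se / m2$est)^2)
  expect_lt(abs(w[1] - w_mc), 3 * se_w + 1e-6)
})

test_that("posterior_mixture dispatches and honors degenerate weights", {
  post <- posterior_mixture(we_prior_mvn(), we_data_full(),
                            data_cov = we_data_full()$cov)
  expect_equal(round(post$weights[1], 2), 0.52)
  expect_equal(round(post$components[[1]]$mean, 2), c(5.77, 6.72))
  expect_equal(round(post$components[[2]]$mean, 2), c(5.99, 7.89))

  single <- mixture_prior(list(we_prior_mvn()$components[[1]]), weights = 1)
  p1 <- posterior_mixture(single, we_data_full(),
                          data_cov = we_data_full()$cov)
  expect_equal(p1$weights, 1)
  expect_equal(p1$components[[1]],
               update_mvn_full(we_prior_mvn()$components[[1]],
                               we_data_full(), we_data_full()$cov))

  expect_error(posterior_mixture(we_prior_product(), we_data_full()),
               "gibbs_product_mixture")
  expect_error(posterior_mixture(we_prior_mvn(), we_data_full()),
               "data_cov")
})

test_that("mixture weights are proper probabilities", {
  set.seed(51)
  for (i in 1:5) {
    inst <- rand_instance(2, 1)
    inf <- inst$prior
    pr <- mixture_prior(inf, vague_component(inf, 30),
                        weights = c(0.5, 0.5))
    w <- mixture_weights_mvn(pr, inst$data, inst$data_cov, partition(2, 3))
    expect_true(all(w > 0 & w < 1))
    expect_equal(sum(w), 1, tolerance = 1e-12)
  }
})
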