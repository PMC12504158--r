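#' One-dimensional mixture of normal or scaled-t distributions
#'
#' Light container for the marginal law of a linear functional of the mean
#' under a mixture posterior. Component `c` is `N(location_c, scale_c^2)`
#' (`type = "normal"`) or `location_c + scale_c * t(df_c)`
#' (`type = "t"`).
#'
#' @param type `"normal"` or `"t"`.
#' @param weights Component weights summing to 1.
#' @param location,scale Component locations and scales.
#' @param df Component degrees of freedom (t only).
#' @return An object of class `mixture1d`.
#' @export
mixture1d <- function(type = c("normal", "t"), weights, location, scale,
                      df = NULL) {
  type <- match.arg(type)
  stopifnot(length(weights) == length(location),
            length(scale) == length(location), all(scale > 0),
            abs(sum(weights) - 1) < 1e-9)
  if (type == "t") stopifnot(length(df) == length(location), all(df > 0))
  structure(list(type = type, weights = weights, location = location,
                 scale = scale, df = df), class = "mixture1d")
}

#' @export
print.mixture1d <- function(x, ...) {
  cat(sprintf("1-D %s mixture, %d component(s)\n", x$type, length(x$weights)))
  df <- tibble::tibble(weight = x$weights, location = x$location,
                       scale = x$scale)
  if (x$type == "t") df$df <- x$df
  print(df)
  invisible(x)
}

#' Marginal of a linear functional of the mean
#'
#' Projects a mixture posterior (or prior) onto a linear functional
#' `a' mu` of the mean parameters. For multivariate normal mixtures the
#' result is a mixture of normals with means `a' mu_c` and variances
#' `a' Sigma_c a`; for normal-inverse-Wishart mixtures it is a mixture of
#' scaled t distributions with `dof_c - J + 1` degrees of freedom, location
#' `a' mu_c` and squared scale
#' `a' Psi_c a / (lambda_c (dof_c - J + 1))`. Weights carry over.
#'
#' @param post A `mixture_posterior` (kinds `"mvn"` or `"niw"`) or a
#'   [mixture_prior()] of the same families.
#' @param a Numeric coefficient vector over the mean coordinates, e.g. a
#'   visit selector or `c(1, t)` for an intercept-slope projection at time
#'   `t`. Must not be all zero.
#' @return A [mixture1d()].
#' @examples
#' inf <- mvn_params(c(5, 5), matrix(c(1, .5, .5, 1), 2))
#' pr <- mixture_prior(inf, vague_component(inf, 20), weights = c(.5, .5))
#' da <- summary_stats(c(6, 8), matrix(c(18, 5, 5, 22), 2), 30)
#' marginal_mean(posterior_mixture(pr, da, data_cov = da$cov), c(1, 0))
#' @export
marginal_mean <- function(post, a) {
  a <- as.numeric(a)
  if (all(a == 0)) stop("functional coefficients must not be all zero",
                        call. = FALSE)
  if (inherits(post, "mixture_prior")) {
    post <- structure(list(components = post$components,
                           weights = post$weights, kind = post$kind),
                      class = "mixture_posterior")
  }
  stopifnot(inherits(post, "mixture_posterior"))
  comps <- post$components
  if (post$kind == "mvn") {
    stopifnot(length(a) == param_dim(comps[[1]]))
    loc <- vapply(comps, function(c) sum(a * c$mean), numeric(1))
    sc <- vapply(comps, function(c) sqrt(drop(t(a) %*% c$cov %*% a)),
                 numeric(1))
    mixture1d("normal", post$weights, loc, sc)
  } else if (post$kind == "niw") {
    J <- param_dim(comps[[1]])
    stopifnot(length(a) == J)
    df <- vapply(comps, function(c) c$dof - J + 1, numeric(1))
    if (any(df <= 0)) stop("marginal t needs dof - J + 1 > 0", call. = FALSE)
    loc <- vapply(comps, function(c) sum(a * c$mean), numeric(1))
    sc <- vapply(seq_along(comps), function(i) {
      c <- comps[[i]]
      sqrt(drop(t(a) %*% c$scale %*% a) / (c$precision_scalar * df[i]))
    }, numeric(1))
    mixture1d("t", post$weights, loc, sc, df)
  } else {
    stop("partial normal-inverse-Wishart posteriors have no closed-form ",
         "marginal; use sample_partial_niw()", call. = FALSE)
  }
}

#' Mixture CDF, mean and variance
#'
#' @param m A [mixture1d()].
#' @param q Quantile(s).
#' @return `mixture_cdf`: P(X <= q); `mixture_mean`: the mixture mean
#'   (undefined for t components with df <= 1); `mixture_variance`: the
#'   law-of-total-variance mixture variance (df > 2 required for t).
#' @export
mixture_cdf <- function(m, q) {
  stopifnot(inherits(m, "mixture1d"))
  vapply(q, function(qq) {
    z <- (qq - m$location) / m$scale
    p <- if (m$type == "normal") stats::pnorm(z) else stats::pt(z, m$df)
    sum(m$weights * p)
  }, numeric(1))
}

#' @rdname mixture_cdf
#' @export
mixture_mean <- function(m) {
  stopifnot(inherits(m, "mixture1d"))
  if (m$type == "t" && any(m$df <= 1)) {
    stop("mixture mean undefined: a t component has df <= 1", call. = FALSE)
  }
  sum(m$weights * m$location)
}

#' @rdname mixture_cdf
#' @export
mixture_variance <- function(m) {
  stopifnot(inherits(m, "mixture1d"))
  v <- if (m$type == "normal") m$scale^2 else {
    if (any(m$df <= 2)) stop("mixture variance undefined: df <= 2",
                             call. = FALSE)
    m$scale^2 * m$df / (m$df - 2)
  }
  mu <- sum(m$weights * m$location)
  sum(m$weights * (v + m$location^2)) - mu^2
}

#' Equal-tailed credible interval
#'
#' Finds `(lo, hi)` such that the mixture CDF equals `(1 - level)/2` and
#' `1 - (1 - level)/2`, by bracketed root finding on the analytic mixture
#' CDF (normal or t components), or by empirical quantiles when given
#' draws. The initial bracket is the union of component
#' `location +/- 50 scale` ranges, widened by component quantiles so that
#' Cauchy-tailed components (df = 1) are bracketed too.
#'
#' @param x A [mixture1d()] or a numeric vector of posterior draws.
#' @param level Coverage level in (0, 1); default 0.95.
#' @param tol Root-finding tolerance on the probability scale.
#' @param ... Unused.
#' @return Numeric vector `c(lo, hi)`.
#' @export
credible_interval <- function(x, level = 0.95, ...) {
  UseMethod("credible_interval")
}

#' @rdname credible_interval
#' @export
credible_interval.mixture1d <- function(x, level = 0.95, tol = 1e-8, ...) {
  stopifnot(level > 0, level < 1)
  p <- c((1 - level) / 2, 1 - (1 - level) / 2)
  # bracket from component quantiles (handles Cauchy tails)
  qfun <- function(pp) {
    if (x$type == "normal") stats::qnorm(pp, x$location, x$scale)
    else x$location + x$scale * stats::qt(pp, x$df)
  }
  lo0 <- min(x$location - 50 * x$scale, qfun(min(p) / 2))
  hi0 <- max(x$location + 50 * x$scale, qfun(1 - (1 - max(p)) / 2))
  root <- function(pp) {
    stats::uniroot(function(q) mixture_cdf(x, q) - pp,
                   lower = lo0, upper = hi0, tol = tol,
                   extendInt = "upX")$root
  }
  c(root(p[1]), root(p[2]))
}

#' @rdname credible_interval
#' @export
credible_interval.numeric <- function(x, level = 0.95, ...) {
  stopifnot(level > 0, level < 1)
  unname(stats::quantile(x, c((1 - level) / 2, 1 - (1 - level) / 2)))
}

#' Posterior probability below a threshold
#'
#' `P(X < threshold)` for a 1-D mixture marginal or a vector of draws.
#' For a treatment comparison, statistical significance is declared when
#' the posterior probability that the control-minus-active difference is
#' negative reaches 0.975.
#'
#' @param x A [mixture1d()] or numeric draws.
#' @param threshold Threshold; default 0.
#' @return A probability.
#' @export
prob_below <- function(x, threshold = 0) {
  if (inherits(x, "mixture1d")) mixture_cdf(x, threshold)
  else mean(x < threshold)
}

#' Difference of two independent normal-mixture marginals
#'
#' Forms the marginal law of `x - y` for independent 1-D normal mixtures:
#' a mixture over component pairs with means differenced and variances
#' added. Used for the active-minus-control (or control-minus-active)
#' treatment comparison where the two arms are analyzed independently.
#'
#' @param x,y [mixture1d()] objects of type `"normal"`.
#' @return A [mixture1d()] of type `"normal"`.
#' @export
mixture_difference <- function(x, y) {
  stopifnot(inherits(x, "mixture1d"), inherits(y, "mixture1d"),
            x$type == "normal", y$type == "normal")
  grid <- expand.grid(i = seq_along(x$weights), j = seq_along(y$weights))
  mixture1d("normal",
            weights = x$weights[grid$i] * y$weights[grid$j],
            location = x$location[grid$i] - y$location[grid$j],
            scale = sqrt(x$scale[grid$i]^2 + y$scale[grid$j]^2))
}

#' Exact compositional sampling from a partial normal-inverse-Wishart
#' posterior
#'
#' Draws from the non-standard posterior that arises when a
#' normal-inverse-Wishart prior on `J + K` coordinates meets data on the
#' first `J`, by composition along its exact factorization:
#' \enumerate{
#' \item observed-block covariance `A ~ IW(A0', dof_obs)` (the updated
#'   observed-block law),
#' \item observed means `alpha | A ~ N(alpha0', A / lambda0')`,
#' \item Schur complement `S ~ IW(S0, nu0)` with the *prior* scale and
#'   degrees of freedom,
#' \item regression matrix `R | S` matrix-normal centered at `C0 A0^-1`
#'   with row covariance `S` and column covariance `A0^-1`,
#' \item unobserved means
#'   `beta | R, S, alpha ~ N(beta0 + R (alpha - alpha0), S / lambda0)`
#'   with the *prior* precision scalar.
#' }
#'
#' @param post A `partial_niw_posterior` from [update_niw_partial()].
#' @param n_draws Number of draws (`>= 1`).
#' @param seed Integer seed.
#' @param keep_cov Keep the covariance draws (`A`, `S`, `R`) as arrays?
#'   Off by default: without them the observed-block covariance `A` can be
#'   marginalized analytically (`alpha` is multivariate t and `beta` never
#'   conditions on `A`), which permits a vectorized sampler at large
#'   `n_draws`; with them, the full composition is drawn step by step.
#' @return A list with matrices `alpha` (`n_draws x J`) and `beta`
#'   (`n_draws x K`; zero columns when `K = 0`), and when `keep_cov` is
#'   `TRUE` arrays `A` (`J x J x n_draws`), `S` (`K x K x n_draws`) and
#'   `R` (`K x J x n_draws`).
#' @export
sample_partial_niw <- function(post, n_draws, seed = NULL, keep_cov = FALSE) {
  stopifnot(inherits(post, "partial_niw_posterior"), n_draws >= 1)
  if (!is.null(seed)) set.seed(seed)
  obs <- post$obs_niw
  J <- post$part$J; K <- post$part$K
  a0 <- post$prior_obs_scale
  if (isTRUE(keep_cov)) {
    return(sample_partial_niw_looped(post, n_draws))
  }
  # alpha marginal: t with obs dof - J + 1 degrees of freedom
  df_a <- obs$dof - J + 1
  if (df_a <= 0) stop("observed-block dof too small to sample", call. = FALSE)
  lt <- chol_pd(obs$scale / (obs$precision_scalar * df_a))
  z <- matrix(stats::rnorm(n_draws * J), n_draws, J) %*% lt
  g <- sqrt(df_a / stats::rchisq(n_draws, df_a))
  alpha <- sweep(z * g, 2, obs$mean, "+")
  beta <- matrix(0, n_draws, K)
  if (K == 1L) {
    s0 <- post$schur_prior$scale[1, 1]
    s <- s0 / stats::rchisq(n_draws, post$schur_prior$dof)
    la <- chol_pd(pd_solve(a0))           # col cov chol of the regression row
    zr <- matrix(stats::rnorm(n_draws * J), n_draws, J) %*% la
    rmat <- sweep(zr * sqrt(s), 2, drop(post$regression_prior), "+")
    dev <- sweep(alpha, 2, post$unobs_prior_anchor)
    beta[, 1] <- post$unobs_base_mean + rowSums(rmat * dev) +
      stats::rnorm(n_draws) * sqrt(s / post$unobs_precision_scalar)
  } else if (K > 1L) {
    la <- chol_pd(pd_solve(a0))
    for (i in seq_len(n_draws)) {
      s <- riwish(post$schur_prior$scale, post$schur_prior$dof)
      rmat <- post$regression_prior +
        t(chol_pd(s)) %*% matrix(stats::rnorm(K * J), K, J) %*% la
      beta[i, ] <- post$unobs_base_mean +
        drop(rmat %*% (alpha[i, ] - post$unobs_prior_anchor)) +
        drop(t(chol_pd(s / post$unobs_precision_scalar)) %*% stats::rnorm(K))
    }
  }
  list(alpha = alpha, beta = beta)
}

# full step-by-step composition, keeping covariance draws (used by the
# density cross-checks; loops, so intended for moderate n_draws)
sample_partial_niw_looped <- function(post, n_draws) {
  obs <- post$obs_niw
  J <- post$part$J; K <- post$part$K
  a0 <- post$prior_obs_scale
  alpha <- matrix(0, n_draws, J)
  beta <- matrix(0, n_draws, K)
  A_arr <- array(0, c(J, J, n_draws))
  S_arr <- array(0, c(K, K, n_draws))
  R_arr <- array(0, c(K, J, n_draws))
  la <- if (K > 0) chol_pd(pd_solve(a0)) else NULL
  for (i in seq_len(n_draws)) {
    A <- riwish(obs$scale, obs$dof)
    al <- obs$mean +
      drop(t(chol_pd(A / obs$precision_scalar)) %*% stats::rnorm(J))
    alpha[i, ] <- al
    A_arr[, , i] <- A
    if (K > 0) {
      s <- riwish(post$schur_prior$scale, post$schur_prior$dof)
      rmat <- post$regression_prior +
        t(chol_pd(s)) %*% matrix(stats::rnorm(K * J), K, J) %*% la
      beta[i, ] <- post$unobs_base_mean +
        drop(rmat %*% (al - post$unobs_prior_anchor)) +
        drop(t(chol_pd(s / post$unobs_precision_scalar)) %*% stats::rnorm(K))
      S_arr[, , i] <- s
      R_arr[, , i] <- rmat
    }
  }
  list(alpha = alpha, beta = beta, A = A_arr, S = S_arr, R = R_arr)
}

#' Marginal draws of a linear functional under a partial
#' normal-inverse-Wishart mixture posterior
#'
#' Pools component draws of `a' mu` in proportion to the posterior mixture
#' weights (each component sampled by [sample_partial_niw()]).
#'
#' @param post A `mixture_posterior` of kind `"niw_partial"`.
#' @param a Coefficient vector over all `J + K` mean coordinates.
#' @param n_draws Total number of pooled draws.
#' @param seed Integer seed.
#' @return Numeric vector of `n_draws` draws of `a' mu`.
#' @export
sample_marginal_partial_niw <- function(post, a, n_draws = 1e5, seed = NULL) {
  stopifnot(inherits(post, "mixture_posterior"), post$kind == "niw_partial")
  if (!is.null(seed)) set.seed(seed)
  a <- as.numeric(a)
  n_c <- round(post$weights * n_draws)
  n_c[1] <- n_draws - sum(n_c[-1])
  draws <- purrr::map2(post$components, n_c, function(comp, n) {
    if (n == 0) return(numeric(0))
    d <- sample_partial_niw(comp, n)
    mu <- cbind(d$alpha, d$beta)
    drop(mu %*% a)
  })
  unlist(draws)
}
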