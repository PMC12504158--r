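#' Conjugate posterior for a multivariate normal prior, full-dimension data
#'
#' Posterior for the mean of multivariate normal data with known (plug-in)
#' covariance `data_cov` under an [mvn_params()] prior:
#' `cov' = (cov^-1 + n * data_cov^-1)^-1` and
#' `mean' = cov' (cov^-1 mean + n * data_cov^-1 xbar)`.
#'
#' @param prior An [mvn_params()] prior of dimension `J`.
#' @param data A [summary_stats()] object on the same `J` coordinates.
#' @param data_cov Known/plug-in `J x J` covariance matrix of one
#'   observation (often the empirical covariance of the current data).
#' @return An [mvn_params()] posterior.
#' @examples
#' pr <- mvn_params(c(5, 5), matrix(c(1, .5, .5, 1), 2))
#' da <- summary_stats(c(6, 8), matrix(c(18, 5, 5, 22), 2), 30)
#' update_mvn_full(pr, da, da$cov)
#' @export
update_mvn_full <- function(prior, data, data_cov) {
  stopifnot(inherits(prior, "mvn_params"), inherits(data, "summary_data"))
  data_cov <- as.matrix(data_cov)
  J <- param_dim(prior)
  if (data$J != J || nrow(data_cov) != J) {
    stop("prior, data and data_cov dimensions must agree", call. = FALSE)
  }
  if (data$n == 0L) return(prior)
  p0 <- pd_solve(prior$cov)
  pd <- data$n * pd_solve(data_cov)
  v <- symmetrize(pd_solve(p0 + pd))
  mvn_params(drop(v %*% (p0 %*% prior$mean + pd %*% data$xbar)), v)
}

# conformable blocks of a (J+K)-dimensional mvn prior
mvn_blocks <- function(prior, part) {
  J <- part$J
  idx <- seq_len(J)
  list(
    alpha0 = prior$mean[idx],
    beta0 = prior$mean[-idx],
    A0 = prior$cov[idx, idx, drop = FALSE],
    C0 = prior$cov[-idx, idx, drop = FALSE],
    D0 = prior$cov[-idx, -idx, drop = FALSE]
  )
}

#' Partitioned posterior for a multivariate normal prior, reduced-dimension
#' data
#'
#' Posterior over all `J + K` mean coordinates when data are observed only
#' at the first `J`. The observed block gets the usual conjugate update;
#' the unobserved block is shifted by the regression-coefficient matrix
#' `C0 A0^-1` applied to the prior-to-posterior change of the observed
#' means, with covariance `S0 + C0 A0^-1 A0' (C0 A0^-1)^T` where `S0` is
#' the Schur complement of the observed block in the prior covariance.
#' Equivalently, the data precision can be zero-augmented to `J + K`
#' dimensions and the full-dimension update applied; the two constructions
#' agree for any padding of the data mean.
#'
#' @param prior An [mvn_params()] prior of dimension `J + K`.
#' @param data A [summary_stats()] object on the first `J` coordinates.
#' @param data_cov Known/plug-in `J x J` covariance of one observation.
#' @param part A [partition()] with `J` observed coordinates; `K = 0`
#'   reduces exactly to [update_mvn_full()].
#' @return An [mvn_params()] posterior of dimension `J + K`.
#' @export
update_mvn_partial <- function(prior, data, data_cov, part) {
  stopifnot(inherits(prior, "mvn_params"), inherits(part, "partition"))
  if (param_dim(prior) != part$J + part$K) {
    stop("prior dimension must equal J + K", call. = FALSE)
  }
  if (data$J != part$J) stop("data dimension must equal J", call. = FALSE)
  if (part$K == 0L) return(update_mvn_full(prior, data, data_cov))
  b <- mvn_blocks(prior, part)
  obs_post <- update_mvn_full(mvn_params(b$alpha0, b$A0), data, data_cov)
  reg <- b$C0 %*% pd_solve(b$A0)          # regression coefficients C0 A0^-1
  s0 <- b$D0 - reg %*% t(b$C0)            # Schur complement of A0
  a0p <- obs_post$cov
  mean_post <- c(obs_post$mean, b$beta0 + drop(reg %*% (obs_post$mean - b$alpha0)))
  cross <- reg %*% a0p
  cov_post <- rbind(cbind(a0p, t(cross)),
                    cbind(cross, s0 + cross %*% t(reg)))
  mvn_params(mean_post, symmetrize(cov_post))
}

#' Conjugate posterior for a normal-inverse-Wishart prior, full-dimension
#' data
#'
#' Standard conjugate update of the four hyperparameters:
#' `mean' = (lambda * mean + n * xbar) / (lambda + n)`,
#' `scale' = scale + sum_sq_dev + (lambda n / (lambda + n)) (mean - xbar)(mean - xbar)^T`,
#' `lambda' = lambda + n`, `dof' = dof + n`.
#'
#' @param prior An [niw_params()] prior of dimension `J`.
#' @param data A [summary_stats()] object on the same coordinates (its
#'   `sum_sq_dev` is consumed).
#' @return An [niw_params()] posterior.
#' @export
update_niw_full <- function(prior, data) {
  stopifnot(inherits(prior, "niw_params"), inherits(data, "summary_data"))
  if (param_dim(prior) != data$J) {
    stop("prior and data dimensions must agree", call. = FALSE)
  }
  if (data$n == 0L) return(prior)
  n <- data$n
  lam <- prior$precision_scalar
  d <- prior$mean - data$xbar
  niw_params(
    mean = (lam * prior$mean + n * data$xbar) / (lam + n),
    precision_scalar = lam + n,
    scale = prior$scale + data$sum_sq_dev + (lam * n / (lam + n)) * tcrossprod(d),
    dof = prior$dof + n
  )
}

niw_blocks <- function(prior, part) {
  J <- part$J
  idx <- seq_len(J)
  list(
    alpha0 = prior$mean[idx],
    beta0 = prior$mean[-idx],
    A0 = prior$scale[idx, idx, drop = FALSE],
    C0 = prior$scale[-idx, idx, drop = FALSE],
    D0 = prior$scale[-idx, -idx, drop = FALSE]
  )
}

#' Partitioned posterior for a normal-inverse-Wishart prior,
#' reduced-dimension data
#'
#' When a `J + K`-dimensional normal-inverse-Wishart prior meets data on
#' the first `J` coordinates, the posterior is not itself
#' normal-inverse-Wishart. It factorizes into (a) a normal-inverse-Wishart
#' law with fully updated hyperparameters on the observed block, and (b)
#' laws for the unobserved block that keep the *prior* degrees of freedom,
#' Schur-complement scale and precision scalar: the Schur complement
#' `S = D - C A^-1 B` of the covariance retains its prior inverse-Wishart
#' law, the regression matrix `C A^-1` is matrix-normal around its prior
#' value `C0 A0^-1` (row covariance `S`, column covariance `A0^-1`), and
#' the unobserved means are shifted through the sampled regression matrix.
#' With prior degrees of freedom small enough for Cauchy tails, those tails
#' persist in the posterior at unobserved visits.
#'
#' @param prior An [niw_params()] prior of dimension `J + K`.
#' @param data A [summary_stats()] object on the first `J` coordinates.
#' @param part A [partition()]; with `K = 0` the observed part is the
#'   [update_niw_full()] posterior and the unobserved part is empty.
#' @return An object of class `partial_niw_posterior` with fields
#'   `obs_niw` (updated [niw_params()] on the observed block),
#'   `unobs_base_mean` (`beta0`), `unobs_prior_anchor` (`alpha0`),
#'   `regression_prior` (`C0 A0^-1`), `schur_prior` ([iw_params()] with the
#'   prior `S0` and `dof`), `unobs_precision_scalar` (prior `lambda`),
#'   `prior_obs_scale` (the prior observed block `A0`, whose inverse is the
#'   matrix-normal column covariance) and `part`. The observed-block
#'   `obs_niw` carries dof `dof - K + n`, the natural degrees of freedom of
#'   the `J`-dimensional observed-block law.
#' @seealso [sample_partial_niw()] for exact compositional sampling.
#' @export
update_niw_partial <- function(prior, data, part) {
  stopifnot(inherits(prior, "niw_params"), inherits(part, "partition"))
  if (param_dim(prior) != part$J + part$K) {
    stop("prior dimension must equal J + K", call. = FALSE)
  }
  if (data$J != part$J) stop("data dimension must equal J", call. = FALSE)
  b <- niw_blocks(prior, part)
  # the J x J block of an inverse-Wishart(Psi0, nu0) matrix is marginally
  # inverse-Wishart(A0, nu0 - K): the observed block behaves exactly like a
  # J-dimensional NIW prior with dof nu0 - K, updated conjugately
  obs_prior <- niw_params(b$alpha0, prior$precision_scalar, b$A0,
                          prior$dof - part$K)
  obs_niw <- update_niw_full(obs_prior, data)
  if (part$K > 0L) {
    reg <- b$C0 %*% pd_solve(b$A0)
    s0 <- symmetrize(b$D0 - reg %*% t(b$C0))
    schur <- iw_params(s0, prior$dof)
  } else {
    reg <- matrix(0, 0, part$J)
    schur <- NULL
  }
  structure(
    list(obs_niw = obs_niw, unobs_base_mean = b$beta0,
         unobs_prior_anchor = b$alpha0, regression_prior = reg,
         schur_prior = schur, unobs_precision_scalar = prior$precision_scalar,
         prior_obs_scale = b$A0, part = part),
    class = "partial_niw_posterior"
  )
}

#' Posterior mixture weights for a mixture of multivariate normal priors
#'
#' The weight on component `c` is proportional to
#' `w_c * phi(xbar; alpha_c, A_c + data_cov / n)` where `alpha_c`, `A_c`
#' are the observed-block mean and covariance of the component. Computed in
#' log space with Cholesky log-determinants and normalized by log-sum-exp.
#'
#' @param prior A [mixture_prior()] of [mvn_params()] components of
#'   dimension `J + K`.
#' @param data A [summary_stats()] object on the first `J` coordinates.
#' @param data_cov Known/plug-in `J x J` covariance of one observation.
#' @param part A [partition()]; defaults to fully observed.
#' @return Numeric vector of posterior weights (sums to 1, informative
#'   first).
#' @export
mixture_weights_mvn <- function(prior, data, data_cov,
                                part = partition(data$J, param_dim(prior))) {
  stopifnot(inherits(prior, "mixture_prior"), prior$kind == "mvn")
  if (part$J + part$K != param_dim(prior) || data$J != part$J) {
    stop("prior dimension must equal J + K and data dimension J",
         call. = FALSE)
  }
  data_cov <- as.matrix(data_cov)
  idx <- seq_len(part$J)
  lw <- vapply(seq_along(prior$components), function(i) {
    comp <- prior$components[[i]]
    log(prior$weights[i]) +
      ldmvnorm(data$xbar, comp$mean[idx],
               comp$cov[idx, idx, drop = FALSE] + data_cov / data$n)
  }, numeric(1))
  softmax(lw)
}

# log marginal likelihood of the observed block under one niw component,
# up to terms constant across components
lml_niw <- function(comp, data, part) {
  J <- part$J; K <- part$K
  idx <- seq_len(J)
  nu <- comp$dof
  if (nu - K <= J - 1) {
    stop("component dof minus K must exceed J - 1 for the marginal ",
         "likelihood to exist", call. = FALSE)
  }
  a0 <- comp$scale[idx, idx, drop = FALSE]
  obs_prior <- niw_params(comp$mean[idx], comp$precision_scalar, a0, nu - K)
  up <- update_niw_full(obs_prior, data)
  -(J / 2) * log(up$precision_scalar / comp$precision_scalar) +
    lmvgamma(J, (nu + data$n - K) / 2) - lmvgamma(J, (nu - K) / 2) +
    ((nu - K) / 2) * log_det_pd(a0) -
    ((nu + data$n - K) / 2) * log_det_pd(up$scale)
}

#' Posterior mixture weights for a mixture of normal-inverse-Wishart priors
#'
#' Closed-form marginal-likelihood ratio over the observed `J` coordinates:
#' component `c` receives weight proportional to
#' `w_c (lambda_c'/lambda_c)^(-J/2) *`
#' `Gamma_J((nu_c'-K)/2) / Gamma_J((nu_c-K)/2) *`
#' `|A_c|^((nu_c-K)/2) / |A_c'|^((nu_c'-K)/2)`,
#' with all determinants and multivariate gamma terms on the log scale.
#'
#' @param prior A [mixture_prior()] of [niw_params()] components of
#'   dimension `J + K`; each component needs `dof - K > J - 1`.
#' @inheritParams mixture_weights_mvn
#' @return Numeric vector of posterior weights (sums to 1).
#' @export
mixture_weights_niw <- function(prior, data,
                                part = partition(data$J, param_dim(prior))) {
  stopifnot(inherits(prior, "mixture_prior"), prior$kind == "niw")
  if (part$J + part$K != param_dim(prior) || data$J != part$J) {
    stop("prior dimension must equal J + K and data dimension J",
         call. = FALSE)
  }
  lw <- vapply(seq_along(prior$components), function(i) {
    log(prior$weights[i]) + lml_niw(prior$components[[i]], data, part)
  }, numeric(1))
  softmax(lw)
}

#' Mixture posterior from a robust mixture prior
#'
#' Bayesian analysis with a mixture prior yields a mixture posterior:
#' each component is updated by its conjugate rule and the weights by the
#' marginal likelihood of the observed data under each component.
#' Dispatches on the prior family and on whether the data cover all prior
#' coordinates (`part`).
#'
#' @param prior A [mixture_prior()] of [mvn_params()] or [niw_params()]
#'   components (product mixtures have no closed form; use
#'   [gibbs_product_mixture()]).
#' @param data A [summary_stats()] object on the first `J` coordinates.
#' @param data_cov Known/plug-in `J x J` observation covariance; required
#'   for (and only used by) multivariate normal mixtures.
#' @param part A [partition()]; defaults to fully observed.
#' @return An object of class `mixture_posterior`: a list with `components`
#'   (updated [mvn_params()], [niw_params()] or `partial_niw_posterior`
#'   objects), `weights`, `kind` (`"mvn"`, `"niw"` or `"niw_partial"`) and
#'   `part`.
#' @examples
#' inf <- mvn_params(c(5, 5), matrix(c(1, .5, .5, 1), 2))
#' pr <- mixture_prior(inf, vague_component(inf, 20), weights = c(.5, .5))
#' da <- summary_stats(c(6, 8), matrix(c(18, 5, 5, 22), 2), 30)
#' posterior_mixture(pr, da, data_cov = da$cov)
#' @export
posterior_mixture <- function(prior, data, data_cov = NULL,
                              part = partition(data$J, param_dim(prior))) {
  validate_mixture(prior)
  stopifnot(inherits(data, "summary_data"))
  if (prior$kind == "product") {
    stop("product mixtures have no closed-form posterior; ",
         "use gibbs_product_mixture()", call. = FALSE)
  }
  if (prior$kind == "mvn") {
    if (is.null(data_cov)) {
      stop("data_cov is required for multivariate normal mixtures",
           call. = FALSE)
    }
    w <- mixture_weights_mvn(prior, data, data_cov, part)
    comps <- lapply(prior$components, update_mvn_partial,
                    data = data, data_cov = data_cov, part = part)
    kind <- "mvn"
  } else {
    w <- mixture_weights_niw(prior, data, part)
    if (part$K == 0L) {
      comps <- lapply(prior$components, update_niw_full, data = data)
      kind <- "niw"
    } else {
      comps <- lapply(prior$components, update_niw_partial,
                      data = data, part = part)
      kind <- "niw_partial"
    }
  }
  structure(list(components = comps, weights = w, kind = kind, part = part),
            class = "mixture_posterior")
}

#' @export
print.mixture_posterior <- function(x, ...) {
  cat(sprintf("Mixture posterior (%s), weights: %s\n", x$kind,
              paste(format(x$weights, digits = 4), collapse = ", ")))
  invisible(x)
}
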