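# posterior variance of a' mu under a single mvn prior component
component_posterior_var <- function(component, data, data_cov, part, a) {
  post <- update_mvn_partial(component, data, data_cov, part)
  drop(t(a) %*% post$cov %*% a)
}

#' Effective sample size of the current data at a linear functional
#'
#' In a univariate analysis the data contribute `n` participants of
#' information. When data at `J` visits inform, through the prior
#' correlation structure, the mean at a later unobserved visit, the
#' information reaching that visit is less obvious. It is recovered from
#' the variance ratio of two single-component posteriors with priors of
#' known effective size: the informative prior (worth `n0` historical
#' participants) and the vague prior (worth one representative
#' participant). With `r = Var(a'mu | x, vague) / Var(a'mu | x, informative)`,
#' `(n0 + ESS_data) / (1 + ESS_data) = r`, so
#' `ESS_data = (n0 - r) / (r - 1)`.
#'
#' For a finite positive result `r` must lie strictly between 1 and `n0`;
#' outside that range the algebraic solution is still returned, with a
#' warning (`r = 1` returns `Inf`).
#'
#' Under a known-covariance multivariate normal analysis the result depends
#' only on covariances, not on the observed means, so it is deterministic
#' given the design.
#'
#' @param prior_inf,prior_vag Informative and vague [mvn_params()]
#'   components of dimension `J + K`.
#' @param data A [summary_stats()] object on the first `J` coordinates.
#' @param data_cov Known/plug-in `J x J` observation covariance.
#' @param a Coefficient vector over all `J + K` coordinates (e.g. the
#'   final-visit selector).
#' @param n0 Number of historical participants behind the informative
#'   component.
#' @param part A [partition()]; defaults to fully observed.
#' @return The effective sample size of the data at `a`.
#' @export
ess_data <- function(prior_inf, prior_vag, data, data_cov, a, n0,
                     part = partition(data$J, param_dim(prior_inf))) {
  v_inf <- component_posterior_var(prior_inf, data, data_cov, part, a)
  v_vag <- component_posterior_var(prior_vag, data, data_cov, part, a)
  r <- v_vag / v_inf
  if (r == 1) {
    warning("variance ratio is 1: infinite ESS_data")
    return(Inf)
  }
  ess <- (n0 - r) / (r - 1)
  if (r <= 1 || r >= n0) {
    warning(sprintf(
      "variance ratio %.3f outside (1, n0); returning the algebraic solution",
      r))
  }
  ess
}

#' Effective sample size of a mixture prior at a linear functional
#'
#' Applies the variance-ratio relation a second time, now comparing the
#' vague-only posterior with the full mixture posterior:
#' `(ESS_prior + ESS_data) / (1 + ESS_data) = r'` with
#' `r' = Var(a'mu | x, vague) / Var(a'mu | x, mixture)`, so
#' `ESS_prior = r' (1 + ESS_data) - ESS_data`. The mixture posterior
#' variance is computed exactly by the law of total variance over
#' components. The result equals `n0` when all posterior weight is on the
#' informative component, 1 when it is all on the vague component, and can
#' be negative when conflict makes the mixture posterior wider than the
#' vague-only posterior.
#'
#' @param prior A [mixture_prior()] of [mvn_params()] components
#'   (informative, vague).
#' @inheritParams ess_data
#' @return The effective sample size of the mixture prior at `a`.
#' @export
ess_prior <- function(prior, data, data_cov, a, n0,
                      part = partition(data$J, param_dim(prior))) {
  stopifnot(prior$kind == "mvn", length(prior$components) == 2L)
  essd <- ess_data(prior$components[[1]], prior$components[[2]],
                   data, data_cov, a, n0, part)
  post <- posterior_mixture(prior, data, data_cov, part)
  v_mix <- mixture_variance(marginal_mean(post, a))
  v_vag <- component_posterior_var(prior$components[[2]], data, data_cov,
                                   part, a)
  (v_vag / v_mix) * (1 + essd) - essd
}
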