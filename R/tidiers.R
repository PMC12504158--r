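#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mixture posterior
#'
#' One row per component and mean coordinate, with the component weight,
#' posterior mean and posterior variance (multivariate normal mixtures) or
#' location/scale hyperparameters (normal-inverse-Wishart mixtures).
#'
#' @param x A `mixture_posterior`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mixture_posterior <- function(x, ...) {
  purrr::imap(x$components, function(comp, i) {
    if (x$kind == "mvn") {
      tibble::tibble(component = i, weight = x$weights[i],
                     coordinate = seq_along(comp$mean),
                     mean = comp$mean, variance = diag(comp$cov))
    } else if (x$kind == "niw") {
      J <- param_dim(comp)
      df <- comp$dof - J + 1
      tibble::tibble(component = i, weight = x$weights[i],
                     coordinate = seq_len(J), mean = comp$mean,
                     scale = sqrt(diag(comp$scale) /
                                    (comp$precision_scalar * df)),
                     df = df)
    } else {
      obs <- comp$obs_niw
      tibble::tibble(component = i, weight = x$weights[i],
                     coordinate = seq_len(comp$part$J),
                     mean = obs$mean,
                     scale = sqrt(diag(obs$scale) /
                                    (obs$precision_scalar *
                                       (obs$dof - comp$part$J + 1))),
                     df = obs$dof - comp$part$J + 1)
    }
  }) |> dplyr::bind_rows()
}

#' Glance at a mixture posterior
#'
#' @param x A `mixture_posterior`.
#' @param ... Unused.
#' @return A one-row tibble with the posterior weight on the first
#'   (informative) component, the number of components, the family and the
#'   observed/unobserved partition.
#' @export
glance.mixture_posterior <- function(x, ...) {
  tibble::tibble(
    weight_informative = x$weights[1],
    n_components = length(x$components),
    kind = x$kind,
    observed = if (!is.null(x$part)) x$part$J else NA_integer_,
    unobserved = if (!is.null(x$part)) x$part$K else NA_integer_
  )
}

#' Tidy Gibbs draws
#'
#' Posterior summaries (mean, SD, equal-tailed 95% interval, split R-hat)
#' of each sampled parameter.
#'
#' @param x A `gibbs_draws` tibble from [gibbs_product_mixture()].
#' @param ... Unused.
#' @return A tibble with one row per parameter.
#' @export
tidy.gibbs_draws <- function(x, ...) {
  pars <- grep("^(mu|sigma)_", names(x), value = TRUE)
  rh <- split_rhat(x, pars)
  purrr::map(pars, function(p) {
    v <- x[[p]]
    tibble::tibble(term = p, estimate = mean(v), std.error = stats::sd(v),
                   conf.low = unname(stats::quantile(v, 0.025)),
                   conf.high = unname(stats::quantile(v, 0.975)),
                   rhat = rh[[p]])
  }) |> dplyr::bind_rows()
}

#' Glance at Gibbs draws
#'
#' @param x A `gibbs_draws` tibble.
#' @param ... Unused.
#' @return A one-row tibble with chain count, draws per chain, the
#'   frequency of the informative component indicator and the worst split
#'   R-hat.
#' @export
glance.gibbs_draws <- function(x, ...) {
  tibble::tibble(
    n_chains = dplyr::n_distinct(x$chain),
    n_draws = nrow(x),
    weight_informative = mean(x$z == 1),
    max_rhat = max(split_rhat(x))
  )
}
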