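#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

mixture1d_density <- function(m, x) {
  vapply(x, function(q) {
    z <- (q - m$location) / m$scale
    d <- if (m$type == "normal") stats::dnorm(z) else stats::dt(z, m$df)
    sum(m$weights * d / m$scale)
  }, numeric(1))
}

#' Plot a 1-D mixture marginal
#'
#' Density of the mixture together with its weighted components.
#'
#' @param object A [mixture1d()].
#' @param n Grid size.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mixture1d <- function(object, n = 400, ...) {
  lo <- min(object$location - 6 * object$scale)
  hi <- max(object$location + 6 * object$scale)
  x <- seq(lo, hi, length.out = n)
  comp <- purrr::imap(seq_along(object$weights), function(i, ...) {
    m1 <- mixture1d(object$type, 1, object$location[i], object$scale[i],
                    if (object$type == "t") object$df[i])
    tibble::tibble(x = x, density = object$weights[i] * mixture1d_density(m1, x),
                   curve = sprintf("component %d", i))
  }) |> dplyr::bind_rows()
  df <- dplyr::bind_rows(
    tibble::tibble(x = x, density = mixture1d_density(object, x),
                   curve = "mixture"),
    comp
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$density,
                                   color = .data$curve,
                                   linetype = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "a' mu", y = "density", color = NULL,
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Plot mixture-posterior marginals by coordinate
#'
#' Posterior mixture mean and equal-tailed interval per mean coordinate
#' (visit), for conjugate mixture posteriors.
#'
#' @param object A `mixture_posterior` of kind `"mvn"` or `"niw"`.
#' @param level Interval level.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mixture_posterior <- function(object, level = 0.95, ...) {
  d <- param_dim(object$components[[1]])
  df <- purrr::map(seq_len(d), function(j) {
    marg <- marginal_mean(object, as.numeric(seq_len(d) == j))
    ci <- credible_interval(marg, level)
    tibble::tibble(coordinate = j, mean = mixture_mean(marg),
                   lower = ci[1], upper = ci[2])
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$coordinate, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower,
                                          ymax = .data$upper)) +
    ggplot2::labs(x = "coordinate (visit)", y = "posterior mean") +
    ggplot2::theme_minimal()
}

#' Plot simulation-study metrics
#'
#' Rejection rates with Wilson intervals across scenario rows.
#'
#' @param object A `borrow_metrics` tibble (possibly several rows bound
#'   together).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.borrow_metrics <- function(object, ...) {
  df <- dplyr::mutate(
    object,
    label = sprintf("%s/%s\n%s w=%.2g", .data$trajectory, .data$prior_mean,
                    .data$model, .data$prior_weight))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label,
                                   y = .data$rejection_rate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$rejection_lo,
                                          ymax = .data$rejection_hi)) +
    ggplot2::labs(x = NULL, y = "rejection rate") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
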