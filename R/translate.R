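#' Translate a by-visit prior to an intercept-slope prior
#'
#' Maps a multivariate normal prior on per-visit mean outcomes to the
#' implied bivariate prior on the mean intercept and slope of a linear
#' time trajectory, using the generalized least squares estimator
#' equations with design matrix `X = [1, t]`:
#' mean `(X'WX)^-1 X'W mu` and covariance
#' `(X'WX)^-1 X'W Sigma W X (X'WX)^-1` with weight `W = resid_cov^-1`.
#' The default weight is the by-visit prior covariance itself, the natural
#' GLS choice, under which the covariance expression collapses to
#' `(X' Sigma^-1 X)^-1`.
#'
#' @param mvn An [mvn_params()] prior over `V >= 2` visits.
#' @param times Visit times in years (length `V`); slope units are outcome
#'   per year.
#' @param resid_cov Positive-definite `V x V` weighting covariance;
#'   defaults to `mvn$cov`.
#' @return An [mvn_params()] over (intercept, slope).
#' @examples
#' tt <- seq(0, 2, by = 0.25)
#' pr <- mvn_params(3000 - 100 * tt, fvc_byvisit_cov())
#' byvisit_to_intercept_slope(pr, tt)
#' @export
byvisit_to_intercept_slope <- function(mvn, times, resid_cov = mvn$cov) {
  stopifnot(inherits(mvn, "mvn_params"))
  times <- as.numeric(times)
  v <- param_dim(mvn)
  stopifnot(length(times) == v, v >= 2)
  x <- cbind(1, times)
  if (qr(x)$rank < 2) stop("design matrix [1, t] is rank deficient",
                           call. = FALSE)
  w <- pd_solve(as.matrix(resid_cov))
  xtwx_inv <- pd_solve(symmetrize(t(x) %*% w %*% x))
  h <- xtwx_inv %*% t(x) %*% w                      # GLS hat matrix
  mvn_params(drop(h %*% mvn$mean), symmetrize(h %*% mvn$cov %*% t(h)))
}

#' Project an intercept-slope law to a time point
#'
#' Linear projection `a = (1, t)`: mean `mu_1 + t mu_2`, variance
#' `a' Sigma a`.
#'
#' @param mvn An [mvn_params()] over (intercept, slope).
#' @param t Time in years.
#' @return A univariate [mvn_params()].
#' @export
project_intercept_slope <- function(mvn, t) {
  stopifnot(inherits(mvn, "mvn_params"), param_dim(mvn) == 2L)
  a <- c(1, t)
  mvn_params(sum(a * mvn$mean), drop(t(a) %*% mvn$cov %*% a))
}

#' Reduce by-visit summary data to an intercept-slope summary
#'
#' Computes the generalized least squares estimate of the mean intercept
#' and slope from by-visit mean outcomes,
#' `b = (X'W X)^-1 X'W xbar` with `W` the inverse of the per-participant
#' covariance at the observed visits, and its per-participant estimator
#' covariance `(X' cov^-1 X)^-1` (so the estimator of the mean has
#' covariance `(X' cov^-1 X)^-1 / n`). This is the data-side counterpart
#' of [byvisit_to_intercept_slope()]: after reduction, an intercept-slope
#' prior and the likelihood share dimension 2.
#'
#' @param data A [summary_stats()] object at the observed visits.
#' @param times Observed visit times in years.
#' @param cov Known per-participant covariance at the observed visits;
#'   defaults to `data$cov`.
#' @return A [summary_stats()] object with `xbar` the GLS (intercept,
#'   slope) estimate, `cov` its per-participant covariance and the original
#'   `n`.
#' @export
gls_intercept_slope_data <- function(data, times, cov = data$cov) {
  stopifnot(inherits(data, "summary_data"))
  times <- as.numeric(times)
  stopifnot(length(times) == data$J)
  x <- cbind(1, times)
  w <- pd_solve(as.matrix(cov))
  xtwx_inv <- pd_solve(symmetrize(t(x) %*% w %*% x))
  b <- drop(xtwx_inv %*% t(x) %*% w %*% data$xbar)
  summary_stats(b, symmetrize(xtwx_inv), data$n)
}
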