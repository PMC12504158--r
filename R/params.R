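#' Multivariate normal parameters
#'
#' Container for the mean vector and covariance matrix of a multivariate
#' normal distribution. Used both for priors on a mean parameter vector
#' (e.g. by-visit control means, or an intercept and a slope) and as a data
#' model with a known covariance matrix.
#'
#' @param mean Numeric vector of length `d` (outcome units, e.g. mL).
#' @param cov Symmetric positive-definite `d x d` covariance matrix
#'   (outcome units squared).
#'
#' @return An object of class `mvn_params`.
#' @examples
#' mvn_params(c(5, 5), matrix(c(1, 0.5, 0.5, 1), 2))
#' @export
mvn_params <- function(mean, cov) {
  mean <- as.numeric(mean)
  cov <- as.matrix(cov)
  stopifnot(length(mean) == nrow(cov))
  if (!is_symmetric(cov)) stop("cov must be symmetric", call. = FALSE)
  chol_pd(cov, "cov")
  structure(list(mean = mean, cov = symmetrize(cov)), class = "mvn_params")
}

#' Inverse-Wishart parameters
#'
#' Scale matrix and degrees of freedom of an inverse-Wishart prior on a
#' covariance matrix, in the parameterization where `Sigma ~ IW(scale, dof)`
#' is equivalent to `Sigma^-1 ~ Wishart(scale^-1, dof)`.
#'
#' @param scale Symmetric positive-definite `d x d` scale matrix.
#' @param dof Degrees of freedom; must exceed `d - 1` for a proper density.
#'
#' @return An object of class `iw_params`.
#' @export
iw_params <- function(scale, dof) {
  scale <- as.matrix(scale)
  if (!is_symmetric(scale)) stop("scale must be symmetric", call. = FALSE)
  chol_pd(scale, "scale")
  if (dof <= nrow(scale) - 1) {
    stop("dof must exceed dimension - 1 for a proper inverse-Wishart",
         call. = FALSE)
  }
  structure(list(scale = symmetrize(scale), dof = dof), class = "iw_params")
}

#' Normal-inverse-Wishart parameters
#'
#' The four hyperparameters of a normal-inverse-Wishart joint prior on a
#' mean vector and covariance matrix: location `mean`, precision scalar
#' `precision_scalar` (the prior on the mean given `Sigma` has covariance
#' `Sigma / precision_scalar`), scale matrix `scale` and degrees of freedom
#' `dof`. Marginally the mean is multivariate t with `dof - d + 1` degrees
#' of freedom, location `mean` and scale matrix
#' `scale / (precision_scalar * (dof - d + 1))`.
#'
#' @param mean Location vector of length `d`.
#' @param precision_scalar Positive scalar scaling the covariance of the
#'   conditional normal prior on the mean; interpretable as a prior number
#'   of participants.
#' @inheritParams iw_params
#'
#' @return An object of class `niw_params`.
#' @export
niw_params <- function(mean, precision_scalar, scale, dof) {
  iw <- iw_params(scale, dof)
  mean <- as.numeric(mean)
  stopifnot(length(mean) == nrow(iw$scale))
  if (precision_scalar <= 0) stop("precision_scalar must be > 0", call. = FALSE)
  structure(
    list(mean = mean, precision_scalar = precision_scalar,
         scale = iw$scale, dof = dof),
    class = "niw_params"
  )
}

#' Product of independent normal and inverse-Wishart priors
#'
#' Joint prior on `(mu, Sigma)` given by the product of an unconditional
#' multivariate normal prior on the mean and an inverse-Wishart prior on the
#' covariance. Unlike the normal-inverse-Wishart, mean and covariance are a
#' priori independent; the resulting mixture posterior has no closed form
#' and is characterized by Gibbs sampling (see [gibbs_product_mixture()]).
#'
#' @param mean_part An [mvn_params()] prior on the mean.
#' @param cov_part An [iw_params()] prior on the covariance.
#'
#' @return An object of class `product_params`.
#' @export
product_params <- function(mean_part, cov_part) {
  stopifnot(inherits(mean_part, "mvn_params"), inherits(cov_part, "iw_params"))
  if (length(mean_part$mean) != nrow(cov_part$scale)) {
    stop("mean_part and cov_part dimensions disagree", call. = FALSE)
  }
  structure(list(mean_part = mean_part, cov_part = cov_part),
            class = "product_params")
}

#' Dimension of a parameter object
#' @param x A parameter object.
#' @return Integer dimension of the mean parameter.
#' @export
param_dim <- function(x) UseMethod("param_dim")
#' @export
param_dim.mvn_params <- function(x) length(x$mean)
#' @export
param_dim.iw_params <- function(x) nrow(x$scale)
#' @export
param_dim.niw_params <- function(x) length(x$mean)
#' @export
param_dim.product_params <- function(x) length(x$mean_part$mean)
#' @export
param_dim.mixture_prior <- function(x) param_dim(x$components[[1]])

#' Robust mixture prior
#'
#' A convex combination of prior components of a single family. The
#' canonical robust construction has two components: an informative
#' component summarizing a historical (external) control arm, listed first,
#' and a heavy-tailed vague component that carries the information of a
#' single representative participant, so that the posterior discounts the
#' historical data under prior-current data conflict.
#'
#' @param ... Prior components ([mvn_params()], [niw_params()] or
#'   [product_params()]), informative first; alternatively a single list of
#'   components.
#' @param weights Positive weights summing to 1, informative first.
#'
#' @return An object of class `mixture_prior` with elements `components`,
#'   `weights` and `kind` (`"mvn"`, `"niw"` or `"product"`).
#' @examples
#' inf <- mvn_params(c(5, 5), matrix(c(1, 0.5, 0.5, 1), 2))
#' mixture_prior(inf, vague_component(inf, 20), weights = c(0.5, 0.5))
#' @export
mixture_prior <- function(..., weights) {
  components <- list(...)
  if (length(components) == 1L && !inherits(components[[1]], c("mvn_params", "niw_params", "product_params"))) {
    components <- components[[1]]
  }
  kind <- switch(class(components[[1]])[1],
                 mvn_params = "mvn", niw_params = "niw",
                 product_params = "product",
                 stop("unsupported component type", call. = FALSE))
  out <- structure(
    list(components = components, weights = as.numeric(weights), kind = kind),
    class = "mixture_prior"
  )
  validate_mixture(out)
}

#' Validate a mixture prior
#'
#' Checks the mixture invariants: at least one component, homogeneous
#' component type and dimension, strictly positive weights summing to one
#' (within 1e-12), and positive-definite component covariance/scale
#' matrices. Returns the mixture unchanged when valid.
#'
#' @param prior A [mixture_prior()].
#' @return `prior`, invisibly unchanged, if valid; otherwise an error naming
#'   the offending component.
#' @export
validate_mixture <- function(prior) {
  stopifnot(inherits(prior, "mixture_prior"))
  comps <- prior$components
  if (length(comps) < 1L) stop("mixture needs at least one component", call. = FALSE)
  cls <- vapply(comps, function(c) class(c)[1], character(1))
  if (length(unique(cls)) != 1L) {
    stop("mixture components must all be of the same type; found: ",
         paste(unique(cls), collapse = ", "), call. = FALSE)
  }
  dims <- vapply(comps, param_dim, numeric(1))
  if (length(unique(dims)) != 1L) {
    stop("mixture components must share one dimension", call. = FALSE)
  }
  w <- prior$weights
  if (length(w) != length(comps)) {
    stop("need one weight per component", call. = FALSE)
  }
  if (any(w <= 0)) stop("weights must be strictly positive", call. = FALSE)
  if (abs(sum(w) - 1) > 1e-12) stop("weights must sum to 1", call. = FALSE)
  for (i in seq_along(comps)) {
    m <- switch(cls[1],
                mvn_params = comps[[i]]$cov,
                niw_params = comps[[i]]$scale,
                product_params = comps[[i]]$mean_part$cov)
    ok <- tryCatch({ chol(m); TRUE }, error = function(e) FALSE)
    if (!ok) {
      stop(sprintf("component %d covariance/scale is not positive-definite", i),
           call. = FALSE)
    }
  }
  prior
}

#' Build the vague component of a robust mixture prior
#'
#' Downweights an informative component derived from `n0` historical
#' controls so that the vague component carries the information of a single
#' representative participant: for a multivariate normal component the
#' covariance is inflated to `n0 * cov`; for a normal-inverse-Wishart
#' component the precision scalar is deflated to `precision_scalar / n0`
#' (scale matrix and degrees of freedom are left unchanged).
#'
#' @param informative An [mvn_params()] or [niw_params()] informative
#'   component.
#' @param n0 Number of historical controls behind the informative component
#'   (`n0 >= 1`).
#'
#' @return A component of the same class as `informative`.
#' @examples
#' vague_component(mvn_params(c(5, 5), matrix(c(1, 0.5, 0.5, 1), 2)), 20)
#' @export
vague_component <- function(informative, n0) {
  if (n0 < 1) stop("n0 must be at least 1", call. = FALSE)
  UseMethod("vague_component")
}

#' @export
vague_component.mvn_params <- function(informative, n0) {
  mvn_params(informative$mean, n0 * informative$cov)
}

#' @export
vague_component.niw_params <- function(informative, n0) {
  niw_params(informative$mean, informative$precision_scalar / n0,
             informative$scale, informative$dof)
}

#' @export
vague_component.product_params <- function(informative, n0) {
  product_params(vague_component(informative$mean_part, n0),
                 informative$cov_part)
}

#' @export
print.mvn_params <- function(x, ...) {
  cat("Multivariate normal parameters (d =", length(x$mean), ")\n")
  cat("mean:", format(x$mean, digits = 4), "\n")
  cat("cov:\n"); print(x$cov, digits = 4)
  invisible(x)
}

#' @export
print.niw_params <- function(x, ...) {
  cat("Normal-inverse-Wishart parameters (d =", length(x$mean), ")\n")
  cat("mean:", format(x$mean, digits = 4),
      " precision scalar:", format(x$precision_scalar, digits = 4),
      " dof:", format(x$dof, digits = 4), "\n")
  cat("scale:\n"); print(x$scale, digits = 4)
  invisible(x)
}

#' @export
print.mixture_prior <- function(x, ...) {
  cat(sprintf("Mixture of %d %s component(s), weights: %s\n",
              length(x$components), x$kind,
              paste(format(x$weights, digits = 4), collapse = ", ")))
  invisible(x)
}
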