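#' Summary statistics of a current control arm
#'
#' Bundles the sufficient statistics consumed by the posterior updates: the
#' sample mean vector, the empirical covariance matrix, the sample size and
#' the matrix of summed squared deviations around the mean.
#'
#' The package convention for the empirical covariance is the
#' maximum-likelihood divisor `n`, so `sum_sq_dev = n * cov` when only the
#' covariance is supplied. All functions that compute summaries from
#' participant-level data ([read_participants()], [reconstruct_sample()])
#' follow the same convention, so summary-statistics and participant-level
#' workflows give identical posteriors.
#'
#' @param xbar Observed mean vector of length `J`.
#' @param cov `J x J` empirical covariance matrix (divisor `n`).
#' @param n Sample size (`n >= 1`).
#' @param sum_sq_dev Optional `J x J` matrix of summed squared deviations
#'   `sum_i (x_i - xbar)(x_i - xbar)^T`; defaults to `n * cov`.
#'
#' @return An object of class `summary_data` with fields `xbar`, `cov`,
#'   `n`, `sum_sq_dev` and `J`.
#' @examples
#' summary_stats(c(6, 8), matrix(c(18, 5, 5, 22), 2), 30)
#' @export
summary_stats <- function(xbar, cov, n, sum_sq_dev = NULL) {
  xbar <- as.numeric(xbar)
  cov <- as.matrix(cov)
  stopifnot(length(xbar) == nrow(cov), n >= 1)
  if (!is_symmetric(cov)) stop("cov must be symmetric", call. = FALSE)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    stop("cov must be positive-semidefinite", call. = FALSE)
  }
  if (is.null(sum_sq_dev)) sum_sq_dev <- n * cov
  sum_sq_dev <- as.matrix(sum_sq_dev)
  stopifnot(all(dim(sum_sq_dev) == dim(cov)))
  structure(
    list(xbar = xbar, cov = symmetrize(cov), n = as.integer(n),
         sum_sq_dev = symmetrize(sum_sq_dev), J = length(xbar)),
    class = "summary_data"
  )
}

#' Observed/unobserved partition of the prior dimensions
#'
#' The prior may live on `J + K` coordinates (e.g. nine visits over two
#' years) while current data cover only the first `J` (e.g. the five visits
#' of the randomized year). Observed coordinates are always the leading
#' block; reorder the prior first if data are observed elsewhere.
#'
#' @param observed Number of observed (leading) coordinates, `J >= 1`.
#' @param total Total prior dimension `J + K`.
#' @return An object of class `partition` with fields `J` and `K`.
#' @export
partition <- function(observed, total) {
  observed <- as.integer(observed)
  total <- as.integer(total)
  if (observed < 1L) {
    stop("at least one observed coordinate is required (J >= 1); with no ",
         "data the posterior is the prior", call. = FALSE)
  }
  if (total < observed) stop("total must be >= observed", call. = FALSE)
  structure(list(J = observed, K = total - observed), class = "partition")
}

#' @export
print.summary_data <- function(x, ...) {
  cat(sprintf("Summary data: n = %d, J = %d\n", x$n, x$J))
  cat("xbar:", format(x$xbar, digits = 4), "\n")
  invisible(x)
}

#' Reconstruct a participant-level sample from summary statistics
#'
#' Generates an `n x J` matrix whose empirical mean equals `xbar` and whose
#' empirical covariance (divisor `n`) equals `cov` exactly: a standard
#' normal draw is centered, whitened by the Cholesky factor of its own
#' empirical covariance and recolored to the target moments. Used to feed
#' participant-level samplers from published summary statistics.
#'
#' @inheritParams summary_stats
#' @param seed Integer seed for the underlying draw.
#' @return An `n x J` numeric matrix with exact first two moments.
#' @examples
#' x <- reconstruct_sample(c(6, 8), matrix(c(18, 5, 5, 22), 2), 30, seed = 1)
#' colMeans(x)
#' @export
reconstruct_sample <- function(xbar, cov, n, seed = NULL) {
  xbar <- as.numeric(xbar)
  cov <- as.matrix(cov)
  J <- length(xbar)
  if (n <= J) {
    stop("n must exceed J to match a full-rank covariance exactly",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(stats::rnorm(n * J), n, J)
  z <- sweep(z, 2, colMeans(z))
  sz <- crossprod(z) / n
  # whiten against the draw's own moments, recolor to the target
  x <- z %*% backsolve(chol(sz), diag(J)) %*% chol_pd(cov, "cov")
  sweep(x, 2, xbar, "+")
}

#' Read participant-level repeated-measures data
#'
#' Reads a CSV of participant-level outcomes in wide layout (one row per
#' participant, columns `visit_1 ... visit_d`) or long layout (columns
#' `participant_id`, `visit_index`, `value`) and computes the summary
#' statistics used by the posterior updates (empirical covariance with
#' divisor `n`, exact summed squared deviations).
#'
#' Missing values are allowed only as a complete trailing block of visits
#' (all participants unobserved from some visit onwards), matching the
#' leading-block partition model of the posterior updates; interior
#' missingness is rejected.
#'
#' @param path Path to a CSV file.
#' @param layout `"wide"` or `"long"`.
#' @return A [summary_stats()] object on the observed leading block, with
#'   attribute `"total_visits"` carrying the full visit count.
#' @export
read_participants <- function(path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  df <- utils::read.csv(path, check.names = FALSE)
  if (layout == "long") {
    need <- c("participant_id", "visit_index", "value")
    if (!all(need %in% names(df))) {
      stop("long layout needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    wide <- tidyr::pivot_wider(
      tibble::as_tibble(df),
      id_cols = "participant_id",
      names_from = "visit_index", values_from = "value",
      names_prefix = "visit_", names_sort = TRUE
    )
    m <- as.matrix(dplyr::select(wide, -"participant_id"))
  } else {
    vcols <- grep("^visit_", names(df), value = TRUE)
    if (length(vcols) == 0) {
      stop("wide layout needs columns visit_1, visit_2, ...", call. = FALSE)
    }
    vcols <- vcols[order(as.integer(sub("^visit_", "", vcols)))]
    m <- as.matrix(df[, vcols, drop = FALSE])
  }
  total <- ncol(m)
  col_missing <- unname(colSums(is.na(m)))
  observed <- which(col_missing == 0)
  if (length(observed) == 0 || !identical(observed, seq_along(observed))) {
    stop("missing values must form a complete trailing block of visits; ",
         "interior missingness is not supported - reorder coordinates so ",
         "observed visits lead (see ?partition)", call. = FALSE)
  }
  J <- max(observed)
  if (any(col_missing[seq_len(J)] > 0) ||
      any(col_missing[-seq_len(J)] < nrow(m))) {
    stop("missing values must form a complete trailing block of visits; ",
         "interior missingness is not supported - reorder coordinates so ",
         "observed visits lead (see ?partition)", call. = FALSE)
  }
  obs <- m[, seq_len(J), drop = FALSE]
  n <- nrow(obs)
  xbar <- colMeans(obs)
  ssd <- crossprod(sweep(obs, 2, xbar))
  out <- summary_stats(xbar, ssd / n, n, sum_sq_dev = ssd)
  attr(out, "total_visits") <- total
  out
}
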