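# log inverse-Wishart density (unnormalized terms kept: used only in
# component-indicator ratios where dimensions match)
ldiwish <- function(sigma, scale, dof) {
  J <- nrow(scale)
  (dof / 2) * log_det_pd(scale) - (dof * J / 2) * log(2) - lmvgamma(J, dof / 2) -
    ((dof + J + 1) / 2) * log_det_pd(sigma) -
    0.5 * sum(diag(scale %*% pd_solve(sigma)))
}

#' Gibbs sampler for a mixture of independent normal x inverse-Wishart
#' product priors
#'
#' Characterizes the posterior for a mixture prior whose components place
#' an unconditional multivariate normal prior on the mean and an
#' independent inverse-Wishart prior on the covariance. The posterior has
#' no closed form; a latent component indicator `z` makes every conditional
#' conjugate:
#' \enumerate{
#' \item `z | mu, Sigma` is categorical with probabilities proportional to
#'   `w_c * phi(mu; mean_c, cov_c) * iw(Sigma; scale_c, dof_c)`;
#' \item `mu | Sigma, z` is the conjugate normal update of the component-z
#'   normal prior with the likelihood `xbar ~ N(mu, Sigma / n)`;
#' \item `Sigma | mu, z` is inverse-Wishart with scale
#'   `scale_z + sum_i (x_i - mu)(x_i - mu)^T` and dof `dof_z + n`.
#' }
#' No tuning parameters are involved. All post-burn-in draws are kept
#' (thinning 1).
#'
#' @param prior A [mixture_prior()] of [product_params()] components.
#' @param x Participant-level `n x J` data matrix (`n >= 2`).
#' @param n_iter Iterations per chain (default 5000).
#' @param n_burn Burn-in iterations discarded per chain (default 1000).
#' @param n_chains Number of chains (default 4), each initialized at the
#'   data moments with small jitter.
#' @param seed Integer seed.
#' @return A tibble of class `gibbs_draws` with columns `chain`, `iter`,
#'   `z` (component indicator, 1 = informative), `mu_1 ... mu_J` and the
#'   lower-triangular covariance entries `sigma_i_j`.
#' @examples
#' \donttest{
#' inf <- product_params(mvn_params(c(5, 5), matrix(c(1, .5, .5, 1), 2)),
#'                       iw_params(matrix(c(20, 10, 10, 20), 2), 2))
#' pr <- mixture_prior(inf, vague_component(inf, 20), weights = c(.5, .5))
#' x <- reconstruct_sample(c(6, 8), matrix(c(18, 5, 5, 22), 2), 30, seed = 1)
#' d <- gibbs_product_mixture(pr, x, n_iter = 500, n_burn = 100,
#'                            n_chains = 2, seed = 1)
#' mean(d$mu_1)
#' }
#' @export
gibbs_product_mixture <- function(prior, x, n_iter = 5000, n_burn = 1000,
                                  n_chains = 4, seed = NULL) {
  validate_mixture(prior)
  stopifnot(prior$kind == "product")
  x <- as.matrix(x)
  n <- nrow(x); J <- ncol(x)
  if (n < 2) stop("need at least 2 participants", call. = FALSE)
  if (param_dim(prior) != J) {
    stop("prior and data dimensions must agree", call. = FALSE)
  }
  if (n_iter <= n_burn) stop("n_iter must exceed n_burn", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  xbar <- colMeans(x)
  ssd <- crossprod(sweep(x, 2, xbar))
  comps <- prior$components
  n_comp <- length(comps)
  lw0 <- log(prior$weights)
  prec_mean <- lapply(comps, function(c) pd_solve(c$mean_part$cov))
  keep <- n_iter - n_burn
  lower <- which(lower.tri(diag(J), diag = TRUE), arr.ind = TRUE)
  res <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    mu <- xbar + stats::rnorm(J, 0, sqrt(diag(ssd) / n) / 10)
    sigma <- symmetrize(ssd / n)
    out <- matrix(0, keep, 2 + J + nrow(lower))
    for (it in seq_len(n_iter)) {
      lp <- vapply(seq_len(n_comp), function(c) {
        lw0[c] + ldmvnorm(mu, comps[[c]]$mean_part$mean, comps[[c]]$mean_part$cov) +
          ldiwish(sigma, comps[[c]]$cov_part$scale, comps[[c]]$cov_part$dof)
      }, numeric(1))
      z <- sample.int(n_comp, 1, prob = softmax(lp))
      sig_inv <- pd_solve(sigma)
      v <- symmetrize(pd_solve(prec_mean[[z]] + n * sig_inv))
      m <- v %*% (prec_mean[[z]] %*% comps[[z]]$mean_part$mean +
                    n * sig_inv %*% xbar)
      mu <- drop(m) + drop(t(chol_pd(v)) %*% stats::rnorm(J))
      sc <- ssd + n * tcrossprod(xbar - mu)
      sigma <- riwish(comps[[z]]$cov_part$scale + sc,
                      comps[[z]]$cov_part$dof + n)
      if (it > n_burn) {
        out[it - n_burn, ] <- c(it, z, mu, sigma[lower])
      }
    }
    res[[ch]] <- tibble::as_tibble(
      stats::setNames(as.data.frame(out),
                      c("iter", "z", paste0("mu_", seq_len(J)),
                        paste0("sigma_", lower[, 1], "_", lower[, 2])))
    ) |>
      dplyr::mutate(chain = ch, .before = 1)
  }
  structure(dplyr::bind_rows(res), class = c("gibbs_draws", "tbl_df", "tbl",
                                             "data.frame"))
}

#' Split-chain potential scale reduction factor
#'
#' Rank-free split R-hat: each chain is halved, and the classic
#' between/within variance ratio is computed over the resulting half
#' chains. Values near 1 indicate the chains mix over a common
#' distribution.
#'
#' @param draws A `gibbs_draws` tibble.
#' @param pars Column names to assess; default all `mu_`/`sigma_` columns.
#' @return Named numeric vector of split R-hat values.
#' @export
split_rhat <- function(draws, pars = NULL) {
  stopifnot(inherits(draws, "gibbs_draws") || is.data.frame(draws))
  if (is.null(pars)) {
    pars <- grep("^(mu|sigma)_", names(draws), value = TRUE)
  }
  vapply(pars, function(p) {
    halves <- draws |>
      dplyr::group_by(.data$chain) |>
      dplyr::mutate(half = (dplyr::row_number() - 1) %/%
                      (dplyr::n() / 2)) |>
      dplyr::ungroup() |>
      dplyr::group_by(.data$chain, .data$half) |>
      dplyr::summarise(m = mean(.data[[p]]), v = stats::var(.data[[p]]),
                       n = dplyr::n(), .groups = "drop")
    m <- length(halves$m)
    nn <- mean(halves$n)
    b <- nn * stats::var(halves$m)
    w <- mean(halves$v)
    sqrt(((nn - 1) / nn * w + b / nn) / w)
  }, numeric(1))
}
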