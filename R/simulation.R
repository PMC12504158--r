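#' By-visit FVC covariance of the historical control mean
#'
#' The informative-component covariance matrix for the mean FVC outcome at
#' nine quarterly visits over two years: variance 3380 mL^2 at each visit
#' (a standard error of about 58 mL from 200 historical controls, i.e. a
#' per-participant standard deviation of about 822 mL) with Toeplitz
#' correlations 0.98, 0.97, ..., 0.91 decreasing by 0.01 per lag.
#'
#' @param n_visits Number of visits (default 9).
#' @param variance Per-visit variance of the mean (default 3380).
#' @param lag_step Correlation decrement per lag (default 0.01): the lag-k
#'   correlation is `1 - lag_step * (k + 1)`, i.e. 0.98, 0.97, ... at the
#'   default.
#' @return An `n_visits x n_visits` covariance matrix.
#' @export
fvc_byvisit_cov <- function(n_visits = 9, variance = 3380, lag_step = 0.01) {
  k <- abs(outer(seq_len(n_visits), seq_len(n_visits), "-"))
  corr <- ifelse(k == 0, 1, 1 - lag_step - lag_step * k)
  variance * corr
}

#' Control-arm mean trajectory
#'
#' Mean FVC trajectories used for prior means and simulated current control
#' arms, anchored at 3000 mL at baseline with a treatment effect of
#' `effect_at_2y` mL at two years:
#' \describe{
#' \item{null}{constant 3000 at all visits;}
#' \item{linear}{linear decline reaching `3000 - effect_at_2y` at 2 years
#'   (half the effect at 1 year);}
#' \item{dog_leg}{linear decline reaching `3000 - effect_at_2y` at 1 year,
#'   then constant;}
#' \item{double_dog_leg}{constant over the first third (to 2/3 years),
#'   linear decline over the middle third, constant at
#'   `3000 - effect_at_2y` over the final third.}
#' }
#'
#' @param kind One of `"null"`, `"linear"`, `"dog_leg"`,
#'   `"double_dog_leg"`.
#' @param effect_at_2y Treatment effect in mL at two years (>= 0).
#' @param visit_times Visit times in years.
#' @param baseline Baseline mean (default 3000 mL).
#' @return Mean vector along `visit_times`.
#' @examples
#' control_trajectory("dog_leg", 200)
#' @export
control_trajectory <- function(kind = c("null", "linear", "dog_leg",
                                        "double_dog_leg"),
                               effect_at_2y = 0,
                               visit_times = seq(0, 2, by = 0.25),
                               baseline = 3000) {
  kind <- match.arg(kind)
  stopifnot(effect_at_2y >= 0)
  t <- visit_times
  e <- effect_at_2y
  drop_frac <- switch(kind,
    null = rep(0, length(t)),
    linear = t / 2,
    dog_leg = pmin(t, 1),
    double_dog_leg = pmin(pmax((t - 2 / 3) / (2 / 3), 0), 1)
  )
  baseline - e * drop_frac
}

#' Trial-design scenario for the borrowing simulation study
#'
#' Bundles the design constants of the motivating open-label-extension
#' study: a randomized trial with `n_per_arm = 150` participants per arm,
#' nine quarterly visits over two years of which the control arm is
#' observed for the first five (the randomized year), a historical control
#' arm of `n0 = 200` participants behind the informative prior component,
#' and participant-level covariance `n0 *` [fvc_byvisit_cov()] (so every
#' per-visit standard deviation is about 822 mL). The active arm has mean
#' 3000 mL at every visit in every scenario.
#'
#' @param trajectory_kind Current control trajectory (see
#'   [control_trajectory()]).
#' @param effect_at_2y Treatment effect in mL at two years.
#' @param prior_mean_kind Shape of the (informative = vague) prior means:
#'   `"linear"` (declining 25 mL per visit to 2800) or `"dog_leg"`
#'   (declining to 2800 at one year, then constant). Both use
#'   `effect 200` shapes as in the planning priors.
#' @param analysis_model `"by_visit"` (9-dimensional prior, partial update
#'   over the 5 observed visits) or `"intercept_slope"` (bivariate prior,
#'   GLS-reduced data).
#' @param prior_weight Prior weight on the informative component in
#'   `[0, 1]` (0 and 1 select the fixed vague/informative prior).
#' @param n_per_arm,n0 Current per-arm and historical sample sizes.
#' @param visit_times Visit schedule in years.
#' @param observed_visits Number of leading visits observed on control.
#' @return A list of class `borrow_scenario`.
#' @export
scenario <- function(trajectory_kind = "null", effect_at_2y = 0,
                     prior_mean_kind = c("linear", "dog_leg"),
                     analysis_model = c("by_visit", "intercept_slope"),
                     prior_weight = 0.5, n_per_arm = 150, n0 = 200,
                     visit_times = seq(0, 2, by = 0.25),
                     observed_visits = 5) {
  prior_mean_kind <- match.arg(prior_mean_kind)
  analysis_model <- match.arg(analysis_model)
  stopifnot(prior_weight >= 0, prior_weight <= 1)
  sigma_bv <- fvc_byvisit_cov(length(visit_times))
  structure(list(
    trajectory_kind = trajectory_kind, effect_at_2y = effect_at_2y,
    prior_mean_kind = prior_mean_kind, analysis_model = analysis_model,
    prior_weight = prior_weight, n_per_arm = n_per_arm, n0 = n0,
    visit_times = visit_times, observed_visits = observed_visits,
    sigma_bv = sigma_bv, participant_cov = n0 * sigma_bv,
    control_mean = control_trajectory(trajectory_kind, effect_at_2y,
                                      visit_times),
    active_mean = rep(3000, length(visit_times))
  ), class = "borrow_scenario")
}

#' Simulate one replicate trial
#'
#' Draws `n_per_arm` multivariate normal participants per arm with the
#' scenario covariance: the control arm restricted to the observed leading
#' visits, the active arm over all visits with mean 3000 mL throughout.
#'
#' @param scn A [scenario()].
#' @param seed Optional integer seed for this replicate.
#' @return A list with [summary_stats()] elements `control` (observed
#'   visits) and `active` (all visits).
#' @export
simulate_trial <- function(scn, seed = NULL) {
  stopifnot(inherits(scn, "borrow_scenario"))
  if (!is.null(seed)) set.seed(seed)
  jj <- seq_len(scn$observed_visits)
  lc <- chol_pd(scn$participant_cov[jj, jj, drop = FALSE])
  la <- chol_pd(scn$participant_cov)
  xc <- rmvnorm_chol(scn$n_per_arm, scn$control_mean[jj], lc)
  xa <- rmvnorm_chol(scn$n_per_arm, scn$active_mean, la)
  mk <- function(x) {
    xbar <- colMeans(x)
    ssd <- crossprod(sweep(x, 2, xbar))
    summary_stats(xbar, ssd / nrow(x), nrow(x), sum_sq_dev = ssd)
  }
  list(control = mk(xc), active = mk(xa))
}

# analysis context precomputed once per scenario: prior mixture, known
# covariances, projection functional, deterministic ESS_data
scenario_context <- function(scn) {
  v <- length(scn$visit_times)
  jj <- seq_len(scn$observed_visits)
  t_end <- scn$visit_times[v]
  prior_mu <- control_trajectory(
    switch(scn$prior_mean_kind, linear = "linear", dog_leg = "dog_leg"),
    effect_at_2y = 200, visit_times = scn$visit_times)
  cov5 <- scn$participant_cov[jj, jj, drop = FALSE]
  if (scn$analysis_model == "by_visit") {
    inf <- mvn_params(prior_mu, scn$sigma_bv)
    a <- as.numeric(seq_len(v) == v)
    part <- partition(scn$observed_visits, v)
    data_cov <- cov5
    times <- NULL
  } else {
    inf <- byvisit_to_intercept_slope(mvn_params(prior_mu, scn$sigma_bv),
                                      scn$visit_times)
    a <- c(1, t_end)
    part <- partition(2, 2)
    # per-participant covariance of the GLS (intercept, slope) estimate
    x5 <- cbind(1, scn$visit_times[jj])
    data_cov <- pd_solve(symmetrize(t(x5) %*% pd_solve(cov5) %*% x5))
    times <- scn$visit_times[jj]
  }
  vag <- vague_component(inf, scn$n0)
  w <- scn$prior_weight
  eps <- 1e-12  # weight 0/1 handled as the corresponding fixed prior
  prior <- if (w > eps && w < 1 - eps) {
    mixture_prior(inf, vag, weights = c(w, 1 - w))
  } else if (w >= 1 - eps) {
    mixture_prior(list(inf), weights = 1)
  } else {
    mixture_prior(list(vag), weights = 1)
  }
  active_var <- scn$participant_cov[v, v] / scn$n_per_arm
  essd <- ess_data(inf, vag,
                   data = summary_stats(numeric(part$J),
                                        diag(part$J), scn$n_per_arm),
                   data_cov = data_cov, a = a, n0 = scn$n0, part = part)
  list(prior = prior, inf = inf, vag = vag, a = a, part = part,
       data_cov = data_cov, cov5 = cov5, times = times,
       active_var = active_var, essd = essd, t_end = t_end, v = v)
}

#' Analyze one simulated replicate
#'
#' Runs the borrowing analysis of a single replicate: the control arm is
#' analyzed with the scenario's robust mixture prior under the
#' known-covariance multivariate normal model (partial update over the
#' observed visits for the by-visit model; full update of the GLS-reduced
#' (intercept, slope) summary for the intercept-slope model), the active
#' arm with a flat-limit normal posterior (no borrowing), and the
#' final-visit treatment comparison is evaluated against the one-sided
#' 0.975 significance rule.
#'
#' @param scn A [scenario()].
#' @param trial A replicate from [simulate_trial()].
#' @param ctx Internal precomputed context (recomputed when `NULL`).
#' @return A one-row tibble with the replicate's posterior weight on the
#'   informative component, control-mean estimate and bias at the final
#'   visit, posterior SD, prior ESS, posterior probability that the
#'   control-minus-active difference is negative, and the rejection
#'   indicator.
#' @export
analyze_rep <- function(scn, trial, ctx = NULL) {
  if (is.null(ctx)) ctx <- scenario_context(scn)
  data <- trial$control
  if (scn$analysis_model == "intercept_slope") {
    # GLS-weighted by the known by-visit covariance of the observed year
    data <- gls_intercept_slope_data(data, ctx$times, cov = ctx$cov5)
  }
  post <- posterior_mixture(ctx$prior, data, data_cov = ctx$data_cov,
                            part = ctx$part)
  marg <- marginal_mean(post, ctx$a)
  w_inf <- if (length(post$weights) == 2L) post$weights[1] else
    scn$prior_weight
  m_mix <- mixture_mean(marg)
  v_mix <- mixture_variance(marg)
  # active arm: flat-limit posterior at the final visit
  active_marg <- mixture1d("normal", 1, trial$active$xbar[ctx$v],
                           sqrt(ctx$active_var))
  diff <- mixture_difference(marg, active_marg)   # control - active
  p_below <- prob_below(diff, 0)
  v_vag <- component_posterior_var(ctx$vag, data, ctx$data_cov, ctx$part,
                                   ctx$a)
  ess_pr <- (v_vag / v_mix) * (1 + ctx$essd) - ctx$essd
  tibble::tibble(
    posterior_weight = w_inf,
    control_estimate = m_mix,
    bias = m_mix - scn$control_mean[ctx$v],
    se = sqrt(v_mix),
    ess_prior = ess_pr,
    prob_below_zero = p_below,
    reject = p_below >= 0.975
  )
}

#' Run the operating-characteristics study for one scenario
#'
#' Simulates `reps` replicate trials, analyzes each with [analyze_rep()],
#' and averages the replicate metrics into one row: average posterior
#' weight on the informative component, average control bias at the final
#' visit (mL), average posterior SE (mL), average prior ESS, and the
#' rejection rate (type-I error under null trajectories, power otherwise)
#' with its Wilson 95% interval.
#'
#' @param scn A [scenario()].
#' @param reps Number of replicate trials.
#' @param seed Master seed driving the whole study.
#' @return A one-row tibble of class `borrow_metrics`.
#' @examples
#' \donttest{
#' run_study(scenario("null", analysis_model = "intercept_slope"),
#'           reps = 200, seed = 1)
#' }
#' @export
run_study <- function(scn, reps = 1e4, seed = 1) {
  stopifnot(inherits(scn, "borrow_scenario"), reps >= 1)
  set.seed(seed)
  ctx <- scenario_context(scn)
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    rows[[r]] <- analyze_rep(scn, simulate_trial(scn), ctx)
  }
  per_rep <- dplyr::bind_rows(rows)
  rate <- mean(per_rep$reject)
  wil <- wilson_interval(sum(per_rep$reject), reps)
  out <- tibble::tibble(
    trajectory = scn$trajectory_kind, effect_at_2y = scn$effect_at_2y,
    prior_mean = scn$prior_mean_kind, model = scn$analysis_model,
    prior_weight = scn$prior_weight, reps = reps,
    avg_posterior_weight = mean(per_rep$posterior_weight),
    avg_bias = mean(per_rep$bias),
    avg_se = mean(per_rep$se),
    avg_ess_prior = mean(per_rep$ess_prior),
    ess_data = ctx$essd,
    rejection_rate = rate,
    rejection_lo = wil[1], rejection_hi = wil[2]
  )
  class(out) <- c("borrow_metrics", class(out))
  out
}

wilson_interval <- function(x, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}
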