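# mvborrow

Multivariate Bayesian dynamic borrowing with robust mixture priors, for
repeated-measures normal outcomes and external control arms.

## The problem

Open-label extensions of randomized trials collect long-term data on the
active treatment but not on control: after the randomized phase (say 52
weeks), control participants switch to active treatment, so there is no
concurrent comparator at the long-term visit (say week 104). An external
control arm of `n0` historical participants can supply that comparator —
if it is commensurate with the current trial. Dynamic borrowing makes the
degree of reliance on the historical data a function of how well it
predicts the current control data.

`mvborrow` implements robust mixture priors for *multivariate* normal
data: the prior on the mean outcome vector (e.g. FVC in mL at each visit)
is a two-component mixture of an informative component summarizing the
historical controls and a vague component worth a single representative
participant. Crucially, the prior may cover more visits than the current
data: with a prior over nine visits (two years) and control data at the
first five (one year), the package computes the exact partitioned
posterior, so that the week-104 control mean has a genuine posterior
distribution informed by one year of current data and the prior
correlation structure.

## The model

Data `x_i ~ N(mu, Sigma)`, `i = 1..n`, over `J` observed coordinates.
Priors on `(mu, Sigma)`:

1. known covariance, `mu ~ w_inf N(mu_inf, Sigma_inf) + w_vag N(mu_vag,
   n0 * Sigma_inf)` — closed-form mixture posterior, including for
   reduced-dimension data via the Schur complement and the regression
   matrix `C0 A0^-1`;
2. normal-inverse-Wishart mixture — closed-form, with a structured
   non-NIW posterior when data cover fewer visits than the prior, sampled
   exactly by composition;
3. independent normal x inverse-Wishart products — no closed form,
   characterized by a latent-indicator Gibbs sampler.

Posterior mixture weights are the prior weights reweighted by each
component's marginal likelihood (computed in log space). Effective sample
sizes of the data and of the prior at any linear functional of the mean
follow from posterior variance ratios; by-visit priors translate to
intercept–slope priors by generalized least squares; and a simulation
engine reproduces trial operating characteristics (posterior weight,
bias, SE, prior ESS, type-I error and power).

## Worked example

A two-visit control arm (`n = 30`, observed mean `(6, 8)`, covariance
`[[18, 5], [5, 22]]`) analyzed with an equipoise mixture prior built from
20 historical controls:

```r
library(mvborrow)

inf   <- mvn_params(c(5, 5), matrix(c(1, 0.5, 0.5, 1), 2))
prior <- mixture_prior(inf, vague_component(inf, 20), weights = c(0.5, 0.5))
data  <- summary_stats(c(6, 8), matrix(c(18, 5, 5, 22), 2), n = 30)

post <- posterior_mixture(prior, data, data_cov = data$cov)
post
#> Mixture posterior (mvn), weights: 0.5216, 0.4784

m1 <- marginal_mean(post, c(1, 0))   # visit-1 mean
round(c(mean = mixture_mean(m1), credible_interval(m1)), 2)
#> mean           
#> 5.88 4.54 7.28
```

The posterior puts weight 0.52 on the informative component: the visit-1
data sit comfortably in the historical distribution, so the interval
(4.54, 7.28) is materially narrower than a no-borrowing analysis would
give. If only visit 1 were observed (`partition(1, 2)`), the weight rises
to 0.73 and the *unobserved* visit-2 mean still has a proper posterior,
mean 5.36 with 95% interval (0.32, 10.65), pulled upward from the prior
mean 5 by the observed visit-1 data through the prior correlation.

The same surface drives the trial-design engine:

```r
run_study(scenario("dog_leg", effect_at_2y = 200,
                   prior_mean_kind = "dog_leg",
                   analysis_model = "by_visit"),
          reps = 1e4, seed = 1)
```

which returns one tidy row per scenario with the average posterior
weight, week-104 control bias and SE in mL, average prior ESS, and the
rejection rate (posterior probability ≥ 0.975 that the control-minus-
active week-104 difference is negative) with its Wilson interval.

A thin command-line wrapper lives at `inst/cli/mvborrow.R`
(`analyze`, `simulate`, `ess`, `translate-prior` subcommands) over
packaged YAML configurations in `inst/extdata/`.

## Vignette

`vignettes/dynamic-borrowing.Rmd` documents the model, the partitioned
posteriors, the empirical-covariance divisor convention, the ESS
relations, the GLS prior translation, what the simulation engine does and
does not emulate, and the package's numerical choices.
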