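# edabisect

Hierarchical Bayesian modeling of temporal bisection under ensemble
context.

## The problem

In a temporal-bisection task, an observer hears a probe duration and
judges whether it is closer to a learned *short* or *long* standard. The
resulting psychometric function is summarized by the point of subjective
equality (PSE, the duration judged "long" half the time) and the
just-noticeable difference (JND, the 75%–50% threshold distance).
Empirically both depend on the *distribution* of probe durations the
observer experiences — its spacing, its mean, and its spread — not just on
the two standards. `edabisect` is for researchers in time perception and
computational psychophysics who want to simulate such experiments, fit
psychometric functions, and formally compare accounts of what internal
reference observers use.

## The models

All models share one decision rule. For probe $X$ and bisection reference
$X_{BP}$:

$$\log\frac{p}{1-p} \;=\; \alpha + \beta\left(\frac{X}{X_{BP}} - 1\right),
\qquad y \mid p \sim \text{Bernoulli}(p),$$

a ratio comparison equivalent to subtraction on a log scale (Weber
scaling). Per participant-condition, $\alpha$ and $\beta$ follow Gaussian
hyper-distributions. Five families differ in the reference:

1. **simple** — midpoint (or geometric mean) of the two standards;
2. **spacing** — unweighted mean of all probe durations;
3. **ensemble_mean** — frequency-weighted ensemble mean, fixed;
4. **two_stage** — the ensemble mean with trial-to-trial fluctuation,
   $X_{BP} \sim N(\mu, \sigma)$;
5. **eda** (ensemble-distribution account) — the fluctuating ensemble-mean
   reference *plus* sensitivity scaled by the set's inverse relative
   spread, $\beta \sim N(k\,\mu/\sigma_X,\ \sigma_\beta)$.

Models are fit by MCMC (JAGS) and compared by WAIC and by the Euclidean
distance between model-predicted and observed (PSE, JND) pairs.

## Worked example

Simulate a cohort of ensemble-distribution observers on the two built-in
sets that share a mean (925 ms) but differ in spread (U: 491 ms, IT:
175 ms), then fit and compare two accounts:

```r
library(edabisect)

ensemble_stats(builtin_sets())
#> # A tibble: 6 × 7
#>   set   n_durations block_length    am    gm    sd cv_inv
#>   <chr>       <int>        <int> <dbl> <dbl> <dbl>  <dbl>
#> 1 PS              7           56  888.  800.  401.   2.22
#> 2 NS              7           56 1112  1018.  401.   2.77
#> 3 DF              7           56  800   728.  346.   2.31
#> 4 AF              7           56 1200  1138.  346.   3.46
#> 5 U               8           72  925   781.  491.   1.89
#> 6 IT              8           72  925   906.  175    5.29

sets <- builtin_sets()[c("U", "IT")]
cohort <- simulate_cohort(sets, cohort_hyperparams(),  # k = 3, xbp_sd = 60
                          n_participants = 15, blocks_per_condition = 3,
                          seed = 7, mode = "eda")

specs <- list(
  model_spec("eda", xbp_mode = "marginal", seed = 1,
             adapt = 500, warmup = 1000, draws = 500, thin = 4, rhat_max = Inf),
  model_spec("ensemble_mean", seed = 1,
             adapt = 500, warmup = 1000, draws = 500, thin = 4, rhat_max = Inf)
)
cmp <- compare_models(cohort$trials, specs, sets)
cmp$summary[, c("model", "waic_mean", "mean_distance", "rank")]
#> # A tibble: 2 × 4
#>   model            waic_mean mean_distance  rank
#>   <chr>                <dbl>         <dbl> <int>
#> 1 eda/AM                20.2          19.1     1
#> 2 ensemble_mean/AM      21.0          16.8     2
```

Reading the output: `waic_mean` is the WAIC per participant-condition
cell (lower = better out-of-sample fit; the generating `eda` family wins),
and `mean_distance` is the average Euclidean distance in ms between each
participant's model-predicted and observed (PSE, JND) pair — on a single
cohort the two measures need not agree, which is exactly why both are
reported. Observed
psychometric summaries themselves come from `fit_psychometric(cohort$trials)`,
posterior parameter summaries from `tidy(fit)`, and
`autoplot(cmp)` draws the per-participant prediction-error scatter.

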