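# shared fixtures: small designs and fast MCMC settings used across tests

tiny_set <- function() duration_set(c(400, 800, 1200, 1600), c(3L, 3L, 3L, 3L), "TINY")

# a small cohort for MCMC smoke tests: few observers, one block
tiny_cohort <- function(seed = 42, mode = "ensemble_mean",
                        sets = builtin_sets()["DF"]) {
  simulate_cohort(sets, cohort_hyperparams(xbp_sd = 30),
                  n_participants = 4, blocks_per_condition = 1,
                  seed = seed, mode = mode)
}

# reduced-draw MCMC settings for smoke tests (convergence guard off:
# these runs check mechanics, not inference quality)
fast_spec <- function(family, ...) {
  model_spec(family, chains = 2, adapt = 200, warmup = 300, draws = 200,
             thin = 1, rhat_max = Inf, ...)
}

# run test code under a fixed RNG seed
withr_seed_test <- function(seed, code) {
  set.seed(seed)
  force(code)
}

# brute-force ensemble statistics over the fully expanded per-trial
# duration multiset of one block (independent of the weighted formulas)
expanded_stats <- function(set) {
  x <- rep(set$duration_ms, set$count)
  list(am = mean(x), gm = exp(mean(log(x))),
       sd = sqrt(mean((x - mean(x))^2)))
}
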