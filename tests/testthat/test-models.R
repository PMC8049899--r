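test_that("reference centers follow each family's rule", {
  sets <- builtin_sets()
  # midpoint of the standards, regardless of the interior spacing
  expect_equal(reference_center("simple", sets$DF), 1000)
  expect_equal(reference_center("simple", sets$PS), 1000)
  expect_equal(reference_center("simple", sets$DF, "GM"), sqrt(400 * 1600))
  # unweighted probe mean
  expect_equal(reference_center("spacing", sets$DF), mean(seq(400, 1600, 200)))
  expect_equal(reference_center("spacing", sets$PS, "GM"),
               exp(mean(log(sets$PS$duration_ms))))
  # frequency-weighted ensemble means
  expect_equal(reference_center("ensemble_mean", sets$DF), 800)
  expect_equal(reference_center("two_stage", sets$AF), 1200)
  expect_equal(reference_center("eda", sets$U), 925)
  # weighted geometric mean, checked against an expanded-multiset oracle
  dfgm <- exp(mean(log(rep(sets$DF$duration_ms, sets$DF$count))))
  expect_equal(reference_center("ensemble_mean", sets$DF, "GM"), dfgm, tolerance = 1e-12)
  expect_equal(round(dfgm, 1), 727.6)
  # a model_spec carries its own reference variant
  expect_equal(reference_center(model_spec("ensemble_mean", "GM"), sets$DF), dfgm)
})

test_that("trial log-likelihood matches a brute-force evaluation", {
  expect_equal(trial_loglik(0, 5, 800, 800, 1), log(0.5))
  expect_equal(trial_loglik(0, 5, 800, 800, 0), log(0.5))
  withr_seed_test(17, {
    for (i in 1:20) {
      a <- runif(1, -2, 2); b <- runif(1, 0.5, 30)
      x <- runif(1, 300, 1700); xbp <- runif(1, 500, 1500)
      y <- rbinom(1, 1, 0.5)
      # independent route: evaluate the relation's two outcome
      # probabilities directly from the log-odds
      q <- a + b * (x / xbp - 1)
      oracle <- log(ifelse(y == 1, exp(q) / (1 + exp(q)), 1 / (1 + exp(q))))
      expect_lt(abs(trial_loglik(a, b, xbp, x, y) - oracle), 1e-10)
    }
  })
  # additivity over a block
  a <- 0.4; b <- 12; xbp <- 900
  x <- seq(500, 1500, 100); y <- as.integer(x > 900)
  expect_equal(sum(trial_loglik(a, b, xbp, x, y)),
               log(prod(ifelse(y == 1,
                               response_probability(a, b, x, xbp),
                               1 - response_probability(a, b, x, xbp)))))
  expect_error(trial_loglik(0, 5, -1, 800, 1), "positive")
})

test_that("the log-odds are invariant under common rescaling (Weber scaling)", {
  withr_seed_test(5, {
    for (i in 1:10) {
      a <- runif(1, -1, 1); b <- runif(1, 1, 20)
      x <- runif(5, 400, 1600); xbp <- runif(1, 600, 1400); cc <- runif(1, 0.1, 10)
      expect_equal(response_probability(a, b, x, xbp),
                   response_probability(a, b, cc * x, cc * xbp), tolerance = 1e-12)
    }
  })
})

test_that("the eda prior scales sensitivity by the inverse relative spread", {
  st <- ensemble_stats(builtin_sets()[c("U", "IT")])
  k <- 2.5
  mu_u <- k * st$am[st$set == "U"] / st$sd[st$set == "U"]
  mu_it <- k * st$am[st$set == "IT"] / st$sd[st$set == "IT"]
  # equal means: the hyper-mean ratio is exactly the inverse SD ratio
  expect_equal(mu_it / mu_u, st$sd[st$set == "U"] / st$sd[st$set == "IT"])
})

test_that("Gauss-Hermite quadrature reproduces Gaussian moments", {
  gh <- gauss_hermite(9)
  expect_equal(sum(gh$weights), 1, tolerance = 1e-12)
  mu <- 900; s <- 60
  xq <- mu + sqrt(2) * s * gh$nodes
  expect_equal(sum(gh$weights * xq), mu, tolerance = 1e-9)
  expect_equal(sum(gh$weights * (xq - mu)^2), s^2, tolerance = 1e-6)
  expect_equal(sum(gh$weights * (xq - mu)^4), 3 * s^4, tolerance = 1e-3)
})

test_that("the marginal likelihood nests the fixed-reference model as sigma -> 0", {
  # with vanishing fluctuation the quadrature mixture collapses onto the
  # fixed-center logistic, so the two-stage likelihood converges to the
  # ensemble-mean likelihood
  gh <- gauss_hermite(9)
  a <- 0.3; b <- 11; center <- 800
  x <- seq(400, 1600, 200)
  p_fixed <- response_probability(a, b, x, center)
  for (s in c(10, 1, 1e-3)) {
    p_marg <- colSums(gh$weights * t(sapply(gh$nodes, function(z) {
      response_probability(a, b, x, max(center + sqrt(2) * s * z, 1))
    })))
    if (s == 1e-3) expect_equal(p_marg, p_fixed, tolerance = 1e-8)
  }
  gap10 <- max(abs(colSums(gh$weights * t(sapply(gh$nodes, function(z) {
    response_probability(a, b, x, max(center + sqrt(2) * 10 * z, 1))
  }))) - p_fixed))
  expect_gt(gap10, 1e-8)  # a real fluctuation does change the curve
})

test_that("model fits are reproducible and carry diagnostics and loglik", {
  ch <- tiny_cohort()
  sp <- fast_spec("ensemble_mean", seed = 12)
  f1 <- fit_model(ch$trials, sp, builtin_sets()["DF"])
  f2 <- fit_model(ch$trials, sp, builtin_sets()["DF"])
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$loglik, f2$loglik)
  # one loglik column per participant-duration cell, one row per kept draw
  expect_equal(ncol(f1$loglik), nrow(f1$obs))
  expect_equal(nrow(f1$loglik), 2 * 200)
  expect_true(all(c("mu_alpha", "sigma_alpha", "mu_beta", "sigma_beta")
                  %in% f1$diagnostics$parameter))
  expect_true(all(f1$draws[, "sigma_beta"] > 0))
  # a different seed gives different draws
  f3 <- fit_model(ch$trials, fast_spec("ensemble_mean", seed = 13),
                  builtin_sets()["DF"])
  expect_false(identical(f1$draws, f3$draws))
})

test_that("eda fits expose k instead of mu_beta; latent families expose xbp", {
  ch <- tiny_cohort(mode = "eda")
  fe <- fit_model(ch$trials, fast_spec("eda", seed = 2), builtin_sets()["DF"])
  expect_true("k" %in% colnames(fe$draws))
  expect_false("mu_beta" %in% colnames(fe$draws))
  expect_true("sigma_bp" %in% colnames(fe$draws))
  expect_true("xbp[1]" %in% colnames(fe$draws))
  expect_true(all(fe$draws[, "sigma_bp"] > 0))
  expect_true(all(fe$draws[, grepl("^xbp", colnames(fe$draws))] > 0))
  fm <- fit_model(ch$trials, fast_spec("eda", seed = 2, xbp_mode = "marginal"),
                  builtin_sets()["DF"])
  expect_false(any(grepl("^xbp\\[", colnames(fm$draws))))
  expect_true("sigma_bp" %in% colnames(fm$draws))
})

test_that("unknown conditions and families are rejected", {
  ch <- tiny_cohort()
  expect_error(fit_model(ch$trials, fast_spec("ensemble_mean"), builtin_sets()["U"]),
               "no duration set")
  expect_error(model_spec("range_frequency"))
})

test_that("the convergence guard trips on deliberately short chains", {
  ch <- tiny_cohort(mode = "eda")
  sp <- model_spec("eda", chains = 2, adapt = 30, warmup = 5, draws = 30,
                   thin = 1, seed = 1, rhat_max = 1.000001)
  expect_error(fit_model(ch$trials, sp, builtin_sets()["DF"]), "R-hat")
})

test_that("a two-stage posterior tracks the empirical bisection point", {
  # identical zero-bias observers with a fixed reference and many trials:
  # the latent X_BP must land near the 50% point of the pooled psychometric
  # function (individual latents are partially pooled toward the shared
  # center, so the cohort level is where the consistency is exact)
  set <- builtin_sets()$U
  ch <- simulate_cohort(list(set), cohort_hyperparams(sigma_alpha = 0,
                                                      sigma_beta = 0, xbp_sd = 0),
                        n_participants = 8, blocks_per_condition = 10,
                        seed = 77, mode = "ensemble_mean")
  pooled <- fit_psychometric(ch$trials, pool = TRUE)
  fit <- fit_model(ch$trials, model_spec("two_stage", chains = 2, adapt = 500,
                                         warmup = 1500, draws = 750, thin = 4,
                                         seed = 6, rhat_max = Inf),
                   list(set))
  xbp_hat <- mean(sapply(seq_len(nrow(fit$cells)), function(s) {
    mean(edabisect:::param_draws(fit$draws, "xbp", s))
  }))
  expect_lt(abs(xbp_hat - pooled$pse), 15)
})

test_that("posterior predictions recover PSE and JND structure", {
  ch <- tiny_cohort(seed = 55)
  fit <- fit_model(ch$trials, fast_spec("ensemble_mean", seed = 9),
                   builtin_sets()["DF"])
  pred <- posterior_predict_pse_jnd(fit)
  expect_equal(nrow(pred), nrow(fit$cells))
  expect_true(all(pred$converged))
  expect_true(all(pred$pse > 400 & pred$pse < 1600))
  # predicted probabilities at the posterior mean match a direct evaluation
  s <- 1
  rows <- fit$obs[fit$obs$cell == s, ]
  pbar <- colMeans(edabisect:::cell_prob_draws(fit, s, rows$duration_ms))
  a <- mean(fit$draws[, "alpha[1]"]); b <- mean(fit$draws[, "beta[1]"])
  direct <- response_probability(a, b, rows$duration_ms, 800)
  expect_lt(max(abs(pbar - direct)), 0.05)
})

test_that("steeper sensitivity gives a smaller predicted JND", {
  x <- seq(400, 1600, 200)
  jnd_of <- function(beta) {
    p <- response_probability(0, beta, x, 900)
    fit_cumulative_gaussian(tibble::tibble(duration_ms = x, n_trials = 100,
                                           n_long = 100 * p))$jnd
  }
  jnds <- vapply(c(5, 10, 20), jnd_of, 0)
  expect_true(all(diff(jnds) < 0))
  # with no bias the predicted PSE sits at the reference
  p <- response_probability(0, 10, x, 900)
  f <- fit_cumulative_gaussian(tibble::tibble(duration_ms = x, n_trials = 100,
                                              n_long = 100 * p))
  expect_lt(abs(f$pse - 900), 5)
})

test_that("fits serialize to plain-text draws plus JSON metadata", {
  ch <- tiny_cohort()
  fit <- fit_model(ch$trials, fast_spec("simple", seed = 4), builtin_sets()["DF"])
  d <- file.path(tempdir(), "fitdir")
  write_fit(fit, d)
  expect_true(all(file.exists(file.path(d, c("draws.csv", "loglik.csv", "meta.json")))))
  meta <- jsonlite::read_json(file.path(d, "meta.json"))
  expect_equal(meta$spec$family, "simple")
  expect_equal(meta$spec$seed, 4)
})
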