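#' Model families for the bisection decision models
#'
#' Five hierarchical accounts of where the bisection reference comes from:
#' * `simple` — the reference is the midpoint of the two standards only
#'   (arithmetic midpoint, or their geometric mean in the GM variant);
#' * `spacing` — the unweighted mean of all probe durations;
#' * `ensemble_mean` — the frequency-weighted (ensemble) mean of the
#'   presented distribution, fixed across trials;
#' * `two_stage` — the ensemble mean, but as a latent reference that varies
#'   around it with a fitted scale (partial assimilation);
#' * `eda` — the ensemble-distribution account: the two-stage latent
#'   reference plus decision sensitivity whose hyper-mean scales with the
#'   set's mean-to-spread ratio, `beta ~ N(k * am / sd, sigma_beta)`.
#' @return Character vector of the five family names.
#' @export
model_families <- function() {
  c("simple", "spacing", "ensemble_mean", "two_stage", "eda")
}

#' Specify a bisection decision model
#'
#' @param family One of [model_families()].
#' @param reference `"AM"` (default, the reported variant) or `"GM"`.
#' @param chains,adapt,warmup,draws MCMC settings: number of chains, adaptation
#'   iterations, burn-in iterations, and retained draws per chain.
#' @param thin Thinning interval (`draws` are kept after thinning, so
#'   `draws * thin` sampling iterations are run).
#' @param seed Integer seed; chains are seeded deterministically from it, so
#'   the same seed and data give identical retained draws.
#' @param rhat_max Convergence guard: [fit_model()] errors if any monitored
#'   parameter has split-chain R-hat above this (set `Inf` to disable).
#' @param xbp_mode For `two_stage`/`eda`: `"latent"` (default) fits the
#'   fluctuating reference as one latent per participant-condition cell;
#'   `"marginal"` integrates a trial-level fluctuating reference out of the
#'   likelihood by Gauss-Hermite quadrature.
#' @param gh_order Quadrature order for `xbp_mode = "marginal"`.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(family, reference = c("AM", "GM"),
                       chains = 2, adapt = 1000, warmup = 3000, draws = 1250,
                       thin = 8, seed = 1L, rhat_max = 1.05,
                       xbp_mode = c("latent", "marginal"), gh_order = 9) {
  family <- match.arg(family, model_families())
  reference <- match.arg(reference)
  xbp_mode <- match.arg(xbp_mode)
  structure(
    list(family = family, reference = reference,
         chains = as.integer(chains), adapt = as.integer(adapt),
         warmup = as.integer(warmup), draws = as.integer(draws),
         thin = as.integer(thin), seed = as.integer(seed), rhat_max = rhat_max,
         xbp_mode = xbp_mode, gh_order = as.integer(gh_order)),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s/%s, %d chain(s) x %d draws, seed %d\n",
              x$family, x$reference, x$chains, x$draws, x$seed))
  invisible(x)
}

model_label <- function(spec) paste(spec$family, spec$reference, sep = "/")

#' Deterministic center of the bisection reference
#'
#' The reference-center rule of each model family: `simple` uses only the
#' short and long standards (their arithmetic midpoint or geometric mean);
#' `spacing` uses the unweighted mean of the probe durations (arithmetic or
#' geometric); `ensemble_mean`, `two_stage` and `eda` use the
#' frequency-weighted ensemble mean (AM or GM). For the latent-reference
#' families this is the center the latent fluctuates around.
#'
#' @param family A family name from [model_families()], or a [model_spec()]
#'   (whose `reference` then takes precedence).
#' @param set A [duration_set()].
#' @param reference `"AM"` or `"GM"`.
#' @return Reference center in ms.
#' @examples
#' reference_center("ensemble_mean", builtin_sets()$DF)  # 800
#' reference_center("simple", builtin_sets()$DF)         # 1000
#' @export
reference_center <- function(family, set, reference = c("AM", "GM")) {
  if (inherits(family, "model_spec")) {
    reference <- family$reference
    family <- family$family
  }
  family <- match.arg(family, model_families())
  reference <- match.arg(reference)
  set <- as_duration_set(set)
  if (family == "simple") {
    s <- standards(set)
    return(if (reference == "AM") mean(s) else sqrt(prod(s)))
  }
  if (family == "spacing") {
    x <- set$duration_ms
    return(if (reference == "AM") mean(x) else exp(mean(log(x))))
  }
  if (reference == "AM") arithmetic_mean(set) else geometric_mean(set)
}

#' Bernoulli log-likelihood of bisection responses
#'
#' Log-probability of observed binary responses under the logistic-in-ratio
#' psychometric relation (see [response_probability()]). Vectorized over
#' trials.
#'
#' @param alpha,beta Psychometric parameters.
#' @param xbp_ms Bisection reference(s), ms (> 0).
#' @param duration_ms Probe duration(s), ms.
#' @param response_long Binary responses (0/1).
#' @return Vector of per-trial log-likelihoods.
#' @export
trial_loglik <- function(alpha, beta, xbp_ms, duration_ms, response_long) {
  if (any(xbp_ms <= 0)) stop("bisection reference `xbp_ms` must be positive", call. = FALSE)
  if (!all(response_long %in% c(0, 1))) stop("`response_long` must be 0/1", call. = FALSE)
  q <- alpha + beta * (duration_ms / xbp_ms - 1)
  # log P(y) = y*q - log(1 + e^q), computed stably
  response_long * q - log1p(exp(-abs(q))) - pmax(q, 0)
}

# Gauss-Hermite nodes/weights (physicists' convention, weight exp(-z^2)),
# by Golub-Welsch on the Jacobi matrix; weights normalized to sum(w)=1 when
# used as a Normal quadrature via x = mu + sqrt(2) sigma z.
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(list(nodes = 0, weights = 1))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = (e$vectors[1, ]^2)[ord])
}

# Assemble the JAGS model string for a spec. Cells s = participant-condition;
# observations o = binomially aggregated duration cells. Priors are weakly
# informative: mu_alpha ~ N(0,2); sigma_alpha ~ half-N(2); mu_beta ~ N(10,10)
# truncated positive; sigma_beta, k ~ half-N(10); the latent-reference scale
# sigma_bp ~ half-N(range/2), in ms.
jags_model_code <- function(spec) {
  latent <- spec$family %in% c("two_stage", "eda")
  beta_mean <- if (spec$family == "eda") "k * amsd[cond[s]]" else "mu_beta"

  xbp_block <- if (!latent) {
    "    xbp[s] <- center[cond[s]]"
  } else if (spec$xbp_mode == "latent") {
    "    xbp[s] ~ dnorm(center[cond[s]], tau_bp) T(1, )"
  } else {
    ""  # marginal mode: no per-cell xbp node
  }

  lik_block <- if (latent && spec$xbp_mode == "marginal") {
    paste(
      "  for (o in 1:N) {",
      "    for (q in 1:Q) {",
      "      xq[o, q] <- ifelse(center[ocond[o]] + 1.4142135623730951 * sigma_bp * z[q] > 1,",
      "                         center[ocond[o]] + 1.4142135623730951 * sigma_bp * z[q], 1)",
      "      pq[o, q] <- ilogit(alpha[cell[o]] + beta[cell[o]] * (x[o] / xq[o, q] - 1))",
      "    }",
      "    p[o] <- inprod(w[1:Q], pq[o, 1:Q])",
      "    y[o] ~ dbin(p[o], n[o])",
      "    loglik[o] <- logdensity.bin(y[o], p[o], n[o])",
      "  }", sep = "\n")
  } else {
    paste(
      "  for (o in 1:N) {",
      "    logit(p[o]) <- alpha[cell[o]] + beta[cell[o]] * (x[o] / xbp[cell[o]] - 1)",
      "    y[o] ~ dbin(p[o], n[o])",
      "    loglik[o] <- logdensity.bin(y[o], p[o], n[o])",
      "  }", sep = "\n")
  }

  hyper_block <- paste(
    "  mu_alpha ~ dnorm(0, 0.25)",
    "  sigma_alpha ~ dnorm(0, 0.25) T(0, )",
    "  tau_alpha <- 1 / (sigma_alpha * sigma_alpha + 1e-9)",
    "  sigma_beta ~ dnorm(0, 0.01) T(0, )",
    "  tau_beta <- 1 / (sigma_beta * sigma_beta + 1e-9)",
    if (spec$family == "eda") "  k ~ dnorm(0, 0.01) T(0, )"
    else "  mu_beta ~ dnorm(10, 0.01) T(0, )",
    if (latent) paste(
      "  sigma_bp ~ dnorm(0, tau_bp_prior) T(0, )",
      "  tau_bp <- 1 / (sigma_bp * sigma_bp + 1e-9)", sep = "\n"),
    sep = "\n")

  paste(
    "model {",
    lik_block,
    "  for (s in 1:S) {",
    "    alpha[s] ~ dnorm(mu_alpha, tau_alpha)",
    paste0("    beta[s] ~ dnorm(", beta_mean, ", tau_beta)"),
    xbp_block,
    "  }",
    hyper_block,
    "}", sep = "\n")
}

#' Fit a hierarchical bisection model by MCMC
#'
#' Fits one of the five decision models to a trial-level dataset. Trials are
#' first aggregated to binomial counts per participant, condition and
#' duration (equivalent to the per-trial Bernoulli likelihood up to a
#' constant, and much faster); the pointwise log-likelihood is kept at this
#' cell granularity for WAIC. Participant-condition psychometric parameters
#' `alpha` and `beta` get Gaussian hyper-priors; the bisection reference is
#' fixed at [reference_center()] for `simple`/`spacing`/`ensemble_mean`,
#' and for `two_stage`/`eda` it is a latent per participant-condition with
#' prior `Normal(center, sigma_bp)` (or a trial-level fluctuation
#' marginalized by quadrature when `xbp_mode = "marginal"`), with `sigma_bp`
#' a fitted positive scale. Under `eda` the sensitivity hyper-mean is
#' `k * am / sd` of each condition's set, with a single `k` shared across
#' conditions.
#'
#' Sampling runs in JAGS; split-chain R-hat and effective sample size are
#' computed for every monitored parameter, and the fit errors if any R-hat
#' exceeds `spec$rhat_max`.
#'
#' @param trials Trial table (`participant`, `condition`, `duration_ms`,
#'   `response_long`), e.g. `simulate_cohort(...)$trials` or
#'   [read_bisection_data()] output.
#' @param spec A [model_spec()].
#' @param sets List of [duration_set()]s covering every condition in
#'   `trials`; unknown conditions are an error.
#' @param quiet Suppress JAGS progress output (default `TRUE`).
#' @return Object of class `bisect_fit`: list with `draws` (matrix, retained
#'   draws by parameter), `loglik` (draws x observation cells),
#'   `cells`/`obs` (index tables), `conditions` (reference centers and
#'   mean-to-spread ratios), `diagnostics` (R-hat, ESS per parameter), and
#'   the `spec`.
#' @export
fit_model <- function(trials, spec, sets, quiet = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  sets <- resolve_sets(trials, sets)
  obs <- aggregate_proportions(trials)
  stopifnot(all(c("participant", "condition") %in% names(obs)))

  cells <- obs |>
    dplyr::distinct(.data$participant, .data$condition) |>
    dplyr::arrange(.data$participant, .data$condition) |>
    dplyr::mutate(cell = dplyr::row_number())
  conditions <- tibble::tibble(condition = names(sets)) |>
    dplyr::mutate(
      cond = dplyr::row_number(),
      center = purrr::map_dbl(.data$condition, ~ reference_center(spec, sets[[.x]])),
      amsd = purrr::map_dbl(.data$condition, function(cc) {
        s <- ensemble_stats(sets[[cc]])
        if (s$sd == 0) stop("eda scaling undefined for zero-spread set", call. = FALSE)
        s$am / s$sd
      })
    )
  obs <- obs |>
    dplyr::inner_join(cells, by = c("participant", "condition")) |>
    dplyr::inner_join(conditions, by = "condition") |>
    dplyr::arrange(.data$cell, .data$duration_ms)

  latent <- spec$family %in% c("two_stage", "eda")
  marginal <- latent && spec$xbp_mode == "marginal"
  rng <- diff(range(obs$duration_ms))

  data <- list(
    N = nrow(obs), S = nrow(cells),
    x = obs$duration_ms, y = obs$n_long, n = obs$n_trials,
    cell = obs$cell,
    cond = (cells |> dplyr::inner_join(conditions, by = "condition"))$cond,
    center = conditions$center
  )
  if (spec$family == "eda") data$amsd <- conditions$amsd
  if (latent) data$tau_bp_prior <- 1 / (rng / 2)^2
  if (marginal) {
    gh <- gauss_hermite(spec$gh_order)
    data$Q <- spec$gh_order
    data$z <- gh$nodes
    data$w <- gh$weights
    data$ocond <- obs$cond
  }

  inits <- lapply(seq_len(spec$chains), function(ch) {
    ini <- list(
      .RNG.name = "base::Mersenne-Twister",
      .RNG.seed = spec$seed * 1000L + ch,
      mu_alpha = 0, sigma_alpha = 0.5, sigma_beta = 2,
      alpha = rep(0, data$S), beta = rep(8, data$S)
    )
    if (spec$family == "eda") ini$k <- 2 else ini$mu_beta <- 8
    if (latent) ini$sigma_bp <- rng / 20
    if (latent && !marginal) ini$xbp <- data$center[data$cond]
    ini
  })

  monitors <- c("mu_alpha", "sigma_alpha", "sigma_beta",
                if (spec$family == "eda") "k" else "mu_beta",
                "alpha", "beta",
                if (latent) "sigma_bp",
                if (latent && !marginal) "xbp",
                "loglik")

  run <- function() {
    m <- rjags::jags.model(textConnection(jags_model_code(spec)), data = data,
                           inits = inits, n.chains = spec$chains,
                           n.adapt = spec$adapt, quiet = quiet)
    if (spec$warmup > 0) update(m, spec$warmup, progress.bar = "none")
    rjags::coda.samples(m, monitors, n.iter = spec$draws * spec$thin,
                        thin = spec$thin, progress.bar = "none")
  }
  samples <- if (quiet) suppressWarnings(run()) else run()

  all_draws <- do.call(rbind, lapply(samples, as.matrix))
  is_ll <- grepl("^loglik\\[", colnames(all_draws))
  ll <- all_draws[, is_ll, drop = FALSE]
  # restore observation order (coda sorts names lexicographically)
  ll <- ll[, order(as.integer(sub("^loglik\\[(\\d+)\\]$", "\\1", colnames(ll)))),
           drop = FALSE]
  draws <- all_draws[, !is_ll, drop = FALSE]

  param_samples <- lapply(samples, function(s) s[, !is_ll, drop = FALSE])
  diagnostics <- mcmc_diagnostics(coda::as.mcmc.list(
    lapply(param_samples, coda::as.mcmc)))
  worst <- max(diagnostics$rhat, na.rm = TRUE)
  if (is.finite(spec$rhat_max) && worst > spec$rhat_max) {
    stop(sprintf("MCMC did not converge: max R-hat %.3f > %.3f (model %s)",
                 worst, spec$rhat_max, model_label(spec)), call. = FALSE)
  }

  structure(
    list(draws = draws, loglik = ll,
         cells = cells, obs = obs, conditions = conditions,
         diagnostics = diagnostics, spec = spec,
         n_chains = spec$chains, n_draws = nrow(draws)),
    class = "bisect_fit"
  )
}

mcmc_diagnostics <- function(mcmc_list) {
  nm <- colnames(mcmc_list[[1]])
  rhat <- if (length(mcmc_list) >= 2) {
    # per-parameter univariate PSRF; constant chains yield NA, treated as 1
    g <- try(coda::gelman.diag(mcmc_list, autoburnin = FALSE,
                               multivariate = FALSE)$psrf[, 1], silent = TRUE)
    if (inherits(g, "try-error")) rep(NA_real_, length(nm)) else g
  } else rep(NA_real_, length(nm))
  ess <- coda::effectiveSize(mcmc_list)
  tibble::tibble(parameter = nm,
                 rhat = ifelse(is.finite(rhat), rhat, 1),
                 ess = as.numeric(ess[nm]))
}

#' @export
print.bisect_fit <- function(x, ...) {
  cat(sprintf("<bisect_fit> %s, %d cells, %d obs, %d draws (%d chain(s)), max R-hat %.3f\n",
              model_label(x$spec), nrow(x$cells), nrow(x$obs), x$n_draws,
              x$n_chains, max(x$diagnostics$rhat, na.rm = TRUE)))
  invisible(x)
}

#' @rdname fit_model
#' @param x,object A `bisect_fit`.
#' @param ... Unused.
#' @export
tidy.bisect_fit <- function(x, ...) {
  est <- colMeans(x$draws)
  sds <- apply(x$draws, 2, stats::sd)
  tibble::tibble(term = names(est), estimate = unname(est),
                 std.error = unname(sds)) |>
    dplyr::left_join(x$diagnostics, by = c(term = "parameter"))
}

#' @rdname fit_model
#' @export
glance.bisect_fit <- function(x, ...) {
  w <- waic(x$loglik)
  tibble::tibble(family = x$spec$family, reference = x$spec$reference,
                 n_cells = nrow(x$cells), n_obs = nrow(x$obs),
                 n_draws = x$n_draws,
                 waic = w$waic, lppd = w$lppd, p_waic = w$p_waic,
                 max_rhat = max(x$diagnostics$rhat, na.rm = TRUE))
}

# column of draws for an indexed parameter; JAGS drops the index when the
# monitored vector has length one
param_draws <- function(draws, base, s) {
  nm <- sprintf("%s[%d]", base, s)
  if (nm %in% colnames(draws)) return(draws[, nm])
  if (s == 1 && base %in% colnames(draws)) return(draws[, base])
  stop("parameter ", nm, " not found in draws", call. = FALSE)
}

# draws x durations matrix of response probabilities for one cell
cell_prob_draws <- function(fit, s, x) {
  spec <- fit$spec
  a <- param_draws(fit$draws, "alpha", s)
  b <- param_draws(fit$draws, "beta", s)
  cond <- fit$cells$condition[s]
  center <- fit$conditions$center[match(cond, fit$conditions$condition)]
  latent <- spec$family %in% c("two_stage", "eda")
  if (!latent) {
    xbp <- rep(center, length(a))
    plogis(outer(a, rep(1, length(x))) +
             outer(b, rep(1, length(x))) * (outer(xbp^-1, x) - 1))
  } else if (spec$xbp_mode == "latent") {
    xbp <- param_draws(fit$draws, "xbp", s)
    plogis(outer(a, rep(1, length(x))) +
             outer(b, rep(1, length(x))) * (outer(xbp^-1, x) - 1))
  } else {
    sb <- fit$draws[, "sigma_bp"]
    gh <- gauss_hermite(spec$gh_order)
    p <- matrix(0, length(a), length(x))
    for (q in seq_len(spec$gh_order)) {
      xq <- pmax(center + sqrt(2) * sb * gh$nodes[q], 1)
      p <- p + gh$weights[q] *
        plogis(outer(a, rep(1, length(x))) +
                 outer(b, rep(1, length(x))) * (outer(xq^-1, x) - 1))
    }
    p
  }
}

#' Predict PSE and JND from a fitted model
#'
#' For each participant-condition cell, averages the predicted "long"
#' probability over the posterior draws at each probe duration of that
#' cell's set, then fits the cumulative-Gaussian psychometric function to
#' the posterior-mean curve (weighted by the observed trial counts) to
#' obtain the model-predicted PSE and JND — the quantities compared against
#' the observed psychometric fits.
#'
#' @param fit A `bisect_fit` from [fit_model()].
#' @return Tibble with one row per participant-condition: `participant`,
#'   `condition`, `pse`, `sigma`, `jnd`, `converged`.
#' @export
posterior_predict_pse_jnd <- function(fit) {
  stopifnot(inherits(fit, "bisect_fit"))
  purrr::map_dfr(seq_len(nrow(fit$cells)), function(s) {
    rows <- fit$obs[fit$obs$cell == s, ]
    pbar <- colMeans(cell_prob_draws(fit, s, rows$duration_ms))
    f <- fit_cumulative_gaussian(tibble::tibble(
      duration_ms = rows$duration_ms,
      n_trials = rows$n_trials,
      n_long = rows$n_trials * pbar
    ))
    tibble::tibble(participant = fit$cells$participant[s],
                   condition = fit$cells$condition[s],
                   pse = f$pse, sigma = f$sigma, jnd = f$jnd,
                   converged = f$converged)
  })
}

#' Serialize a model fit to plain text
#'
#' Writes the retained draws and the pointwise log-likelihood matrix as CSV,
#' plus a JSON metadata file (model specification, seed, diagnostics, cell
#' and condition tables).
#'
#' @param fit A `bisect_fit`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "bisect_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tibble::as_tibble(fit$draws), file.path(dir, "draws.csv"))
  readr::write_csv(tibble::as_tibble(fit$loglik), file.path(dir, "loglik.csv"))
  meta <- list(spec = unclass(fit$spec),
               diagnostics = fit$diagnostics,
               cells = fit$cells, conditions = fit$conditions)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
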