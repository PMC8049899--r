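#' Probability of a "long" response
#'
#' The generative psychometric relation of the decision models: the log-odds
#' of judging probe duration `x` as "long" are linear in the ratio of the
#' probe to the bisection reference,
#' `log(p / (1 - p)) = alpha + beta * (x / xbp - 1)`,
#' so that a ratio comparison on a linear scale stands in for a subtractive
#' comparison on an internal log scale (Weber scaling). `alpha` is a response
#' bias at the reference; `beta` is the decision sensitivity (slope).
#'
#' @param alpha Intercept (dimensionless); 0 means no bias at the reference.
#' @param beta Sensitivity (dimensionless); larger is steeper.
#' @param duration_ms Probe duration(s), ms.
#' @param xbp_ms Bisection reference(s), ms; must be strictly positive.
#' @return Probability (vector) of a "long" response.
#' @examples
#' response_probability(0, 10, 880, 800)
#' @export
response_probability <- function(alpha, beta, duration_ms, xbp_ms) {
  if (any(xbp_ms <= 0)) stop("bisection reference `xbp_ms` must be positive", call. = FALSE)
  plogis(alpha + beta * (duration_ms / xbp_ms - 1))
}

#' Observer parameters for the synthetic-data generator
#'
#' @param alpha,beta Psychometric intercept and sensitivity of
#'   [response_probability()].
#' @param xbp_center Center of the observer's bisection reference, ms (> 0).
#' @param xbp_sd Trial-to-trial fluctuation scale of the reference, ms (>= 0);
#'   0 gives a fixed reference.
#' @return One-row tibble of generative parameters.
#' @export
observer_params <- function(alpha = 0, beta = 9, xbp_center = 800, xbp_sd = 0) {
  stopifnot(xbp_center > 0, xbp_sd >= 0)
  tibble::tibble(alpha = alpha, beta = beta,
                 xbp_center = xbp_center, xbp_sd = xbp_sd)
}

#' Cohort hyperparameters for the synthetic-data generator
#'
#' Participant-level psychometric parameters are drawn from Gaussian
#' hyper-distributions: `alpha ~ N(mu_alpha, sigma_alpha)` and, for all
#' generative modes except `eda`, `beta ~ N(mu_beta, sigma_beta)`. In `eda`
#' mode the sensitivity hyper-mean is tied to the stimulus statistics of each
#' condition, `beta ~ N(k * am / sd, sigma_beta)`: narrower sets make
#' steeper observers. `xbp_sd` is the shared trial-to-trial fluctuation
#' scale of the bisection reference (used by the `two_stage` and `eda`
#' modes; the fixed-reference modes ignore it).
#'
#' Defaults describe the synthetic cohorts used throughout the package's
#' checks: mild bias heterogeneity, sensitivity around 9 (JNDs near 110 ms
#' for references near 900 ms), `k = 3`, and a 60-ms reference fluctuation.
#'
#' @param mu_alpha,sigma_alpha Hyper-mean/SD of the intercept.
#' @param mu_beta,sigma_beta Hyper-mean/SD of the sensitivity.
#' @param k Ensemble scaling factor linking the sensitivity hyper-mean to
#'   the set's mean-to-spread ratio (`eda` mode only; > 0).
#' @param xbp_sd Shared reference fluctuation scale, ms (>= 0).
#' @return One-row tibble of hyperparameters.
#' @export
cohort_hyperparams <- function(mu_alpha = 0, sigma_alpha = 0.3,
                               mu_beta = 9, sigma_beta = 1,
                               k = 3, xbp_sd = 60) {
  stopifnot(sigma_alpha >= 0, sigma_beta >= 0, k > 0, xbp_sd >= 0)
  tibble::tibble(mu_alpha = mu_alpha, sigma_alpha = sigma_alpha,
                 mu_beta = mu_beta, sigma_beta = sigma_beta,
                 k = k, xbp_sd = xbp_sd)
}

# one truncated-normal reference draw per trial; truncation at 1 ms keeps the
# ratio in the psychometric relation well defined
draw_references <- function(n, center, sd) {
  if (sd == 0) return(rep(center, n))
  pmax(rnorm(n, center, sd), 1)
}

#' Simulate one block of bisection trials
#'
#' Emits exactly one block: every duration of the set appears exactly
#' `count` times, in a seeded random order. Per trial, a bisection reference
#' is drawn from `Normal(xbp_center, xbp_sd)` truncated at 1 ms, and the
#' binary response is Bernoulli with probability [response_probability()].
#'
#' @param set A [duration_set()].
#' @param params One-row data frame from [observer_params()].
#' @param seed Integer seed; same seed and inputs give the identical block.
#' @return Tibble with one row per trial: `trial`, `duration_ms`, `xbp_ms`
#'   (the realized reference, kept as generative ground truth), and
#'   `response_long` (0/1).
#' @export
simulate_block <- function(set, params, seed = 1L) {
  set <- as_duration_set(set)
  stopifnot(is.data.frame(params), nrow(params) == 1)
  withr_seed(seed, {
    durs <- rep(set$duration_ms, set$count)
    durs <- durs[sample.int(length(durs))]
    xbp <- draw_references(length(durs), params$xbp_center, params$xbp_sd)
    p <- response_probability(params$alpha, params$beta, durs, xbp)
    tibble::tibble(
      trial = seq_along(durs),
      duration_ms = durs,
      xbp_ms = xbp,
      response_long = rbinom(length(durs), 1L, p)
    )
  })
}

# run code under a local RNG state seeded with `seed`
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Simulate a cohort of synthetic observers
#'
#' Generates a full trial-level dataset from a hierarchical generative model:
#' per participant and condition, psychometric parameters are drawn from the
#' hyper-distributions of [cohort_hyperparams()]; the bisection-reference
#' center follows the reference rule of the chosen generative `mode`
#' (see [reference_center()]); and each block is produced by
#' [simulate_block()]. In the fixed-reference modes (`simple`, `spacing`,
#' `ensemble_mean`) the reference does not fluctuate; in `two_stage` and
#' `eda` it fluctuates from trial to trial with scale `xbp_sd`, and in `eda`
#' the sensitivity hyper-mean additionally scales with each set's
#' mean-to-spread ratio.
#'
#' @param sets A [duration_set()] or list of them; one condition per set.
#' @param hyper One-row data frame from [cohort_hyperparams()].
#' @param n_participants Number of observers (>= 1).
#' @param blocks_per_condition Blocks simulated per condition (default 6,
#'   i.e. one 336-trial session for a 56-trial block design).
#' @param seed Integer master seed; all randomness derives from it.
#' @param mode Generative family: one of `"simple"`, `"spacing"`,
#'   `"ensemble_mean"`, `"two_stage"`, `"eda"`.
#' @param reference `"AM"` or `"GM"` reference-center variant.
#' @return List of class `bisect_cohort`:
#'   * `trials`: tibble `participant, condition, block, trial, duration_ms,
#'     xbp_ms, response_long`;
#'   * `observers`: ground-truth manifest of the drawn per-participant
#'     parameters (`participant, condition, alpha, beta, xbp_center,
#'     xbp_sd`);
#'   * `config`: the hyperparameters, mode, reference, seed.
#' @examples
#' ch <- simulate_cohort(builtin_sets()[c("DF", "AF")],
#'                       cohort_hyperparams(), n_participants = 2,
#'                       blocks_per_condition = 1, seed = 7, mode = "eda")
#' dplyr::count(ch$trials, condition)
#' @export
simulate_cohort <- function(sets, hyper = cohort_hyperparams(),
                            n_participants = 15, blocks_per_condition = 6,
                            seed = 1L, mode = "eda", reference = "AM") {
  mode <- match.arg(mode, model_families())
  if (inherits(sets, "duration_set")) sets <- list(sets)
  sets <- rlang::set_names(sets, purrr::map_chr(sets, set_name))
  stopifnot(is.data.frame(hyper), nrow(hyper) == 1, n_participants >= 1)
  fluctuates <- mode %in% c("two_stage", "eda")

  withr_seed(seed, {
    grid <- tidyr::expand_grid(
      participant = sprintf("P%02d", seq_len(n_participants)),
      condition = names(sets)
    )
    observers <- dplyr::mutate(
      grid,
      alpha = rnorm(dplyr::n(), hyper$mu_alpha, hyper$sigma_alpha),
      beta_mean = purrr::map_dbl(.data$condition, function(cc) {
        if (mode == "eda") {
          s <- ensemble_stats(sets[[cc]])
          hyper$k * s$am / s$sd
        } else hyper$mu_beta
      }),
      beta = rnorm(dplyr::n(), .data$beta_mean, hyper$sigma_beta),
      xbp_center = purrr::map_dbl(.data$condition, function(cc) {
        reference_center(mode, sets[[cc]], reference)
      }),
      xbp_sd = if (fluctuates) hyper$xbp_sd else 0
    )
    block_seeds <- matrix(
      sample.int(.Machine$integer.max, nrow(observers) * blocks_per_condition),
      nrow = nrow(observers)
    )
    trials <- purrr::map_dfr(seq_len(nrow(observers)), function(i) {
      ob <- observers[i, ]
      purrr::map_dfr(seq_len(blocks_per_condition), function(b) {
        bl <- simulate_block(sets[[ob$condition]],
                             observer_params(ob$alpha, ob$beta,
                                             ob$xbp_center, ob$xbp_sd),
                             seed = block_seeds[i, b])
        dplyr::mutate(bl, participant = ob$participant,
                      condition = ob$condition, block = b,
                      .before = 1)
      })
    })
  })

  structure(
    list(
      trials = dplyr::select(trials, "participant", "condition", "block",
                             "trial", "duration_ms", "xbp_ms", "response_long"),
      observers = dplyr::select(observers, -"beta_mean"),
      config = c(as.list(hyper),
                 list(mode = mode, reference = reference, seed = as.integer(seed),
                      n_participants = n_participants,
                      blocks_per_condition = blocks_per_condition))
    ),
    class = "bisect_cohort"
  )
}

#' @export
print.bisect_cohort <- function(x, ...) {
  cat(sprintf(
    "<bisect_cohort> %d trials, %d participants, %d condition(s), mode '%s', seed %d\n",
    nrow(x$trials), length(unique(x$trials$participant)),
    length(unique(x$trials$condition)), x$config$mode, x$config$seed
  ))
  invisible(x)
}

#' Read or write a trial-level bisection dataset
#'
#' CSV round trip with the schema
#' `participant,condition,block,trial,duration_ms,response_long` (extra
#' columns such as the generative `xbp_ms` are preserved on write and read).
#'
#' @param data Trial table (e.g. `simulate_cohort(...)$trials`).
#' @param path File path.
#' @return `read_bisection_data()` returns a tibble;
#'   `write_bisection_data()` invisibly returns `path`.
#' @export
write_bisection_data <- function(data, path) {
  need <- c("participant", "condition", "block", "trial", "duration_ms",
            "response_long")
  stopifnot(all(need %in% names(data)))
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname write_bisection_data
#' @export
read_bisection_data <- function(path) {
  d <- readr::read_csv(path, col_types = readr::cols(
    participant = readr::col_character(),
    condition = readr::col_character(),
    .default = readr::col_double()
  ))
  d$response_long <- as.integer(d$response_long)
  d
}

#' Write a plain-text run manifest
#'
#' Key-value record (one `key = value` line each) of a simulation's
#' ground-truth configuration, including the seed.
#'
#' @param cohort A `bisect_cohort` from [simulate_cohort()].
#' @param path File path for the manifest; the drawn per-participant
#'   parameters are written alongside as `<path>.observers.csv`.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(cohort, path) {
  stopifnot(inherits(cohort, "bisect_cohort"))
  cfg <- cohort$config
  lines <- sprintf("%s = %s", names(cfg),
                   vapply(cfg, function(v) paste(format(v), collapse = ","), ""))
  writeLines(lines, path)
  readr::write_csv(cohort$observers, paste0(path, ".observers.csv"))
  invisible(path)
}
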