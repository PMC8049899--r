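#' Aggregate trials into response proportions
#'
#' Collapses a trial table to one row per probe duration with the number of
#' trials and of "long" responses — the binomial sufficient statistics the
#' psychometric fit consumes. If `participant` / `condition` columns are
#' present they are kept as grouping columns, so the output holds one
#' psychometric table per participant-condition cell.
#'
#' @param trials Trial table with `duration_ms` and `response_long` columns.
#' @return Tibble with columns (grouping columns,) `duration_ms`,
#'   `n_trials`, `n_long`, `prop_long`, sorted by duration within group.
#' @export
aggregate_proportions <- function(trials) {
  if (!is.data.frame(trials) || nrow(trials) == 0) {
    stop("`trials` must be a nonempty data frame", call. = FALSE)
  }
  stopifnot(all(c("duration_ms", "response_long") %in% names(trials)))
  if (!all(trials$response_long %in% c(0, 1))) {
    stop("`response_long` must be binary 0/1", call. = FALSE)
  }
  keys <- intersect(c("participant", "condition"), names(trials))
  trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "duration_ms")))) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_long = sum(.data$response_long),
      .groups = "drop"
    ) |>
    dplyr::mutate(prop_long = .data$n_long / .data$n_trials) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(keys, "duration_ms"))))
}

# negative binomial log-likelihood of the cumulative-Gaussian psychometric
# function; probabilities clamped away from 0/1 for finite likelihoods
cg_nll <- function(par, x, n, y) {
  p <- pnorm((x - par[1]) / exp(par[2]))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(y * log(p) + (n - y) * log1p(-p))
}

#' Fit a cumulative-Gaussian psychometric function
#'
#' Maximum-likelihood fit of `P(long | x) = pnorm((x - pse) / sigma)` to
#' binomial response counts, by direct optimization of the binomial
#' log-likelihood over `(pse, log sigma)`. The fit is two-parameter (no
#' lapse or guess rates). To guard against local optima on steep data, the
#' optimizer is multi-started from `sigma` at 1/10, 1/4 and 1/2 of the
#' duration range. The just-noticeable difference is the distance between
#' the 75% and 50% thresholds, `jnd = qnorm(0.75) * sigma`; `sigma` itself
#' (the SD of the fitted function) is exposed alongside.
#'
#' Degenerate data are flagged rather than silently fitted: if all responses
#' are identical, or the likelihood pushes `sigma` beyond 100x the stimulus
#' range (a flat, slope-unidentified dataset) or below 1e-6x the range (a
#' step, where the threshold is only bracketed), `converged` is `FALSE` and
#' a diagnostic message is attached.
#'
#' @param proportions Table from [aggregate_proportions()] for a single
#'   participant-condition cell: columns `duration_ms`, `n_trials`,
#'   `n_long` (fractional counts are accepted, e.g. for posterior-mean
#'   predictions). At least 3 distinct durations are required.
#' @return Object of class `psychometric_fit`: a list with `pse`, `sigma`,
#'   `jnd`, `loglik`, `converged`, `message`, and the fitted `data`.
#' @examples
#' pr <- tibble::tibble(duration_ms = seq(400, 1600, 200), n_trials = 48,
#'                      n_long = round(48 * pnorm((duration_ms - 900) / 150)))
#' fit_cumulative_gaussian(pr)
#' @export
fit_cumulative_gaussian <- function(proportions) {
  stopifnot(is.data.frame(proportions),
            all(c("duration_ms", "n_trials", "n_long") %in% names(proportions)))
  x <- proportions$duration_ms
  n <- proportions$n_trials
  y <- proportions$n_long
  if (length(unique(x)) < 3) stop("need >= 3 distinct durations", call. = FALSE)
  if (any(y < 0) || any(y > n)) stop("need 0 <= n_long <= n_trials", call. = FALSE)

  bad <- function(msg, pse = NA_real_, sigma = NA_real_, ll = NA_real_) {
    new_psychometric_fit(pse, sigma, ll, FALSE, msg, proportions)
  }
  if (sum(y) == 0 || sum(y) == sum(n)) {
    return(bad("all responses identical; psychometric function unidentified"))
  }

  rng <- diff(range(x))
  # crude 50%-crossing start for the threshold
  ph <- y / n
  pse0 <- if (any(ph >= 0.5) && any(ph < 0.5)) {
    i <- which(ph >= 0.5)[1]
    if (i == 1) x[1] else {
      x[i - 1] + (0.5 - ph[i - 1]) / max(ph[i] - ph[i - 1], 1e-9) * (x[i] - x[i - 1])
    }
  } else mean(range(x))

  fits <- lapply(c(rng / 10, rng / 4, rng / 2), function(s0) {
    optim(c(pse0, log(s0)), cg_nll, x = x, n = n, y = y,
          method = "Nelder-Mead",
          control = list(maxit = 2000, reltol = 1e-12))
  })
  best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  pse <- best$par[1]
  sigma <- exp(best$par[2])
  ll <- -best$value

  if (sigma > 100 * rng) {
    return(bad("slope unidentified (fitted sigma exceeds 100x the stimulus range)",
               pse, sigma, ll))
  }
  if (sigma < 1e-6 * rng) {
    return(bad("near-degenerate slope (step-like data); PSE only bracketed",
               pse, sigma, ll))
  }
  new_psychometric_fit(pse, sigma, ll, best$convergence == 0,
                       if (best$convergence == 0) "" else "optimizer did not converge",
                       proportions)
}

new_psychometric_fit <- function(pse, sigma, loglik, converged, message, data) {
  structure(
    list(pse = pse, sigma = sigma, jnd = qnorm(0.75) * sigma,
         loglik = loglik, converged = converged, message = message,
         data = data),
    class = "psychometric_fit"
  )
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("<psychometric_fit> PSE %.1f ms, sigma %.1f ms, JND %.1f ms, %s\n",
              x$pse, x$sigma, x$jnd,
              if (x$converged) "converged" else paste("NOT converged:", x$message)))
  invisible(x)
}

#' @rdname fit_cumulative_gaussian
#' @param x A `psychometric_fit`.
#' @param ... Unused.
#' @export
tidy.psychometric_fit <- function(x, ...) {
  tibble::tibble(
    term = c("pse", "sigma", "jnd"),
    estimate = c(x$pse, x$sigma, x$jnd)
  )
}

#' @rdname fit_cumulative_gaussian
#' @export
glance.psychometric_fit <- function(x, ...) {
  tibble::tibble(pse = x$pse, sigma = x$sigma, jnd = x$jnd,
                 logLik = x$loglik, converged = x$converged,
                 nobs = sum(x$data$n_trials))
}

#' Batch psychometric fitting over a dataset
#'
#' Fits [fit_cumulative_gaussian()] per participant-condition cell (the
#' default), or to proportions pooled over participants within condition
#' (`pool = TRUE`, the group-curve view).
#'
#' @param trials Trial table (`participant`, `condition`, `duration_ms`,
#'   `response_long`).
#' @param pool Pool participants within condition before fitting?
#' @return Tibble with one row per fitted cell: identifiers plus `pse`,
#'   `sigma`, `jnd`, `loglik`, `converged`.
#' @examples
#' ch <- simulate_cohort(builtin_sets()["DF"], n_participants = 2,
#'                       blocks_per_condition = 2, seed = 1)
#' fit_psychometric(ch$trials)
#' @export
fit_psychometric <- function(trials, pool = FALSE) {
  props <- aggregate_proportions(trials)
  keys <- intersect(c("participant", "condition"), names(props))
  if (pool) keys <- setdiff(keys, "participant")
  props |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(d, g) {
      f <- fit_cumulative_gaussian(d)
      tibble::tibble(pse = f$pse, sigma = f$sigma, jnd = f$jnd,
                     loglik = f$loglik, converged = f$converged)
    }) |>
    dplyr::ungroup()
}

#' Plot a fitted psychometric function
#'
#' @param object A `psychometric_fit`.
#' @param ... Unused.
#' @return A ggplot: observed proportions and the fitted cumulative
#'   Gaussian, with the PSE marked.
#' @export
autoplot.psychometric_fit <- function(object, ...) {
  d <- object$data
  xs <- seq(min(d$duration_ms), max(d$duration_ms), length.out = 200)
  curve <- tibble::tibble(duration_ms = xs,
                          p = pnorm((xs - object$pse) / object$sigma))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$duration_ms)) +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$p), color = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$n_long / .data$n_trials)) +
    ggplot2::geom_vline(xintercept = object$pse, linetype = 2, color = "grey40") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 3, color = "grey70") +
    ggplot2::labs(x = "probe duration (ms)", y = "P(\"long\")") +
    ggplot2::theme_minimal()
}
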