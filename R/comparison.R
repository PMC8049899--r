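#' Watanabe-Akaike information criterion
#'
#' WAIC from a pointwise log-likelihood matrix (posterior draws in rows, one
#' column per observation): the log pointwise predictive density
#' `lppd = sum_i log mean_s exp(ll[s, i])` (computed via a stable
#' log-sum-exp), the variance-based effective-parameter penalty
#' `p_waic = sum_i var_s(ll[s, i])`, and `waic = -2 * (lppd - p_waic)`.
#' Lower is better.
#'
#' @param loglik Matrix (draws x observations) of pointwise log-likelihoods;
#'   all entries must be finite and at least two draws are required.
#' @return One-row tibble: `waic`, `lppd`, `p_waic`, `n_obs`.
#' @examples
#' ll <- matrix(log(c(.5, .4, .6, .5, .45, .55)), nrow = 3)
#' waic(ll)
#' @export
waic <- function(loglik) {
  loglik <- as.matrix(loglik)
  if (nrow(loglik) < 2 || ncol(loglik) < 1) {
    stop("need >= 2 draws and >= 1 observation", call. = FALSE)
  }
  if (!all(is.finite(loglik))) stop("non-finite log-likelihood entries", call. = FALSE)
  mx <- apply(loglik, 2, max)
  lppd <- sum(mx + log(colMeans(exp(sweep(loglik, 2, mx)))))
  p_waic <- sum(apply(loglik, 2, var))
  tibble::tibble(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic,
                 n_obs = ncol(loglik))
}

#' Per-cell WAIC of a fitted model
#'
#' Splits the pointwise log-likelihood of a [fit_model()] result by
#' participant-condition cell and computes WAIC within each. WAIC is
#' additive over independent observations, so the totals sum to the
#' whole-data WAIC; cell-level values support averaging over participants,
#' conditions, or both.
#'
#' @param fit A `bisect_fit`.
#' @return Tibble: `participant`, `condition`, `waic`, `lppd`, `p_waic`,
#'   `n_obs`.
#' @export
waic_by_cell <- function(fit) {
  stopifnot(inherits(fit, "bisect_fit"))
  purrr::map_dfr(seq_len(nrow(fit$cells)), function(s) {
    idx <- which(fit$obs$cell == s)
    dplyr::bind_cols(fit$cells[s, c("participant", "condition")],
                     waic(fit$loglik[, idx, drop = FALSE]))
  })
}

#' Euclidean PSE-JND prediction error
#'
#' Joins model-predicted and observed (PSE, JND) pairs by participant and
#' condition and returns the per-cell errors `d_pse = pse_pred - pse_obs`,
#' `d_jnd = jnd_pred - jnd_obs`, and the Euclidean distance
#' `sqrt(d_pse^2 + d_jnd^2)` (ms). The mean of `distance` is the summary the
#' model ranking uses.
#'
#' @param predicted,observed Tibbles with columns `participant`,
#'   `condition`, `pse`, `jnd` (e.g. [posterior_predict_pse_jnd()] and
#'   [fit_psychometric()] output). Every predicted cell must match exactly
#'   one observed cell and vice versa.
#' @return Tibble: `participant`, `condition`, `d_pse`, `d_jnd`, `distance`.
#' @examples
#' obs <- tibble::tibble(participant = "P1", condition = "DF",
#'                       pse = 800, jnd = 100)
#' prd <- dplyr::mutate(obs, pse = 803, jnd = 104)
#' pse_jnd_distance(prd, obs)  # distance 5
#' @export
pse_jnd_distance <- function(predicted, observed) {
  need <- c("participant", "condition", "pse", "jnd")
  stopifnot(all(need %in% names(predicted)), all(need %in% names(observed)))
  if (nrow(predicted) != nrow(observed)) {
    stop("predicted and observed must have the same number of cells", call. = FALSE)
  }
  j <- dplyr::inner_join(
    dplyr::select(predicted, dplyr::all_of(need)),
    dplyr::select(observed, dplyr::all_of(need)),
    by = c("participant", "condition"), suffix = c("_pred", "_obs")
  )
  if (nrow(j) != nrow(predicted)) {
    stop("predicted and observed cells do not align", call. = FALSE)
  }
  j |>
    dplyr::transmute(
      .data$participant, .data$condition,
      d_pse = .data$pse_pred - .data$pse_obs,
      d_jnd = .data$jnd_pred - .data$jnd_obs,
      distance = sqrt(.data$d_pse^2 + .data$d_jnd^2)
    )
}

#' Fit and compare bisection decision models
#'
#' Runs the whole comparison pipeline on one dataset: observed PSE/JND per
#' participant-condition by maximum-likelihood psychometric fitting, then,
#' for each requested model, an MCMC fit, per-cell WAIC, posterior-predicted
#' PSE/JND, and the Euclidean PSE-JND prediction errors. Models are ranked
#' by mean WAIC over participant-condition cells (lower is better). A model
#' whose fit fails is recorded with its error message and the comparison
#' continues.
#'
#' @param trials Trial table (see [fit_model()]).
#' @param specs List of [model_spec()]s (a single spec is accepted).
#' @param sets List of [duration_set()]s covering the dataset's conditions.
#' @param keep_fits Keep the full `bisect_fit` objects in the result?
#' @param quiet Suppress JAGS progress output.
#' @return Object of class `bisect_comparison`: list with
#'   * `summary`: per-model tibble (`model`, `family`, `reference`,
#'     `waic_mean`, `waic_total`, `lppd`, `p_waic`, `mean_distance`, `rank`,
#'     `error`);
#'   * `waic_cells`: per-model, per-cell WAIC table;
#'   * `errors`: per-model, per-participant (d_pse, d_jnd, distance);
#'   * `observed` / `predicted`: the (PSE, JND) tables;
#'   * `fits`: named list of fits (if `keep_fits`).
#' @export
compare_models <- function(trials, specs, sets, keep_fits = FALSE,
                           quiet = TRUE) {
  if (inherits(specs, "model_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1, all(purrr::map_lgl(specs, inherits, "model_spec")))
  observed <- fit_psychometric(trials)

  per_model <- purrr::map(specs, function(sp) {
    label <- model_label(sp)
    res <- tryCatch({
      fit <- fit_model(trials, sp, sets, quiet = quiet)
      cells <- waic_by_cell(fit)
      predicted <- posterior_predict_pse_jnd(fit)
      err <- pse_jnd_distance(predicted, observed)
      list(label = label, fit = fit, cells = cells, predicted = predicted,
           err = err, error = NA_character_)
    }, error = function(e) {
      list(label = label, fit = NULL, cells = NULL, predicted = NULL,
           err = NULL, error = conditionMessage(e))
    })
    res$spec <- sp
    res
  })

  summary <- purrr::map_dfr(per_model, function(m) {
    if (!is.na(m$error)) {
      return(tibble::tibble(model = m$label, family = m$spec$family,
                            reference = m$spec$reference,
                            waic_mean = NA_real_, waic_total = NA_real_,
                            lppd = NA_real_, p_waic = NA_real_,
                            mean_distance = NA_real_, error = m$error))
    }
    tibble::tibble(
      model = m$label, family = m$spec$family, reference = m$spec$reference,
      waic_mean = mean(m$cells$waic), waic_total = sum(m$cells$waic),
      lppd = sum(m$cells$lppd), p_waic = sum(m$cells$p_waic),
      mean_distance = mean(m$err$distance), error = NA_character_
    )
  }) |>
    dplyr::mutate(rank = dplyr::min_rank(.data$waic_mean))

  keep <- function(field) {
    purrr::map_dfr(per_model, function(m) {
      if (is.null(m[[field]])) return(NULL)
      dplyr::mutate(m[[field]], model = m$label, .before = 1)
    })
  }

  structure(
    list(summary = summary,
         waic_cells = keep("cells"),
         errors = keep("err"),
         predicted = keep("predicted"),
         observed = observed,
         fits = if (keep_fits) {
           rlang::set_names(purrr::map(per_model, "fit"),
                            purrr::map_chr(per_model, "label"))
         }),
    class = "bisect_comparison"
  )
}

#' @export
print.bisect_comparison <- function(x, ...) {
  cat("<bisect_comparison>\n")
  print(dplyr::arrange(x$summary, .data$rank))
  invisible(x)
}

#' @rdname compare_models
#' @param x,object A `bisect_comparison`.
#' @param ... Unused.
#' @export
tidy.bisect_comparison <- function(x, ...) x$summary

#' @rdname compare_models
#' @export
glance.bisect_comparison <- function(x, ...) {
  ok <- dplyr::filter(x$summary, is.na(.data$error))
  tibble::tibble(n_models = nrow(x$summary),
                 n_failed = sum(!is.na(x$summary$error)),
                 best_model = ok$model[which.min(ok$waic_mean)],
                 best_waic_mean = min(ok$waic_mean))
}

#' Plot PSE-JND prediction errors by model
#'
#' Scatter of per-participant prediction errors (predicted minus observed
#' PSE against predicted minus observed JND), one panel color per model;
#' perfect prediction sits at the origin.
#'
#' @param object A `bisect_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bisect_comparison <- function(object, ...) {
  ggplot2::ggplot(object$errors,
                  ggplot2::aes(x = .data$d_pse, y = .data$d_jnd,
                               color = .data$model)) +
    ggplot2::geom_hline(yintercept = 0, color = "grey80") +
    ggplot2::geom_vline(xintercept = 0, color = "grey80") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "prediction error in PSE (ms)",
                  y = "prediction error in JND (ms)") +
    ggplot2::theme_minimal()
}

#' Serialize a comparison report
#'
#' Writes the comparison summary as JSON plus delimited-text tables
#' (summary, per-cell WAIC, per-participant errors, observed and predicted
#' PSE/JND) and the prediction-error figure.
#'
#' @param comparison A `bisect_comparison`.
#' @param dir Output directory (created if needed).
#' @param figure Also write `prediction_errors.png`?
#' @return Invisibly, `dir`.
#' @export
write_comparison <- function(comparison, dir, figure = TRUE) {
  stopifnot(inherits(comparison, "bisect_comparison"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(comparison$summary, file.path(dir, "summary.csv"))
  readr::write_csv(comparison$waic_cells, file.path(dir, "waic_cells.csv"))
  readr::write_csv(comparison$errors, file.path(dir, "errors.csv"))
  readr::write_csv(comparison$observed, file.path(dir, "observed_pse_jnd.csv"))
  readr::write_csv(comparison$predicted, file.path(dir, "predicted_pse_jnd.csv"))
  jsonlite::write_json(comparison$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (figure && nrow(comparison$errors) > 0) {
    ggplot2::ggsave(file.path(dir, "prediction_errors.png"),
                    autoplot(comparison), width = 6, height = 4, dpi = 150)
  }
  invisible(dir)
}
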