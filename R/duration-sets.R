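#' Define a duration set
#'
#' A duration set is the design object of a temporal-bisection session: an
#' ordered collection of probe durations together with the number of times
#' each is presented per block. The shortest and longest durations double as
#' the short and long standards. Frequencies are stored as integer per-block
#' counts (not probabilities) so that one simulated block realizes the design
#' distribution exactly.
#'
#' @param durations Numeric vector of probe durations in ms; strictly
#'   positive and strictly increasing.
#' @param counts Integer vector of per-block presentation counts, one per
#'   duration, each >= 1.
#' @param name Label for the set (e.g. `"PS"`, `"U"`, or any user label).
#' @return A tibble of class `duration_set` with columns `duration_ms` and
#'   `count`, one row per probe duration, carrying the set name and the
#'   standards (min and max duration) as attributes.
#' @examples
#' duration_set(seq(400, 1600, 200), 7:1, name = "DF")
#' @export
duration_set <- function(durations, counts, name = "set") {
  durations <- as.numeric(durations)
  counts <- as.integer(counts)
  if (length(durations) == 0) stop("`durations` must be nonempty", call. = FALSE)
  if (any(!is.finite(durations)) || any(durations <= 0)) {
    stop("all durations must be finite and strictly positive", call. = FALSE)
  }
  if (is.unsorted(durations, strictly = TRUE)) {
    stop("durations must be strictly increasing", call. = FALSE)
  }
  if (length(counts) != length(durations)) {
    stop("`counts` must have one entry per duration", call. = FALSE)
  }
  if (any(is.na(counts)) || any(counts < 1L)) {
    stop("all counts must be integers >= 1", call. = FALSE)
  }
  out <- tibble::tibble(duration_ms = durations, count = counts)
  class(out) <- c("duration_set", class(out))
  attr(out, "set_name") <- as.character(name)[1]
  attr(out, "standards") <- c(short = min(durations), long = max(durations))
  out
}

#' @export
print.duration_set <- function(x, ...) {
  cat(sprintf(
    "<duration_set '%s'> %d durations, block length %d, standards %g/%g ms\n",
    set_name(x), nrow(x), sum(x$count),
    attr(x, "standards")[["short"]], attr(x, "standards")[["long"]]
  ))
  NextMethod()
}

#' @rdname duration_set
#' @param set A `duration_set`.
#' @export
set_name <- function(set) attr(set, "set_name") %||% "set"

#' @rdname duration_set
#' @export
standards <- function(set) {
  s <- attr(set, "standards")
  if (is.null(s)) s <- c(short = min(set$duration_ms), long = max(set$duration_ms))
  s
}

as_duration_set <- function(x, name = NULL) {
  if (inherits(x, "duration_set")) return(x)
  stopifnot(is.data.frame(x), all(c("duration_ms", "count") %in% names(x)))
  duration_set(x$duration_ms, x$count, name = name %||% "set")
}

#' The six built-in duration sets
#'
#' Returns the six session designs used across the three bisection
#' experiments the package models: log-spaced positively (PS) and negatively
#' (NS) skewed sets of seven uniformly presented durations; equally spaced
#' sets with descending (DF) and ascending (AF) presentation frequency; and
#' equally spaced sets with U-shaped (U) and inverted-T-shaped (IT)
#' frequency profiles, which share a mean but differ in spread. PS/NS/DF/AF
#' blocks hold 56 trials; U/IT blocks hold 72.
#'
#' @return A named list of six [duration_set()] objects
#'   (`PS`, `NS`, `DF`, `AF`, `U`, `IT`).
#' @examples
#' ensemble_stats(builtin_sets())
#' @export
builtin_sets <- function() {
  list(
    PS = duration_set(c(400, 504, 636, 800, 1008, 1270, 1600), rep(8L, 7), "PS"),
    NS = duration_set(c(400, 730, 992, 1200, 1366, 1496, 1600), rep(8L, 7), "NS"),
    DF = duration_set(seq(400, 1600, 200), 2L * (7:1), "DF"),
    AF = duration_set(seq(400, 1600, 200), 2L * (1:7), "AF"),
    U  = duration_set(seq(400, 1450, 150), c(30L, 2L, 2L, 2L, 2L, 2L, 2L, 30L), "U"),
    IT = duration_set(seq(400, 1450, 150), c(2L, 2L, 2L, 30L, 30L, 2L, 2L, 2L), "IT")
  )
}

#' Ensemble statistics of a duration set
#'
#' Frequency-weighted summary statistics of the probe-duration distribution,
#' which serve as candidate bisection references: the arithmetic mean
#' `am = sum(f * x) / sum(f)`, the geometric mean
#' `gm = exp(sum(f * log x) / sum(f))`, the population standard deviation
#' `sd = sqrt(sum(f * (x - am)^2) / sum(f))`, and the inverse coefficient of
#' variation `cv_inv = am / sd` (the quantity that scales decision
#' sensitivity under the ensemble-distribution account). The population
#' (divide-by-N) SD is used because the set is a design quantity, not a
#' sample.
#'
#' @param sets A single [duration_set()] or a (named) list of them.
#' @return A tibble with one row per set: `set`, `n_durations`,
#'   `block_length`, `am`, `gm`, `sd`, `cv_inv` (ms where dimensional).
#' @examples
#' ensemble_stats(builtin_sets()$DF)
#' @export
ensemble_stats <- function(sets) {
  if (inherits(sets, "duration_set")) sets <- list(sets)
  purrr::map_dfr(sets, function(s) {
    s <- as_duration_set(s)
    am <- arithmetic_mean(s)
    sd <- ensemble_sd(s)
    tibble::tibble(
      set = set_name(s),
      n_durations = nrow(s),
      block_length = sum(s$count),
      am = am,
      gm = geometric_mean(s),
      sd = sd,
      cv_inv = if (sd > 0) am / sd else Inf
    )
  })
}

#' @rdname ensemble_stats
#' @export
arithmetic_mean <- function(sets) {
  s <- as_duration_set(sets)
  sum(s$count * s$duration_ms) / sum(s$count)
}

#' @rdname ensemble_stats
#' @export
geometric_mean <- function(sets) {
  s <- as_duration_set(sets)
  if (any(s$duration_ms <= 0)) stop("geometric mean needs positive durations", call. = FALSE)
  exp(sum(s$count * log(s$duration_ms)) / sum(s$count))
}

#' @rdname ensemble_stats
#' @export
ensemble_sd <- function(sets) {
  s <- as_duration_set(sets)
  am <- arithmetic_mean(s)
  sqrt(sum(s$count * (s$duration_ms - am)^2) / sum(s$count))
}

#' Read or write a duration-set definition file
#'
#' Plain-text round trip for set designs: a CSV with columns
#' `duration_ms,count`, one row per probe duration. The set name is taken
#' from the file name (without extension) unless given.
#'
#' @param path File path.
#' @param name Optional set label; defaults to the file's base name.
#' @return `read_duration_set()` returns a [duration_set()];
#'   `write_duration_set()` invisibly returns `path`.
#' @export
read_duration_set <- function(path, name = NULL) {
  d <- readr::read_csv(path, col_types = readr::cols(
    duration_ms = readr::col_double(), count = readr::col_integer()
  ))
  duration_set(d$duration_ms, d$count,
               name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' @rdname read_duration_set
#' @param set A [duration_set()] to serialize.
#' @export
write_duration_set <- function(set, path) {
  set <- as_duration_set(set)
  readr::write_csv(tibble::tibble(duration_ms = set$duration_ms, count = set$count), path)
  invisible(path)
}

#' Resolve duration sets for a dataset
#'
#' Matches the `condition` labels of a trial table against a list of
#' registered duration sets, erroring on unknown conditions.
#'
#' @param data A trial table with a `condition` column.
#' @param sets A list of [duration_set()] objects (named, or carrying names).
#' @return Named list of `duration_set`s covering every condition in `data`.
#' @keywords internal
resolve_sets <- function(data, sets) {
  if (inherits(sets, "duration_set")) sets <- list(sets)
  nm <- names(sets)
  if (is.null(nm) || any(nm == "")) nm <- purrr::map_chr(sets, set_name)
  sets <- rlang::set_names(sets, nm)
  conds <- unique(as.character(data$condition))
  missing <- setdiff(conds, nm)
  if (length(missing) > 0) {
    stop("no duration set registered for condition(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sets[conds]
}
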