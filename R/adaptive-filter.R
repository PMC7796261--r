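#' Select a subject's sample cycle
#'
#' From a set of beats acquired at rest (static state), selects the beat
#' whose Euclidean distance to the ideal one-cycle ECG is smallest — the
#' maximum-similarity beat that serves as the subject's normalization
#' template. Ties are broken by the lowest index.
#'
#' @param static_cycles non-empty list of [ecg_cycle] objects, all
#'   length-matched to the ideal cycle.
#' @param ideal an [ideal_cycle] (or numeric waveform) of the same length.
#' @return An object of class `sample_cycle` with elements `samples`,
#'   `subject_id`, `distance_to_ideal` and `index` (position of the chosen
#'   beat in `static_cycles`).
#' @export
select_sample_cycle <- function(static_cycles, ideal) {
  if (length(static_cycles) < 1L)
    stop("`static_cycles` must be non-empty", call. = FALSE)
  y <- if (inherits(ideal, c("ideal_cycle", "ecg_cycle"))) ideal$samples
       else as.numeric(ideal)
  d <- vapply(static_cycles, function(cy) {
    if (length(cy$samples) != length(y))
      stop("cycles must be length-matched to the ideal cycle", call. = FALSE)
    dist_euclidean(cy$samples, y)
  }, numeric(1))
  i <- which.min(d) # which.min returns the first (lowest-index) minimum
  cy <- static_cycles[[i]]
  structure(list(samples = cy$samples, fs = cy$fs, r_index = cy$r_index,
                 subject_id = cy$subject_id, distance_to_ideal = d[i],
                 index = i),
            class = c("sample_cycle", "ecg_cycle"))
}

#' @export
print.sample_cycle <- function(x, ...) {
  cat(sprintf("<sample_cycle> subject %s, distance to ideal %.4g mV (beat #%d)\n",
              x$subject_id, x$distance_to_ideal, x$index))
  invisible(x)
}

#' Similarity profile of a cycle set against a sample cycle
#'
#' Computes the per-beat Euclidean distance `S` of each cycle to the
#' subject's sample cycle, together with its minimum `k` and maximum `l`.
#' The adaptive threshold `Th` lives on the integer grid `0, 1, ...,
#' ceiling(l - k)` spanned by these bounds. When the spread `l - k` of raw
#' distances is below one (so the integer grid would be degenerate) and
#' `unit = "auto"`, the profile is expressed instead as a percentage
#' dissimilarity `100 - to_percent(S, median(S))`, where integer steps are
#' one percentage point.
#'
#' @param cycles non-empty list of [ecg_cycle] objects (all length-matched
#'   to the sample cycle), or directly a numeric vector of distances.
#' @param sample a [sample_cycle] (ignored when `cycles` is numeric).
#' @param unit `"auto"`, `"distance"` (raw mV distances) or `"percent"`.
#' @return An object of class `similarity_profile` with elements `S`, `k`,
#'   `l`, `unit` and `grid` (the admissible integer thresholds).
#' @export
similarity_profile <- function(cycles, sample = NULL,
                               unit = c("auto", "distance", "percent")) {
  unit <- match.arg(unit)
  if (is.numeric(cycles)) {
    S <- as.numeric(cycles)
    if (!length(S)) stop("`cycles` must be non-empty", call. = FALSE)
  } else {
    if (length(cycles) < 1L)
      stop("`cycles` must be non-empty", call. = FALSE)
    stopifnot(!is.null(sample))
    S <- vapply(cycles, function(cy)
      dist_euclidean(cy$samples, sample$samples), numeric(1))
  }
  if (unit == "percent" || (unit == "auto" && diff(range(S)) < 1 &&
                            any(S > 0))) {
    scale <- stats::median(S[S > 0])
    if (is.finite(scale) && scale > 0) {
      S <- 100 - to_percent(S, scale)
      unit <- "percent"
    } else unit <- "distance"
  } else if (unit == "auto") unit <- "distance"
  k <- min(S); l <- max(S)
  structure(list(S = S, k = k, l = l, unit = unit,
                 grid = 0:(ceiling(l - k) + 1L)),
            class = "similarity_profile")
}

#' @export
print.similarity_profile <- function(x, ...) {
  cat(sprintf("<similarity_profile> %d cycle(s), S in [%.4g, %.4g] (%s units), Th grid 0..%d\n",
              length(x$S), x$k, x$l, x$unit, max(x$grid)))
  invisible(x)
}

#' Filter beats by the adaptive threshold
#'
#' Keeps the beats whose similarity value satisfies `S < k + Th`, where `k`
#' is the minimum of `S` and `Th` is an integer threshold on the profile's
#' grid. At `Th = 0` the strict rule would keep nothing, so the
#' minimum-distance beat(s) are always retained — downstream
#' classification never receives an empty set. The kept count is
#' non-decreasing in `Th`, and any `Th > l - k` keeps every beat.
#'
#' @param profile a [similarity_profile].
#' @param cycles the cycle list the profile was computed from (optional;
#'   kept cycles are returned when provided).
#' @param Th non-negative integer threshold.
#' @return An object of class `normalized_set` with elements `kept_indices`,
#'   `cycles` (possibly `NULL`), `S`, `Th`, `pass_rate` and `n_total`.
#' @export
filter_cycles <- function(profile, cycles = NULL, Th) {
  if (Th < 0) stop("`Th` must be a non-negative integer", call. = FALSE)
  Th <- as.integer(round(Th))
  S <- profile$S
  keep <- S < profile$k + Th
  keep[S == profile$k] <- TRUE # non-empty guard: argmin always kept
  idx <- which(keep)
  structure(
    list(kept_indices = idx,
         cycles = if (!is.null(cycles)) cycles[idx] else NULL,
         S = S, Th = Th,
         pass_rate = length(idx) / length(S),
         n_total = length(S)),
    class = "normalized_set")
}

#' @export
print.normalized_set <- function(x, ...) {
  cat(sprintf("<normalized_set> kept %d / %d cycle(s) at Th = %d (pass rate %.1f%%)\n",
              length(x$kept_indices), x$n_total, x$Th, 100 * x$pass_rate))
  invisible(x)
}

#' Choose the smallest threshold reaching a pass rate
#'
#' Sweeps the integer threshold grid and returns the smallest `Th` whose
#' pass rate (fraction of beats kept, the permit similarity rate) reaches
#' `min_pass`. The top of the grid keeps every beat, so a solution always
#' exists.
#'
#' @param profile a [similarity_profile].
#' @param min_pass required pass rate in `(0, 1]`.
#' @return Integer threshold.
#' @export
choose_threshold <- function(profile, min_pass) {
  if (min_pass <= 0 || min_pass > 1)
    stop("`min_pass` must lie in (0, 1]", call. = FALSE)
  for (Th in profile$grid) {
    if (filter_cycles(profile, Th = Th)$pass_rate >= min_pass) return(Th)
  }
  max(profile$grid)
}

#' Report kept/rejected beats as a data frame
#'
#' @param nset a `normalized_set` from [filter_cycles].
#' @return Data frame with columns `cycle_id`, `S`, `kept`.
#' @export
normalization_report <- function(nset) {
  data.frame(cycle_id = seq_along(nset$S), S = nset$S,
             kept = seq_along(nset$S) %in% nset$kept_indices)
}
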