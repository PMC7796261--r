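#' Single-lead ECG record
#'
#' Container for a single-lead (Lead-I) ECG time series: a numeric vector of
#' voltages in millivolts, the sampling rate in Hz, optional subject and
#' acquisition-condition labels, and optional R-peak annotations.
#'
#' Annotations are 1-based sample indices of R peaks, strictly increasing and
#' inside the record.
#'
#' @param samples numeric vector of voltages (mV); must be finite.
#' @param fs sampling rate in Hz; must be positive.
#' @param subject_id optional subject label.
#' @param condition optional acquisition condition
#'   (`"sit"`, `"slide_touch"`, `"post_exercise"`, `"driving"`).
#' @param annotations optional integer vector of R-peak sample indices
#'   (1-based), strictly increasing.
#' @return An object of class `ecg_record`.
#' @examples
#' rec <- ecg_record(sin(2 * pi * 1.2 * seq(0, 10, by = 1 / 250)), fs = 250)
#' rec
#' @export
ecg_record <- function(samples, fs, subject_id = NA_character_,
                       condition = NA_character_, annotations = NULL) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  if (any(!is.finite(samples)))
    stop("`samples` must be finite", call. = FALSE)
  if (!is.null(annotations)) {
    annotations <- as.integer(annotations)
    if (length(annotations) &&
        (any(annotations < 1L) || any(annotations > length(samples)) ||
         any(diff(annotations) <= 0L)))
      stop("`annotations` must be strictly increasing sample indices inside the record",
           call. = FALSE)
  }
  structure(
    list(samples = samples, fs = fs,
         subject_id = as.character(subject_id),
         condition = as.character(condition),
         annotations = annotations),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  dur <- length(x$samples) / x$fs
  cat(sprintf("<ecg_record> %d samples @ %g Hz (%.1f s)\n",
              length(x$samples), x$fs, dur))
  if (!is.na(x$subject_id)) cat("  subject:  ", x$subject_id, "\n", sep = "")
  if (!is.na(x$condition))  cat("  condition:", x$condition, "\n")
  if (!is.null(x$annotations))
    cat(sprintf("  R peaks:   %d annotated\n", length(x$annotations)))
  invisible(x)
}

#' @export
length.ecg_record <- function(x) length(x$samples)

# Replace samples while keeping fs/labels/annotations; internal.
set_samples <- function(record, samples) {
  stopifnot(length(samples) == length(record$samples))
  record$samples <- as.numeric(samples)
  record
}

#' Detected R-peak set
#'
#' R-peak sample indices (1-based) with their sampling rate. Indices are
#' strictly increasing and at least one refractory period (0.2 s) apart.
#'
#' @param indices integer vector of R-peak sample indices (1-based).
#' @param fs sampling rate in Hz.
#' @return An object of class `rpeak_set`.
#' @export
rpeak_set <- function(indices, fs) {
  indices <- as.integer(indices)
  if (length(indices) && any(diff(indices) <= 0L))
    stop("R-peak indices must be strictly increasing", call. = FALSE)
  if (length(indices) > 1L && any(diff(indices) < 0.2 * fs))
    stop("consecutive R peaks violate the 0.2 s refractory period", call. = FALSE)
  structure(list(indices = indices, fs = fs), class = "rpeak_set")
}

#' @export
print.rpeak_set <- function(x, ...) {
  cat(sprintf("<rpeak_set> %d peaks @ %g Hz", length(x$indices), x$fs))
  if (length(x$indices) > 1L) {
    rr <- diff(x$indices) / x$fs
    cat(sprintf(" (mean HR %.1f bpm)", 60 / mean(rr)))
  }
  cat("\n")
  invisible(x)
}

#' Single ECG beat (one cycle)
#'
#' A fixed-window beat cut around an R peak. `r_index` is the 0-based offset
#' of the R peak inside the window, i.e. the number of samples to the left of
#' R; with the default 0.3 s pre-window this is `round(0.3 * fs)` (sample
#' `r_index + 1` of the vector in R's 1-based indexing).
#'
#' @param samples numeric waveform (mV).
#' @param fs sampling rate in Hz.
#' @param r_index 0-based offset of the R peak inside the window.
#' @param subject_id,condition optional labels.
#' @param peaks optional named list with numeric vectors `voltage` and
#'   `location` (0-based sample offsets), each named `P,Q,R,S,T`.
#' @return An object of class `ecg_cycle`.
#' @export
ecg_cycle <- function(samples, fs, r_index, subject_id = NA_character_,
                      condition = NA_character_, peaks = NULL) {
  samples <- as.numeric(samples)
  r_index <- as.integer(r_index)
  if (r_index < 0L || r_index >= length(samples))
    stop("`r_index` must lie inside the window", call. = FALSE)
  structure(
    list(samples = samples, fs = fs, r_index = r_index,
         subject_id = as.character(subject_id),
         condition = as.character(condition), peaks = peaks),
    class = "ecg_cycle"
  )
}

#' @export
print.ecg_cycle <- function(x, ...) {
  cat(sprintf("<ecg_cycle> %d samples @ %g Hz, R at offset %d\n",
              length(x$samples), x$fs, x$r_index))
  invisible(x)
}

#' Stack a list of cycles into a matrix
#'
#' @param cycles list of [ecg_cycle] objects of equal length.
#' @return Numeric matrix, one row per cycle.
#' @export
cycles_to_matrix <- function(cycles) {
  stopifnot(length(cycles) > 0L)
  lens <- vapply(cycles, function(cy) length(cy$samples), integer(1))
  if (length(unique(lens)) != 1L)
    stop("cycles have unequal lengths; match_length() them first", call. = FALSE)
  m <- do.call(rbind, lapply(cycles, function(cy) cy$samples))
  rownames(m) <- vapply(cycles, function(cy) cy$subject_id, character(1))
  m
}
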