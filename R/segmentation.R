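#' Cut an ECG record into fixed-window beats
#'
#' Fiducial segmentation: one window per R peak, spanning `pre` seconds to
#' the left of R (the P-wave side) and `post` seconds to the right (the
#' T-wave side). With the defaults at 2000 Hz every beat is
#' `round(0.3 * fs) + round(0.4 * fs) = 1400` samples with R at 0-based
#' offset 600. Beats whose window does not fit inside the record are
#' dropped (the count is reported via a message).
#'
#' @param record an [ecg_record].
#' @param peaks an [rpeak_set].
#' @param pre seconds included left of each R peak (default 0.3).
#' @param post seconds included right of each R peak (default 0.4).
#' @return List of [ecg_cycle] objects.
#' @export
segment_cycles <- function(record, peaks, pre = 0.3, post = 0.4) {
  if (pre <= 0 || post <= 0)
    stop("`pre` and `post` must be positive", call. = FALSE)
  if (!length(peaks$indices)) {
    warning("empty R-peak set: no cycles segmented", call. = FALSE)
    return(list())
  }
  fs <- record$fs
  n_pre <- round(pre * fs)
  n_post <- round(post * fs)
  n <- length(record$samples)
  out <- list()
  dropped <- 0L
  for (r in peaks$indices) {
    start <- r - n_pre
    end <- r + n_post - 1L
    if (start < 1L || end > n) { dropped <- dropped + 1L; next }
    out[[length(out) + 1L]] <- ecg_cycle(
      record$samples[start:end], fs, r_index = n_pre,
      subject_id = record$subject_id, condition = record$condition)
  }
  if (dropped > 0L)
    message(sprintf("segment_cycles: dropped %d beat(s) at record edges", dropped))
  out
}

#' Resample a beat to a target length
#'
#' Linearly interpolates the waveform onto a uniform grid of
#' `target_length` samples so beats can be compared with the ideal cycle at
#' the same size. The first and last samples are preserved and the R offset
#' is rescaled proportionally. A call with the current length returns the
#' cycle unchanged.
#'
#' @param cycle an [ecg_cycle].
#' @param target_length desired number of samples (>= 2).
#' @return The resampled [ecg_cycle].
#' @export
match_length <- function(cycle, target_length) {
  if (target_length < 2)
    stop("`target_length` must be at least 2", call. = FALSE)
  n <- length(cycle$samples)
  if (n == target_length) return(cycle)
  y <- stats::approx(seq(0, 1, length.out = n), cycle$samples,
                     xout = seq(0, 1, length.out = target_length))$y
  cycle$samples <- y
  cycle$fs <- cycle$fs * (target_length - 1) / (n - 1)
  cycle$r_index <- as.integer(round(cycle$r_index * (target_length - 1) / (n - 1)))
  cycle
}

#' Write / read a cycle set as matrix CSV
#'
#' Serializes equal-length cycles as a matrix CSV (one row per beat) plus a
#' sidecar metadata CSV (`subject_id`, `condition`, `fs`, `r_index`).
#'
#' @param cycles list of equal-length [ecg_cycle] objects.
#' @param path path of the matrix CSV; metadata goes to
#'   `<path minus extension>_meta.csv`.
#' @return `write_cycles` returns `path` invisibly; `read_cycles` returns a
#'   list of [ecg_cycle] objects.
#' @export
write_cycles <- function(cycles, path) {
  m <- cycles_to_matrix(cycles)
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  meta <- data.frame(
    subject_id = vapply(cycles, function(cy) cy$subject_id, character(1)),
    condition = vapply(cycles, function(cy) cy$condition, character(1)),
    fs = vapply(cycles, function(cy) cy$fs, numeric(1)),
    r_index = vapply(cycles, function(cy) cy$r_index, integer(1)))
  utils::write.csv(meta, meta_path(path), row.names = FALSE)
  invisible(path)
}

#' @rdname write_cycles
#' @export
read_cycles <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ","))
  meta <- utils::read.csv(meta_path(path))
  lapply(seq_len(nrow(m)), function(i)
    ecg_cycle(as.numeric(m[i, ]), fs = meta$fs[i], r_index = meta$r_index[i],
              subject_id = meta$subject_id[i], condition = meta$condition[i]))
}

meta_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), "_meta.csv")
}
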