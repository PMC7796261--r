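#' Zero-phase Butterworth bandpass filter
#'
#' Removes low-frequency drift and high-frequency noise with a zero-phase
#' (forward-backward) Butterworth bandpass. The record mean is subtracted
#' before filtering; length, sampling rate and labels are preserved.
#'
#' @param record an [ecg_record].
#' @param low,high cutoff frequencies in Hz, `0 < low < high < fs/2`.
#' @param order filter order (applied twice by the forward-backward pass).
#' @return The filtered [ecg_record].
#' @export
bandpass <- function(record, low = 0.5, high = 40, order = 4) {
  fs <- record$fs
  if (low <= 0 || high <= low || high >= fs / 2)
    stop("cutoffs must satisfy 0 < low < high < fs/2", call. = FALSE)
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  x <- record$samples - mean(record$samples)
  set_samples(record, signal::filtfilt(bf, x))
}

#' Detect R peaks (Pan-Tompkins)
#'
#' QRS detection by the Pan-Tompkins stages: 5-15 Hz bandpass, centered
#' five-point derivative, squaring, 150 ms moving-window integration, and
#' adaptive dual thresholds with search-back and a 0.2 s refractory period.
#' Each detection is snapped to the local maximum of the input samples
#' within +/- 25 ms. Detection is deterministic.
#'
#' @param record an [ecg_record] of at least 2 s.
#' @return An [rpeak_set].
#' @export
detect_r_peaks <- function(record) {
  fs <- record$fs
  x <- record$samples
  if (length(x) < 2 * fs)
    stop("record shorter than 2 s: insufficient data for QRS detection",
         call. = FALSE)
  if (max(abs(x - mean(x))) < 1e-12) return(rpeak_set(integer(0), fs))

  bf <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  xb <- signal::filtfilt(bf, x - mean(x))
  # centered five-point derivative (zero group delay)
  d <- stats::filter(xb, c(1, 2, 0, -2, -1) * fs / 8, sides = 2)
  d[is.na(d)] <- 0
  sq <- as.numeric(d)^2
  # centered moving-window integration, 150 ms
  nw <- max(3L, round(0.15 * fs))
  mwi <- stats::filter(sq, rep(1 / nw, nw), sides = 2)
  mwi[is.na(mwi)] <- 0
  mwi <- as.numeric(mwi)

  # candidate peaks of the integrated signal
  cand <- local_maxima(mwi, min_dist = round(0.2 * fs))
  if (!length(cand)) return(rpeak_set(integer(0), fs))

  # robust threshold initialization from the candidate amplitude
  # distribution of the whole record (offline detector): quantiles are
  # insensitive to a motion burst landing in any particular stretch
  spki <- unname(stats::quantile(mwi[cand], 0.90))
  npki <- unname(stats::quantile(mwi[cand], 0.50))
  thr1 <- npki + 0.25 * (spki - npki)
  refr <- round(0.2 * fs)
  qrs <- integer(0)
  rr_avg <- NA_real_
  last_q <- -Inf
  i <- 1L
  while (i <= length(cand)) {
    p <- cand[i]
    a <- mwi[p]
    if (a > thr1 && (p - last_q) > refr) {
      qrs <- c(qrs, p)
      if (length(qrs) > 1L) {
        rrs <- diff(utils::tail(qrs, 9L))
        rr_avg <- mean(rrs)
      }
      last_q <- p
      # clip outlier amplitudes (artifact bursts) so they cannot run the
      # signal threshold away from genuine QRS energy
      spki <- 0.125 * min(a, 4 * spki) + 0.875 * spki
    } else {
      npki <- 0.125 * a + 0.875 * npki
      # search-back: no QRS for 1.66 * average RR -> accept the largest
      # candidate above the lower threshold in the gap
      if (!is.na(rr_avg) && (p - last_q) > 1.66 * rr_avg) {
        gap <- cand[cand > last_q + refr & cand <= p]
        if (length(gap)) {
          gap <- gap[mwi[gap] > 0.5 * thr1]
          if (length(gap)) {
            pb <- gap[which.max(mwi[gap])]
            qrs <- sort(c(qrs, pb))
            last_q <- max(qrs)
            spki <- 0.25 * mwi[pb] + 0.75 * spki
          }
        }
      }
    }
    thr1 <- npki + 0.25 * (spki - npki)
    i <- i + 1L
  }
  # final search-back over the tail of the record
  if (length(qrs) && !is.na(rr_avg) &&
      (length(mwi) - max(qrs)) > 1.66 * rr_avg) {
    gap <- cand[cand > max(qrs) + refr]
    gap <- gap[mwi[gap] > 0.5 * thr1]
    if (length(gap)) qrs <- sort(c(qrs, gap[which.max(mwi[gap])]))
  }
  if (!length(qrs)) return(rpeak_set(integer(0), fs))

  # snap each detection to the local maximum of the input within +/- 25 ms
  snap <- round(0.025 * fs)
  snap <- as.integer(snap)
  peaks <- vapply(as.integer(qrs), function(p) {
    lo <- max(1L, p - snap); hi <- min(length(x), p + snap)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  peaks <- sort(unique(peaks))
  # enforce the refractory period after snapping (keep the larger peak)
  keep <- rep(TRUE, length(peaks))
  j <- 1L
  for (k in seq_along(peaks)[-1]) {
    if (peaks[k] - peaks[j] < refr) {
      if (x[peaks[k]] > x[peaks[j]]) { keep[j] <- FALSE; j <- k }
      else keep[k] <- FALSE
    } else j <- k
  }
  rpeak_set(peaks[keep], fs)
}

# indices of strict local maxima separated by at least min_dist samples
local_maxima <- function(v, min_dist) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  idx <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  if (!length(idx)) return(integer(0))
  ord <- idx[order(v[idx], decreasing = TRUE)]
  taken <- integer(0)
  for (p in ord)
    if (!length(taken) || all(abs(taken - p) >= min_dist))
      taken <- c(taken, p)
  sort(taken)
}

#' Moving-average smoothing that spares the QRS complex
#'
#' Applies a centered moving average everywhere except inside the windows
#' `[R - qrs_halfwidth, R + qrs_halfwidth]` around each detected R peak,
#' which are left bit-identical: the QRS complex carries the
#' subject-specific morphology and must not be blurred.
#'
#' @param record an [ecg_record].
#' @param peaks an [rpeak_set] for the record.
#' @param window moving-average length in seconds.
#' @param qrs_halfwidth protected half-width around each R peak, seconds.
#' @return The smoothed [ecg_record].
#' @export
smooth_outside_qrs <- function(record, peaks, window = 0.025,
                               qrs_halfwidth = 0.060) {
  if (window <= 0 || qrs_halfwidth <= 0)
    stop("`window` and `qrs_halfwidth` must be positive", call. = FALSE)
  fs <- record$fs
  x <- record$samples
  nw <- max(1L, round(window * fs))
  sm <- as.numeric(stats::filter(x, rep(1 / nw, nw), sides = 2))
  # centered filter leaves NAs at the edges; keep the original there
  sm[is.na(sm)] <- x[is.na(sm)]
  if (!length(peaks$indices)) {
    warning("empty R-peak set: smoothing the whole record", call. = FALSE)
    return(set_samples(record, sm))
  }
  hw <- round(qrs_halfwidth * fs)
  protect <- unique(unlist(lapply(peaks$indices, function(r)
    max(1L, r - hw):min(length(x), r + hw))))
  sm[protect] <- x[protect]
  set_samples(record, sm)
}

#' Remove baseline wander by piecewise linear regression
#'
#' Estimates the slow baseline from knots placed 66% of the way through
#' each RR interval (the TP segment, where the trace rests at baseline),
#' valued at the local 50 ms median, connects them by first-order (linear)
#' segments, and subtracts the result so the trace is calibrated to zero.
#'
#' @param record an [ecg_record].
#' @param peaks an [rpeak_set] with at least two peaks.
#' @return The baseline-corrected [ecg_record].
#' @export
remove_baseline <- function(record, peaks) {
  r <- peaks$indices
  if (length(r) < 2L)
    stop("at least two R peaks are required for baseline removal",
         call. = FALSE)
  fs <- record$fs
  x <- record$samples
  n <- length(x)
  knots <- round(r[-length(r)] + 0.66 * diff(r))
  hw <- max(1L, round(0.025 * fs))
  vals <- vapply(knots, function(k) {
    lo <- max(1L, k - hw); hi <- min(n, k + hw)
    stats::median(x[lo:hi])
  }, numeric(1))
  if (length(knots) == 1L) {
    base <- rep(vals, n)
  } else {
    base <- stats::approx(knots, vals, xout = seq_len(n), rule = 2)$y
  }
  set_samples(record, x - base)
}

#' Run the full denoising chain
#'
#' Frequency filter, R-peak detection, QRS-sparing smoothing and baseline
#' removal, in that order. Returns the cleaned record together with the
#' detected peaks.
#'
#' @param record an [ecg_record].
#' @param config a [pipeline_config] (only the preprocessing fields are
#'   used).
#' @return List with elements `record` (cleaned [ecg_record]) and `peaks`
#'   (an [rpeak_set]).
#' @export
preprocess_record <- function(record, config = pipeline_config(fs = record$fs)) {
  rec <- bandpass(record, config$bandpass_low, config$bandpass_high,
                  config$bandpass_order)
  peaks <- detect_r_peaks(rec)
  if (length(peaks$indices)) {
    rec <- smooth_outside_qrs(rec, peaks, config$smooth_window,
                              config$qrs_halfwidth)
  }
  if (length(peaks$indices) >= 2L) rec <- remove_baseline(rec, peaks)
  list(record = rec, peaks = peaks)
}
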