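#' Averaged P,Q,R,S,T peak statistics
#'
#' Mean voltage and mean sample location of the five characteristic peaks of
#' one cardiac cycle, averaged over a set of annotated beats. Locations are
#' 0-based sample offsets within the beat window and must be strictly ordered
#' P < Q < R < S < T; the R voltage must be the maximum of the five.
#'
#' @param voltage named numeric vector (`P,Q,R,S,T`), mean voltages in mV.
#' @param location named numeric vector (`P,Q,R,S,T`), mean 0-based sample
#'   locations.
#' @param n_cycles number of beats averaged.
#' @return An object of class `peak_stats`.
#' @export
peak_stats <- function(voltage, location, n_cycles = 1L) {
  waves <- c("P", "Q", "R", "S", "T")
  voltage <- voltage[waves]
  location <- location[waves]
  if (any(is.na(voltage)) || any(is.na(location)))
    stop("`voltage` and `location` must both be named P,Q,R,S,T", call. = FALSE)
  if (any(diff(location) <= 0))
    stop("peak locations must be strictly ordered P < Q < R < S < T", call. = FALSE)
  if (voltage[["R"]] < max(voltage))
    stop("R voltage must be the maximum of the five peak voltages", call. = FALSE)
  structure(list(voltage = voltage, location = location,
                 n_cycles = as.integer(n_cycles)),
            class = "peak_stats")
}

#' @export
print.peak_stats <- function(x, ...) {
  cat(sprintf("<peak_stats> averaged over %d cycle(s)\n", x$n_cycles))
  df <- data.frame(wave = names(x$voltage),
                   mean_voltage_mv = unname(x$voltage),
                   mean_location_sample = unname(x$location))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Average peak information over annotated beats
#'
#' Computes, for each of the P, Q, R, S and T waves, the arithmetic mean of
#' the annotated peak voltage and sample location across a set of beats.
#'
#' @param cycles list of [ecg_cycle] objects, each carrying a `peaks`
#'   annotation with `voltage` and `location` entries for all five waves.
#' @return A [peak_stats] object with `n_cycles` set.
#' @export
compute_peak_stats <- function(cycles) {
  if (length(cycles) < 1L)
    stop("at least one annotated cycle is required", call. = FALSE)
  waves <- c("P", "Q", "R", "S", "T")
  volt <- matrix(NA_real_, length(cycles), 5L, dimnames = list(NULL, waves))
  loc <- volt
  for (i in seq_along(cycles)) {
    pk <- cycles[[i]]$peaks
    for (w in waves) {
      if (is.null(pk) || is.na(pk$voltage[w]) || is.na(pk$location[w]))
        stop(sprintf("cycle %d is missing the %s peak annotation", i, w),
             call. = FALSE)
    }
    volt[i, ] <- pk$voltage[waves]
    loc[i, ] <- pk$location[waves]
  }
  peak_stats(colMeans(volt), colMeans(loc), n_cycles = length(cycles))
}

#' Interpolate between two peaks
#'
#' Bridges the segment between two vertices `(x1, y1)` and `(x2, y2)` on the
#' sample grid `n`. The slope is `w = (y2 - y1) / (x2 - x1)`. Order 1 gives
#' the straight line `y1 + w * (n - x1)`. Order 2 gives the normalized
#' quadratic `y1 + (y2 - y1) * ((n - x1) / (x2 - x1))^2`, which leaves the
#' first vertex flat and accelerates into the second; both orders reproduce
#' `y1` at `n = x1` and `y2` at `n = x2` exactly.
#'
#' @param x1,y1 first vertex (sample location, mV).
#' @param x2,y2 second vertex; `x2 > x1` required.
#' @param order 1 (linear) or 2 (quadratic).
#' @param n numeric vector of sample locations at which to evaluate.
#' @return Numeric vector of interpolated voltages at `n`.
#' @examples
#' interpolate_segment(0, 0, 2, 4, order = 1, n = 0:2) # 0 2 4
#' @export
interpolate_segment <- function(x1, y1, x2, y2, order, n) {
  if (x2 <= x1)
    stop("degenerate segment: `x2` must exceed `x1`", call. = FALSE)
  if (!order %in% c(1, 2))
    stop("`order` must be 1 or 2", call. = FALSE)
  t <- (n - x1) / (x2 - x1)
  if (order == 1) y1 + (y2 - y1) * t else y1 + (y2 - y1) * t^2
}

# Default per-segment interpolation orders: rounded waves get the quadratic
# bridge, the straight QRS limbs the linear one.
default_order_map <- function() {
  c(onset = 2, pq = 2, qr = 1, rs = 1, st = 2, offset = 2)
}

#' Generate the ideal one-cycle ECG
#'
#' Builds a noise-free single-beat waveform that passes exactly through the
#' five averaged P,Q,R,S,T vertices of `stats`, connecting them (and the
#' 0 mV baseline at the window edges) with first- or second-order
#' interpolated bridges.
#'
#' @param stats a [peak_stats] object.
#' @param target_length total waveform length in samples; must cover the
#'   vertex span.
#' @param order_map named numeric vector assigning interpolation order (1 or
#'   2) to segments `onset` (window start to P), `pq`, `qr`, `rs`, `st` and
#'   `offset` (T to window end). Defaults to quadratic bridges for the
#'   rounded waves and linear limbs for Q-R and R-S.
#' @return An object of class `ideal_cycle` with elements `samples`,
#'   `length`, `peak_indices` (0-based vertex locations) and `fs` (`NA`
#'   unless supplied downstream).
#' @export
generate_ideal_cycle <- function(stats, target_length,
                                 order_map = default_order_map()) {
  stopifnot(inherits(stats, "peak_stats"))
  loc <- round(stats$location)
  v <- stats$voltage
  if (target_length < loc[["T"]] - loc[["P"]])
    stop("`target_length` is shorter than the P-to-T vertex span", call. = FALSE)
  if (loc[["T"]] > target_length - 1)
    stop("`target_length` must cover the T-peak location", call. = FALSE)
  om <- default_order_map()
  om[names(order_map)] <- order_map
  # vertex chain including baseline anchors at the window edges
  xs <- c(0, loc)
  ys <- c(0, v)
  seg_order <- c(om[["onset"]], om[["pq"]], om[["qr"]], om[["rs"]], om[["st"]])
  if (loc[["P"]] == 0) { xs <- xs[-1]; ys <- ys[-1]; seg_order <- seg_order[-1] }
  xs <- c(xs, target_length - 1)
  ys <- c(ys, 0)
  seg_order <- c(seg_order, om[["offset"]])
  if (loc[["T"]] == target_length - 1) {
    xs <- xs[-length(xs)]; ys <- ys[-length(ys)]
    seg_order <- seg_order[-length(seg_order)]
  }
  out <- numeric(target_length)
  for (s in seq_len(length(xs) - 1L)) {
    grid <- xs[s]:xs[s + 1L]
    out[grid + 1L] <- interpolate_segment(xs[s], ys[s], xs[s + 1L], ys[s + 1L],
                                          order = seg_order[s], n = grid)
  }
  # vertices are exact by construction; enforce against rounding of the grid
  out[loc + 1L] <- v
  structure(list(samples = out, length = target_length,
                 peak_indices = loc, fs = NA_real_),
            class = "ideal_cycle")
}

#' @export
print.ideal_cycle <- function(x, ...) {
  cat(sprintf("<ideal_cycle> %d samples; vertices at %s\n", x$length,
              paste(sprintf("%s=%d", names(x$peak_indices), x$peak_indices),
                    collapse = " ")))
  invisible(x)
}

#' Typical adult peak statistics for a given sampling rate
#'
#' A package-chosen, population-typical set of P,Q,R,S,T vertex voltages and
#' locations for a 0.7 s beat window with R placed 0.3 s from the window
#' start. These are synthetic defaults representative of normal sinus rhythm
#' morphology; any [peak_stats] computed from annotated data can be used in
#' their place.
#'
#' @param fs sampling rate in Hz.
#' @return A [peak_stats] object on the sample grid of `fs`.
#' @export
default_peak_stats <- function(fs) {
  peak_stats(
    voltage = c(P = 0.15, Q = -0.15, R = 1.10, S = -0.25, T = 0.35),
    location = round(c(P = 0.13, Q = 0.26, R = 0.30, S = 0.34, T = 0.52) * fs),
    n_cycles = 1L
  )
}

#' Write / read peak statistics as CSV
#'
#' Serializes a [peak_stats] object to a three-column CSV
#' (`wave`, `mean_voltage_mv`, `mean_location_sample`).
#'
#' @param stats a [peak_stats] object.
#' @param path file path.
#' @return `write_peak_stats` returns `path` invisibly; `read_peak_stats`
#'   returns a [peak_stats] object.
#' @export
write_peak_stats <- function(stats, path) {
  df <- data.frame(wave = names(stats$voltage),
                   mean_voltage_mv = unname(stats$voltage),
                   mean_location_sample = unname(stats$location),
                   n_cycles = stats$n_cycles)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peak_stats
#' @export
read_peak_stats <- function(path) {
  df <- utils::read.csv(path)
  peak_stats(stats::setNames(df$mean_voltage_mv, df$wave),
             stats::setNames(df$mean_location_sample, df$wave),
             n_cycles = df$n_cycles[1])
}
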