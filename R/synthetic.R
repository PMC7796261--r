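#' Per-subject ECG morphology template
#'
#' Describes a subject's beat morphology as the five P,Q,R,S,T peak voltages
#' (mV) and their time offsets relative to the R peak (seconds, R at 0),
#' together with the resting heart rate and the fractional standard
#' deviation of the RR interval.
#'
#' @param subject_id subject label.
#' @param peak_voltages named numeric vector (`P,Q,R,S,T`), mV; R must be
#'   the strict maximum.
#' @param peak_offsets named numeric vector (`P,Q,R,S,T`), seconds relative
#'   to R; must be strictly ordered with `R = 0`.
#' @param heart_rate beats per minute, in \[40, 180\].
#' @param hr_jitter fractional standard deviation of the RR interval.
#' @return An object of class `subject_template`.
#' @export
subject_template <- function(subject_id, peak_voltages, peak_offsets,
                             heart_rate, hr_jitter = 0.03) {
  waves <- c("P", "Q", "R", "S", "T")
  peak_voltages <- peak_voltages[waves]
  peak_offsets <- peak_offsets[waves]
  if (any(is.na(peak_voltages)) || any(is.na(peak_offsets)))
    stop("peak voltages and offsets must be named P,Q,R,S,T", call. = FALSE)
  if (peak_voltages[["R"]] <= max(peak_voltages[setdiff(waves, "R")]))
    stop("R voltage must strictly exceed the other peak voltages", call. = FALSE)
  if (any(diff(peak_offsets) <= 0) || peak_offsets[["R"]] != 0)
    stop("peak offsets must be strictly ordered P < Q < R(=0) < S < T", call. = FALSE)
  if (heart_rate < 40 || heart_rate > 180)
    stop("`heart_rate` must lie in [40, 180] bpm", call. = FALSE)
  if (hr_jitter < 0)
    stop("`hr_jitter` must be non-negative", call. = FALSE)
  structure(list(subject_id = as.character(subject_id),
                 peak_voltages = peak_voltages, peak_offsets = peak_offsets,
                 heart_rate = heart_rate, hr_jitter = hr_jitter),
            class = "subject_template")
}

#' @export
print.subject_template <- function(x, ...) {
  cat(sprintf("<subject_template> %s: HR %.0f bpm (jitter %.1f%%)\n",
              x$subject_id, x$heart_rate, 100 * x$hr_jitter))
  cat("  voltages (mV):",
      paste(sprintf("%s=%.2f", names(x$peak_voltages), x$peak_voltages),
            collapse = " "), "\n")
  invisible(x)
}

#' Generate a seeded cohort of subject templates
#'
#' Draws `n_subjects` morphology templates with per-subject peak voltages,
#' peak timings and heart rates. Generation is deterministic under `seed`
#' and templates differ pairwise in their peak-voltage vectors.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param seed integer RNG seed.
#' @return List of [subject_template] objects.
#' @export
make_cohort <- function(n_subjects, seed = 1L) {
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop("`n_subjects` must be a positive count", call. = FALSE)
  n_subjects <- as.integer(n_subjects)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lapply(seq_len(n_subjects), function(i) {
    repeat {
      v <- c(P = stats::rnorm(1, 0.15, 0.04),
             Q = stats::rnorm(1, -0.15, 0.05),
             R = stats::rnorm(1, 1.10, 0.15),
             S = stats::rnorm(1, -0.25, 0.08),
             T = stats::rnorm(1, 0.35, 0.08))
      o <- c(P = stats::rnorm(1, -0.17, 0.015),
             Q = stats::rnorm(1, -0.040, 0.005),
             R = 0,
             S = stats::rnorm(1, 0.040, 0.005),
             T = stats::rnorm(1, 0.22, 0.02))
      hr <- stats::runif(1, 55, 95)
      ok <- v[["R"]] > max(v[c("P", "Q", "S", "T")]) &&
        all(diff(o) > 0) && o[["P"]] < -0.08 && o[["T"]] > 0.12
      if (ok) break
    }
    subject_template(sprintf("S%03d", i), v, o, heart_rate = hr,
                     hr_jitter = 0.03)
  })
}

# save/restore the global RNG state so seeded generators do not disturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Acquisition-condition noise profile
#'
#' Additive noise model for synthetic acquisition: sinusoidal baseline
#' wander (respiration), powerline interference, broadband white noise, and
#' transient motion-artifact bursts (amplitude-modulated band-limited noise
#' segments of 0.3-1.0 s at a Poisson rate). The four presets emulate
#' seated, slide-touch, post-exercise and driving acquisition; the sitting
#' condition has no artifact bursts.
#'
#' @param condition one of `"sit"`, `"slide_touch"`, `"post_exercise"`,
#'   `"driving"`, or `"custom"`.
#' @param baseline_wander_amp,baseline_wander_freq wander amplitude (mV) and
#'   frequency (Hz).
#' @param powerline_amp,powerline_freq powerline amplitude (mV) and
#'   frequency (Hz).
#' @param white_noise_std white-noise standard deviation (mV).
#' @param artifact_burst_rate burst events per minute.
#' @param artifact_burst_amp burst amplitude (mV).
#' @return An object of class `noise_profile`.
#' @export
noise_profile <- function(condition = c("sit", "slide_touch", "post_exercise",
                                        "driving", "custom"),
                          baseline_wander_amp = NULL,
                          baseline_wander_freq = NULL,
                          powerline_amp = NULL, powerline_freq = 60,
                          white_noise_std = NULL,
                          artifact_burst_rate = NULL,
                          artifact_burst_amp = NULL) {
  condition <- match.arg(condition)
  preset <- switch(condition,
    sit           = list(bw = 0.05, bwf = 0.25, pl = 0.01, wn = 0.010, br = 0,  ba = 0),
    slide_touch   = list(bw = 0.10, bwf = 0.30, pl = 0.02, wn = 0.020, br = 6,  ba = 0.4),
    post_exercise = list(bw = 0.20, bwf = 0.40, pl = 0.02, wn = 0.030, br = 4,  ba = 0.5),
    driving       = list(bw = 0.15, bwf = 0.30, pl = 0.03, wn = 0.050, br = 12, ba = 0.9),
    custom        = list(bw = 0,    bwf = 0.25, pl = 0,    wn = 0,     br = 0,  ba = 0)
  )
  p <- list(
    condition = condition,
    baseline_wander_amp = baseline_wander_amp %||% preset$bw,
    baseline_wander_freq = baseline_wander_freq %||% preset$bwf,
    powerline_amp = powerline_amp %||% preset$pl,
    powerline_freq = powerline_freq,
    white_noise_std = white_noise_std %||% preset$wn,
    artifact_burst_rate = artifact_burst_rate %||% preset$br,
    artifact_burst_amp = artifact_burst_amp %||% preset$ba
  )
  amps <- unlist(p[c("baseline_wander_amp", "powerline_amp", "white_noise_std",
                     "artifact_burst_rate", "artifact_burst_amp")])
  if (any(amps < 0)) stop("noise amplitudes and rates must be >= 0", call. = FALSE)
  if (condition == "sit" && p$artifact_burst_rate != 0)
    stop("the sit condition has no artifact bursts", call. = FALSE)
  structure(p, class = "noise_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.noise_profile <- function(x, ...) {
  cat(sprintf(
    "<noise_profile> %s: wander %.2f mV @ %.2f Hz, powerline %.2f mV, white %.3f mV, bursts %.0f/min x %.1f mV\n",
    x$condition, x$baseline_wander_amp, x$baseline_wander_freq,
    x$powerline_amp, x$white_noise_std, x$artifact_burst_rate,
    x$artifact_burst_amp))
  invisible(x)
}

# Build one beat waveform for a template at sampling rate fs, via the ideal
# one-cycle interpolation applied to the template's own vertices. The beat
# window is [-0.3 s, +0.4 s] around R.
template_beat <- function(template, fs, pre = 0.3, post = 0.4) {
  n_pre <- round(pre * fs)
  n_post <- round(post * fs)
  loc <- round(template$peak_offsets * fs) + n_pre
  st <- peak_stats(template$peak_voltages, loc)
  generate_ideal_cycle(st, target_length = n_pre + n_post)
}

# Peak statistics implied by a template on the fs sample grid (R at 0.3 s).
template_peak_stats <- function(template, fs, pre = 0.3) {
  loc <- round(template$peak_offsets * fs) + round(pre * fs)
  peak_stats(template$peak_voltages, loc)
}

#' Synthesize a single-lead ECG record
#'
#' Tiles the template's interpolated beat waveform at RR intervals drawn
#' from the template heart rate with truncated-normal jitter (clipped at
#' three standard deviations), then adds the noise profile's components.
#' Ground-truth R-peak sample indices are returned as annotations; the
#' rhythm is drawn from an RNG stream independent of the noise stream, so
#' the annotated ground truth is unaffected by any noise setting.
#'
#' @param template a [subject_template].
#' @param noise a [noise_profile].
#' @param duration record duration in seconds.
#' @param fs sampling rate in Hz (>= 250).
#' @param seed integer RNG seed.
#' @return An [ecg_record] with `annotations` set to the true R-peak
#'   indices (1-based).
#' @export
synthesize_record <- function(template, noise, duration, fs, seed = 1L) {
  if (duration <= 0) stop("`duration` must be positive", call. = FALSE)
  if (fs < 250) stop("`fs` must be at least 250 Hz", call. = FALSE)
  n <- round(duration * fs)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  # --- rhythm + clean morphology (seed stream 1) ---
  set.seed(seed)
  beat <- template_beat(template, fs)
  n_pre <- round(0.3 * fs)
  rr0 <- 60 / template$heart_rate
  r_times <- numeric(0)
  t_cur <- 0.35 # first R placed clear of the record start
  while (t_cur < duration - 0.05) {
    r_times <- c(r_times, t_cur)
    jit <- stats::rnorm(1, 0, template$hr_jitter)
    jit <- max(min(jit, 3 * template$hr_jitter), -3 * template$hr_jitter)
    t_cur <- t_cur + rr0 * (1 + jit)
  }
  r_idx <- round(r_times * fs) + 1L
  x <- numeric(n)
  for (r in r_idx) {
    i0 <- r - n_pre            # 1-based start of the beat window
    src <- seq_along(beat$samples)
    dst <- i0 + src - 1L
    keep <- dst >= 1L & dst <= n
    x[dst[keep]] <- x[dst[keep]] + beat$samples[src[keep]]
  }

  # --- additive noise (independent seed stream) ---
  set.seed((seed %% 1000000L) * 2011L + 17L)
  tt <- (seq_len(n) - 1) / fs
  ph <- stats::runif(2, 0, 2 * pi)
  x_noise <- noise$baseline_wander_amp *
    sin(2 * pi * noise$baseline_wander_freq * tt + ph[1]) +
    noise$powerline_amp * sin(2 * pi * noise$powerline_freq * tt + ph[2])
  if (noise$white_noise_std > 0)
    x_noise <- x_noise + stats::rnorm(n, 0, noise$white_noise_std)
  if (noise$artifact_burst_rate > 0 && noise$artifact_burst_amp > 0) {
    n_bursts <- stats::rpois(1, noise$artifact_burst_rate * duration / 60)
    for (b in seq_len(n_bursts)) {
      len <- round(stats::runif(1, 0.3, 1.0) * fs)
      start <- sample.int(max(n - len, 1L), 1L)
      burst <- motion_burst(len, fs, noise$artifact_burst_amp)
      idx <- start:(start + len - 1L)
      idx <- idx[idx <= n]
      x_noise[idx] <- x_noise[idx] + burst[seq_along(idx)]
    }
  }
  ecg_record(x + x_noise, fs, subject_id = template$subject_id,
             condition = noise$condition,
             annotations = r_idx[r_idx >= 1L & r_idx <= n])
}

# Amplitude-modulated band-limited (1-10 Hz) noise burst, Hann envelope.
motion_burst <- function(len, fs, amp) {
  w <- stats::rnorm(len + 2 * round(0.2 * fs))
  bf <- signal::butter(2, c(1, 10) / (fs / 2), type = "pass")
  f <- signal::filtfilt(bf, w)
  f <- f[round(0.2 * fs) + seq_len(len)]
  f <- f / max(stats::sd(f), 1e-12)
  env <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = len))
  amp * env * f
}

#' Synthesize registration and recognition records for a cohort
#'
#' Convenience wrapper producing, for each template, one registration record
#' acquired sitting and one recognition record under the requested
#' condition. Seeds are derived deterministically from `seed` and the
#' subject index.
#'
#' @param templates list of [subject_template] objects.
#' @param condition recognition-condition name (see [noise_profile]).
#' @param reg_duration,rec_duration durations in seconds.
#' @param fs sampling rate in Hz.
#' @param seed integer seed.
#' @return Named list (by subject) of lists with elements `registration`
#'   and `recognition`.
#' @export
synthesize_cohort_records <- function(templates, condition = "driving",
                                      reg_duration = 60, rec_duration = 60,
                                      fs = 500, seed = 1L) {
  out <- lapply(seq_along(templates), function(i) {
    s <- (seed %% 100000L) * 1000L + i
    list(
      registration = synthesize_record(templates[[i]], noise_profile("sit"),
                                       reg_duration, fs, seed = s),
      recognition = synthesize_record(templates[[i]], noise_profile(condition),
                                      rec_duration, fs, seed = s + 500L)
    )
  })
  names(out) <- vapply(templates, function(tp) tp$subject_id, character(1))
  out
}

#' Write a cohort manifest CSV
#'
#' Writes each record of a cohort as a two-column CSV (via [write_record])
#' and a manifest CSV (`subject_id`, `condition`, `role`, `path`, `seed`).
#'
#' @param records output of [synthesize_cohort_records].
#' @param dir output directory (created if missing).
#' @param seed the seed recorded in the manifest.
#' @return Path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(records, dir, seed = NA_integer_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (sid in names(records)) {
    for (role in c("registration", "recognition")) {
      rec <- records[[sid]][[role]]
      path <- file.path(dir, sprintf("%s_%s.csv", sid, role))
      write_record(rec, path, format = "csv")
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, condition = rec$condition, role = role,
        path = path, seed = seed)
    }
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}
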