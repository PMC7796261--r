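# Shared fixtures, generated in code. A small per-session cache avoids
# re-synthesizing the same records across test files.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# one clean 30 s record at 500 Hz, HR ~70
clean_record <- function() fixture("clean_record", {
  tpl <- make_cohort(1, seed = 11)[[1]]
  synthesize_record(tpl, noise_profile("custom"), duration = 30, fs = 500,
                    seed = 11)
})

# preprocessed version of clean_record
clean_pp <- function() fixture("clean_pp", {
  preprocess_record(clean_record())
})

# annotated synthetic cycles for peak-stat averaging: vertex data drawn
# around typical morphology
random_peak_stats <- function(seed) {
  set.seed(seed)
  v <- c(P = runif(1, 0.05, 0.3), Q = runif(1, -0.4, -0.05),
         R = runif(1, 0.8, 1.6), S = runif(1, -0.5, -0.05),
         T = runif(1, 0.1, 0.5))
  loc <- sort(sample(5:345, 5))
  names(loc) <- c("P", "Q", "R", "S", "T")
  peak_stats(v, loc)
}

# cycles with annotated peaks built directly from vertex draws
annotated_cycles <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    st <- random_peak_stats(seed * 1000 + i)
    ic <- generate_ideal_cycle(st, 350)
    ecg_cycle(ic$samples, fs = 500, r_index = st$location[["R"]],
              peaks = list(voltage = st$voltage, location = st$location))
  })
}

# add a deterministic additive drift to a record's samples
set_drift <- function(record, drift) {
  ecg_record(record$samples + drift, record$fs, record$subject_id,
             record$condition, record$annotations)
}

# spectral power below 0.5 Hz (periodogram via FFT)
lf_power <- function(x, fs) {
  n <- length(x)
  sp <- abs(fft(x - mean(x)))^2 / n
  freqs <- (seq_len(n) - 1) * fs / n
  sum(sp[freqs > 0 & freqs < 0.5])
}

# length-matched static cycles for one subject
subject_static_cycles <- function(tpl, n_sec = 30, fs = 500, seed = 21) {
  rec <- synthesize_record(tpl, noise_profile("sit"), duration = n_sec,
                           fs = fs, seed = seed)
  pp <- preprocess_record(rec)
  suppressMessages(segment_cycles(pp$record, pp$peaks))
}
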