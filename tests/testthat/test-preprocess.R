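test_that("bandpass rejects DC and drift but passes in-band components", {
  fs <- 500
  tt <- seq(0, 20, by = 1 / fs)
  dc <- ecg_record(rep(2, length(tt)), fs)
  out <- bandpass(dc)
  expect_lt(max(abs(out$samples)), 1e-6 * 2)

  mid <- seq(5 * fs, 15 * fs) # steady-state stretch, away from edges
  in_band <- ecg_record(sin(2 * pi * 10 * tt), fs)
  amp_in <- max(abs(bandpass(in_band)$samples[mid]))
  expect_gt(amp_in, 0.95)
  expect_lt(amp_in, 1.05)

  drift <- ecg_record(sin(2 * pi * 0.1 * tt), fs)
  expect_lt(max(abs(bandpass(drift)$samples[mid])), 0.10)

  expect_error(bandpass(in_band, low = 0, high = 40), "cutoffs")
  expect_error(bandpass(in_band, low = 1, high = 300), "cutoffs")
  expect_length(bandpass(in_band)$samples, length(tt))
})

test_that("R detection is accurate on clean records and deterministic", {
  pp <- clean_pp()
  rec <- clean_record()
  det <- pp$peaks$indices
  truth <- rec$annotations
  expect_true(abs(length(det) - length(truth)) <= 1)
  # every true beat matched within +/- 10 ms
  tol <- round(0.010 * rec$fs)
  hits <- vapply(truth, function(a) min(abs(det - a)) <= tol, logical(1))
  expect_true(all(hits))
  expect_identical(detect_r_peaks(pp$record)$indices,
                   detect_r_peaks(pp$record)$indices)

  flat <- ecg_record(rep(0, 5 * 500), 500)
  expect_length(detect_r_peaks(flat)$indices, 0)
  expect_error(detect_r_peaks(ecg_record(rnorm(200), 500)), "2 s")
})

test_that("R detection stays sensitive under driving-grade motion artifacts", {
  tpl <- make_cohort(3, seed = 31)
  se <- vapply(1:5, function(s) {
    rec <- synthesize_record(tpl[[(s %% 3) + 1]], noise_profile("driving"),
                             duration = 30, fs = 500, seed = 100 + s)
    pp <- preprocess_record(rec)
    tol <- round(0.050 * rec$fs)
    mean(vapply(rec$annotations, function(a)
      min(abs(pp$peaks$indices - a)) <= tol, logical(1)))
  }, numeric(1))
  expect_gte(mean(se), 0.9)
})

test_that("QRS-sparing smoothing preserves QRS samples and damps noise elsewhere", {
  fs <- 500
  const <- ecg_record(rep(1.5, 10 * fs), fs)
  pk <- rpeak_set(seq(fs, 9 * fs, by = fs), fs)
  sm <- smooth_outside_qrs(const, pk)
  expect_equal(sm$samples, const$samples)

  set.seed(5)
  noisy <- ecg_record(rnorm(10 * fs), fs)
  out <- smooth_outside_qrs(noisy, pk, window = 0.025,
                            qrs_halfwidth = 0.060)
  hw <- round(0.060 * fs)
  protected <- unlist(lapply(pk$indices, function(r) (r - hw):(r + hw)))
  expect_identical(out$samples[protected], noisy$samples[protected])
  outside <- setdiff(seq(2 * fs, 3 * fs), protected)
  expect_gt(var(noisy$samples[outside]) / var(out$samples[outside]), 5)

  expect_warning(smooth_outside_qrs(noisy, rpeak_set(integer(0), fs)),
                 "empty")
})

test_that("baseline removal flattens linear drift and respiratory wander", {
  tpl <- make_cohort(1, seed = 41)[[1]]
  clean <- synthesize_record(tpl, noise_profile("custom"), 30, 500, seed = 41)
  pk <- rpeak_set(clean$annotations, clean$fs)

  drift <- set_drift(clean, seq(0, 1, length.out = length(clean$samples)))
  fixed <- remove_baseline(drift, pk)
  expect_lt(sqrt(mean((fixed$samples - remove_baseline(clean, pk)$samples)^2)),
            0.05)

  tt <- (seq_along(clean$samples) - 1) / clean$fs
  wander <- set_drift(clean, 0.5 * sin(2 * pi * 0.2 * tt))
  fixed2 <- remove_baseline(wander, pk)
  p_before <- lf_power(wander$samples, clean$fs)
  p_after <- lf_power(fixed2$samples, clean$fs)
  expect_lt(p_after, 0.1 * p_before)

  zero <- ecg_record(rep(0, 10 * 500), 500)
  expect_equal(remove_baseline(zero, rpeak_set(c(1000, 2000), 500))$samples,
               zero$samples)
  expect_error(remove_baseline(clean, rpeak_set(1000L, 500)), "two R peaks")
})

test_that("preprocessing preserves length, rate and labels, and is near-idempotent", {
  rec <- clean_record()
  pp <- clean_pp()
  expect_length(pp$record$samples, length(rec$samples))
  expect_identical(pp$record$fs, rec$fs)
  expect_identical(pp$record$subject_id, rec$subject_id)

  # idempotence on a record that actually carries wander
  tt <- (seq_along(rec$samples) - 1) / rec$fs
  wander <- set_drift(bandpass(rec), 0.4 * sin(2 * pi * 0.2 * tt))
  pk <- detect_r_peaks(wander)
  once <- remove_baseline(wander, pk)
  twice <- remove_baseline(once, pk)
  change1 <- sqrt(mean((once$samples - wander$samples)^2))
  change2 <- sqrt(mean((twice$samples - once$samples)^2))
  expect_lt(change2, 0.01 * change1)
})
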