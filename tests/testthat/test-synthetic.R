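test_that("cohort generation is seeded and produces distinct valid templates", {
  a <- make_cohort(5, seed = 1)
  b <- make_cohort(5, seed = 1)
  expect_identical(a, b)
  expect_error(make_cohort(0), "positive")

  one <- make_cohort(1, seed = 7)[[1]]
  expect_s3_class(one, "subject_template")
  expect_gt(one$peak_voltages[["R"]],
            max(one$peak_voltages[c("P", "Q", "S", "T")]))
  expect_true(all(diff(one$peak_offsets) > 0))
  expect_true(one$heart_rate >= 40 && one$heart_rate <= 180)

  big <- make_cohort(50, seed = 3)
  V <- t(vapply(big, function(tp) tp$peak_voltages, numeric(5)))
  dmin <- min(dist(V))
  expect_gt(dmin, 0)
})

test_that("synthesized records have the right length, rhythm and determinism", {
  tpl <- make_cohort(1, seed = 2)[[1]]
  tpl$heart_rate <- 60
  tpl$hr_jitter <- 0
  rec <- synthesize_record(tpl, noise_profile("custom"), duration = 10,
                           fs = 500, seed = 5)
  expect_length(rec$samples, 5000)
  expect_true(abs(length(rec$annotations) - 10) <= 1)

  rec2 <- synthesize_record(tpl, noise_profile("custom"), duration = 10,
                            fs = 500, seed = 5)
  expect_identical(rec$samples, rec2$samples)

  expect_error(synthesize_record(tpl, noise_profile("sit"), duration = 10,
                                 fs = 200), "250")
  expect_error(synthesize_record(tpl, noise_profile("sit"), duration = 0,
                                 fs = 500), "positive")
})

test_that("noise never moves the annotated ground truth and driving is noisier", {
  tpl <- make_cohort(1, seed = 3)[[1]]
  clean <- synthesize_record(tpl, noise_profile("custom"), 20, 500, seed = 9)
  for (cond in c("sit", "slide_touch", "post_exercise", "driving")) {
    noisy <- synthesize_record(tpl, noise_profile(cond), 20, 500, seed = 9)
    expect_identical(noisy$annotations, clean$annotations)
  }
  sit <- synthesize_record(tpl, noise_profile("sit"), 20, 500, seed = 9)
  drv <- synthesize_record(tpl, noise_profile("driving"), 20, 500, seed = 9)
  expect_gt(var(drv$samples), var(sit$samples))
})

test_that("sit profile rejects artifact bursts and amplitudes validate", {
  expect_error(noise_profile("sit", artifact_burst_rate = 3), "sit")
  expect_error(noise_profile("custom", white_noise_std = -1), ">= 0")
  expect_identical(noise_profile("sit")$artifact_burst_rate, 0)
})

test_that("cohort records and manifest round-trip through CSV", {
  tpl <- make_cohort(2, seed = 4)
  recs <- synthesize_cohort_records(tpl, condition = "slide_touch",
                                    reg_duration = 5, rec_duration = 5,
                                    fs = 250, seed = 4)
  dir <- withr::local_tempdir()
  mpath <- write_cohort(recs, dir, seed = 4)
  man <- read.csv(mpath)
  expect_equal(nrow(man), 4)
  back <- read_record(man$path[1], format = "csv")
  orig <- recs[[man$subject_id[1]]][[man$role[1]]]
  expect_equal(back$samples, orig$samples, tolerance = 1e-6)
  expect_identical(back$annotations, orig$annotations)
})
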