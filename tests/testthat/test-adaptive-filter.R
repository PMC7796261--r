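make_profile <- function(S) similarity_profile(S, unit = "distance")

test_that("sample-cycle selection is an exact argmin with first-index ties", {
  tpl <- make_cohort(1, seed = 51)[[1]]
  cyc <- subject_static_cycles(tpl, n_sec = 30, seed = 51)
  ideal_len <- length(cyc[[1]]$samples)
  ideal <- generate_ideal_cycle(default_peak_stats(500), ideal_len)

  samp <- select_sample_cycle(cyc, ideal)
  d <- vapply(cyc, function(cy) sqrt(sum((cy$samples - ideal$samples)^2)),
              numeric(1))
  expect_identical(samp$index, which.min(d))
  expect_equal(samp$distance_to_ideal, min(d))

  # an exact copy of the ideal wins with distance zero
  copy <- ecg_cycle(ideal$samples, 500, r_index = cyc[[1]]$r_index)
  samp2 <- select_sample_cycle(c(cyc, list(copy)), ideal)
  expect_equal(samp2$distance_to_ideal, 0)
  expect_identical(samp2$index, length(cyc) + 1L)

  # equidistant duplicates: lowest index chosen
  two <- list(cyc[[2]], cyc[[2]])
  expect_identical(select_sample_cycle(two, ideal)$index, 1L)

  expect_error(select_sample_cycle(list(), ideal), "non-empty")
  short <- ecg_cycle(rep(0, 10), 500, r_index = 1L)
  expect_error(select_sample_cycle(list(short), ideal), "length-matched")
})

test_that("similarity profiles carry exact bounds", {
  tpl <- make_cohort(1, seed = 52)[[1]]
  cyc <- subject_static_cycles(tpl, n_sec = 20, seed = 52)
  samp <- select_sample_cycle(cyc, cyc[[1]])
  prof <- similarity_profile(cyc, samp, unit = "distance")
  d <- vapply(cyc, function(cy) sqrt(sum((cy$samples - samp$samples)^2)),
              numeric(1))
  expect_equal(prof$S, d)
  expect_equal(prof$k, min(d))
  expect_equal(prof$l, max(d))

  same <- similarity_profile(list(cyc[[1]], cyc[[1]]),
                             select_sample_cycle(list(cyc[[1]]), cyc[[1]]),
                             unit = "distance")
  expect_equal(same$S, c(0, 0))
  expect_equal(c(same$k, same$l), c(0, 0))

  single <- make_profile(3.7)
  expect_equal(c(single$k, single$l), c(3.7, 3.7))
  expect_error(similarity_profile(numeric(0)), "non-empty")
})

test_that("threshold filtering implements S < k + Th with a non-empty guard", {
  prof <- make_profile(c(2, 5, 9))
  expect_identical(filter_cycles(prof, Th = 4)$kept_indices, c(1L, 2L))
  expect_identical(filter_cycles(prof, Th = 0)$kept_indices, 1L)
  expect_identical(filter_cycles(prof, Th = 8)$kept_indices, c(1L, 2L, 3L))
  expect_error(filter_cycles(prof, Th = -1), "non-negative")

  # kept count non-decreasing in Th; top of grid keeps all
  set.seed(6)
  for (i in 1:30) {
    S <- runif(sample(3:40, 1), 0, 50)
    pr <- make_profile(S)
    kept <- vapply(pr$grid, function(th)
      length(filter_cycles(pr, Th = th)$kept_indices), integer(1))
    expect_true(all(diff(kept) >= 0))
    expect_identical(kept[length(kept)], length(S))
    expect_identical(filter_cycles(pr, Th = 0)$kept_indices,
                     which(S == min(S)))
  }
})

test_that("choose_threshold returns the smallest grid value reaching the pass rate", {
  prof <- make_profile(c(2, 5, 9))
  expect_identical(choose_threshold(prof, 0.5), 4L)
  expect_identical(choose_threshold(make_profile(1.23), 0.99), 0L)
  full <- choose_threshold(prof, 1)
  expect_identical(filter_cycles(prof, Th = full)$pass_rate, 1)
  expect_identical(full, 8L)
  expect_error(choose_threshold(prof, 0), "min_pass")
})

test_that("filtering purifies artifact-laden cycle sets", {
  # 30 clean + 5 heavily corrupted beats: some threshold keeps >= 90% of
  # the clean and <= 20% of the corrupted ones, and the kept mean distance
  # never exceeds the overall mean
  tpl <- make_cohort(1, seed = 53)[[1]]
  cyc <- subject_static_cycles(tpl, n_sec = 40, seed = 53)[1:30]
  set.seed(53)
  corrupted <- lapply(1:5, function(i) {
    cy <- cyc[[i]]
    cy$samples <- cy$samples + rnorm(length(cy$samples), 0, 0.8)
    cy
  })
  all_cyc <- c(cyc, corrupted)
  samp <- select_sample_cycle(cyc, cyc[[1]])
  prof <- similarity_profile(all_cyc, samp, unit = "distance")
  is_clean <- c(rep(TRUE, 30), rep(FALSE, 5))

  found <- FALSE
  for (th in prof$grid) {
    ns <- filter_cycles(prof, Th = th)
    kept <- seq_along(all_cyc) %in% ns$kept_indices
    expect_lte(mean(prof$S[kept]), mean(prof$S) + 1e-12)
    if (mean(kept[is_clean]) >= 0.9 && mean(kept[!is_clean]) <= 0.2)
      found <- TRUE
  }
  expect_true(found)
})

test_that("normalization report tabulates kept beats", {
  prof <- make_profile(c(2, 5, 9))
  rep_ <- normalization_report(filter_cycles(prof, Th = 4))
  expect_identical(rep_$kept, c(TRUE, TRUE, FALSE))
  expect_equal(rep_$S, c(2, 5, 9))
})
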