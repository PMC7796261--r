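test_that("peak averaging matches a brute-force oracle and validates input", {
  cyc <- annotated_cycles(1, seed = 1)
  cyc[[1]]$peaks$voltage[["R"]] <- 1.2
  st <- compute_peak_stats(cyc)
  expect_equal(st$voltage[["R"]], 1.2)

  three <- annotated_cycles(3, seed = 2)
  for (i in 1:3) three[[i]]$peaks$voltage[["R"]] <- i
  st3 <- compute_peak_stats(three)
  expect_equal(st3$voltage[["R"]], 2)

  many <- annotated_cycles(100, seed = 3)
  st100 <- compute_peak_stats(many)
  # independent averaging oracle: plain column means over the annotations
  vm <- colMeans(do.call(rbind, lapply(many, function(cy) cy$peaks$voltage)))
  lm <- colMeans(do.call(rbind, lapply(many, function(cy) cy$peaks$location)))
  expect_equal(unname(st100$voltage), unname(vm[c("P","Q","R","S","T")]))
  expect_equal(unname(st100$location), unname(lm[c("P","Q","R","S","T")]))
  expect_identical(st100$n_cycles, 100L)

  bad <- annotated_cycles(1, seed = 4)
  bad[[1]]$peaks$voltage <- bad[[1]]$peaks$voltage[c("P", "Q", "R", "S")]
  expect_error(compute_peak_stats(bad), "T peak")
})

test_that("segment interpolation honors endpoints, slope and the quadratic form", {
  # line through (0,0)-(2,4): slope 2, midpoint 2
  expect_equal(interpolate_segment(0, 0, 2, 4, order = 1, n = 1), 2)
  expect_equal(interpolate_segment(0, 0, 2, 4, order = 1, n = c(0, 2)), c(0, 4))
  # endpoint identity for both orders on arbitrary segments
  for (ord in 1:2) {
    expect_equal(interpolate_segment(3, -1.5, 9, 2.5, ord, n = 3), -1.5)
    expect_equal(interpolate_segment(3, -1.5, 9, 2.5, ord, n = 9), 2.5)
  }
  # normalized quadratic: y1 + (y2-y1) * t^2 at t = 0.5
  expect_equal(interpolate_segment(0, 0, 4, 8, order = 2, n = 2), 2)
  expect_error(interpolate_segment(1, 0, 1, 1, order = 1, n = 1), "degenerate")
})

test_that("generated ideal cycles pass exactly through their vertices", {
  for (seed in 1:25) {
    st <- random_peak_stats(seed)
    ic <- generate_ideal_cycle(st, 350)
    expect_identical(ic$length, 350)
    expect_equal(ic$samples[st$location + 1], unname(st$voltage))
    expect_true(all(is.finite(ic$samples)))
  }
})

test_that("collinear vertices with order-1 segments reproduce the line", {
  loc <- c(P = 50, Q = 100, R = 150, S = 200, T = 250)
  v <- c(P = 0.5, Q = 1.0, R = 1.5, S = 1.0, T = 0.5) # R still the max
  # P-Q-R collinear ascending, R-S-T collinear descending
  st <- peak_stats(v, loc)
  ic <- generate_ideal_cycle(st, 300, order_map = c(pq = 1, qr = 1, rs = 1,
                                                    st = 1))
  seg <- ic$samples[(loc[["P"]] + 1):(loc[["R"]] + 1)]
  expect_equal(seg, seq(0.5, 1.5, length.out = length(seg)))
  seg2 <- ic$samples[(loc[["R"]] + 1):(loc[["T"]] + 1)]
  expect_equal(seg2, seq(1.5, 0.5, length.out = length(seg2)))
  # order-1 segments are affine: zero second differences inside a segment
  expect_equal(max(abs(diff(seg, differences = 2))), 0)
})

test_that("Q-to-R order-1 segment is monotone and scaling in y is linear", {
  st <- random_peak_stats(7)
  ic <- generate_ideal_cycle(st, 350)
  qr <- ic$samples[(st$location[["Q"]] + 1):(st$location[["R"]] + 1)]
  expect_true(all(diff(qr) >= 0)) # QV < RV always holds here
  # linearity in voltage
  st2 <- peak_stats(st$voltage * 3, st$location)
  ic2 <- generate_ideal_cycle(st2, 350)
  expect_equal(ic2$samples, ic$samples * 3)
  expect_error(generate_ideal_cycle(st, st$location[["T"]] -
                                      st$location[["P"]] - 5), "span|cover")
})

test_that("peak stats round-trip through CSV", {
  st <- random_peak_stats(9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_peak_stats(st, path)
  back <- read_peak_stats(path)
  expect_equal(back$voltage, st$voltage)
  expect_equal(back$location, st$location)
})
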