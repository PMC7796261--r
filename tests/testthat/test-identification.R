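enrolled_fixture <- function() fixture("enrolled_fixture", {
  tpls <- make_cohort(5, seed = 61)
  recs <- synthesize_cohort_records(tpls, condition = "sit",
                                    reg_duration = 40, rec_duration = 20,
                                    fs = 360, seed = 61)
  cyc <- list(); labs <- character(0); held <- list()
  for (sid in names(recs)) {
    pp <- preprocess_record(recs[[sid]]$registration)
    cc <- suppressMessages(segment_cycles(pp$record, pp$peaks))
    cyc <- c(cyc, cc); labs <- c(labs, rep(sid, length(cc)))
    ph <- preprocess_record(recs[[sid]]$recognition)
    held[[sid]] <- suppressMessages(segment_cycles(ph$record, ph$peaks))
  }
  list(cycles = cyc, labels = labs, held = held)
})

test_that("enrollment validates its inputs", {
  fx <- enrolled_fixture()
  expect_error(ecg_identifier(fx$cycles[1:3], rep("A", 3)), "two subjects")
  expect_error(ecg_identifier(fx$cycles[1:3], c("A", "B")), "one entry per")
})

test_that("nearest-template identification recovers held-out static subjects", {
  fx <- enrolled_fixture()
  fit <- ecg_identifier(fx$cycles, fx$labels, method = "nearest")
  expect_s3_class(fit, "ecg_identifier")
  preds <- vapply(names(fx$held), function(sid)
    predict(fit, fx$held[[sid]])$label, character(1))
  expect_gte(mean(preds == names(fx$held)), 0.95)

  # probes identical to one subject's training beats give that subject
  sid1 <- fx$labels[1]
  own <- fx$cycles[fx$labels == sid1][1:3]
  pr <- predict(fit, own)
  expect_identical(pr$label, sid1)
  expect_equal(rowSums(pr$per_cycle), rep(1, 3))
  expect_error(predict(fit, list()), "non-empty")
})

test_that("LSTM identification recovers a small cohort deterministically", {
  fx <- enrolled_fixture()
  # parameter recovery over several seeds: held-out static beats are
  # assigned to the right subject nearly always
  accs <- vapply(1:5, function(s) {
    cfg <- lstm_config(input_length = 40, dense_widths = c(64, 32), seed = s)
    fit <- ecg_identifier(fx$cycles, fx$labels, method = "lstm",
                          config = cfg)
    preds <- vapply(names(fx$held), function(sid)
      predict(fit, fx$held[[sid]])$label, character(1))
    mean(preds == names(fx$held))
  }, numeric(1))
  expect_gte(mean(accs), 0.95)

  cfg <- lstm_config(input_length = 40, dense_widths = c(64, 32), seed = 5)
  fit <- ecg_identifier(fx$cycles, fx$labels, method = "lstm", config = cfg)
  expect_lt(utils::tail(fit$loss, 1), fit$loss[1])
  fit2 <- ecg_identifier(fx$cycles, fx$labels, method = "lstm", config = cfg)
  p1 <- predict(fit, fx$held[[1]])
  p2 <- predict(fit2, fx$held[[1]])
  expect_identical(p1$scores, p2$scores)
  expect_equal(sum(p1$scores), 1)
})

test_that("confusion accounting and the accuracy formula are exact", {
  expect_equal(accuracy(list(TP = 9, TN = 90, FP = 1, FN = 0)), 0.99)
  expect_equal(accuracy(list(TP = 5, TN = 20, FP = 0, FN = 0)), 1)
  set.seed(8)
  for (i in 1:25) {
    cts <- as.list(setNames(sample(0:50, 4), c("TP", "TN", "FP", "FN")))
    if (sum(unlist(cts)) == 0) next
    expect_equal(accuracy(cts),
                 (cts$TP + cts$TN) / (cts$TP + cts$FN + cts$FP + cts$TN))
  }
  expect_error(accuracy(list(TP = 0, TN = 0, FP = 0, FN = 0)), "all-zero")

  cc <- confusion_counts(c("A", "B", "B"), c("A", "B", "A"), n_classes = 4)
  expect_identical(cc$TP, 2L)
  expect_identical(cc$FP, 1L)
  expect_identical(cc$FN, 1L)
  expect_identical(cc$TN, 2L * 3L + 1L * 2L)
  expect_identical(cc$TP + cc$TN + cc$FP + cc$FN, 3L * 4L)

  # accuracy never decreases when errors decrease at fixed TP/TN
  a1 <- accuracy(list(TP = 10, TN = 40, FP = 5, FN = 5))
  a2 <- accuracy(list(TP = 10, TN = 40, FP = 3, FN = 5))
  expect_gte(a2, a1)
})
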