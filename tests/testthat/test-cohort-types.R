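test_that("channel and exercise enumerations have the study's structure", {
  info <- muscle_channel_info()
  expect_equal(nrow(info), 8L)
  expect_setequal(info$side, c("L", "R"))
  expect_equal(sum(info$side == "L"), 4L)
  expect_length(unique(info$muscle), 4L)
  expect_length(exercise_types(), 4L)
  expect_true(all(info$region %in% c("thoracic", "lumbar")))
})

test_that("recording constructor enforces shape, weeks and sampling rate", {
  sig <- matrix(rnorm(8 * 100), 8, 100)
  rec <- emg_recording("P1", 8L, "quadruped", sig)
  expect_s3_class(rec, "emg_recording")
  expect_equal(rownames(rec$signals), muscle_channels())
  expect_error(emg_recording("P1", 12L, "quadruped", sig), "week")
  expect_error(emg_recording("P1", 0L, "plank", sig), "exercise")
  expect_error(emg_recording("P1", 0L, "quadruped", sig[1:4, ]), "8 x T")
  expect_error(emg_recording("P1", 0L, "quadruped", sig, sample_rate_hz = 500),
               "Nyquist")
  sig[3, 5] <- NA
  expect_error(emg_recording("P1", 0L, "quadruped", sig), "finite")
})

test_that("convex-side map follows the curve direction with S-curve default", {
  left <- make_static(curve_direction = "left")
  right <- make_static(curve_direction = "right")
  expect_equal(left$convex_thoracic, "L")
  expect_equal(left$convex_lumbar, "R")
  expect_equal(right$convex_thoracic, "R")
  expect_equal(right$convex_lumbar, "L")
})

test_that("validate_cohort accepts a complete simulated cohort", {
  sim <- tiny_sim(2L)
  report <- validate_cohort(sim$cohort)
  expect_s3_class(report, "data.frame")
  expect_equal(nrow(report), 0L)
})

test_that("validate_cohort reports range, completeness and orphan violations", {
  sim <- tiny_sim(2L)
  chrt <- sim$cohort

  # out-of-range SRS-22 (scale tops out at 5)
  bad <- chrt
  bad$outcomes$srs22[1L] <- 5.7
  rep1 <- validate_cohort(bad)
  expect_equal(rep1$rule, "srs22_range")

  # a missing (patient, week, exercise) recording is identified precisely
  bad2 <- chrt
  drop <- which(vapply(bad2$recordings, function(r) {
    r$week == 16L && r$exercise == "bar_squat" &&
      r$patient_id == chrt$statics$patient_id[1L]
  }, logical(1)))
  bad2$recordings <- bad2$recordings[-drop]
  rep2 <- validate_cohort(bad2)
  expect_equal(rep2$rule, "recording_missing")
  expect_equal(rep2$patient_id, chrt$statics$patient_id[1L])
  expect_equal(rep2$week, 16L)
  expect_equal(rep2$exercise, "bar_squat")

  # recording whose patient is absent from statics
  bad3 <- chrt
  bad3$statics <- bad3$statics[-1L, ]
  rep3 <- validate_cohort(bad3, complete = FALSE)
  expect_true("recording_orphan" %in% rep3$rule)
  expect_true("outcome_orphan" %in% rep3$rule)

  # validate_cohort is total: malformed elements are reported, not thrown
  bad4 <- chrt
  bad4$recordings[[1L]] <- list(not = "a recording")
  expect_no_error(rep4 <- validate_cohort(bad4))
  expect_true("recording_type" %in% rep4$rule)
})

test_that("a complete cohort of n patients has exactly 16 n recordings", {
  for (n in c(1L, 3L)) {
    sim <- tiny_sim(n)
    expect_length(sim$cohort$recordings, 16L * n)
    expect_equal(nrow(validate_cohort(sim$cohort)), 0L)
  }
})
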