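fs <- 1000
tt <- (0:(8 * fs - 1)) / fs

sine_gain <- function(f, spec = filter_spec()) {
  x <- sin(2 * pi * f * tt)
  y <- bandpass_filter(x, fs, spec)
  mid <- 2000:6000
  sqrt(2) * rms(y[mid])
}

test_that("band-pass rejects DC and stop-band, passes the band", {
  dc <- bandpass_filter(rep(100, 20 * fs), fs)
  expect_lt(rms(dc), 0.1)
  expect_lt(sine_gain(5), 0.05)            # 5 Hz: deep stop band
  expect_gt(sine_gain(100), 0.99)          # 100 Hz: flat pass band
  expect_lt(abs(sine_gain(100) - 1), 0.01)
})

test_that("empirical magnitude matches the closed-form Butterworth response", {
  for (f in c(10, 20, 50, 200, 400, 470)) {
    expect_lt(abs(sine_gain(f) - bandpass_gain(f, fs)), 1e-3)
  }
  # causal mode: magnitude is the unsquared response
  spec_c <- filter_spec(mode = "causal")
  for (f in c(50, 200)) {
    expect_lt(abs(sine_gain(f, spec_c) - bandpass_gain(f, fs, spec_c)), 1e-3)
  }
})

test_that("filtering is linear and zero-phase mode has no lag", {
  set.seed(1)
  x1 <- rnorm(4000)
  x2 <- rnorm(4000)
  lhs <- bandpass_filter(2 * x1 + 3 * x2, fs)
  rhs <- 2 * bandpass_filter(x1, fs) + 3 * bandpass_filter(x2, fs)
  expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-9)

  xs <- sin(2 * pi * 80 * tt[1:4000])
  ys <- bandpass_filter(xs, fs)
  cc <- ccf(ys, xs, lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("band and length preconditions are enforced", {
  expect_error(bandpass_filter(rnorm(1000), 700), "infeasible")
  expect_error(bandpass_filter(rnorm(5), fs), "too short")
  expect_error(filter_spec(low_hz = 400, high_hz = 20))
})

test_that("rms matches closed forms and is scale-equivariant", {
  expect_equal(rms(rep(3.5, 10)), 3.5)
  expect_equal(rms(c(3, -4)), sqrt(12.5))
  expect_equal(rms(numeric(5)), 0)
  expect_error(rms(numeric(0)), "empty")
  set.seed(2)
  x <- rnorm(100)
  expect_equal(rms(-2.5 * x), 2.5 * rms(x))
})

test_that("pmsi identities: symmetry, reciprocity, dominance classification", {
  expect_equal(pmsi(7, 7), 1)
  expect_equal(pmsi(38.57, 25.56), 38.57 / 25.56)   # ratio of cohort means
  expect_equal(pmsi(38.57, 25.56), 1.5090, tolerance = 1e-4)
  expect_equal(pmsi(20, 40), 0.5)                   # concave-dominant
  expect_lt(pmsi(20, 40), 1)
  for (pair in list(c(3, 11), c(0.4, 2))) {
    expect_equal(pmsi(pair[1], pair[2]) * pmsi(pair[2], pair[1]), 1)
  }
  expect_error(pmsi(10, 0), "zero")
})

test_that("extract_features maps convex sides and scales correctly", {
  base <- matrix(rnorm(8 * 1500, 0, 20), 8, 1500)
  sym <- base
  sym[seq(2, 8, 2), ] <- sym[seq(1, 7, 2), ]  # R channels copy L channels
  rec <- emg_recording("P1", 0L, "quadruped", sym)
  st <- make_static()
  f <- extract_features(rec, st)
  expect_true(all(abs(f$pmsi - 1) < 1e-12))

  # doubling the convex-side channels doubles every PMSI
  left <- make_static()   # thoracic convex L, lumbar convex R
  cx_rows <- c(1L, 4L, 5L, 7L)  # ES_L, MF_R, RA_L, EO_L
  amp <- sym
  amp[cx_rows, ] <- 2 * amp[cx_rows, ]
  f2 <- extract_features(emg_recording("P1", 0L, "quadruped", amp), left)
  expect_true(all(abs(f2$pmsi - 2) < 1e-9))

  # flipping the curve direction inverts each ratio
  right <- make_static(curve_direction = "right")
  f3 <- extract_features(emg_recording("P1", 0L, "quadruped", amp), right)
  expect_equal(unname(f2$pmsi * f3$pmsi), rep(1, 4), tolerance = 1e-9)
})

test_that("model inputs have the contracted shape, padding and normalization", {
  st <- make_static()
  rec20 <- make_recording(T = 20000L)
  mi <- build_model_inputs(rec20, st, tensor_spec(100, 2000L))
  expect_equal(dim(mi$tensor), c(8L, 2000L))
  expect_equal(length(mi$static), 19L)
  expect_equal(unname(mi$static[c("sex_female", "sex_male")]), c(1, 0))
  # z-scored channels
  expect_lt(max(abs(rowMeans(mi$tensor))), 1e-10)
  expect_lt(max(abs(apply(mi$tensor, 1, sd) - 1)), 1e-10)
  # future-week PMSI slots are zero for a week-0 recording
  expect_true(all(mi$static[grep("_w(8|16|24)$", names(mi$static))] == 0))
  expect_true(all(mi$static[grep("_w0$", names(mi$static))] != 0))

  # an 18-s recording is centred with 100 zeros each side
  rec18 <- make_recording(T = 18000L)
  mi18 <- build_model_inputs(rec18, st, tensor_spec(100, 2000L,
                                                    normalization = "none"))
  expect_true(all(mi18$tensor[, 1:100] == 0))
  expect_true(all(mi18$tensor[, 1901:2000] == 0))
  expect_false(any(mi18$tensor[, 101] == 0))

  expect_error(build_model_inputs(rec20, st, tensor_spec(2000, 100L)),
               "target rate")
})
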