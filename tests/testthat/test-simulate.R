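test_that("statics generator is deterministic and respects edge cases", {
  p <- tiny_params(5L, seed = 9L)
  a <- simulate_statics(p)
  b <- simulate_statics(p)
  expect_identical(a, b)
  expect_equal(nrow(simulate_statics(tiny_params(0L))), 0L)
  expect_true(all(a$age >= 10 & a$age <= 18))
  expect_true(all(a$bmi > 0))
  expect_true(all(a$risser >= 0 & a$risser <= 5))
})

test_that("statics moments match the cohort targets at n = 5000", {
  st <- simulate_statics(sim_params(n_patients = 5000L, seed = 3L))
  expect_lt(abs(mean(st$age) - 14.6), 0.1)
  expect_lt(abs(mean(st$sex == "female") - 0.46), 0.02)
  expect_lt(abs(mean(st$curve_direction == "left") - 0.647), 0.02)
  expect_lt(abs(mean(st$bmi) - 17.29), 0.06)
})

test_that("outcome moments track the published baseline/post values", {
  p <- sim_params(n_patients = 5000L, seed = 4L)
  st <- simulate_statics(p)
  oc <- simulate_outcomes(st, p)$outcomes
  expect_lt(abs(mean(oc$cobb_L[oc$week == 0]) - 15.28), 0.2)
  expect_lt(abs(mean(oc$cobb_L[oc$week == 24]) - 9.53), 0.2)
  expect_lt(abs(mean(oc$cobb_T[oc$week == 0]) - 19.12), 0.2)
  expect_lt(abs(mean(oc$bst[oc$week == 0]) - 88.34), 2)
  expect_lt(abs(mean(oc$bst[oc$week == 24]) - 109.85), 2)
  expect_lt(abs(mean(oc$srs22[oc$week == 0]) - 3.25), 0.05)
  expect_lt(abs(mean(oc$art_T[oc$week == 0]) - 8.97), 0.15)
  expect_lt(abs(mean(oc$art_L[oc$week == 0]) - 4.36), 0.15)
  expect_true(all(oc$bst >= 0 & oc$bst <= 240))
  expect_true(all(oc$srs22 >= 1 & oc$srs22 <= 5))
})

test_that("latent Cobb trajectories are linear in week", {
  sim <- tiny_sim(3L)
  traj <- sim$ground_truth$trajectories
  for (pid in unique(traj$patient_id)) {
    tr <- traj[traj$patient_id == pid, ]
    v0 <- tr$cobb_T[tr$week == 0]
    v24 <- tr$cobb_T[tr$week == 24]
    expect_equal(tr$cobb_T[tr$week == 8], v0 + (v24 - v0) / 3)
    # interpolated midpoint equals the average of the endpoints
    panel <- sim$cohort$outcomes[sim$cohort$outcomes$patient_id == pid, ]
    expect_equal(cobb_at_week(panel, 12, "lumbar"),
                 (panel$cobb_L[panel$week == 0] +
                    panel$cobb_L[panel$week == 24]) / 2)
  }
})

test_that("recording synthesis yields the designed length and asymmetry", {
  p <- sim_params(n_patients = 1L, seed = 5L)
  st <- simulate_statics(p)
  oc <- simulate_outcomes(st, p)$outcomes
  rec <- synthesize_recording(st[1L, ], oc, 0L, "quadruped", p, seed = 10L)
  expect_equal(ncol(rec$signals), 20000L)  # 20 s at 1000 Hz

  # zero regional Cobb means a symmetric pair by construction
  oc0 <- oc
  oc0$cobb_T[] <- 0
  oc0$cobb_L[] <- 0
  p0 <- tiny_params(1L, seed = 6L, duration_s = 4)
  feats <- extract_features(
    synthesize_recording(st[1L, ], oc0, 0L, "quadruped", p0, seed = 11L),
    st[1L, ])
  expect_lt(abs(feats$pmsi[["erector_spinae"]] - 1), 0.08)

  # same seed, same recording
  r1 <- synthesize_recording(st[1L, ], oc, 0L, "quadruped", p0, seed = 3L)
  r2 <- synthesize_recording(st[1L, ], oc, 0L, "quadruped", p0, seed = 3L)
  expect_identical(r1$signals, r2$signals)
  expect_error(synthesize_recording(st[1L, ], oc, 3L, "quadruped", p0, 1L),
               "week")
})

test_that("band-passed RMS of synthesized channels matches the latent target", {
  sim <- tiny_sim(2L, duration_s = 4)
  gt <- sim$ground_truth$rms_targets
  rec <- sim$cohort$recordings[[1L]]
  feats <- extract_features(
    rec, sim$cohort$statics[sim$cohort$statics$patient_id == rec$patient_id, ])
  tg <- gt[gt$patient_id == rec$patient_id & gt$week == rec$week, ]
  tgv <- tg$target_rms_uv[match(muscle_channels(), tg$channel)]
  # per-recording lognormal gain sd is 0.02; allow 4 sd
  expect_true(all(abs(log(feats$rms / tgv)) < 0.08))
})

test_that("pre-filter and post-filter RMS differ (artifact components present)", {
  sim <- tiny_sim(2L)
  rec <- sim$cohort$recordings[[1L]]
  raw_rms <- apply(rec$signals, 1L, rms)
  filt_rms <- extract_features(
    rec, sim$cohort$statics[sim$cohort$statics$patient_id == rec$patient_id, ])$rms
  expect_true(all(raw_rms > filt_rms))  # out-of-band power removed
  expect_gt(min(raw_rms - filt_rms), 0.5)
})

test_that("erector spinae PMSI correlates positively with thoracic Cobb", {
  # latent targets at cohort scale (the measured PMSI tracks these targets
  # to within the small per-recording gain noise; see the RMS-target test)
  p <- sim_params(n_patients = 143L, seed = 13L)
  st <- simulate_statics(p)
  gt <- simulate_outcomes(st, p)$ground_truth
  tg <- gt$rms_targets[gt$rms_targets$week == 0L &
                         grepl("erector", gt$rms_targets$channel), ]
  es <- merge(tg, st[, c("patient_id", "convex_thoracic")])
  es$side <- sub(".*_", "", es$channel)
  cx <- es[es$side == es$convex_thoracic, ]
  cc <- es[es$side != es$convex_thoracic, ]
  pm <- cx$target_rms_uv / cc$target_rms_uv[match(cx$patient_id,
                                                  cc$patient_id)]
  cobb <- gt$trajectories$cobb_T[match(paste(cx$patient_id, 0),
                                       paste(gt$trajectories$patient_id,
                                             gt$trajectories$week))]
  expect_gt(cor(pm, cobb, method = "spearman"), 0)

  # and the measured PMSI of a small simulated cohort agrees with the
  # latent ratio per patient
  sim <- tiny_sim(4L, duration_s = 1)
  prep <- semgcobb:::prepare_cohort_inputs(sim$cohort, tiny_tensor_spec(100L))
  gt2 <- sim$ground_truth$rms_targets
  for (i in which(prep$meta$week == 0L)[1:4]) {
    pid <- prep$meta$patient_id[i]
    tg2 <- gt2[gt2$patient_id == pid & gt2$week == 0L, ]
    stt <- sim$cohort$statics[sim$cohort$statics$patient_id == pid, ]
    cxc <- paste0("erector_spinae_", stt$convex_thoracic)
    ccc <- setdiff(grep("erector", tg2$channel, value = TRUE), cxc)
    latent <- tg2$target_rms_uv[tg2$channel == cxc] /
      tg2$target_rms_uv[tg2$channel == ccc]
    expect_equal(unname(prep$pmsi[i, "erector_spinae"]), latent,
                 tolerance = 0.1)
  }
})

test_that("identical (params, seed) give bit-identical cohorts", {
  a <- simulate_cohort(tiny_params(2L, seed = 77L))
  b <- simulate_cohort(tiny_params(2L, seed = 77L))
  expect_identical(a$cohort$statics, b$cohort$statics)
  expect_identical(a$cohort$outcomes, b$cohort$outcomes)
  expect_identical(lapply(a$cohort$recordings, `[[`, "signals"),
                   lapply(b$cohort$recordings, `[[`, "signals"))
})
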