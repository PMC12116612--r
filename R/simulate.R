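#' Simulation parameters for a synthetic AIS cohort
#'
#' Defaults encode the study design and the published cohort statistics:
#' 143 patients, four 20-s isometric exercise holds recorded on 8 channels at
#' 1000 Hz at weeks 0/8/16/24, age 14.6 +/- 2.7 y (46% female), baseline
#' thoracic/lumbar Cobb 19.12 +/- 5.95 / 15.28 +/- 6.71 degrees with lumbar
#' post-treatment 9.53 +/- 4.21, and erector spinae RMS 38.57 (convex) /
#' 25.56 (concave) microvolt with mean PMSI 1.37.
#'
#' The convex/concave asymmetry of a paraspinal pair is `1 + asym_gain *
#' regional Cobb * eta`, where `eta` is a patient-level lognormal modifier
#' tied to the BMI latent. Its loading is derived in closed form so that the
#' cohort jointly matches the convex mean, the concave mean and the mean
#' ratio (a mean-of-ratios below the ratio-of-means requires positive
#' covariance between activation level and asymmetry; independence cannot
#' produce it).
#'
#' @param n_patients cohort size.
#' @param seed integer master seed; every stochastic stage derives a
#'   deterministic sub-seed from it.
#' @param duration_s,sample_rate_hz hold length (s) and sampling rate (Hz).
#' @param age_mean,age_sd,frac_female,bmi_mean,bmi_sd,risser_mean,risser_sd
#'   demographic targets (means are matched after truncation).
#' @param frac_left_curve probability the main curve is convex to the left.
#' @param cobbT0_mean,cobbT0_sd,cobbL0_mean,cobbL0_sd baseline Cobb targets,
#'   degrees, truncated to \[5, 40\].
#' @param cobbL24_mean,cobbL24_sd lumbar post-treatment targets.
#' @param cobbT_reduction_frac mean fractional thoracic Cobb reduction over 24
#'   weeks; default mirrors the lumbar relative reduction 1 - 9.53/15.28
#'   (the thoracic post-treatment cell is not published).
#' @param reduction_conc concentration of the Beta-distributed per-patient
#'   retention fraction.
#' @param rms_concave_mean,rms_concave_sd,rms_convex_mean,rms_convex_sd
#'   erector spinae band-passed RMS targets, microvolt.
#' @param pmsi0_mean target mean baseline erector spinae PMSI.
#' @param asym_gain PMSI-Cobb coupling per degree; `NULL` derives
#'   `(pmsi0_mean - 1) / cobbT0_mean`. Set to 0 for a no-signal cohort.
#' @param asym_noise_sd log-sd of the asymmetry modifier not explained by the
#'   BMI latent (the irreducible noise of the Cobb signal).
#' @param level_bmi_corr correlation between the activation-level latent and
#'   the BMI latent.
#' @param rec_noise_sd per-recording, per-channel lognormal gain sd.
#' @param artifact_amp RMS amplitude (microvolt) of sub-20 Hz motion/baseline
#'   artifact added to each raw channel.
#' @param hf_noise_amp RMS amplitude (microvolt) of >400 Hz contamination.
#' @param artT_couple,artL_couple degrees of trunk rotation per degree of
#'   (mean-centred) regional Cobb; the lumbar coupling is deliberately weak.
#' @param artT_noise_sd,artL_noise_sd,srs22_noise_sd,bst_noise_sd outcome
#'   noise scales. SRS-22 receives independent noise only (no EMG coupling).
#' @param bst_couple seconds of Biering-Sorensen hold per unit of the
#'   activation-level latent.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_patients = 143L, seed = 1L,
                       duration_s = 20, sample_rate_hz = 1000,
                       age_mean = 14.6, age_sd = 2.7, frac_female = 0.46,
                       bmi_mean = 17.29, bmi_sd = 1.23,
                       risser_mean = 1.52, risser_sd = 1.21,
                       frac_left_curve = 0.647,
                       cobbT0_mean = 19.12, cobbT0_sd = 5.95,
                       cobbL0_mean = 15.28, cobbL0_sd = 6.71,
                       cobbL24_mean = 9.53, cobbL24_sd = 4.21,
                       cobbT_reduction_frac = NULL,
                       reduction_conc = 170,
                       rms_concave_mean = 25.56, rms_concave_sd = 7.83,
                       rms_convex_mean = 38.57, rms_convex_sd = 7.43,
                       pmsi0_mean = 1.37,
                       asym_gain = NULL,
                       asym_noise_sd = 0.10,
                       level_bmi_corr = 0.9,
                       rec_noise_sd = 0.02,
                       artifact_amp = 10, hf_noise_amp = 3,
                       artT_couple = 0.30, artL_couple = 0.18,
                       artT_noise_sd = 1.8, artL_noise_sd = 2.36,
                       srs22_noise_sd = 0.29,
                       bst_couple = 23, bst_noise_sd = 26.6) {
  if (is.null(cobbT_reduction_frac)) {
    cobbT_reduction_frac <- 1 - cobbL24_mean / cobbL0_mean
  }
  if (is.null(asym_gain)) asym_gain <- (pmsi0_mean - 1) / cobbT0_mean
  p <- as.list(environment())
  stopifnot(p$n_patients >= 0, p$duration_s > 0, p$sample_rate_hz > 800,
            p$frac_female >= 0, p$frac_female <= 1,
            p$frac_left_curve >= 0, p$frac_left_curve <= 1,
            p$age_sd >= 0, p$cobbT0_sd >= 0, p$cobbL0_sd >= 0,
            p$rms_concave_sd >= 0, p$rms_convex_sd >= 0,
            p$asym_gain >= 0, p$rec_noise_sd >= 0,
            p$level_bmi_corr >= 0, p$level_bmi_corr <= 1)
  structure(p, class = "sim_params")
}

# Per-muscle scale of the concave-side level relative to erector spinae.
# Only erector spinae values are published; the remaining pairs use fixed
# documented ratios of the same generative family.
MUSCLE_LEVEL_SCALE <- c(erector_spinae = 1, multifidus = 0.85,
                        rectus_abdominis = 0.45, external_oblique = 0.55)
# Relative strength of the Cobb-asymmetry coupling per pair: the paraspinal
# pairs carry the full coupling; abdominal pairs a weak echo of the thoracic
# curve.
MUSCLE_ASYM_SCALE <- c(erector_spinae = 1, multifidus = 1,
                       rectus_abdominis = 0.3, external_oblique = 0.3)
MUSCLE_REGION <- c(erector_spinae = "thoracic", multifidus = "lumbar",
                   rectus_abdominis = "thoracic", external_oblique = "thoracic")

# Lognormal loading of the asymmetry modifier on the BMI latent, solved so
# that E[convex] = rms_convex_mean given E[concave] and E[PMSI] (see
# sim_params docs). Zero when there is no asymmetry signal.
asym_level_loading <- function(p) {
  if (p$asym_gain <= 0) return(0)
  excess <- p$rms_convex_mean - p$rms_concave_mean * p$pmsi0_mean
  excess / (p$asym_gain * p$cobbT0_mean * p$rms_concave_sd * p$level_bmi_corr)
}

patient_latents <- function(patient_id, p) {
  with_seed(derive_seed(p$seed, "latent", patient_id), {
    list(v = rnorm(1), eps = rnorm(1))
  })
}

#' Simulate patient statics
#'
#' @param params a [sim_params()] object.
#' @return statics data.frame, one row per patient (see [patient_static()]).
#' @export
simulate_statics <- function(params) {
  p <- params
  n <- as.integer(p$n_patients)
  ids <- sprintf("P%04d", seq_len(n))
  if (n == 0L) {
    return(patient_static("x", 14, "female", 17, 1, "left")[0, ])
  }
  with_seed(derive_seed(p$seed, "statics"), {
    u <- rnorm(n)                       # BMI latent, reused downstream
    bmi <- pmax(1, p$bmi_mean + p$bmi_sd * u)
    age <- rtruncnorm_cal(n, p$age_mean, p$age_sd, 10, 18)
    risser <- rtruncnorm_cal(n, p$risser_mean, p$risser_sd, 0, 5)
    sex <- ifelse(rbinom(n, 1L, p$frac_female) == 1L, "female", "male")
    left <- rbinom(n, 1L, p$frac_left_curve) == 1L
    do.call(rbind, lapply(seq_len(n), function(i) {
      patient_static(ids[i], age[i], sex[i], bmi[i], risser[i],
                     if (left[i]) "left" else "right")
    }))
  })
}

linear_path <- function(w, v0, v24) v0 + (v24 - v0) * w / 24

#' Linearly interpolated Cobb trajectory
#'
#' Cobb angles are measured radiographically at weeks 0 and 24 only; the
#' latent trajectory between them is linear in week.
#'
#' @param panel outcome rows for one patient (as from [outcome_panel()]).
#' @param week week at which to evaluate.
#' @param region `"thoracic"` or `"lumbar"`.
#' @return Cobb angle in degrees.
#' @export
cobb_at_week <- function(panel, week, region = c("thoracic", "lumbar")) {
  region <- match.arg(region)
  var <- if (region == "thoracic") "cobb_T" else "cobb_L"
  v0 <- panel[[var]][panel$week == 0L]
  v24 <- panel[[var]][panel$week == 24L]
  if (!length(v0) || !length(v24) || is.na(v0) || is.na(v24)) {
    abort_semg("Cobb trajectory needs week-0 and week-24 values",
               "semgcobb_missing_cobb")
  }
  linear_path(week, v0, v24)
}

#' Simulate clinical outcomes for a cohort
#'
#' Draws baseline Cobb angles from mean-calibrated truncated normals, applies
#' per-patient Beta-distributed retention fractions so the week-24 cohort
#' moments match their targets, and generates ART, SRS-22 and BST at all four
#' weeks as monotone mean trends plus noise calibrated to the published
#' baseline/post values. ART-T couples moderately to thoracic Cobb and BST to
#' the activation-level latent; ART-L couples only weakly and SRS-22 not at
#' all, so their near-unpredictability is a designed property of the cohort.
#'
#' @param statics data.frame from [simulate_statics()].
#' @param params a [sim_params()] object.
#' @return list with `outcomes` (data.frame, 4 rows per patient) and
#'   `ground_truth` (list: `trajectories` data.frame of latent weekly Cobb
#'   values; `rms_targets` data.frame of per (patient, week, channel) target
#'   band-passed RMS).
#' @export
simulate_outcomes <- function(statics, params) {
  p <- params
  n <- nrow(statics)
  if (n == 0L) {
    return(list(outcomes = outcome_panel("x")[0, ],
                ground_truth = list(trajectories = NULL, rms_targets = NULL)))
  }
  ids <- statics$patient_id
  with_seed(derive_seed(p$seed, "outcomes"), {
    cobb_T0 <- rtruncnorm_cal(n, p$cobbT0_mean, p$cobbT0_sd, 5, 40)
    cobb_L0 <- rtruncnorm_cal(n, p$cobbL0_mean, p$cobbL0_sd, 5, 40)
    m_T <- 1 - p$cobbT_reduction_frac
    m_L <- p$cobbL24_mean / p$cobbL0_mean
    nu <- p$reduction_conc
    r_T <- rbeta(n, m_T * nu, (1 - m_T) * nu)
    r_L <- rbeta(n, m_L * nu, (1 - m_L) * nu)
    cobb_T24 <- cobb_T0 * r_T
    cobb_L24 <- cobb_L0 * r_L

    u <- (statics$bmi - p$bmi_mean) / p$bmi_sd
    lat <- lapply(ids, patient_latents, p = p)
    v <- vapply(lat, `[[`, numeric(1), "v")
    z_level <- p$level_bmi_corr * u + sqrt(1 - p$level_bmi_corr^2) * v

    rows <- vector("list", n * 4L)
    traj <- vector("list", n * 4L)
    k <- 0L
    for (i in seq_len(n)) {
      for (w in MEASUREMENT_WEEKS) {
        k <- k + 1L
        cT <- linear_path(w, cobb_T0[i], cobb_T24[i])
        cL <- linear_path(w, cobb_L0[i], cobb_L24[i])
        mean_cT <- linear_path(w, p$cobbT0_mean, p$cobbT0_mean * m_T)
        mean_cL <- linear_path(w, p$cobbL0_mean, p$cobbL24_mean)
        art_T <- max(0, linear_path(w, 8.97, 3.64) +
                       p$artT_couple * (cT - mean_cT) +
                       rnorm(1, 0, p$artT_noise_sd))
        art_L <- max(0, linear_path(w, 4.36, 2.23) +
                       p$artL_couple * (cL - mean_cL) +
                       rnorm(1, 0, p$artL_noise_sd))
        srs <- min(5, max(1, linear_path(w, 3.25, 4.54) +
                            rnorm(1, 0, p$srs22_noise_sd)))
        bst <- min(240, max(0, linear_path(w, 88.34, 109.85) +
                              p$bst_couple * z_level[i] +
                              rnorm(1, 0, p$bst_noise_sd)))
        rows[[k]] <- outcome_panel(
          ids[i], week = w,
          cobb_T = if (w %in% c(0L, 24L)) cT else NA_real_,
          cobb_L = if (w %in% c(0L, 24L)) cL else NA_real_,
          art_T = art_T, art_L = art_L, srs22 = srs, bst = bst)
        traj[[k]] <- data.frame(patient_id = ids[i], week = w,
                                cobb_T = cT, cobb_L = cL,
                                stringsAsFactors = FALSE)
      }
    }
    outcomes <- do.call(rbind, rows)
    trajectories <- do.call(rbind, traj)
    gt_rms <- rms_target_table(statics, outcomes, p)
    list(outcomes = outcomes,
         ground_truth = list(trajectories = trajectories,
                             rms_targets = gt_rms))
  })
}

# Deterministic per (patient, week, channel) target band-passed RMS. The same
# target applies to all four exercises; only per-recording gain noise varies
# between recordings.
channel_rms_targets <- function(static, panel, week, p) {
  info <- muscle_channel_info()
  u <- (static$bmi - p$bmi_mean) / p$bmi_sd
  lat <- patient_latents(static$patient_id, p)
  z_level <- p$level_bmi_corr * u + sqrt(1 - p$level_bmi_corr^2) * lat$v
  rho <- asym_level_loading(p)
  tau <- p$asym_noise_sd
  eta <- exp(rho * u - rho^2 / 2 + tau * lat$eps - tau^2 / 2)

  out <- numeric(8)
  names(out) <- info$code
  for (m in names(MUSCLE_LEVEL_SCALE)) {
    scale <- MUSCLE_LEVEL_SCALE[[m]]
    region <- MUSCLE_REGION[[m]]
    concave_level <- max(3, scale * (p$rms_concave_mean +
                                       p$rms_concave_sd * z_level))
    cobb_w <- cobb_at_week(panel, week, region)
    gain <- p$asym_gain * MUSCLE_ASYM_SCALE[[m]]
    eta_m <- if (MUSCLE_ASYM_SCALE[[m]] == 1) eta else 1
    ratio <- 1 + gain * cobb_w * eta_m
    convex_side <- if (region == "thoracic") static$convex_thoracic
                   else static$convex_lumbar
    concave_side <- if (convex_side == "L") "R" else "L"
    out[paste0(m, "_", convex_side)] <- concave_level * ratio
    out[paste0(m, "_", concave_side)] <- concave_level
  }
  out
}

rms_target_table <- function(statics, outcomes, p) {
  rows <- list()
  for (i in seq_len(nrow(statics))) {
    static <- statics[i, ]
    panel <- outcomes[outcomes$patient_id == static$patient_id, ]
    for (w in MEASUREMENT_WEEKS) {
      tg <- channel_rms_targets(static, panel, w, p)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = static$patient_id, week = w,
        channel = names(tg), target_rms_uv = unname(tg),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Cached spectral shaping for in-band synthetic noise: the zero-phase
# Butterworth band-pass magnitude on the FFT grid, plus the analytic factor
# by which one further pass of the analysis band-pass shrinks the RMS of
# noise with this spectrum (used so the *band-passed* RMS of a synthesized
# channel equals its calibration target).
.semg_cache <- new.env(parent = emptyenv())
band_shape <- function(nT, rate) {
  key <- sprintf("shape_%d_%g", nT, rate)
  if (is.null(.semg_cache[[key]])) {
    f <- (seq_len(nT) - 1) * rate / nT
    ffold <- pmin(f, rate - f)
    g <- bandpass_gain(ffold, rate, filter_spec(mode = "zero_phase"))
    corr <- sqrt(sum(g^4) / sum(g^2))
    .semg_cache[[key]] <- list(g = g, corr = corr)
  }
  .semg_cache[[key]]
}

#' Synthesize one sEMG recording
#'
#' Each channel is in-band (20--400 Hz) shaped Gaussian noise scaled exactly
#' to its target RMS, plus a sub-20 Hz baseline-wander component of RMS
#' `artifact_amp` and a >400 Hz component of RMS `hf_noise_amp`. The target
#' RMS of the convex-side member of a paraspinal pair exceeds the concave
#' side by `1 + asym_gain * regional Cobb * eta` (see [sim_params()]), so the
#' band-passed PMSI of the recording tracks the patient's Cobb angle.
#'
#' @param static one statics row.
#' @param panel outcome rows for the patient.
#' @param week measurement week.
#' @param exercise exercise code.
#' @param params a [sim_params()] object.
#' @param seed integer seed for this recording's noise.
#' @return an [emg_recording()].
#' @export
synthesize_recording <- function(static, panel, week, exercise, params,
                                 seed = 1L) {
  p <- params
  week <- assert_week(week)
  targets <- channel_rms_targets(static, panel, week, p)
  rate <- p$sample_rate_hz
  nT <- round(p$duration_s * rate)
  shape <- band_shape(nT, rate)
  tt <- (seq_len(nT) - 1) / rate
  with_seed(seed, {
    gains <- exp(p$rec_noise_sd * rnorm(8) - p$rec_noise_sd^2 / 2)
    sig <- matrix(0, 8L, nT)
    for (ch in 1:8) {
      x <- Re(stats::fft(stats::fft(rnorm(nT)) * shape$g, inverse = TRUE)) / nT
      x <- x * (targets[ch] * gains[ch]) / (sqrt(mean(x^2)) * shape$corr)
      f_lo <- runif(2, c(0.3, 5), c(5, 15))
      # two unit-RMS-sum sinusoids: each has RMS 1/sqrt(2)
      art <- p$artifact_amp *
        (sin(2 * pi * f_lo[1] * tt + runif(1, 0, 2 * pi)) +
         sin(2 * pi * f_lo[2] * tt + runif(1, 0, 2 * pi)))
      f_hi <- runif(1, 410, 0.96 * rate / 2)
      hf <- sqrt(2) * p$hf_noise_amp *
        sin(2 * pi * f_hi * tt + runif(1, 0, 2 * pi))
      sig[ch, ] <- x + art + hf
    }
    emg_recording(static$patient_id, week, exercise, sig, rate)
  })
}

#' Simulate a complete cohort
#'
#' Composes [simulate_statics()], [simulate_outcomes()] and
#' [synthesize_recording()] into a complete cohort: one recording per
#' (patient, week, exercise), i.e. 16 per patient and 2288 for the default
#' 143-patient design. Fully deterministic given `params$seed`.
#'
#' @param params a [sim_params()] object.
#' @return list with `cohort` (a `semg_cohort`) and `ground_truth` (see
#'   [simulate_outcomes()]).
#' @export
simulate_cohort <- function(params) {
  p <- params
  statics <- simulate_statics(p)
  sim <- simulate_outcomes(statics, p)
  outcomes <- sim$outcomes
  n <- nrow(statics)
  recs <- vector("list", n * 16L)
  k <- 0L
  for (i in seq_len(n)) {
    static <- statics[i, ]
    panel <- outcomes[outcomes$patient_id == static$patient_id, ]
    for (w in MEASUREMENT_WEEKS) {
      for (ex in exercise_types()) {
        k <- k + 1L
        recs[[k]] <- synthesize_recording(
          static, panel, w, ex, p,
          seed = derive_seed(p$seed, "rec", static$patient_id, w, ex))
      }
    }
  }
  list(cohort = cohort(statics, outcomes, recs), ground_truth = sim$ground_truth)
}
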