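#' Band-pass filter specification
#'
#' The study's signal conditioning: a fourth-order Butterworth band-pass with
#' 20 Hz and 400 Hz cutoffs. The 20 Hz edge removes slow motion/respiration
#' artifact; the 400 Hz edge removes high-frequency noise. The default
#' zero-phase mode applies the filter forward and backward, which introduces
#' no phase shift and squares the magnitude response (effective order-8
#' attenuation); causal mode applies it once.
#'
#' @param order filter order (per pass).
#' @param low_hz,high_hz band edges in Hz.
#' @param mode `"zero_phase"` (default) or `"causal"`.
#' @return list of class `filter_spec`.
#' @export
filter_spec <- function(order = 4L, low_hz = 20, high_hz = 400,
                        mode = c("zero_phase", "causal")) {
  mode <- match.arg(mode)
  stopifnot(order >= 1, low_hz > 0, high_hz > low_hz)
  structure(list(order = as.integer(order), low_hz = low_hz,
                 high_hz = high_hz, mode = mode),
            class = "filter_spec")
}

filter_pad <- function(spec, sample_rate_hz) {
  max(3L * (2L * spec$order), as.integer(ceiling(3 * sample_rate_hz /
                                                   spec$low_hz)))
}

check_band <- function(spec, sample_rate_hz) {
  if (spec$high_hz >= sample_rate_hz / 2) {
    abort_semg(sprintf(
      "upper band edge %g Hz infeasible at %g Hz sampling (Nyquist %g)",
      spec$high_hz, sample_rate_hz, sample_rate_hz / 2),
      "semgcobb_bad_band")
  }
}

design_bandpass <- function(spec, sample_rate_hz) {
  key <- sprintf("butter_%d_%g_%g_%g", spec$order, spec$low_hz,
                 spec$high_hz, sample_rate_hz)
  if (is.null(.semg_cache[[key]])) {
    .semg_cache[[key]] <- signal::butter(
      spec$order, c(spec$low_hz, spec$high_hz) / (sample_rate_hz / 2),
      type = "pass")
  }
  .semg_cache[[key]]
}

# One IIR pass via the C filter primitives (direct form: FIR numerator then
# recursive denominator), zero initial state.
iir_pass <- function(b, a, x) {
  nb <- length(b)
  v <- stats::filter(c(numeric(nb - 1L), x), b, method = "convolution",
                     sides = 1L)
  v <- v[-seq_len(nb - 1L)]
  as.numeric(stats::filter(v, -a[-1L], method = "recursive"))
}

# Forward-backward (zero-phase) filtering with reflected edge extension to
# suppress end transients. Matrix input is filtered column-wise in one C
# pass.
zero_phase_filter <- function(b, a, x, pad = NULL) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  p <- min(n - 1L, pad %||% (3L * (max(length(a), length(b)) - 1L)))
  front <- 2 * x[rep(1L, p), , drop = FALSE] - x[(p + 1L):2L, , drop = FALSE]
  back <- 2 * x[rep(n, p), , drop = FALSE] -
    x[(n - 1L):(n - p), , drop = FALSE]
  y <- iir_pass_mat(b, a, rbind(front, x, back))
  y <- iir_pass_mat(b, a, y[nrow(y):1L, , drop = FALSE])
  y <- y[nrow(y):1L, , drop = FALSE][(p + 1L):(p + n), , drop = FALSE]
  if (vec) as.numeric(y) else y
}

iir_pass_mat <- function(b, a, x) {
  nb <- length(b)
  v <- stats::filter(rbind(matrix(0, nb - 1L, ncol(x)), x), b,
                     method = "convolution", sides = 1L)
  v <- v[-seq_len(nb - 1L), , drop = FALSE]
  y <- stats::filter(v, -a[-1L], method = "recursive")
  matrix(as.numeric(y), nrow(x), ncol(x))
}

#' Apply the Butterworth band-pass filter
#'
#' @param x numeric vector (one channel).
#' @param sample_rate_hz sampling rate in Hz.
#' @param spec a [filter_spec()].
#' @return filtered vector, same length as `x`.
#' @export
bandpass_filter <- function(x, sample_rate_hz, spec = filter_spec()) {
  check_band(spec, sample_rate_hz)
  if (length(x) < 3 * spec$order) {
    abort_semg(sprintf("sequence too short to filter (%d < %d)",
                       length(x), 3 * spec$order), "semgcobb_short_signal")
  }
  bf <- design_bandpass(spec, sample_rate_hz)
  if (spec$mode == "zero_phase") {
    # pad long enough for the slow dynamics at the low band edge to settle
    zero_phase_filter(bf$b, bf$a, x,
                      pad = filter_pad(spec, sample_rate_hz))
  } else {
    iir_pass(bf$b, bf$a, x)
  }
}

# All 8 channels of a recording in one filtering pass: signals is [C x T],
# returns the same shape.
bandpass_channels <- function(signals, sample_rate_hz, spec = filter_spec()) {
  check_band(spec, sample_rate_hz)
  bf <- design_bandpass(spec, sample_rate_hz)
  M <- t(signals)
  out <- if (spec$mode == "zero_phase") {
    zero_phase_filter(bf$b, bf$a, M, pad = filter_pad(spec, sample_rate_hz))
  } else {
    iir_pass_mat(bf$b, bf$a, M)
  }
  t(out)
}

# Anti-alias + stride for all channels at once (FFT convolution).
decimate_channels <- function(signals, rate, target_rate) {
  if (target_rate > rate) {
    abort_semg("target rate exceeds recording rate", "semgcobb_bad_tensor")
  }
  factor <- round(rate / target_rate)
  if (factor <= 1L) return(signals)
  key <- sprintf("fir_%g_%g", rate, target_rate)
  if (is.null(.semg_cache[[key]])) {
    .semg_cache[[key]] <- signal::fir1(64L, (0.9 * target_rate) / rate)
  }
  h <- .semg_cache[[key]]
  half <- (length(h) - 1L) %/% 2L
  M <- t(signals)
  np <- stats::nextn(nrow(M) + length(h) - 1L, c(2L, 3L, 5L))
  H <- stats::fft(c(h, numeric(np - length(h))))
  Xp <- rbind(M, matrix(0, np - nrow(M), ncol(M)))
  Y <- Re(stats::mvfft(stats::mvfft(Xp) * H, inverse = TRUE)) / np
  Y <- Y[(half + 1L):(half + nrow(M)), , drop = FALSE]
  t(Y[seq(1L, nrow(Y), by = factor), , drop = FALSE])
}

#' Closed-form magnitude response of the band-pass stage
#'
#' Analytic order-`n` Butterworth band-pass magnitude evaluated at the
#' bilinear-prewarped digital frequency, so it describes the discrete filter
#' exactly; in zero-phase mode the magnitude is squared (forward-backward
#' application). Used as the independent check of the time-domain filter.
#'
#' @param f frequency in Hz (vectorised).
#' @param sample_rate_hz sampling rate in Hz.
#' @param spec a [filter_spec()].
#' @return gain in \[0, 1\].
#' @export
bandpass_gain <- function(f, sample_rate_hz, spec = filter_spec()) {
  check_band(spec, sample_rate_hz)
  warp <- function(x) tan(pi * x / sample_rate_hz)
  w <- warp(f); w1 <- warp(spec$low_hz); w2 <- warp(spec$high_hz)
  g <- 1 / sqrt(1 + ((w^2 - w1 * w2) / ((w2 - w1) * w))^(2 * spec$order))
  g[f == 0] <- 0
  if (spec$mode == "zero_phase") g^2 else g
}

#' Root mean square amplitude
#'
#' `sqrt(mean(x^2))` -- the amplitude feature extracted from each filtered
#' sEMG channel, in the units of the input (microvolt).
#'
#' @param x numeric vector, length >= 1.
#' @return nonnegative scalar.
#' @export
rms <- function(x) {
  if (length(x) == 0L) abort_semg("rms of empty sequence", "semgcobb_empty")
  sqrt(mean(x^2))
}

#' Paraspinal muscle symmetry index
#'
#' Ratio of convex-side to concave-side RMS. A value near 1 indicates
#' symmetric activation; > 1 means the convex side dominates, < 1 the
#' concave side.
#'
#' @param rms_convex,rms_concave nonnegative RMS amplitudes.
#' @return the ratio.
#' @export
pmsi <- function(rms_convex, rms_concave) {
  stopifnot(rms_convex >= 0, rms_concave >= 0)
  if (any(rms_concave == 0)) {
    abort_semg("PMSI undefined: concave-side RMS is zero", "semgcobb_zero_rms")
  }
  rms_convex / rms_concave
}

muscle_pairs <- function() unique(muscle_channel_info()$muscle)

convex_side_for <- function(static, muscle) {
  region <- MUSCLE_REGION[[muscle]]
  if (region == "thoracic") static$convex_thoracic else static$convex_lumbar
}

#' Extract RMS and PMSI features from a recording
#'
#' Band-pass filters every channel, computes per-channel RMS, then one PMSI
#' per muscle pair with the convex side taken from the patient's regional
#' convex-side map (erector spinae and the abdominal pairs follow the
#' thoracic map, multifidus the lumbar map).
#'
#' @param recording an [emg_recording()].
#' @param static the patient's statics row.
#' @param spec a [filter_spec()].
#' @return list of class `semg_features`: `rms` (named, 8), `pmsi` (named by
#'   muscle pair), `sex`, `bmi`, plus the recording's identity fields.
#' @export
extract_features <- function(recording, static, spec = filter_spec()) {
  stopifnot(inherits(recording, "emg_recording"))
  filt <- bandpass_channels(recording$signals, recording$sample_rate_hz,
                            spec)
  rms_ch <- apply(filt, 1L, rms)
  names(rms_ch) <- muscle_channels()
  pmsi_pair <- vapply(muscle_pairs(), function(m) {
    cx <- convex_side_for(static, m)
    cc <- if (cx == "L") "R" else "L"
    pmsi(rms_ch[[paste0(m, "_", cx)]], rms_ch[[paste0(m, "_", cc)]])
  }, numeric(1))
  structure(list(patient_id = recording$patient_id, week = recording$week,
                 exercise = recording$exercise, rms = rms_ch,
                 pmsi = pmsi_pair, sex = static$sex, bmi = static$bmi),
            class = "semg_features")
}

#' Model-input tensor specification
#'
#' Controls how a filtered recording becomes the network's time-series input:
#' decimation to `target_rate_hz` after anti-alias low-pass filtering, then
#' central cropping/zero-padding to `target_len` samples, then optional
#' per-channel z-scoring.
#'
#' @param target_rate_hz resampling rate (must not exceed the recording
#'   rate); default 100 Hz, so a 20-s hold gives 2000 steps.
#' @param target_len time steps of the tensor.
#' @param normalization `"per_channel_zscore"` (default) or `"none"`.
#' @return list of class `tensor_spec`.
#' @export
tensor_spec <- function(target_rate_hz = 100, target_len = 2000L,
                        normalization = c("per_channel_zscore", "none")) {
  normalization <- match.arg(normalization)
  stopifnot(target_len >= 1, target_rate_hz > 0)
  structure(list(target_rate_hz = target_rate_hz,
                 target_len = as.integer(target_len),
                 normalization = normalization),
            class = "tensor_spec")
}

decimate_channel <- function(x, rate, target_rate) {
  if (target_rate > rate) {
    abort_semg("target rate exceeds recording rate", "semgcobb_bad_tensor")
  }
  factor <- round(rate / target_rate)
  if (factor <= 1L) return(x)
  key <- sprintf("fir_%g_%g", rate, target_rate)
  if (is.null(.semg_cache[[key]])) {
    # linear-phase FIR anti-alias low-pass, cutoff at 0.45 x target rate
    .semg_cache[[key]] <- signal::fir1(64L, (0.9 * target_rate) / rate)
  }
  h <- .semg_cache[[key]]
  half <- (length(h) - 1L) %/% 2L
  # FFT-based linear convolution; symmetric FIR, so centring removes the delay
  y <- stats::convolve(x, rev(h), type = "open")
  y <- y[(half + 1L):(half + length(x))]
  y[seq(1L, length(y), by = factor)]
}

pad_or_crop <- function(x, target_len) {
  n <- length(x)
  if (n == target_len) return(x)
  if (n > target_len) {
    start <- (n - target_len) %/% 2L
    return(x[(start + 1L):(start + target_len)])
  }
  left <- (target_len - n) %/% 2L
  c(numeric(left), x, numeric(target_len - n - left))
}

#' Build the model inputs for one recording
#'
#' @param recording an [emg_recording()].
#' @param static the patient's statics row.
#' @param tspec a [tensor_spec()].
#' @param fspec a [filter_spec()].
#' @param pmsi_history optional named list `week -> named pmsi vector` for
#'   this patient (one entry per measurement week with features available).
#'   Only weeks up to and including the recording's week enter the static
#'   vector (no future leakage); the slots of later weeks are zero. When
#'   omitted, the recording's own PMSI fills its own week slot.
#' @return list with `tensor` (8 x `target_len` matrix) and `static` (named
#'   numeric: sex one-hot, BMI, and 4 PMSI slots per measurement week --
#'   zero where not yet available).
#' @export
build_model_inputs <- function(recording, static, tspec = tensor_spec(),
                               fspec = filter_spec(), pmsi_history = NULL) {
  stopifnot(inherits(recording, "emg_recording"))
  rate <- recording$sample_rate_hz
  filt <- bandpass_channels(recording$signals, rate, fspec)
  down <- decimate_channels(filt, rate, tspec$target_rate_hz)
  tens <- t(apply(down, 1L, pad_or_crop, target_len = tspec$target_len))
  if (tspec$normalization == "per_channel_zscore") {
    mu <- rowMeans(tens)
    sdv <- apply(tens, 1L, sd)
    sdv[sdv == 0] <- 1
    tens <- (tens - mu) / sdv
  }
  rownames(tens) <- muscle_channels()

  if (is.null(pmsi_history)) {
    feats <- extract_features(recording, static, fspec)
    pmsi_history <- setNames(list(feats$pmsi), as.character(recording$week))
  }
  pairs <- muscle_pairs()
  slots <- c(sex_female = as.numeric(static$sex == "female"),
             sex_male = as.numeric(static$sex == "male"),
             bmi = as.numeric(static$bmi))
  for (w in MEASUREMENT_WEEKS) {
    vals <- setNames(numeric(length(pairs)),
                     paste0("pmsi_", pairs, "_w", w))
    if (w <= recording$week && !is.null(pmsi_history[[as.character(w)]])) {
      pv <- pmsi_history[[as.character(w)]]
      vals[] <- log(as.numeric(pv[pairs]))  # ratio features enter in logs
    }
    slots <- c(slots, vals)
  }
  list(tensor = tens, static = slots)
}
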