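#' Training protocol specification
#'
#' Adam, at most 100 epochs, early stopping after 10 epochs without
#' validation improvement, a 7:3 train/test split. Splitting is grouped by
#' patient by default so no patient contributes samples to two partitions;
#' 10% of the training patients are carved out as the validation set that
#' drives early stopping, leaving the test set untouched.
#'
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience (epochs without validation-loss
#'   improvement).
#' @param train_frac fraction of patients (or samples) assigned to training.
#' @param val_frac_of_train fraction of the training patients carved out for
#'   validation.
#' @param seed seed for the split and the training loop.
#' @param group_by_patient split at patient granularity (default) rather than
#'   sample granularity.
#' @return list of class `train_spec`.
#' @export
train_spec <- function(max_epochs = 100L, patience = 10L, train_frac = 0.7,
                       val_frac_of_train = 0.1, seed = 1L,
                       group_by_patient = TRUE) {
  stopifnot(train_frac > 0, train_frac < 1, patience <= max_epochs,
            patience >= 1, val_frac_of_train > 0, val_frac_of_train < 1)
  structure(list(max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), train_frac = train_frac,
                 val_frac_of_train = val_frac_of_train,
                 seed = as.integer(seed),
                 group_by_patient = isTRUE(group_by_patient)),
            class = "train_spec")
}

COBB_TARGETS <- c("cobb_T", "cobb_L")

# One filtering pass per recording feeding both the feature set and the
# network tensor; returns everything dataset assembly needs.
prepare_cohort_inputs <- function(chrt, tspec = tensor_spec(),
                                  fspec = filter_spec()) {
  recs <- chrt$recordings
  R <- length(recs)
  stopifnot(R > 0)
  tensors <- array(0, c(R, 8L, tspec$target_len))
  rms_mat <- matrix(0, R, 8L, dimnames = list(NULL, muscle_channels()))
  pmsi_mat <- matrix(0, R, length(muscle_pairs()),
                     dimnames = list(NULL, muscle_pairs()))
  meta <- data.frame(patient_id = character(R), week = integer(R),
                     exercise = character(R), stringsAsFactors = FALSE)
  statics_by_id <- split(chrt$statics, chrt$statics$patient_id)
  for (i in seq_len(R)) {
    rec <- recs[[i]]
    static <- statics_by_id[[rec$patient_id]]
    rate <- rec$sample_rate_hz
    filt <- bandpass_channels(rec$signals, rate, fspec)
    rms_ch <- apply(filt, 1L, rms)
    names(rms_ch) <- muscle_channels()
    rms_mat[i, ] <- rms_ch
    pmsi_mat[i, ] <- vapply(muscle_pairs(), function(m) {
      cx <- convex_side_for(static, m)
      cc <- if (cx == "L") "R" else "L"
      pmsi(rms_ch[[paste0(m, "_", cx)]], rms_ch[[paste0(m, "_", cc)]])
    }, numeric(1))
    down <- decimate_channels(filt, rate, tspec$target_rate_hz)
    tens <- t(apply(down, 1L, pad_or_crop, target_len = tspec$target_len))
    if (tspec$normalization == "per_channel_zscore") {
      mu <- rowMeans(tens)
      sdv <- apply(tens, 1L, sd)
      sdv[sdv == 0] <- 1
      tens <- (tens - mu) / sdv
    }
    tensors[i, , ] <- tens
    meta$patient_id[i] <- rec$patient_id
    meta$week[i] <- rec$week
    meta$exercise[i] <- rec$exercise
  }
  list(tensors = tensors, rms = rms_mat, pmsi = pmsi_mat, meta = meta,
       tensor_spec = tspec, filter_spec = fspec)
}

static_vector_names <- function() {
  # order matches the assembly loop: the 4 pair slots of week 0 first, then
  # week 8, 16, 24
  c("sex_female", "sex_male", "bmi",
    as.vector(outer(paste0("pmsi_", muscle_pairs()),
                    paste0("_w", MEASUREMENT_WEEKS), paste0)))
}

#' Assemble a supervised dataset for one target
#'
#' Cobb targets give one sample per (patient, exercise) at each of weeks 0
#' and 24 with the target equal to that week's regional Cobb angle; the
#' other targets give one sample per (patient, exercise, week). Each sample
#' carries the network tensor, the static vector (sex, BMI, and the
#' PMSI values of the same exercise from all measurement weeks up to and
#' including the sample's week -- no future leakage), and the flat feature
#' vector used by the SVR baseline (per-channel RMS, current PMSI, statics).
#'
#' @param chrt a complete `semg_cohort`.
#' @param target_name one of `"cobb_T"`, `"cobb_L"`, `"art_T"`, `"art_L"`,
#'   `"srs22"`, `"bst"`.
#' @param tspec,fspec tensor and filter specifications.
#' @param prepared optional result of a previous internal preparation pass
#'   over the same cohort (lets a benchmark over several targets filter each
#'   recording only once).
#' @return list of class `semg_dataset` with elements `X` (array
#'   \[N, 8, len\]), `S`, `F` (matrices), `y` (N x 1), `patient_id`, `week`,
#'   `exercise`, `target_name`.
#' @export
make_supervised_samples <- function(chrt, target_name,
                                    tspec = tensor_spec(),
                                    fspec = filter_spec(),
                                    prepared = NULL) {
  if (!target_name %in% OUTCOME_VARS) {
    abort_semg(sprintf("unknown target '%s'", target_name),
               "semgcobb_bad_target")
  }
  prepared <- prepared %||% prepare_cohort_inputs(chrt, tspec, fspec)
  meta <- prepared$meta
  weeks_needed <- if (target_name %in% COBB_TARGETS) c(0L, 24L)
                  else MEASUREMENT_WEEKS
  sel <- which(meta$week %in% weeks_needed)
  n <- length(sel)
  oc <- chrt$outcomes
  statics_by_id <- split(chrt$statics, chrt$statics$patient_id)

  S <- matrix(0, n, length(static_vector_names()),
              dimnames = list(NULL, static_vector_names()))
  Fm <- matrix(0, n, 8L + length(muscle_pairs()) + 3L)
  colnames(Fm) <- c(muscle_channels(), paste0("pmsi_", muscle_pairs()),
                    "sex_female", "sex_male", "bmi")
  y <- matrix(0, n, 1L)
  for (k in seq_len(n)) {
    i <- sel[k]
    pid <- meta$patient_id[i]
    wk <- meta$week[i]
    ex <- meta$exercise[i]
    static <- statics_by_id[[pid]]
    lab <- oc[[target_name]][oc$patient_id == pid & oc$week == wk]
    if (length(lab) != 1L || is.na(lab)) {
      abort_semg(sprintf("missing %s label for (%s, week %d)",
                         target_name, pid, wk), "semgcobb_missing_label")
    }
    y[k, 1L] <- lab
    sv <- c(as.numeric(static$sex == "female"),
            as.numeric(static$sex == "male"),
            static$bmi)
    # PMSI and RMS are strictly positive, right-skewed ratio/amplitude
    # features: both enter the models in log scale (zero = not available)
    for (w in MEASUREMENT_WEEKS) {
      j <- which(meta$patient_id == pid & meta$exercise == ex &
                   meta$week == w)
      sv <- c(sv, if (w <= wk && length(j) == 1L) log(prepared$pmsi[j, ])
                  else numeric(length(muscle_pairs())))
    }
    S[k, ] <- sv
    Fm[k, ] <- c(log(prepared$rms[i, ]), log(prepared$pmsi[i, ]),
                 as.numeric(static$sex == "female"),
                 as.numeric(static$sex == "male"), static$bmi)
  }
  structure(list(X = prepared$tensors[sel, , , drop = FALSE], S = S, F = Fm,
                 y = y, patient_id = meta$patient_id[sel],
                 week = meta$week[sel], exercise = meta$exercise[sel],
                 target_name = target_name,
                 tensor_spec = prepared$tensor_spec,
                 filter_spec = prepared$filter_spec),
            class = "semg_dataset")
}

#' @export
print.semg_dataset <- function(x, ...) {
  cat(sprintf("<semg_dataset:%s> %d samples, %d patients, weeks {%s}\n",
              x$target_name, nrow(x$y), length(unique(x$patient_id)),
              paste(sort(unique(x$week)), collapse = ", ")))
  invisible(x)
}

#' Subset a supervised dataset by sample index
#'
#' @param ds a `semg_dataset`.
#' @param idx integer sample indices.
#' @return a `semg_dataset`.
#' @export
ds_subset <- function(ds, idx) {
  out <- ds
  out$X <- ds$X[idx, , , drop = FALSE]
  out$S <- ds$S[idx, , drop = FALSE]
  out$F <- ds$F[idx, , drop = FALSE]
  out$y <- ds$y[idx, , drop = FALSE]
  out$patient_id <- ds$patient_id[idx]
  out$week <- ds$week[idx]
  out$exercise <- ds$exercise[idx]
  out
}

n_samples <- function(ds) nrow(ds$y)

#' Split a dataset into train / validation / test
#'
#' Grouped (patient-level) splitting by default: `floor(train_frac * n)`
#' patients to training, the rest to test, and `val_frac_of_train` of the
#' training patients carved out for validation -- no patient ever appears in
#' two partitions. Sample-level splitting is available for comparison with
#' protocols that ignore patient grouping.
#'
#' @param ds a `semg_dataset`.
#' @param spec a [train_spec()].
#' @return list with `semg_dataset`s `train`, `val`, `test`.
#' @export
split_dataset <- function(ds, spec = train_spec()) {
  with_seed(derive_seed(spec$seed, "split"), {
    if (spec$group_by_patient) {
      patients <- unique(ds$patient_id)
      if (length(patients) < 3L) {
        abort_semg("grouped splitting needs at least 3 patients",
                   "semgcobb_too_few")
      }
      patients <- sample(patients)
      n_train <- floor(spec$train_frac * length(patients))
      if (n_train < 2L || n_train >= length(patients)) {
        abort_semg("split leaves an empty partition", "semgcobb_too_few")
      }
      train_p <- patients[seq_len(n_train)]
      test_p <- setdiff(patients, train_p)
      n_val <- max(1L, ceiling(spec$val_frac_of_train * length(train_p)))
      val_p <- train_p[seq_len(n_val)]
      train_p <- setdiff(train_p, val_p)
      list(train = ds_subset(ds, which(ds$patient_id %in% train_p)),
           val = ds_subset(ds, which(ds$patient_id %in% val_p)),
           test = ds_subset(ds, which(ds$patient_id %in% test_p)))
    } else {
      n <- n_samples(ds)
      if (n < 10L) abort_semg("too few samples", "semgcobb_too_few")
      idx <- sample(n)
      n_train <- floor(spec$train_frac * n)
      train_i <- idx[seq_len(n_train)]
      test_i <- idx[(n_train + 1L):n]
      n_val <- max(1L, ceiling(spec$val_frac_of_train * length(train_i)))
      val_i <- train_i[seq_len(n_val)]
      train_i <- setdiff(train_i, val_i)
      list(train = ds_subset(ds, train_i), val = ds_subset(ds, val_i),
           test = ds_subset(ds, test_i))
    }
  })
}

col_scaler <- function(M) {
  mu <- colMeans(M)
  sdv <- apply(M, 2L, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(mean = mu, sd = sdv)
}

#' Train a model
#'
#' Neural kinds: minimises mean squared error with Adam (batch size and
#' learning rate from the model config) on feature- and target-standardised
#' data, stopping at the earlier of `max_epochs` or `patience` epochs
#' without validation-loss improvement, and restoring the best-validation
#' weights. The SVR kind fits one epsilon-regression per output on the flat
#' features (deterministic; the epoch loop does not apply).
#'
#' @param handle a `semg_model`.
#' @param train,val `semg_dataset`s.
#' @param spec a [train_spec()].
#' @return the trained `semg_model`; neural models carry a `history`
#'   data.frame of per-epoch train/val loss.
#' @export
train_model <- function(handle, train, val, spec = train_spec()) {
  if (n_samples(train) == 0L || (handle$kind != "svr" && n_samples(val) == 0L)) {
    abort_semg("train and val must be nonempty", "semgcobb_too_few")
  }
  if (handle$kind == "svr") return(train_svr(handle, train))
  cfg <- handle$config

  s_sc <- col_scaler(train$S)
  y_sc <- col_scaler(train$y)
  handle$scalers <- list(s_mean = s_sc$mean, s_sd = s_sc$sd,
                         y_mean = y_sc$mean, y_sd = y_sc$sd)
  Str <- scale_cols(train$S, s_sc$mean, s_sc$sd)
  ytr <- scale_cols(train$y, y_sc$mean, y_sc$sd)
  Sva <- scale_cols(val$S, s_sc$mean, s_sc$sd)
  yva <- scale_cols(val$y, y_sc$mean, y_sc$sd)

  n <- n_samples(train)
  T <- dim(train$X)[3]
  Xm_tr <- array_to_mat(train$X)   # [T*n x C], laid out once
  Xm_va <- array_to_mat(val$X)
  n_va <- n_samples(val)
  state <- adam_init(handle$params)
  best <- list(loss = Inf, params = handle$params, bn = handle$bn, epoch = 0L)
  bad <- 0L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  with_seed(derive_seed(spec$seed, "fit"), {
    for (epoch in seq_len(spec$max_epochs)) {
      ord <- sample(n)
      ep_loss <- 0
      nb <- 0L
      for (start in seq(1L, n, by = cfg$batch_size)) {
        ii <- ord[start:min(start + cfg$batch_size - 1L, n)]
        rows <- rep((ii - 1L) * T, each = T) + seq_len(T)
        lg <- nn_loss_grad(handle, Xm_tr[rows, , drop = FALSE], T,
                           length(ii), Str[ii, , drop = FALSE],
                           ytr[ii, , drop = FALSE], train = TRUE)
        if (!is.finite(lg$loss)) {
          abort_semg(sprintf(
            "non-finite training loss at epoch %d (lr %.4g): aborting",
            epoch, cfg$learning_rate), "semgcobb_diverged")
        }
        handle$bn <- lg$bn
        gr <- clip_grads(lg$grads, cfg$grad_clip)
        st <- adam_step(handle$params, gr, state, cfg$learning_rate)
        handle$params <- st$params
        state <- st$state
        ep_loss <- ep_loss + lg$loss
        nb <- nb + 1L
      }
      val_pred <- nn_forward(handle, Xm_va, T, n_va, Sva,
                             train = FALSE)$yhat
      val_loss <- mean((val_pred - yva)^2)
      hist <- rbind(hist, data.frame(epoch = epoch,
                                     train_loss = ep_loss / nb,
                                     val_loss = val_loss))
      if (val_loss < best$loss) {
        best <- list(loss = val_loss, params = handle$params,
                     bn = handle$bn, epoch = epoch)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= spec$patience) break
      }
    }
  })
  handle$params <- best$params
  handle$bn <- best$bn
  handle$history <- hist
  handle$trained <- TRUE
  handle$y_clamp <- clamp_range(train$y)
  handle
}

# Outcomes are bounded clinical quantities: trained models never
# extrapolate beyond the observed training range (plus a 10% margin).
clamp_range <- function(y) {
  r <- range(y)
  r + c(-1, 1) * 0.1 * diff(r)
}

train_svr <- function(handle, train) {
  cfg <- handle$config
  f_sc <- col_scaler(train$F)
  y_sc <- col_scaler(train$y)
  Fs <- scale_cols(train$F, f_sc$mean, f_sc$sd)
  ys <- scale_cols(train$y, y_sc$mean, y_sc$sd)
  handle$feature_dim <- ncol(train$F)
  handle$scalers <- list(f_mean = f_sc$mean, f_sd = f_sc$sd,
                         y_mean = y_sc$mean, y_sd = y_sc$sd)
  gamma <- cfg$svr_gamma %||% (1 / ncol(Fs))
  handle$svr_fits <- lapply(seq_len(ncol(ys)), function(j) {
    e1071::svm(x = Fs, y = ys[, j], type = "eps-regression",
               kernel = "radial", cost = cfg$svr_cost,
               epsilon = cfg$svr_epsilon, gamma = gamma, scale = FALSE)
  })
  handle$trained <- TRUE
  handle$y_clamp <- clamp_range(train$y)
  handle
}

#' Predict every sample of a dataset
#'
#' Dispatches on the model kind: neural models consume the tensor and
#' static views, the SVR baseline the flat features -- so any trained
#' `semg_model` can score any `semg_dataset`.
#'
#' @param handle a trained `semg_model`.
#' @param ds a `semg_dataset`.
#' @return matrix \[n_samples, n_outputs\].
#' @export
predict_dataset <- function(handle, ds) {
  if (handle$kind == "svr") {
    predict(handle, features = ds$F)
  } else {
    predict(handle, X = ds$X, S = ds$S)
  }
}
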