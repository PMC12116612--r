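#' Model configuration
#'
#' Hyperparameters of the four regression models. The defaults mirror the
#' tuned search space: dilation rates (2, 4, 8, 16, 32) with kernel size 3 in
#' the TCN module, dropout 0.1--0.5, LSTM widths in \{128, 256, 512\}, fully
#' connected head of 128/64/32 nodes, Adam with batch size 16.
#'
#' @param kind one of `"tcn_lstm"`, `"tcn"`, `"lstm"`, `"svr"`.
#' @param dilations strictly increasing integer dilation rates; one causal
#'   conv block per rate.
#' @param kernel_size convolution kernel length.
#' @param n_filters filters per conv layer.
#' @param conv_dropout,lstm_dropout dropout rates in \[0, 1).
#' @param lstm_units hidden units per LSTM layer.
#' @param n_lstm_layers LSTM depth.
#' @param fc_nodes widths of the fused head's hidden layers.
#' @param static_fc widths of the static-feature branch.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param n_outputs regression outputs.
#' @param lstm_pool temporal average-pooling factor between the TCN stack and
#'   the LSTM module of the hybrid (caps the recurrence length).
#' @param max_lstm_len for the LSTM-only model, the input is strided down to
#'   at most this many steps.
#' @param residual add skip connections around each conv block (the plain
#'   text description has none; canonical residual blocks are optional).
#' @param grad_clip global gradient-norm clip (0 disables).
#' @param svr_cost,svr_epsilon,svr_gamma RBF support-vector-regression
#'   hyperparameters (`svr_gamma = NULL` uses 1/n_features).
#' @return list of class `model_config`.
#' @export
model_config <- function(kind = c("tcn_lstm", "tcn", "lstm", "svr"),
                         dilations = c(2L, 4L, 8L, 16L, 32L),
                         kernel_size = 3L, n_filters = 32L,
                         conv_dropout = 0.2, lstm_units = 128L,
                         n_lstm_layers = 2L, lstm_dropout = 0.2,
                         fc_nodes = c(128L, 64L, 32L),
                         static_fc = c(32L, 16L),
                         learning_rate = 0.001, batch_size = 16L,
                         n_outputs = 1L, lstm_pool = 16L,
                         max_lstm_len = 500L, residual = FALSE,
                         grad_clip = 5,
                         svr_cost = 10, svr_epsilon = 0.1, svr_gamma = NULL) {
  kind <- match.arg(kind)
  stopifnot(kernel_size >= 1, n_filters >= 1, lstm_units >= 1,
            n_lstm_layers >= 1, batch_size >= 1, n_outputs >= 1,
            learning_rate > 0, lstm_pool >= 1, max_lstm_len >= 1)
  if (any(diff(dilations) <= 0)) {
    abort_semg("`dilations` must be strictly increasing", "semgcobb_bad_config")
  }
  for (d in c(conv_dropout, lstm_dropout)) {
    if (d < 0 || d >= 1) {
      abort_semg("dropout rates must lie in [0, 1)", "semgcobb_bad_config")
    }
  }
  structure(as.list(environment()), class = "model_config")
}

receptive_field <- function(config) {
  1L + (config$kernel_size - 1L) * sum(config$dilations)
}

new_handle <- function(kind, config, input_shape, static_dim, params, bn,
                       feature_dim = NULL) {
  structure(list(kind = kind, config = config, input_shape = input_shape,
                 static_dim = static_dim, feature_dim = feature_dim,
                 params = params, bn = bn, trained = FALSE, scalers = NULL,
                 svr_fits = NULL, history = NULL),
            class = "semg_model")
}

#' @export
print.semg_model <- function(x, ...) {
  cat(sprintf("<semg_model:%s> %s, %s parameters\n", x$kind,
              if (x$trained) "trained" else "untrained",
              format(parameter_count(x), big.mark = ",")))
  invisible(x)
}

check_kind <- function(config, want) {
  if (!identical(config$kind, want)) {
    abort_semg(sprintf("config$kind is '%s' but the %s builder was called",
                       config$kind, want), "semgcobb_kind_mismatch")
  }
}

conv_stack_params <- function(config, cin, zero) {
  lapply(seq_along(config$dilations), function(l) {
    init_conv_block(if (l == 1L) cin else config$n_filters,
                    config$n_filters, config$kernel_size, zero = zero,
                    residual = config$residual)
  })
}

bn_init <- function(config) {
  lapply(seq_along(config$dilations), function(l) {
    list(mean = numeric(config$n_filters), var = rep(1, config$n_filters))
  })
}

lstm_stack_params <- function(config, cin, zero) {
  lapply(seq_len(config$n_lstm_layers), function(l) {
    init_lstm_layer(if (l == 1L) cin else config$lstm_units,
                    config$lstm_units, zero = zero)
  })
}

check_receptive_field <- function(config, input_shape) {
  rf <- receptive_field(config)
  if (rf > input_shape[2]) {
    abort_semg(sprintf(
      "receptive field %d exceeds input length %d: shrink the dilations",
      rf, input_shape[2]), "semgcobb_receptive_field")
  }
}

#' Build the TCN-LSTM hybrid model
#'
#' Four modules in sequence: (1) a TCN of one dilated causal conv block per
#' dilation rate (conv + ReLU, then batch normalization, then dropout); (2)
#' an LSTM stack over the (temporally pooled) TCN features, of which the
#' final hidden state is retained; (3) a fully connected branch embedding the
#' static patient features; (4) an output head that concatenates (2) and (3)
#' and applies the fully connected layers to produce the regression outputs.
#'
#' @param config a [model_config()] with matching `kind`.
#' @param input_shape integer c(channels, time steps) of the input tensor.
#' @param static_dim length of the static feature vector.
#' @param seed RNG seed for weight initialisation.
#' @param init `"default"` (fan-in-scaled random) or `"zero"`.
#' @return an object of class `semg_model`.
#' @export
build_tcn_lstm <- function(config, input_shape, static_dim, seed = 1L,
                           init = c("default", "zero")) {
  check_kind(config, "tcn_lstm")
  init <- match.arg(init)
  check_receptive_field(config, input_shape)
  zero <- init == "zero"
  with_seed(seed, {
    params <- list(
      conv = conv_stack_params(config, input_shape[1], zero),
      lstm = lstm_stack_params(config, config$n_filters, zero),
      static_fc = init_dense(c(static_dim, config$static_fc), zero),
      head = init_dense(c(config$lstm_units + tail(config$static_fc, 1L),
                          config$fc_nodes, config$n_outputs), zero))
    new_handle("tcn_lstm", config, input_shape, static_dim, params,
               bn_init(config))
  })
}

#' Build the TCN-only model
#'
#' As [build_tcn_lstm()] but the LSTM module is replaced by global average
#' pooling of the TCN features over time.
#'
#' @inheritParams build_tcn_lstm
#' @return a `semg_model`.
#' @export
build_tcn <- function(config, input_shape, static_dim, seed = 1L,
                      init = c("default", "zero")) {
  check_kind(config, "tcn")
  init <- match.arg(init)
  check_receptive_field(config, input_shape)
  zero <- init == "zero"
  with_seed(seed, {
    params <- list(
      conv = conv_stack_params(config, input_shape[1], zero),
      static_fc = init_dense(c(static_dim, config$static_fc), zero),
      head = init_dense(c(config$n_filters + tail(config$static_fc, 1L),
                          config$fc_nodes, config$n_outputs), zero))
    new_handle("tcn", config, input_shape, static_dim, params,
               bn_init(config))
  })
}

#' Build the LSTM-only model
#'
#' The time series (strided down to at most `max_lstm_len` steps) feeds the
#' LSTM stack directly; static branch and output head as in the hybrid.
#'
#' @inheritParams build_tcn_lstm
#' @return a `semg_model`.
#' @export
build_lstm <- function(config, input_shape, static_dim, seed = 1L,
                       init = c("default", "zero")) {
  check_kind(config, "lstm")
  init <- match.arg(init)
  zero <- init == "zero"
  with_seed(seed, {
    params <- list(
      lstm = lstm_stack_params(config, input_shape[1], zero),
      static_fc = init_dense(c(static_dim, config$static_fc), zero),
      head = init_dense(c(config$lstm_units + tail(config$static_fc, 1L),
                          config$fc_nodes, config$n_outputs), zero))
    new_handle("lstm", config, input_shape, static_dim, params, NULL)
  })
}

#' Build the SVR baseline
#'
#' An RBF-kernel support vector regressor (one per output) over the flat
#' feature vector of per-channel RMS, PMSI values and static features -- the
#' strongest fair shallow baseline; it never sees the raw time series.
#'
#' @param config a [model_config()] with `kind = "svr"`.
#' @param static_dim,feature_dim lengths of the static and flat feature
#'   vectors.
#' @return a `semg_model`.
#' @export
build_svr <- function(config, static_dim, feature_dim) {
  check_kind(config, "svr")
  new_handle("svr", config, NULL, static_dim, list(), NULL,
             feature_dim = feature_dim)
}

#' Build a model of any kind
#'
#' Dispatcher over the four builders so the harness can treat model kinds
#' uniformly.
#'
#' @inheritParams build_tcn_lstm
#' @param feature_dim flat feature dimension (used by the SVR baseline).
#' @return a `semg_model`.
#' @export
build_model <- function(config, input_shape, static_dim, feature_dim = NULL,
                        seed = 1L, init = "default") {
  switch(config$kind,
         tcn_lstm = build_tcn_lstm(config, input_shape, static_dim, seed, init),
         tcn = build_tcn(config, input_shape, static_dim, seed, init),
         lstm = build_lstm(config, input_shape, static_dim, seed, init),
         svr = build_svr(config, static_dim, feature_dim))
}

#' Number of trainable parameters
#'
#' @param handle a `semg_model`.
#' @return integer count (for the SVR baseline: number of fitted support
#'   vector coefficients, `NA` before fitting).
#' @export
parameter_count <- function(handle) {
  if (handle$kind == "svr") {
    if (is.null(handle$svr_fits)) return(NA_integer_)
    return(sum(vapply(handle$svr_fits, function(f) length(f$coefs),
                      numeric(1))))
  }
  param_count(handle$params)
}

# ---- forward / backward dispatch ----

lstm_stride <- function(T, max_len) max(1L, ceiling(T / max_len))

# Xm is the [T*N x C] batch layout produced by array_to_mat(); T and N must
# be passed alongside (they cannot be recovered from the matrix alone).
nn_forward <- function(h, Xm, T, N, S, train = FALSE) {
  cfg <- h$config
  cache <- list(N = N, T = T)
  bn <- h$bn

  if (h$kind %in% c("tcn_lstm", "tcn")) {
    conv_caches <- vector("list", length(cfg$dilations))
    for (l in seq_along(cfg$dilations)) {
      fb <- conv_block_forward(Xm, T, N, h$params$conv[[l]],
                               cfg$dilations[l], bn[[l]], train,
                               cfg$conv_dropout, cfg$residual)
      Xm <- fb$out
      bn[[l]] <- fb$bn_run
      conv_caches[[l]] <- fb$cache
    }
    cache$conv <- conv_caches
    if (h$kind == "tcn_lstm") {
      pl <- avg_pool_forward(Xm, T, N, cfg$lstm_pool)
      cache$pool <- pl
      seq_in <- pl$out
      T2 <- ceiling(T / cfg$lstm_pool)
    } else {
      gp <- global_pool_forward(Xm, T, N)
      cache$gap <- gp
      ts_feat <- gp$out
    }
  }
  if (h$kind == "lstm") {
    s <- lstm_stride(T, cfg$max_lstm_len)
    keep <- seq(1L, T, by = s)
    T2 <- length(keep)
    rows <- rep((seq_len(N) - 1L) * T, each = T2) + keep
    seq_in <- Xm[rows, , drop = FALSE]
    cache$stride_keep <- keep
  }
  if (h$kind %in% c("tcn_lstm", "lstm")) {
    lcaches <- vector("list", cfg$n_lstm_layers)
    lmasks <- vector("list", cfg$n_lstm_layers)
    for (l in seq_len(cfg$n_lstm_layers)) {
      lf <- lstm_layer_forward(seq_in, T2, N, h$params$lstm[[l]])
      lcaches[[l]] <- lf$cache
      out_seq <- lf$seq
      if (train && cfg$lstm_dropout > 0 && l < cfg$n_lstm_layers) {
        lmasks[[l]] <- dropout_mask(nrow(out_seq), ncol(out_seq),
                                    cfg$lstm_dropout)
        out_seq <- out_seq * lmasks[[l]]
      }
      seq_in <- out_seq
      ts_feat <- lf$h_last
    }
    cache$lstm <- lcaches
    cache$lstm_masks <- lmasks
    cache$T2 <- T2
  }

  sf <- dense_forward(S, h$params$static_fc, final_linear = FALSE)
  cache$static <- sf$caches
  Z <- cbind(ts_feat, sf$out)
  cache$ts_dim <- ncol(ts_feat)
  hd <- dense_forward(Z, h$params$head, final_linear = TRUE)
  cache$head <- hd$caches
  list(yhat = hd$out, cache = cache, bn = bn)
}

nn_backward <- function(h, cache, dY) {
  cfg <- h$config
  N <- cache$N; T <- cache$T
  grads <- list()

  hb <- dense_backward(dY, h$params$head, cache$head)
  grads$head <- hb$grads
  dZ <- hb$dX
  d_ts <- dZ[, seq_len(cache$ts_dim), drop = FALSE]
  d_st <- dZ[, -seq_len(cache$ts_dim), drop = FALSE]
  sb <- dense_backward(d_st, h$params$static_fc, cache$static)
  grads$static_fc <- sb$grads

  if (h$kind %in% c("tcn_lstm", "lstm")) {
    T2 <- cache$T2
    dHlast <- d_ts
    dSeq <- NULL
    lgrads <- vector("list", cfg$n_lstm_layers)
    for (l in rev(seq_len(cfg$n_lstm_layers))) {
      lb <- lstm_layer_backward(cache$lstm[[l]], h$params$lstm[[l]],
                                dSeq, dHlast)
      lgrads[[l]] <- lb$grads
      dSeq <- lb$dIn
      if (l > 1L && !is.null(cache$lstm_masks[[l - 1L]])) {
        dSeq <- dSeq * cache$lstm_masks[[l - 1L]]
      }
      dHlast <- matrix(0, N, cfg$lstm_units)
    }
    grads$lstm <- lgrads
    d_seq_in <- dSeq
  }

  if (h$kind %in% c("tcn_lstm", "tcn")) {
    dXm <- if (h$kind == "tcn_lstm") {
      avg_pool_backward(d_seq_in, cache$pool)
    } else {
      global_pool_backward(d_ts, cache$gap)
    }
    cgrads <- vector("list", length(cfg$dilations))
    for (l in rev(seq_along(cfg$dilations))) {
      cb <- conv_block_backward(dXm, h$params$conv[[l]], cache$conv[[l]])
      cgrads[[l]] <- cb$grads
      dXm <- cb$dX
    }
    grads$conv <- cgrads
  }
  grads[names(h$params)]
}

nn_loss_grad <- function(h, Xm, T, N, S, y, train = TRUE) {
  fw <- nn_forward(h, Xm, T, N, S, train = train)
  resid <- fw$yhat - y
  loss <- mean(resid^2)
  dY <- 2 * resid / length(resid)
  grads <- nn_backward(h, fw$cache, dY)
  list(loss = loss, grads = grads, bn = fw$bn)
}

# Conv-stack features in eval mode (used by the receptive-field probe).
nn_conv_stack_eval <- function(h, X) {
  cfg <- h$config
  N <- dim(X)[1]; T <- dim(X)[3]
  Xm <- array_to_mat(X)
  for (l in seq_along(cfg$dilations)) {
    Xm <- conv_block_forward(Xm, T, N, h$params$conv[[l]], cfg$dilations[l],
                             h$bn[[l]], FALSE, 0, cfg$residual)$out
  }
  Xm
}

scale_cols <- function(M, mean, sd) sweep(sweep(M, 2L, mean, "-"), 2L, sd, "/")

#' Predict from a fitted (or raw) model
#'
#' @param object a `semg_model`.
#' @param X array \[N, channels, time\] of input tensors (neural kinds).
#' @param S matrix \[N, static_dim\] of static features (neural kinds).
#' @param features matrix \[N, feature_dim\] of flat features (SVR kind).
#' @param chunk batch size used internally.
#' @param ... unused.
#' @return matrix \[N, n_outputs\].
#' @export
predict.semg_model <- function(object, X = NULL, S = NULL, features = NULL,
                               chunk = 64L, ...) {
  h <- object
  if (h$kind == "svr") {
    if (is.null(h$svr_fits)) {
      abort_semg("SVR model must be trained before prediction",
                 "semgcobb_untrained")
    }
    if (ncol(features) != h$feature_dim) {
      abort_semg(sprintf("feature_dim mismatch: got %d, expected %d",
                         ncol(features), h$feature_dim),
                 "semgcobb_feature_dim")
    }
    Fs <- scale_cols(features, h$scalers$f_mean, h$scalers$f_sd)
    out <- vapply(h$svr_fits, function(fit) as.numeric(predict(fit, Fs)),
                  numeric(nrow(Fs)))
    out <- matrix(out, nrow = nrow(Fs))
    out <- out * h$scalers$y_sd[col(out)] + h$scalers$y_mean[col(out)]
    return(apply_clamp(out, h$y_clamp))
  }
  stopifnot(length(dim(X)) == 3L, nrow(S) == dim(X)[1])
  if (!is.null(h$scalers)) S <- scale_cols(S, h$scalers$s_mean, h$scalers$s_sd)
  N <- dim(X)[1]
  T <- dim(X)[3]
  out <- matrix(0, N, h$config$n_outputs)
  for (start in seq(1L, N, by = chunk)) {
    ii <- start:min(start + chunk - 1L, N)
    Xm <- array_to_mat(X[ii, , , drop = FALSE])
    out[ii, ] <- nn_forward(h, Xm, T, length(ii),
                            S[ii, , drop = FALSE], train = FALSE)$yhat
  }
  if (!is.null(h$scalers)) {
    out <- out * h$scalers$y_sd[col(out)] + h$scalers$y_mean[col(out)]
  }
  apply_clamp(out, h$y_clamp)
}

apply_clamp <- function(out, clamp) {
  if (is.null(clamp)) return(out)
  pmin(pmax(out, clamp[1L]), clamp[2L])
}
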