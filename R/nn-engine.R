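# Minimal reverse-mode engine for the TCN / LSTM / fusion architectures.
#
# Batch layout: a batch of N recordings with C channels and T steps is held
# as a matrix [T*N x C] with row index r = t + (n-1)*T (time fastest). A
# dilated causal convolution with kernel K is then K time-shifted matrix
# products, which keeps everything inside BLAS. All backward passes are
# hand-derived and checked against central finite differences in the tests.

sigmoid <- function(x) 1 / (1 + exp(-x))

BN_EPS <- 1e-5

tn_key <- function(T, N, tag, extra = "") sprintf("%s_%d_%d_%s", tag, T, N, extra)

shift_index <- function(T, N, L) {
  key <- tn_key(T, N, "shift", L)
  if (is.null(.semg_cache[[key]])) {
    tp <- rep(seq_len(T), N)
    idx <- which(tp > L)
    .semg_cache[[key]] <- list(dst = idx, src = idx - L)
  }
  .semg_cache[[key]]
}

shift_full_index <- function(T, N, L) {
  # maps each destination row to its source row L steps earlier within the
  # same sample; rows with no source are listed in `bad`
  key <- tn_key(T, N, "shiftf", L)
  if (is.null(.semg_cache[[key]])) {
    tp <- rep(seq_len(T), N)
    bad <- which(tp - L < 1L | tp - L > T)
    idx <- seq_len(T * N) - L
    idx[bad] <- 1L
    .semg_cache[[key]] <- list(idx = idx, bad = bad)
  }
  .semg_cache[[key]]
}

shift_rows <- function(X, T, N, L) {
  if (L == 0L) return(X)
  ix <- shift_full_index(T, N, L)
  Y <- X[ix$idx, , drop = FALSE]
  Y[ix$bad, ] <- 0
  Y
}

shift_rows_back <- function(dY, T, N, L) {
  if (L == 0L) return(dY)
  ix <- shift_full_index(T, N, -L)   # scatter = gather in the other direction
  dX <- dY[ix$idx, , drop = FALSE]
  dX[ix$bad, ] <- 0
  dX
}

# Column-wise affine ops without sweep() (sweep aperm-copies large matrices).
col_scale <- function(X, v) {
  for (j in seq_along(v)) X[, j] <- X[, j] * v[j]
  X
}

col_scale_shift <- function(X, sc, sh) {
  for (j in seq_along(sc)) X[, j] <- X[, j] * sc[j] + sh[j]
  X
}

col_shift <- function(X, v) {
  for (j in seq_along(v)) X[, j] <- X[, j] + v[j]
  X
}

pool_group <- function(T, N, p) {
  key <- tn_key(T, N, "pool", p)
  if (is.null(.semg_cache[[key]])) {
    T2 <- as.integer(ceiling(T / p))   # trailing group may be partial
    tp <- rep(ceiling(seq_len(T) / p), N)
    nn <- rep(seq_len(N) - 1L, each = T)
    .semg_cache[[key]] <- tp + nn * T2
  }
  .semg_cache[[key]]
}

dropout_mask <- function(nr, nc, rate) {
  matrix((runif(nr * nc) >= rate) / (1 - rate), nr, nc)
}

# ---- dilated causal conv block: conv -> ReLU -> batch norm -> dropout ----

conv_block_forward <- function(X, T, N, prm, dilation, bn_run, train, drop_rate,
                               residual = FALSE) {
  K <- length(prm$W)
  Xsh <- vector("list", K)
  Xsh[[1L]] <- X
  pre <- X %*% prm$W[[1L]]
  for (j in seq_len(K)[-1L]) {
    Xsh[[j]] <- shift_rows(X, T, N, (j - 1L) * dilation)
    pre <- pre + Xsh[[j]] %*% prm$W[[j]]
  }
  pre <- col_shift(pre, prm$b)
  act <- pre * (pre > 0)
  if (train) {
    mu <- colMeans(act)
    vr <- colMeans(act^2) - mu^2
    bn_run$mean <- 0.9 * bn_run$mean + 0.1 * mu
    bn_run$var <- 0.9 * bn_run$var + 0.1 * vr
  } else {
    mu <- bn_run$mean
    vr <- bn_run$var
  }
  istd <- 1 / sqrt(vr + BN_EPS)
  xhat <- col_scale_shift(act, istd, -mu * istd)
  out <- col_scale_shift(xhat, prm$gamma, prm$beta)
  mask <- NULL
  if (train && drop_rate > 0) {
    mask <- dropout_mask(nrow(out), ncol(out), drop_rate)
    out <- out * mask
  }
  skip <- NULL
  if (residual) {
    skip <- if (is.null(prm$Ws)) X else X %*% prm$Ws
    out <- out + skip
  }
  list(out = out, bn_run = bn_run,
       cache = list(X = X, Xsh = Xsh, pre = pre, xhat = xhat, istd = istd,
                    mask = mask, T = T, N = N, dilation = dilation,
                    residual = residual))
}

conv_block_backward <- function(dOut, prm, cache) {
  dX_skip <- NULL
  dWs <- NULL
  if (cache$residual) {
    dX_skip <- if (is.null(prm$Ws)) dOut else dOut %*% t(prm$Ws)
    if (!is.null(prm$Ws)) dWs <- crossprod(cache$X, dOut)
  }
  if (!is.null(cache$mask)) dOut <- dOut * cache$mask
  n <- nrow(dOut)
  dgamma <- colSums(dOut * cache$xhat)
  dbeta <- colSums(dOut)
  dxhat <- col_scale(dOut, prm$gamma)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dact <- col_shift(dxhat, -s1 / n) -
    col_scale(cache$xhat, s2 / n)
  dact <- col_scale(dact, cache$istd)
  dpre <- dact * (cache$pre > 0)
  K <- length(prm$W)
  dW <- vector("list", K)
  dX <- matrix(0, nrow(cache$X), ncol(cache$X))
  for (j in seq_len(K)) {
    dW[[j]] <- crossprod(cache$Xsh[[j]], dpre)
    dX <- dX + shift_rows_back(dpre %*% t(prm$W[[j]]), cache$T, cache$N,
                               (j - 1L) * cache$dilation)
  }
  db <- colSums(dpre)
  grads <- list(W = dW, b = db, gamma = dgamma, beta = dbeta)
  if (cache$residual) {
    dX <- dX + dX_skip
    if (!is.null(dWs)) grads$Ws <- dWs
  }
  list(dX = dX, grads = grads)
}

# ---- pooling ----

avg_pool_forward <- function(X, T, N, p) {
  g <- pool_group(T, N, p)
  list(out = rowsum(X, g) / p, g = g, p = p)
}

avg_pool_backward <- function(dY, cache) {
  dY[cache$g, , drop = FALSE] / cache$p
}

global_pool_forward <- function(X, T, N) {
  g <- rep(seq_len(N), each = T)
  list(out = rowsum(X, g) / T, g = g, T = T)
}

global_pool_backward <- function(dY, cache) {
  dY[cache$g, , drop = FALSE] / cache$T
}

# ---- LSTM layer (batch BPTT) ----

lstm_layer_forward <- function(In, T, N, prm) {
  H <- nrow(prm$Wh)
  h <- matrix(0, N, H)
  cc <- matrix(0, N, H)
  seq_out <- matrix(0, T * N, H)
  steps <- vector("list", T)
  bmat <- matrix(rep(prm$b, each = N), N, 4L * H)
  for (t in seq_len(T)) {
    ridx <- t + (seq_len(N) - 1L) * T
    Xt <- In[ridx, , drop = FALSE]
    G <- Xt %*% prm$Wx + h %*% prm$Wh + bmat
    i <- sigmoid(G[, 1:H, drop = FALSE])
    f <- sigmoid(G[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(G[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigmoid(G[, (3 * H + 1):(4 * H), drop = FALSE])
    cprev <- cc
    cc <- f * cprev + i * g
    tc <- tanh(cc)
    hprev <- h
    h <- o * tc
    seq_out[ridx, ] <- h
    steps[[t]] <- list(ridx = ridx, i = i, f = f, g = g, o = o,
                       cprev = cprev, tc = tc, hprev = hprev)
  }
  list(seq = seq_out, h_last = h,
       cache = list(steps = steps, In = In, T = T, N = N, H = H))
}

lstm_layer_backward <- function(cache, prm, dSeq, dHlast) {
  T <- cache$T; N <- cache$N; H <- cache$H
  dWx <- matrix(0, nrow(prm$Wx), ncol(prm$Wx))
  dWh <- matrix(0, H, 4L * H)
  db <- numeric(4L * H)
  dIn <- matrix(0, nrow(cache$In), ncol(cache$In))
  carry_h <- dHlast
  carry_c <- matrix(0, N, H)
  for (t in rev(seq_len(T))) {
    st <- cache$steps[[t]]
    dh <- carry_h
    if (!is.null(dSeq)) dh <- dh + dSeq[st$ridx, , drop = FALSE]
    do_ <- dh * st$tc
    dc <- carry_c + dh * st$o * (1 - st$tc^2)
    di <- dc * st$g
    df <- dc * st$cprev
    dg <- dc * st$i
    carry_c <- dc * st$f
    G <- cbind(di * st$i * (1 - st$i), df * st$f * (1 - st$f),
               dg * (1 - st$g^2), do_ * st$o * (1 - st$o))
    Xt <- cache$In[st$ridx, , drop = FALSE]
    dWx <- dWx + crossprod(Xt, G)
    dWh <- dWh + crossprod(st$hprev, G)
    db <- db + colSums(G)
    dIn[st$ridx, ] <- G %*% t(prm$Wx)
    carry_h <- G %*% t(prm$Wh)
  }
  list(dIn = dIn, grads = list(Wx = dWx, Wh = dWh, b = db))
}

# ---- dense stack ----

dense_forward <- function(X, layers, final_linear = TRUE, train = FALSE,
                          drop_rate = 0) {
  caches <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    pre <- sweep(X %*% layers[[l]]$W, 2L, layers[[l]]$b, "+")
    last <- l == length(layers)
    act <- if (last && final_linear) pre else pre * (pre > 0)
    mask <- NULL
    if (train && drop_rate > 0 && !(last && final_linear)) {
      mask <- dropout_mask(nrow(act), ncol(act), drop_rate)
      act <- act * mask
    }
    caches[[l]] <- list(X = X, pre = pre, mask = mask,
                        linear = last && final_linear)
    X <- act
  }
  list(out = X, caches = caches)
}

dense_backward <- function(dOut, layers, caches) {
  grads <- vector("list", length(layers))
  for (l in rev(seq_along(layers))) {
    cc <- caches[[l]]
    if (!is.null(cc$mask)) dOut <- dOut * cc$mask
    dpre <- if (cc$linear) dOut else dOut * (cc$pre > 0)
    grads[[l]] <- list(W = crossprod(cc$X, dpre), b = colSums(dpre))
    dOut <- dpre %*% t(layers[[l]]$W)
  }
  list(dX = dOut, grads = grads)
}

# ---- parameter utilities ----

he_matrix <- function(nin, nout) {
  matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
}

init_conv_block <- function(cin, cout, K, zero = FALSE, residual = FALSE) {
  W <- lapply(seq_len(K), function(j) {
    if (zero) matrix(0, cin, cout)
    else matrix(rnorm(cin * cout, 0, sqrt(2 / (cin * K))), cin, cout)
  })
  prm <- list(W = W, b = numeric(cout), gamma = rep(1, cout),
              beta = numeric(cout))
  if (residual && cin != cout) {
    prm$Ws <- if (zero) matrix(0, cin, cout) else he_matrix(cin, cout)
  }
  prm
}

init_lstm_layer <- function(cin, H, zero = FALSE) {
  s <- 1 / sqrt(H)
  mk <- function(nr, nc) {
    if (zero) matrix(0, nr, nc) else matrix(runif(nr * nc, -s, s), nr, nc)
  }
  b <- numeric(4L * H)
  if (!zero) b[(H + 1):(2 * H)] <- 1  # forget-gate bias
  list(Wx = mk(cin, 4L * H), Wh = mk(H, 4L * H), b = b)
}

init_dense <- function(dims, zero = FALSE) {
  lapply(seq_len(length(dims) - 1L), function(l) {
    list(W = if (zero) matrix(0, dims[l], dims[l + 1L])
             else he_matrix(dims[l], dims[l + 1L]),
         b = numeric(dims[l + 1L]))
  })
}

param_map <- function(x, f) {
  if (is.list(x)) lapply(x, param_map, f = f) else f(x)
}

param_map2 <- function(x, y, f) {
  if (is.list(x)) {
    out <- vector("list", length(x))
    names(out) <- names(x)
    for (i in seq_along(x)) out[[i]] <- param_map2(x[[i]], y[[i]], f)
    out
  } else f(x, y)
}

param_unlist <- function(x) {
  if (is.list(x)) unlist(lapply(x, param_unlist), use.names = FALSE)
  else as.numeric(x)
}

param_count <- function(x) length(param_unlist(x))

# Global-norm gradient clipping: rescales the whole gradient pytree.
clip_grads <- function(grads, max_norm) {
  if (is.null(max_norm) || max_norm <= 0) return(grads)
  nrm <- sqrt(sum(param_unlist(grads)^2))
  if (!is.finite(nrm) || nrm <= max_norm) return(grads)
  param_map(grads, function(g) g * (max_norm / nrm))
}

adam_init <- function(params) {
  list(m = param_map(params, function(p) p * 0),
       v = param_map(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- param_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- param_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  mhat_scale <- 1 / (1 - beta1^state$t)
  vhat_scale <- 1 / (1 - beta2^state$t)
  upd <- param_map2(state$m, state$v, function(m, v) {
    (m * mhat_scale) / (sqrt(v * vhat_scale) + eps)
  })
  params <- param_map2(params, upd, function(p, u) p - lr * u)
  list(params = params, state = state)
}

# ---- batch assembly ----

# [N, C, T] array -> [T*N x C] matrix with time fastest within sample.
array_to_mat <- function(X) {
  N <- dim(X)[1]; C <- dim(X)[2]; T <- dim(X)[3]
  A <- aperm(X, c(3L, 1L, 2L))
  dim(A) <- c(T * N, C)
  A
}
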