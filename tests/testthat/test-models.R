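test_that("config invariants are enforced", {
  expect_error(model_config("tcn", dilations = c(4L, 2L)), "increasing")
  expect_error(model_config("tcn", conv_dropout = 1), "dropout")
  expect_error(build_tcn(model_config("lstm"), c(8L, 100L), 4L),
               "builder")
  # infeasible receptive field: 1 + 2*(2+4+8+16+32) = 125 > 100
  expect_error(build_tcn_lstm(model_config("tcn_lstm"), c(8L, 100L), 4L),
               "receptive field")
})

test_that("analytic and probed receptive fields agree (125 input steps)", {
  cfg <- model_config("tcn", n_filters = 4L, conv_dropout = 0)
  expect_equal(semgcobb:::receptive_field(cfg), 125L)
  h <- build_tcn(cfg, c(8L, 200L), 4L, seed = 5L)
  # positive weights + positive input make every causal path monotone, so
  # the probe cannot be masked by a dead ReLU unit
  h$params$conv <- lapply(h$params$conv, function(bl) {
    bl$W <- lapply(bl$W, abs)
    bl
  })
  set.seed(1)
  X <- abs(array(rnorm(8 * 200), c(1L, 8L, 200L)))
  base <- semgcobb:::nn_conv_stack_eval(h, X)[200L, ]
  probe <- function(t0) {
    Xp <- X
    Xp[1L, , t0] <- Xp[1L, , t0] + 1
    max(abs(semgcobb:::nn_conv_stack_eval(h, Xp)[200L, ] - base))
  }
  expect_gt(probe(200L - 124L), 0)     # farthest reachable input step
  expect_equal(probe(200L - 126L), 0)  # beyond the receptive field
})

test_that("zero initialisation predicts exactly zero for every architecture", {
  set.seed(4)
  X <- array(rnorm(3 * 8 * 64), c(3L, 8L, 64L))
  S <- matrix(rnorm(3 * 5), 3L, 5L)
  for (kind in c("tcn_lstm", "tcn", "lstm")) {
    h <- build_model(tiny_config(kind), c(8L, 64L), 5L, seed = 2L,
                     init = "zero")
    expect_equal(max(abs(predict(h, X = X, S = S))), 0)
  }
})

test_that("parameter count grows with LSTM width; outputs have n_outputs", {
  counts <- vapply(c(128L, 256L, 512L), function(u) {
    parameter_count(build_tcn_lstm(model_config("tcn_lstm", lstm_units = u),
                                   c(8L, 256L), 10L))
  }, numeric(1))
  expect_true(all(diff(counts) > 0))

  h <- build_model(tiny_config("tcn", n_outputs = 3L), c(8L, 64L), 5L)
  set.seed(1)
  out <- predict(h, X = array(rnorm(2 * 8 * 64), c(2L, 8L, 64L)),
                 S = matrix(rnorm(10), 2L, 5L))
  expect_equal(dim(out), c(2L, 3L))
})

test_that("batch prediction equals element-wise prediction", {
  set.seed(8)
  X <- array(rnorm(7 * 8 * 64), c(7L, 8L, 64L))
  S <- matrix(rnorm(7 * 5), 7L, 5L)
  for (kind in c("tcn_lstm", "tcn", "lstm")) {
    h <- build_model(tiny_config(kind), c(8L, 64L), 5L, seed = 3L)
    batch <- predict(h, X = X, S = S)
    single <- t(vapply(1:7, function(i) {
      predict(h, X = X[i, , , drop = FALSE], S = S[i, , drop = FALSE])[1L, ]
    }, numeric(ncol(batch))))
    expect_equal(batch, matrix(single, nrow = 7L), tolerance = 1e-5)
  }
})

test_that("LSTM hidden width matches config and output is order-sensitive", {
  cfg <- tiny_config("lstm")
  h <- build_lstm(cfg, c(8L, 64L), 5L, seed = 6L)
  expect_equal(ncol(h$params$lstm[[1L]]$Wh) / 4L, cfg$lstm_units)
  set.seed(9)
  X <- array(rnorm(8 * 64), c(1L, 8L, 64L))
  S <- matrix(rnorm(5), 1L, 5L)
  Xrev <- X[, , 64:1, drop = FALSE]
  expect_gt(abs(predict(h, X = X, S = S) - predict(h, X = Xrev, S = S)), 0)
})

test_that("analytic gradients match central finite differences", {
  flat_set <- function(tpl, v) {
    i <- 0
    semgcobb:::param_map(tpl, function(p) {
      n <- length(p); out <- p; out[] <- v[i + seq_len(n)]; i <<- i + n; out
    })
  }
  set.seed(12)
  N <- 4L
  X <- array(rnorm(N * 8 * 40), c(N, 8L, 40L))
  Xm <- semgcobb:::array_to_mat(X)
  S <- matrix(rnorm(N * 5), N, 5L)
  y <- matrix(rnorm(N), N, 1L)
  for (kind in c("tcn_lstm", "tcn", "lstm")) {
    cfg <- tiny_config(kind, conv_dropout = 0, lstm_dropout = 0)
    cfg$dilations <- c(1L, 2L, 4L)
    h <- build_model(cfg, c(8L, 40L), 5L, seed = 21L)
    lg <- semgcobb:::nn_loss_grad(h, Xm, 40L, N, S, y, train = TRUE)
    v0 <- semgcobb:::param_unlist(h$params)
    g_an <- semgcobb:::param_unlist(lg$grads)
    set.seed(5)
    pick <- sample(length(v0), 25L)
    eps <- 1e-5
    g_num <- vapply(pick, function(j) {
      lp <- local({
        hp <- h; vp <- v0; vp[j] <- vp[j] + eps
        hp$params <- flat_set(h$params, vp)
        mean((semgcobb:::nn_forward(hp, Xm, 40L, N, S, TRUE)$yhat - y)^2)
      })
      lm <- local({
        hm <- h; vm <- v0; vm[j] <- vm[j] - eps
        hm$params <- flat_set(h$params, vm)
        mean((semgcobb:::nn_forward(hm, Xm, 40L, N, S, TRUE)$yhat - y)^2)
      })
      (lp - lm) / (2 * eps)
    }, numeric(1))
    rel <- abs(g_num - g_an[pick]) /
      pmax(1e-8, abs(g_num) + abs(g_an[pick]))
    expect_lt(max(rel), 1e-3)
  }
})

test_that("SVR interpolates duplicated points and is deterministic", {
  set.seed(30)
  ds <- fake_dataset(6L, per_patient = 2L, T = 8L)
  dup <- semgcobb:::ds_subset(ds, rep(1:3, each = 4L))
  cfg <- model_config("svr", svr_cost = 1000, svr_epsilon = 0.01)
  h <- build_svr(cfg, ncol(ds$S), ncol(ds$F))
  fit <- train_model(h, dup, dup, train_spec())
  pred <- predict(fit, features = dup$F)
  expect_lt(max(abs(pred - dup$y)), 0.05 * diff(range(dup$y)))

  fit2 <- train_model(h, dup, dup, train_spec())
  expect_equal(predict(fit2, features = dup$F), pred)
  expect_error(predict(fit, features = dup$F[, 1:2]), "feature_dim")
  expect_gt(parameter_count(fit), 0L)
})
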