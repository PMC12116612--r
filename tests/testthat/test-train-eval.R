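test_that("dataset assembly yields the study's sample counts", {
  sim <- tiny_sim(1L)
  prep <- semgcobb:::prepare_cohort_inputs(sim$cohort, tiny_tensor_spec())
  bst <- make_supervised_samples(sim$cohort, "bst", prepared = prep)
  cobb <- make_supervised_samples(sim$cohort, "cobb_T", prepared = prep)
  expect_equal(nrow(bst$y), 16L)   # 4 exercises x 4 weeks
  expect_equal(nrow(cobb$y), 8L)   # 4 exercises x 2 Cobb weeks
  expect_setequal(unique(cobb$week), c(0L, 24L))
  expect_error(make_supervised_samples(sim$cohort, "height"), "target")

  # labels match the outcome table entry for the sample's week
  oc <- sim$cohort$outcomes
  for (k in c(1L, 5L)) {
    expect_equal(cobb$y[k, 1L],
                 oc$cobb_T[oc$patient_id == cobb$patient_id[k] &
                             oc$week == cobb$week[k]])
  }

  # PMSI history: week-0 samples have empty later-week slots, week-24 full
  s0 <- cobb$S[cobb$week == 0L, , drop = FALSE]
  s24 <- cobb$S[cobb$week == 24L, , drop = FALSE]
  later <- grep("_w(8|16|24)$", colnames(cobb$S))
  expect_true(all(s0[, later] == 0))
  expect_true(all(s24[, later] != 0))
})

test_that("missing mandatory labels abort assembly", {
  sim <- tiny_sim(1L)
  chrt <- sim$cohort
  chrt$outcomes$bst[1L] <- NA
  prep <- semgcobb:::prepare_cohort_inputs(chrt, tiny_tensor_spec())
  expect_error(make_supervised_samples(chrt, "bst", prepared = prep),
               "missing bst label")
})

test_that("grouped split gives the 7:3 patient partition with no leakage", {
  ds <- fake_dataset(143L)
  spec <- train_spec(seed = 3L)
  parts <- split_dataset(ds, spec)
  tr_p <- unique(parts$train$patient_id)
  va_p <- unique(parts$val$patient_id)
  te_p <- unique(parts$test$patient_id)
  # floor(0.7 * 143) = 100 training patients (incl. validation carve-out)
  expect_equal(length(tr_p) + length(va_p), 100L)
  expect_equal(length(te_p), 43L)
  expect_length(intersect(c(tr_p, va_p), te_p), 0L)
  expect_length(intersect(tr_p, va_p), 0L)

  parts2 <- split_dataset(ds, spec)
  expect_identical(parts$train$patient_id, parts2$train$patient_id)
  expect_error(split_dataset(fake_dataset(2L), spec), "3 patients")
})

test_that("metrics reproduce their closed forms and identities", {
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(r2(c(1, 2, 3), c(1, 2, 3)), 1)
  y <- c(1, 2, 3)
  expect_equal(rmse(y, c(2, 2, 2)), sqrt(2 / 3))
  expect_equal(r2(y, c(2, 2, 2)), 0)           # predicting the mean
  expect_equal(r2(y, rep(mean(y), 3)), 0)
  expect_error(r2(rep(2, 4), 1:4), "constant")
  expect_error(rmse(1:3, 1:4), "equal")
  set.seed(11)
  yy <- rnorm(50)
  pp <- yy + rnorm(50, 0, 0.3)
  expect_equal(r2(yy, pp),
               1 - (rmse(yy, pp)^2 * 50) / sum((yy - mean(yy))^2),
               tolerance = 1e-9)
})

test_that("early stopping halts at patience + 1 on a validation plateau", {
  # frozen degenerate run: a zero-initialised model predicts exactly the
  # (constant, standardised-to-zero) target, so every gradient is zero and
  # the validation loss plateaus from epoch 1
  ds <- fake_dataset(12L, per_patient = 2L, T = 16L, signal = FALSE)
  ds$y[] <- 15
  cfg <- tiny_config("tcn")
  cfg$dilations <- c(1L, 2L)
  h <- build_tcn(cfg, c(8L, 16L), ncol(ds$S), seed = 2L, init = "zero")
  spec <- train_spec(max_epochs = 100L, patience = 10L, seed = 4L)
  parts <- split_dataset(ds, spec)
  fit <- train_model(h, parts$train, parts$val, spec)
  expect_equal(nrow(fit$history), 11L)   # 1 best epoch + 10 stale epochs
  expect_lte(nrow(fit$history), 100L)
  expect_true(all(diff(cummin(fit$history$val_loss)) <= 0))
})

test_that("neural models overfit a tiny sample (gradient flow sanity)", {
  set.seed(40)
  n <- 8L
  X <- array(rnorm(n * 8 * 64), c(n, 8L, 64L))
  S <- cbind(rnorm(n), rnorm(n))
  y <- matrix(5 * S[, 1L] + 20, n, 1L)
  ds <- structure(list(X = X, S = S, F = cbind(S, S), y = y,
                       patient_id = sprintf("P%d", 1:n),
                       week = rep(0L, n),
                       exercise = rep("quadruped", n),
                       target_name = "cobb_T"),
                  class = "semg_dataset")
  for (kind in c("tcn_lstm", "tcn", "lstm")) {
    cfg <- tiny_config(kind, conv_dropout = 0, lstm_dropout = 0,
                       learning_rate = 0.01)
    h <- build_model(cfg, c(8L, 64L), 2L, seed = 31L)
    # 8 samples in one batch: 300 epochs = 300 optimisation steps
    spec <- train_spec(max_epochs = 300L, patience = 300L, seed = 8L)
    fit <- train_model(h, ds, ds, spec)
    pred <- predict_dataset(fit, ds)
    expect_lt(rmse(ds$y[, 1L], pred[, 1L]), 0.5)
  }
})

test_that("cross-validation folds partition patients and samples exactly", {
  ds <- fake_dataset(12L, per_patient = 4L, T = 16L)
  cfg <- model_config("svr")
  spec <- train_spec(seed = 6L)
  rep <- cross_validate(ds, cfg, spec, k = 3L)
  # every sample appears in a test fold exactly once
  test_rows <- rep$scatter
  expect_equal(nrow(test_rows), nrow(ds$y))
  per_fold <- split(test_rows, test_rows$fold)
  expect_length(per_fold, 3L)
  # strata present: week levels and Total, train and test
  expect_setequal(unique(rep$folds$stratum), c("0", "24", "Total"))
  expect_setequal(unique(rep$folds$split), c("train", "test"))
  # summary has fold means and sds
  expect_true(all(c("rmse_mean", "r2_mean", "rmse_sd", "r2_sd") %in%
                    names(rep$summary)))
  expect_error(cross_validate(ds, cfg, spec, k = 1L), "k >= 2")
})

test_that("hyperparameter search returns the planted optimum", {
  space <- search_space(dropout_grid = c(0.1, 0.2, 0.3),
                        lstm_units_grid = c(128L, 256L),
                        lr_grid = c(0.001, 0.002, 0.003))
  # deterministic evaluation with a unique planted minimum
  eval_fn <- function(cfg) {
    abs(cfg$conv_dropout - 0.2) + abs(cfg$lstm_units - 256L) / 1000 +
      abs(cfg$learning_rate - 0.002) * 100
  }
  # exhaustive oracle over the full grid
  grid <- expand.grid(d = space$dropout_grid, u = space$lstm_units_grid,
                      l = space$lr_grid)
  oracle <- grid[which.min(mapply(function(d, u, l) {
    eval_fn(list(conv_dropout = d, lstm_units = u, learning_rate = l))
  }, grid$d, grid$u, grid$l)), ]

  res <- hyperparameter_search(space, ds = NULL, spec = train_spec(seed = 2L),
                               budget = 5L, eval_fn = eval_fn)
  expect_equal(res$best_config$conv_dropout, oracle$d)
  expect_equal(res$best_config$lstm_units, oracle$u)
  expect_equal(res$best_config$learning_rate, oracle$l)
  expect_false(is.unsorted(res$leaderboard$val_loss))

  # singleton space with budget 1 returns the only possible configuration
  s1 <- search_space(dropout_grid = 0.3, lstm_units_grid = 128L,
                     lr_grid = 0.005)
  r1 <- hyperparameter_search(s1, ds = NULL, spec = train_spec(), budget = 1L,
                              eval_fn = function(cfg) 1)
  expect_equal(r1$best_config$conv_dropout, 0.3)
  expect_equal(nrow(r1$leaderboard), 1L)
})
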