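eval_strata_for <- function(target_name) {
  if (target_name %in% COBB_TARGETS) c(0L, 24L) else MEASUREMENT_WEEKS
}

stratum_metrics <- function(ds, pred, split, strata) {
  rows <- lapply(c(as.list(strata), list("Total")), function(s) {
    idx <- if (identical(s, "Total")) seq_along(ds$week)
           else which(ds$week == s)
    if (!length(idx)) return(NULL)
    yy <- ds$y[idx, 1L]
    pp <- pred[idx, 1L]
    data.frame(stratum = as.character(s), split = split,
               rmse = rmse(yy, pp),
               r2 = if (sd(yy) > 0) r2(yy, pp) else NA_real_,
               n = length(idx), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cross-validate one model configuration on one target
#'
#' Patients are partitioned into `k` mutually exclusive subsets; each serves
#' once as the test set while the remaining subsets form the training set
#' (with a validation carve-out for early stopping). Train and test RMSE and
#' R^2 are reported per measurement-week stratum and overall, as mean and sd
#' over folds.
#'
#' @param ds a `semg_dataset`.
#' @param config a [model_config()].
#' @param spec a [train_spec()].
#' @param k number of folds.
#' @return object of class `semg_eval_report` with `folds`, `summary` and
#'   `scatter` data.frames.
#' @export
cross_validate <- function(ds, config, spec = train_spec(), k = 3L) {
  if (k < 2L) abort_semg("cross-validation needs k >= 2", "semgcobb_bad_k")
  patients <- unique(ds$patient_id)
  if (length(patients) < k) {
    abort_semg("fewer patients than folds", "semgcobb_too_few")
  }
  groups <- with_seed(derive_seed(spec$seed, "cv", ds$target_name), {
    split(sample(patients), rep_len(seq_len(k), length(patients)))
  })
  strata <- eval_strata_for(ds$target_name)
  fold_rows <- list()
  scatter <- list()
  t0 <- proc.time()[["elapsed"]]
  for (f in seq_len(k)) {
    test_idx <- which(ds$patient_id %in% groups[[f]])
    rest <- ds_subset(ds, setdiff(seq_along(ds$patient_id), test_idx))
    test <- ds_subset(ds, test_idx)
    # leakage guard: asserted on every run
    stopifnot(length(intersect(unique(rest$patient_id),
                               unique(test$patient_id))) == 0L)
    rest_p <- unique(rest$patient_id)
    n_val <- max(1L, ceiling(spec$val_frac_of_train * length(rest_p)))
    val_p <- with_seed(derive_seed(spec$seed, "cvval", f), {
      sample(rest_p, n_val)
    })
    tr <- ds_subset(rest, which(!rest$patient_id %in% val_p))
    va <- ds_subset(rest, which(rest$patient_id %in% val_p))
    handle <- build_model(config, input_shape = dim(ds$X)[2:3],
                          static_dim = ncol(ds$S), feature_dim = ncol(ds$F),
                          seed = derive_seed(spec$seed, "init", f))
    fold_spec <- spec
    fold_spec$seed <- derive_seed(spec$seed, "fold", f)
    fitted <- train_model(handle, tr, va, fold_spec)
    pred_tr <- predict_dataset(fitted, tr)
    pred_te <- predict_dataset(fitted, test)
    m <- rbind(stratum_metrics(tr, pred_tr, "train", strata),
               stratum_metrics(test, pred_te, "test", strata))
    m$fold <- f
    m$model <- config$kind
    m$target <- ds$target_name
    fold_rows[[f]] <- m
    scatter[[f]] <- data.frame(model = config$kind, target = ds$target_name,
                               fold = f, week = test$week,
                               true = test$y[, 1L], predicted = pred_te[, 1L],
                               stringsAsFactors = FALSE)
  }
  folds <- do.call(rbind, fold_rows)
  agg <- stats::aggregate(cbind(rmse, r2) ~ model + target + stratum + split,
                          data = folds, FUN = mean, na.action = stats::na.omit)
  sds <- stats::aggregate(cbind(rmse, r2) ~ model + target + stratum + split,
                          data = folds, FUN = sd, na.action = stats::na.omit)
  names(agg)[names(agg) %in% c("rmse", "r2")] <- c("rmse_mean", "r2_mean")
  agg$rmse_sd <- sds$rmse
  agg$r2_sd <- sds$r2
  structure(list(folds = folds, summary = agg,
                 scatter = do.call(rbind, scatter),
                 elapsed_s = proc.time()[["elapsed"]] - t0),
            class = "semg_eval_report")
}

#' @export
print.semg_eval_report <- function(x, ...) {
  cat("<semg_eval_report>\n")
  print(format_eval_report(x), row.names = FALSE)
  invisible(x)
}

#' Tabulate an evaluation report in the benchmark-table layout
#'
#' One row per (target, stratum), columns `<model> train R2` / `test R2`
#' (fold means).
#'
#' @param report a `semg_eval_report`.
#' @param metric `"r2"` or `"rmse"`.
#' @return data.frame.
#' @export
format_eval_report <- function(report, metric = c("r2", "rmse")) {
  metric <- match.arg(metric)
  col <- paste0(metric, "_mean")
  s <- report$summary
  s$cell <- round(s[[col]], 3)
  wide <- stats::reshape(
    s[, c("target", "stratum", "split", "model", "cell")],
    idvar = c("target", "stratum", "split"), timevar = "model",
    v.names = "cell", direction = "wide",
    new.row.names = NULL)
  # order strata numerically with Total last
  ord <- order(wide$target,
               match(wide$stratum, c("0", "8", "16", "24", "Total")),
               wide$split)
  wide[ord, ]
}

merge_eval_reports <- function(reports) {
  structure(list(folds = do.call(rbind, lapply(reports, `[[`, "folds")),
                 summary = do.call(rbind, lapply(reports, `[[`, "summary")),
                 scatter = do.call(rbind, lapply(reports, `[[`, "scatter")),
                 elapsed_s = sum(vapply(reports, `[[`, numeric(1),
                                        "elapsed_s"))),
            class = "semg_eval_report")
}

#' Hyperparameter search space
#'
#' The tuned axes and their grids: dropout 0.1--0.5 in steps of 0.1, LSTM
#' width in \{128, 256, 512\}, learning rate 0.0001--0.01 in steps of
#' 0.0005; dilations, kernel size and head widths are fixed.
#'
#' @param dropout_grid,lstm_units_grid,lr_grid searched grids.
#' @param n_random_draws budget of the random phase.
#' @return list of class `search_space`.
#' @export
search_space <- function(dropout_grid = seq(0.1, 0.5, by = 0.1),
                         lstm_units_grid = c(128L, 256L, 512L),
                         lr_grid = seq(1e-4, 1e-2, by = 5e-4),
                         n_random_draws = 20L) {
  stopifnot(length(dropout_grid) > 0, length(lstm_units_grid) > 0,
            length(lr_grid) > 0)
  structure(list(dropout_grid = dropout_grid,
                 lstm_units_grid = as.integer(lstm_units_grid),
                 lr_grid = lr_grid,
                 n_random_draws = as.integer(n_random_draws)),
            class = "search_space")
}

apply_axes <- function(base_config, axes) {
  cfg <- base_config
  cfg$conv_dropout <- axes$dropout
  cfg$lstm_dropout <- axes$dropout
  cfg$lstm_units <- axes$lstm_units
  cfg$learning_rate <- axes$lr
  cfg
}

grid_neighbors <- function(value, grid) {
  i <- which.min(abs(grid - value))
  unique(grid[pmax(1L, pmin(length(grid), i + (-1:1)))])
}

#' Hyperparameter search (random phase + local grid refinement)
#'
#' A coarse random phase draws `budget` configurations from the full space;
#' a fine grid phase then evaluates every combination of the discrete-axis
#' neighbours of the incumbent. Selection is by validation loss under the
#' split defined by `spec`; fully seeded.
#'
#' @param space a [search_space()].
#' @param ds a `semg_dataset`.
#' @param spec a [train_spec()].
#' @param budget random draws before refinement.
#' @param base_config configuration template carrying the model kind and the
#'   non-searched fields.
#' @param eval_fn optional `function(config) -> validation loss` overriding
#'   the default train-and-score evaluation (dependency injection for cheap
#'   or exhaustive evaluation).
#' @return list with `best_config` and `leaderboard` (sorted, best first).
#' @export
hyperparameter_search <- function(space, ds, spec = train_spec(), budget = 20L,
                                  base_config = model_config("tcn_lstm"),
                                  eval_fn = NULL) {
  stopifnot(budget >= 1)
  if (is.null(eval_fn)) {
    parts <- split_dataset(ds, spec)
    eval_fn <- function(cfg) {
      handle <- build_model(cfg, input_shape = dim(ds$X)[2:3],
                            static_dim = ncol(ds$S),
                            feature_dim = ncol(ds$F),
                            seed = derive_seed(spec$seed, "search-init"))
      fitted <- train_model(handle, parts$train, parts$val, spec)
      if (fitted$kind == "svr") {
        pv <- predict_dataset(fitted, parts$val)
        mean((pv - parts$val$y)^2)
      } else {
        min(fitted$history$val_loss)
      }
    }
  }
  seen <- new.env(parent = emptyenv())
  rows <- list()
  try_axes <- function(axes, phase) {
    key <- sprintf("%.6g|%d|%.6g", axes$dropout, axes$lstm_units, axes$lr)
    if (!is.null(seen[[key]])) return(invisible(NULL))
    cfg <- apply_axes(base_config, axes)
    loss <- eval_fn(cfg)
    seen[[key]] <- loss
    rows[[length(rows) + 1L]] <<- data.frame(
      phase = phase, dropout = axes$dropout, lstm_units = axes$lstm_units,
      lr = axes$lr, val_loss = loss, stringsAsFactors = FALSE)
  }
  pick1 <- function(v) v[sample.int(length(v), 1L)]
  with_seed(derive_seed(spec$seed, "hpsearch"), {
    for (b in seq_len(budget)) {
      try_axes(list(dropout = pick1(space$dropout_grid),
                    lstm_units = pick1(space$lstm_units_grid),
                    lr = pick1(space$lr_grid)), "random")
    }
    lb <- do.call(rbind, rows)
    inc <- lb[which.min(lb$val_loss), ]
    for (d in grid_neighbors(inc$dropout, space$dropout_grid)) {
      for (u in grid_neighbors(inc$lstm_units, space$lstm_units_grid)) {
        for (l in grid_neighbors(inc$lr, space$lr_grid)) {
          try_axes(list(dropout = d, lstm_units = u, lr = l), "grid")
        }
      }
    }
  })
  leaderboard <- do.call(rbind, rows)
  leaderboard <- leaderboard[order(leaderboard$val_loss), ]
  best <- leaderboard[1L, ]
  list(best_config = apply_axes(base_config,
                                list(dropout = best$dropout,
                                     lstm_units = best$lstm_units,
                                     lr = best$lr)),
       leaderboard = leaderboard)
}

#' Benchmark model kinds across targets
#'
#' Runs [cross_validate()] for every (model kind, target) combination and
#' merges the results into one report shaped like the study's comparison
#' table (models as column groups, targets x week strata as rows), plus
#' per-sample test-set scatter data (true vs predicted).
#'
#' @param chrt a complete `semg_cohort`.
#' @param configs named list of [model_config()]s (names are the kinds).
#' @param spec a [train_spec()].
#' @param targets outcome names to benchmark.
#' @param tspec,fspec tensor and filter specifications.
#' @param k folds.
#' @return a `semg_eval_report`.
#' @export
benchmark_models <- function(chrt, configs, spec = train_spec(),
                             targets = OUTCOME_VARS,
                             tspec = tensor_spec(), fspec = filter_spec(),
                             k = 3L) {
  prepared <- prepare_cohort_inputs(chrt, tspec, fspec)
  reports <- list()
  for (target in targets) {
    ds <- make_supervised_samples(chrt, target, tspec, fspec,
                                  prepared = prepared)
    for (cfg in configs) {
      reports[[length(reports) + 1L]] <- cross_validate(ds, cfg, spec, k)
    }
  }
  merge_eval_reports(reports)
}
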