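#' Mean absolute error
#'
#' @param x Predictions.
#' @param y Observed values.
#' @return Non-negative scalar: mean of |x - y|.
#' @export
mae <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) == 0L) abort("empty input")
  mean(abs(x - y))
}

#' Pearson correlation coefficient
#'
#' Sample Pearson correlation between predictions and observations; errors
#' (rather than returning NA) when either input has zero variance.
#'
#' @param x Predictions.
#' @param y Observed values.
#' @return Scalar in [-1, 1].
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) < 2L) abort("need at least two observations")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined: zero variance",
          class = "torsionflux_zero_variance")
  }
  cor(x, y)
}

#' Selection / optimisation objective
#'
#' The scalar objective used both as the genetic-algorithm fitness and for
#' window-size selection: `1 - MAE + PCC`. Higher is better; a perfect
#' predictor scores 2.
#'
#' @param mae Mean absolute error (label scale).
#' @param pcc Pearson correlation coefficient.
#' @return Scalar objective value.
#' @export
objfit <- function(mae, pcc) {
  1 - mae + pcc
}

#' Chain-level fold assignment
#'
#' Shuffles the unique chain ids with the given seed and partitions them
#' into `k` groups whose sizes differ by at most one. All residues of a
#' chain inherit its fold, so no chain ever spans train and test.
#'
#' @param chain_ids Character vector (one entry per row, or the unique ids).
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the shuffle.
#' @return Tibble with columns `chain_id` and `fold`.
#' @export
chain_level_folds <- function(chain_ids, k = 10, seed = 1) {
  ids <- unique(chain_ids)
  if (length(ids) < k) {
    abort(sprintf("only %d chains for %d folds", length(ids), k))
  }
  shuffled <- withr::with_seed(seed, sample(ids))
  tibble(chain_id = shuffled, fold = rep_len(seq_len(k), length(ids))) |>
    arrange(.data$chain_id)
}

#' Gradient-boosted regressor configuration
#'
#' Defaults are the tuned optimum of the fluctuation predictor:
#' learning rate 0.014, 2561 boosting rounds, maximum depth 19, 380 leaves,
#' 138 histogram bins and a 0.52 per-tree feature fraction.
#'
#' @param learning_rate Shrinkage per boosting round.
#' @param n_estimators Number of boosting rounds.
#' @param max_depth Maximum tree depth.
#' @param num_leaves Maximum leaves per tree.
#' @param max_bin Histogram bins for continuous features.
#' @param feature_fraction Fraction of columns sampled per tree.
#' @param min_child_weight Minimum sum of instance weights in a leaf.
#' @param subsample Row subsampling rate per round.
#' @param seed Integer seed for the booster's internal randomness.
#' @return Object of class `taf_regressor_config`.
#' @export
regressor_config <- function(learning_rate = 0.014, n_estimators = 2561,
                             max_depth = 19, num_leaves = 380, max_bin = 138,
                             feature_fraction = 0.52, min_child_weight = 1,
                             subsample = 1, seed = 1) {
  stopifnot(learning_rate > 0, n_estimators >= 1, max_depth >= 1,
            num_leaves >= 2, max_bin >= 2,
            feature_fraction > 0, feature_fraction <= 1)
  structure(list(learning_rate = learning_rate, n_estimators = n_estimators,
                 max_depth = max_depth, num_leaves = num_leaves,
                 max_bin = max_bin, feature_fraction = feature_fraction,
                 min_child_weight = min_child_weight, subsample = subsample,
                 seed = seed),
            class = "taf_regressor_config")
}

# single-threaded, seeded histogram GBT fit (xgboost backend)
fit_gbt <- function(X, y, rc) {
  params <- list(objective = "reg:squarederror",
                 eta = rc$learning_rate,
                 max_depth = rc$max_depth,
                 max_leaves = rc$num_leaves,
                 grow_policy = "lossguide",
                 max_bin = rc$max_bin,
                 colsample_bytree = rc$feature_fraction,
                 min_child_weight = rc$min_child_weight,
                 subsample = rc$subsample,
                 tree_method = "hist",
                 nthread = 1,
                 seed = rc$seed)
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  xgboost::xgb.train(params = params, data = dtrain,
                     nrounds = rc$n_estimators, verbose = 0)
}

predict_gbt <- function(booster, X) {
  predict(booster, xgboost::xgb.DMatrix(X, nthread = 1))
}

#' Train a fluctuation regressor on a feature matrix
#'
#' Fits one gradient-boosted tree regressor for a single target angle
#' (dphi or dpsi) on the supplied (typically windowed, possibly
#' mask-selected) features.
#'
#' @param x A `taf_features` tibble or numeric feature matrix.
#' @param y Numeric label vector, row-aligned with `x`.
#' @param rc A [regressor_config()].
#' @param mask Optional logical vector over feature columns (e.g. a GA
#'   result) restricting the model to the selected columns.
#' @return Object of class `taf_model`.
#' @export
train_fluctuation_model <- function(x, y, rc = regressor_config(), mask = NULL) {
  X <- if (is.matrix(x)) x else feature_matrix(x)
  if (nrow(X) != length(y)) abort("`x` and `y` are not row-aligned")
  if (!is.null(mask)) {
    mask <- as.logical(mask)
    if (length(mask) != ncol(X)) abort("`mask` length must equal feature count")
    X <- X[, mask, drop = FALSE]
  }
  structure(list(booster = fit_gbt(X, y, rc),
                 features = colnames(X), config = rc),
            class = "taf_model")
}

#' @export
print.taf_model <- function(x, ...) {
  cat(sprintf("<taf_model> gradient-boosted regressor on %d features (%d rounds)\n",
              length(x$features), x$config$n_estimators))
  invisible(x)
}

#' Predict fluctuations with a trained model
#'
#' @param object A `taf_model`.
#' @param newdata A `taf_features` tibble or matrix containing (at least)
#'   the model's feature columns.
#' @param ... Unused.
#' @return Tibble with `chain_id`/`residue_index` (when available) and
#'   `prediction`.
#' @export
predict.taf_model <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else feature_matrix(newdata)
  miss <- setdiff(object$features, colnames(X))
  if (length(miss) > 0L) {
    abort(sprintf("newdata lacks %d model feature(s), e.g. %s",
                  length(miss), miss[1]))
  }
  pred <- predict_gbt(object$booster, X[, object$features, drop = FALSE])
  meta <- if (!is.matrix(newdata) && all(c("chain_id", "residue_index") %in% names(newdata))) {
    as_tibble(newdata)[, c("chain_id", "residue_index")]
  } else {
    tibble(row = seq_along(pred))
  }
  bind_cols(meta, tibble(prediction = pred))
}

#' Chain-level k-fold cross-validation of the fluctuation regressor
#'
#' For each fold, trains on the remaining chains and predicts the held-out
#' chains; MAE and PCC are computed on the pooled out-of-fold predictions
#' within each fold and then averaged across folds. The objective
#' [objfit()] is reported on the aggregate MAE/PCC.
#'
#' @param x A `taf_features` tibble or feature matrix.
#' @param y Numeric labels (undefined labels must be excluded beforehand).
#' @param chain_ids Chain id per row (taken from `x` when omitted and `x`
#'   carries a `chain_id` column).
#' @param rc A [regressor_config()].
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold shuffle.
#' @param mask Optional logical feature mask, as in
#'   [train_fluctuation_model()].
#' @return Object of class `taf_cv` with per-fold metrics, aggregate
#'   metrics and the pooled out-of-fold predictions.
#' @export
cross_validate <- function(x, y, chain_ids = NULL, rc = regressor_config(),
                           k = 10, seed = 1, mask = NULL) {
  X <- if (is.matrix(x)) x else feature_matrix(x)
  if (is.null(chain_ids) && !is.matrix(x) && "chain_id" %in% names(x)) {
    chain_ids <- x$chain_id
  }
  if (is.null(chain_ids)) abort("`chain_ids` is required")
  if (nrow(X) != length(y) || length(chain_ids) != length(y)) {
    abort("`x`, `y` and `chain_ids` are not row-aligned")
  }
  if (!is.null(mask)) {
    mask <- as.logical(mask)
    if (length(mask) != ncol(X)) abort("`mask` length must equal feature count")
    if (!any(mask)) abort("empty feature mask")
    X <- X[, mask, drop = FALSE]
  }
  folds <- chain_level_folds(chain_ids, k = k, seed = seed)
  fold_of <- folds$fold[match(chain_ids, folds$chain_id)]
  preds <- vector("list", k)
  fold_metrics <- vector("list", k)
  for (f in seq_len(k)) {
    test <- fold_of == f
    train <- !test
    # structural no-leakage guarantee: folds partition chains
    stopifnot(length(intersect(chain_ids[train], chain_ids[test])) == 0L)
    booster <- fit_gbt(X[train, , drop = FALSE], y[train], rc)
    p <- predict_gbt(booster, X[test, , drop = FALSE])
    preds[[f]] <- tibble(chain_id = chain_ids[test], fold = f,
                         observed = y[test], predicted = p)
    fold_metrics[[f]] <- tibble(fold = f, n = sum(test),
                                mae = mae(p, y[test]), pcc = pcc(p, y[test]))
  }
  per_fold <- bind_rows(fold_metrics)
  agg_mae <- mean(per_fold$mae)
  agg_pcc <- mean(per_fold$pcc)
  structure(list(per_fold = per_fold, folds = folds,
                 predictions = bind_rows(preds),
                 mae = agg_mae, pcc = agg_pcc,
                 objfit = objfit(agg_mae, agg_pcc),
                 k = k, seed = seed, config = rc),
            class = "taf_cv")
}

#' @export
print.taf_cv <- function(x, ...) {
  cat(sprintf("<taf_cv> %d-fold chain-level CV: MAE %.4f, PCC %.4f, objfit %.4f\n",
              x$k, x$mae, x$pcc, x$objfit))
  invisible(x)
}

#' @rdname cross_validate
#' @param x A `taf_cv` object.
#' @param ... Unused.
#' @method tidy taf_cv
#' @export
tidy.taf_cv <- function(x, ...) {
  x$per_fold
}

#' @rdname cross_validate
#' @method glance taf_cv
#' @export
glance.taf_cv <- function(x, ...) {
  tibble(k = x$k, n = sum(x$per_fold$n), mae = x$mae, pcc = x$pcc,
         objfit = x$objfit)
}

#' @rdname cross_validate
#' @param object A `taf_cv` object.
#' @method autoplot taf_cv
#' @export
autoplot.taf_cv <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_abline(linetype = 2, colour = "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "native fluctuation", y = "predicted fluctuation",
                  title = sprintf("%d-fold CV: MAE %.3f, PCC %.3f",
                                  object$k, object$mae, object$pcc)) +
    ggplot2::theme_minimal()
}

#' Percentage improvement over a baseline method
#'
#' MAE improvement is `(base - new) / base * 100` (lower error is better);
#' PCC improvement is `(new - base) / base * 100`; the average improvement
#' is the mean of the two, the summary used in method-comparison tables.
#'
#' @param new_mae,new_pcc Metrics of the evaluated method.
#' @param base_mae,base_pcc Metrics of the baseline (both nonzero).
#' @return One-row tibble: `mae_improvement`, `pcc_improvement`,
#'   `average_improvement` (percent).
#' @export
improvement_table <- function(new_mae, new_pcc, base_mae, base_pcc) {
  if (base_mae == 0 || base_pcc == 0) abort("baseline metrics must be nonzero")
  mi <- (base_mae - new_mae) / base_mae * 100
  pi <- (new_pcc - base_pcc) / base_pcc * 100
  tibble(mae_improvement = mi, pcc_improvement = pi,
         average_improvement = (mi + pi) / 2)
}

#' Window-size sweep
#'
#' Windows the base features at each candidate size, runs chain-level
#' cross-validation, and reports the objective per window size together
#' with the argmax. Mirrors the model-selection step that fixed the
#' production window size at 3.
#'
#' @param x Base (un-windowed) `taf_features` tibble.
#' @param y Labels row-aligned with `x`.
#' @param ws Odd window sizes to try (default 1, 3, 5).
#' @param rc A [regressor_config()].
#' @param k,seed Cross-validation folds and seed.
#' @return Object of class `taf_sweep`: tibble of `ws`, `mae`, `pcc`,
#'   `objfit` with attribute `best_ws`.
#' @export
window_sweep <- function(x, y, ws = c(1, 3, 5), rc = regressor_config(),
                         k = 10, seed = 1) {
  if (any(ws < 1 | ws %% 2 == 0)) abort("all window sizes must be odd and >= 1")
  rows <- lapply(ws, function(w) {
    xw <- window_features(x, w)
    cv <- cross_validate(xw, y, chain_ids = xw$chain_id, rc = rc,
                         k = k, seed = seed)
    tibble(ws = w, mae = cv$mae, pcc = cv$pcc, objfit = cv$objfit)
  })
  res <- bind_rows(rows)
  structure(res, best_ws = res$ws[which.max(res$objfit)],
            class = c("taf_sweep", class(res)))
}

#' Best window size found by a sweep
#'
#' @param sweep A `taf_sweep` object.
#' @return The window size with maximal objective.
#' @export
best_window <- function(sweep) {
  attr(sweep, "best_ws", exact = TRUE)
}

#' @rdname window_sweep
#' @param object A `taf_sweep` object.
#' @param ... Unused.
#' @method autoplot taf_sweep
#' @export
autoplot.taf_sweep <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$ws, y = .data$objfit)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$ws) +
    ggplot2::labs(x = "window size (residues)", y = "objfit = 1 - MAE + PCC") +
    ggplot2::theme_minimal()
}

#' Comparison table against a baseline method
#'
#' Builds the standard method-comparison layout -- one row per method with
#' MAE, PCC and percentage improvements over the first (baseline) row --
#' and optionally writes it as TSV.
#'
#' @param methods Tibble with columns `method`, `mae`, `pcc`; the first row
#'   is the baseline the improvements are computed against.
#' @param path Optional TSV output path.
#' @return Tibble with `method`, `mae`, `pcc`, `mae_improvement`,
#'   `pcc_improvement`, `average_improvement` (percent; NA for the
#'   baseline row).
#' @export
comparison_table <- function(methods, path = NULL) {
  if (nrow(methods) < 1L) abort("`methods` must have at least one row")
  base <- methods[1, ]
  imps <- lapply(seq_len(nrow(methods)), function(i) {
    if (i == 1L) {
      tibble(mae_improvement = NA_real_, pcc_improvement = NA_real_,
             average_improvement = NA_real_)
    } else {
      improvement_table(methods$mae[i], methods$pcc[i], base$mae, base$pcc)
    }
  })
  out <- bind_cols(methods[, c("method", "mae", "pcc")], bind_rows(imps))
  if (!is.null(path)) readr::write_tsv(out, path)
  out
}

#' Plain grid search over regressor hyperparameters
#'
#' Exhaustively cross-validates every combination of the supplied parameter
#' values (all other settings taken from `base`) and returns one row per
#' combination with its aggregate metrics, ordered by decreasing objective.
#' A deliberately simple utility: no sampling or pruning, just the grid.
#'
#' @param x Feature tibble or matrix.
#' @param y Labels row-aligned with `x`.
#' @param grid Named list of parameter values to cross, e.g.
#'   `list(learning_rate = c(0.05, 0.1), max_depth = c(4, 6))`; names must
#'   be [regressor_config()] arguments.
#' @param base A [regressor_config()] supplying the fixed settings.
#' @param chain_ids Chain id per row (taken from `x` when omitted).
#' @param k,seed Cross-validation folds and seed.
#' @return Tibble with one column per grid parameter plus `mae`, `pcc`,
#'   `objfit`, sorted best-first.
#' @export
grid_search <- function(x, y, grid, base = regressor_config(),
                        chain_ids = NULL, k = 10, seed = 1) {
  if (length(grid) == 0L || is.null(names(grid))) {
    abort("`grid` must be a non-empty named list")
  }
  bad <- setdiff(names(grid), names(base))
  if (length(bad) > 0L) {
    abort(sprintf("unknown regressor parameter(s): %s",
                  paste(bad, collapse = ", ")))
  }
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    rc <- base
    for (p in names(grid)) rc[[p]] <- combos[[p]][i]
    cv <- cross_validate(x, y, chain_ids = chain_ids, rc = rc, k = k,
                         seed = seed)
    bind_cols(as_tibble(combos[i, , drop = FALSE]),
              tibble(mae = cv$mae, pcc = cv$pcc, objfit = cv$objfit))
  })
  bind_rows(rows) |> arrange(dplyr::desc(.data$objfit))
}
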