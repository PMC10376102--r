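test_that("MAE matches its definition and is translation invariant", {
  expect_equal(mae(c(1, 2), c(1, 2)), 0)
  expect_equal(mae(c(0, 0), c(1, 3)), 2)
  x <- c(0.1, 0.4, 0.9)
  y <- c(0.2, 0.1, 0.5)
  expect_equal(mae(x + 0.3, y + 0.3), mae(x, y))
  expect_error(mae(1, c(1, 2)), "equal length")
  expect_error(mae(numeric(0), numeric(0)), "empty")
})

test_that("PCC matches the closed form and its invariances", {
  expect_equal(pcc(c(1, 2, 3), 2 * c(1, 2, 3) + 3), 1)
  expect_equal(pcc(c(1, 2, 3), -c(1, 2, 3)), -1)
  expect_equal(pcc(c(1, 2, 3), c(1, 2, 4)), 3 / sqrt(2 * 14 / 3),
               tolerance = 1e-12)
  expect_equal(round(pcc(c(1, 2, 3), c(1, 2, 4)), 4), 0.982)
  x <- withr::with_seed(1, runif(50))
  y <- withr::with_seed(2, runif(50))
  expect_equal(pcc(3 * x + 2, y), pcc(x, y))
  expect_equal(pcc(-3 * x + 2, y), -pcc(x, y))
  expect_error(pcc(rep(1, 5), 1:5), class = "torsionflux_zero_variance")
})

test_that("chain-level folds partition chains near-equally and reproducibly", {
  ids <- sprintf("c%02d", 1:20)
  f <- chain_level_folds(ids, k = 10, seed = 3)
  expect_equal(unname(table(f$fold)), rep(2L, 10), ignore_attr = TRUE)
  expect_equal(anyDuplicated(f$chain_id), 0)
  expect_equal(f, chain_level_folds(ids, k = 10, seed = 3))
  expect_false(identical(f$fold, chain_level_folds(ids, 10, seed = 4)$fold))
  expect_error(chain_level_folds(ids[1:5], k = 10), "folds")
})

test_that("cross-validation learns a noiseless linear signal and reports
           honest structure", {
  sim <- synth_features(signal_spec(n_chains = 12, chain_length = 40, D = 6,
                                    informative = c(1, 3, 5), noise_sd = 0,
                                    seed = 9))
  cv <- cross_validate(sim$features, sim$labels$y, rc = rc_light(),
                       k = 4, seed = 2)
  expect_gt(cv$pcc, 0.95)
  expect_equal(nrow(cv$per_fold), 4)
  expect_equal(sort(unique(cv$predictions$fold)), 1:4)
  # every chain tested exactly once
  tested <- unique(cv$predictions[, c("chain_id", "fold")])
  expect_equal(anyDuplicated(tested$chain_id), 0)
  expect_equal(sum(cv$per_fold$n), nrow(sim$features))
  expect_equal(cv$objfit, 1 - cv$mae + cv$pcc)
  expect_equal(glance(cv)$pcc, cv$pcc)
  expect_equal(nrow(tidy(cv)), 4)
})

test_that("labels independent of features give near-zero CV correlation", {
  sim <- synth_features(signal_spec(n_chains = 10, chain_length = 50, D = 6,
                                    coefficients = 0, intercept = 0.5,
                                    noise_sd = 0.1, seed = 13))
  cv <- cross_validate(sim$features, sim$labels$y, rc = rc_light(),
                       k = 5, seed = 3)
  expect_lt(abs(cv$pcc), 0.1)
})

test_that("CV correlation tracks the theoretical signal-to-noise ceiling", {
  # one informative column, U(0,1) signal (sd = 1/sqrt(12)), noise sd chosen
  # for a population correlation of 0.80
  # labels y = 0.25 + 0.5 X + eps stay inside [0, 1] (no clipping distortion)
  rho <- 0.8
  noise_sd <- 0.5 * sqrt(1 / 12) * sqrt(1 / rho^2 - 1)
  sim <- synth_features(signal_spec(n_chains = 20, chain_length = 150, D = 3,
                                    informative = 2, coefficients = 0.5,
                                    noise_sd = noise_sd, intercept = 0.25,
                                    seed = 17))
  cv <- cross_validate(sim$features, sim$labels$y,
                       rc = rc_light(n_estimators = 200), k = 5, seed = 4)
  expect_lt(abs(cv$pcc - rho), 0.05)
})

test_that("percentage improvements follow the comparison-table convention", {
  imp <- improvement_table(new_mae = 0.1, new_pcc = 0.6,
                           base_mae = 0.2, base_pcc = 0.5)
  expect_equal(imp$mae_improvement, 50)
  expect_equal(imp$pcc_improvement, 20)
  expect_equal(imp$average_improvement, 35)
  expect_error(improvement_table(0.1, 0.5, 0, 0.5), "nonzero")
  # the published psi improvement pair averages to the published value
  bench <- reference_benchmarks()
  psi <- bench[bench$angle == "psi" & bench$method == "gbt_selected", ]
  expect_equal(mean(c(psi$mae_improvement, psi$pcc_improvement)),
               psi$average_improvement, tolerance = 0.001)
})

test_that("training and predicting reuse the same feature set, with masks", {
  sim <- synth_features(signal_spec(n_chains = 6, chain_length = 30, D = 5,
                                    informative = c(1, 2), noise_sd = 0,
                                    seed = 21))
  mask <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  model <- train_fluctuation_model(sim$features, sim$labels$y,
                                   rc = rc_light(), mask = mask)
  expect_equal(model$features, c("f1", "f2", "f5"))
  pred <- predict(model, sim$features)
  expect_equal(nrow(pred), nrow(sim$features))
  expect_gt(pcc(pred$prediction, sim$labels$y), 0.9)
  expect_error(predict(model, feature_matrix(sim$features)[, 1:2]), "lacks")
})

test_that("window sweep evaluates every candidate and flags the argmax", {
  sim <- synth_features(signal_spec(n_chains = 8, chain_length = 30, D = 4,
                                    informative = 2, noise_sd = 0.05,
                                    seed = 23))
  sweep <- window_sweep(sim$features, sim$labels$y, ws = c(1, 3),
                        rc = rc_light(), k = 4, seed = 5)
  expect_equal(sweep$ws, c(1, 3))
  expect_equal(nrow(sweep), 2)
  expect_true(best_window(sweep) %in% c(1, 3))
  expect_equal(sweep$objfit, 1 - sweep$mae + sweep$pcc)
  expect_error(window_sweep(sim$features, sim$labels$y, ws = c(2, 3)), "odd")
})

test_that("comparison tables mirror the benchmark layout", {
  methods <- tibble::tibble(method = c("baseline", "boosted"),
                            mae = c(0.135, 0.123), pcc = c(0.602, 0.737))
  f <- withr::local_tempfile(fileext = ".tsv")
  tab <- comparison_table(methods, path = f)
  expect_equal(names(tab), c("method", "mae", "pcc", "mae_improvement",
                             "pcc_improvement", "average_improvement"))
  expect_true(is.na(tab$mae_improvement[1]))
  expect_equal(tab$mae_improvement[2], (0.135 - 0.123) / 0.135 * 100)
  expect_equal(tab$average_improvement[2],
               mean(c(tab$mae_improvement[2], tab$pcc_improvement[2])))
  expect_true(file.exists(f))
})

test_that("grid search crosses parameter values and ranks by objective", {
  sim <- synth_features(signal_spec(n_chains = 6, chain_length = 25, D = 4,
                                    informative = c(1, 3), noise_sd = 0.05,
                                    seed = 29))
  res <- grid_search(sim$features, sim$labels$y,
                     grid = list(learning_rate = c(0.05, 0.2),
                                 max_depth = c(2, 4)),
                     base = rc_light(n_estimators = 30), k = 3, seed = 8)
  expect_equal(nrow(res), 4)
  expect_true(all(c("learning_rate", "max_depth", "objfit") %in% names(res)))
  expect_equal(res$objfit, sort(res$objfit, decreasing = TRUE))
  expect_error(grid_search(sim$features, sim$labels$y,
                           grid = list(bogus = 1)), "unknown regressor")
})
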