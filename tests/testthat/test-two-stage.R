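test_that("confusion-matrix metrics are exact proportions", {
  m <- metrics(confusion_counts(166, 1, 6, 27))
  expect_equal(m$accuracy, 193 / 200)
  expect_equal(m$sensitivity, 166 / 172)
  expect_equal(m$specificity, 27 / 28)
  # diagonal-only matrix: perfect classification
  m1 <- metrics(confusion_counts(50, 0, 0, 10))
  expect_equal(unlist(m1, use.names = FALSE), c(1, 1, 1))
  # identity: accuracy * total = diagonal sum, exactly
  cm <- confusion_counts(123, 24, 7, 46)
  expect_identical(metrics(cm)$accuracy * sum(cm), 123 + 46)
  # undefined column -> NA token
  expect_true(is.na(metrics(confusion_counts(10, 0, 5, 0))$specificity))
  expect_error(metrics(confusion_counts(0, 0, 0, 0)), "no observations")
  expect_error(confusion_counts(-1, 0, 0, 0), "nonnegative")
})

test_that("confusion_matrix counts predictions against truth", {
  pred <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  obs <- c(TRUE, FALSE, FALSE, FALSE, TRUE)
  cm <- confusion_matrix(pred, obs)
  expect_equal(sum(cm), 5)
  expect_equal(cm["missing", "missing"], 1)
  expect_equal(cm["non-missing", "non-missing"], 2)
  expect_equal(cm["missing", "non-missing"], 1)
  expect_equal(cm["non-missing", "missing"], 1)
})

test_that("a threshold-driven missingness rule is learned accurately", {
  set.seed(50)
  X <- matrix(runif(1000 * 5), 1000, dimnames = list(NULL, paste0("p", 1:5)))
  y <- ifelse(X[, 1] > 0.6, NA, 2 * X[, 2] + X[, 3] + rnorm(1000, 0, 0.05))
  tr <- 1:800; te <- 801:1000
  fit <- fit_two_stage(X[tr, ], y[tr], clf = forest_config(300, 2),
                       reg = emulator_spec("lm"), seed = 1)
  pr <- predict(fit, X[te, ])
  cm <- confusion_matrix(pr$predicted_missing, is.na(y[te]))
  expect_gt(metrics(cm)$accuracy, 0.95)
  # rows predicted missing carry the missing token, no regressed value
  expect_true(all(is.na(pr$value[pr$predicted_missing])))
  expect_true(all(!is.na(pr$value[!pr$predicted_missing])))
  # regressor quality on truly observed, predicted-observed rows
  keep <- !pr$predicted_missing & !is.na(y[te])
  expect_lt(rmse(pr$value[keep], y[te][keep]), 0.5 * sd(y[te], na.rm = TRUE))
})

test_that("an (almost) fully observed feature skips the classifier", {
  set.seed(51)
  X <- matrix(runif(100 * 3), 100)
  y <- X[, 1] + rnorm(100, 0, 0.01)
  y[1:3] <- NA   # below the skip threshold
  fit <- fit_two_stage(X, y, reg = emulator_spec("lm"), seed = 1)
  expect_true(fit$skip_classifier)
  pr <- predict(fit, X)
  expect_false(any(pr$predicted_missing))
  expect_error(variable_importance(fit), "skip-classifier")
})

test_that("raising the threshold toward missing never raises sensitivity", {
  set.seed(52)
  X <- matrix(runif(600 * 4), 600, dimnames = list(NULL, paste0("p", 1:4)))
  y <- ifelse(X[, 1] + 0.3 * X[, 2] > 0.8, NA, X[, 3])
  tr <- 1:450; te <- 451:600
  fit <- fit_two_stage(X[tr, ], y[tr], clf = forest_config(300, 2),
                       reg = emulator_spec("lm"), seed = 2)
  sens <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(th) {
    fit$threshold <- th
    pr <- predict(fit, X[te, ])
    metrics(confusion_matrix(pr$predicted_missing, is.na(y[te])))$sensitivity
  }, numeric(1))
  expect_true(all(diff(sens) <= 1e-12))
})

test_that("Gini importance ranks the missingness driver first", {
  top_first <- 0
  for (s in 1:10) {
    set.seed(s + 200)
    X <- matrix(runif(400 * 6), 400,
                dimnames = list(NULL, c(paste0("p", 1:5), "inert_x")))
    y <- ifelse(X[, 1] > 0.55, NA, rnorm(400))
    fit <- fit_two_stage(X, y, clf = forest_config(200, 2),
                         reg = emulator_spec("mean"), seed = s)
    vi <- variable_importance(fit)
    top_first <- top_first + (vi$parameter[1] == "p1")
    expect_true(all(vi$importance >= 0))
    expect_true(all(diff(vi$importance) <= 0))
    # the inert column never outranks the true driver
    expect_gt(vi$importance[vi$parameter == "p1"],
              vi$importance[vi$parameter == "inert_x"])
  }
  expect_gte(top_first, 9)
})

test_that("out-of-bag tuning explores the documented grid", {
  set.seed(53)
  X <- matrix(runif(300 * 5), 300, dimnames = list(NULL, paste0("p", 1:5)))
  y <- ifelse(X[, 1] > 0.5, NA, X[, 2])
  fit <- fit_two_stage(X, y, clf = forest_config(100, 2),
                       reg = emulator_spec("mean"), tune = TRUE, seed = 3)
  expect_false(is.null(fit$tuned))
  expect_setequal(unique(fit$tuned$n_trees), c(500, 800, 1100, 1200))
  expect_true(all(fit$tuned$oob_accuracy >= 0 & fit$tuned$oob_accuracy <= 1))
})

test_that("the pipeline's regressed values match an oracle given truth", {
  syn <- fix_synth()
  X <- syn$params
  y <- syn$features$IDRest_7.min_voltage_between_spikes
  ratios <- vapply(1:5, function(s) {
    set.seed(s + 300)
    te <- sample.int(nrow(X), 60)
    tr <- setdiff(seq_len(nrow(X)), te)
    fit <- fit_two_stage(X[tr, ], y[tr], clf = forest_config(300, 6),
                         reg = emulator_spec("lm"), seed = s)
    pr <- predict(fit, X[te, ])
    keep <- !pr$predicted_missing & !is.na(y[te])
    pipe_rmse <- rmse(pr$value[keep], y[te][keep])
    # oracle: same regressor trained/tested on truly observed rows only
    obs_tr <- tr[!is.na(y[tr])]
    oracle <- fit_emulator(emulator_spec("lm"), X[obs_tr, ], y[obs_tr],
                           seed = s)
    keep_o <- te[!is.na(y[te])]
    oracle_rmse <- rmse(predict(oracle, X[keep_o, ])$mean, y[keep_o])
    pipe_rmse / oracle_rmse
  }, numeric(1))
  expect_true(all(ratios < 1.2))
})
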