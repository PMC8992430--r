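# GPllm selection, laGP, treed model, baselines and the benchmark protocol

test_that("an exactly linear response selects all-linear and matches least squares", {
  set.seed(10)
  X <- matrix(runif(100 * 3), 100, dimnames = list(NULL, c("a", "b", "c")))
  y <- 1 + 2 * X[, 1] - 3 * X[, 2] + 0.5 * X[, 3]
  fit <- llm_select(X, y)
  expect_true(all(fit$indicator == "linear"))
  ols <- lm(y ~ X)
  pr <- predict(fit, X)
  expect_lt(max(abs(pr$mean - fitted(ols))), 1e-6)
})

test_that("a constant response selects linear with zero slope", {
  X <- matrix(runif(50), 50, 1, dimnames = list(NULL, "x"))
  fit <- llm_select(X, rep(2, 50))
  expect_equal(unname(fit$indicator), "linear")
  expect_equal(unname(predict(fit, X)$mean), rep(2, 50))
})

test_that("selection separates a nonlinear from a linear dimension", {
  ok <- 0
  for (s in 1:10) {
    set.seed(s + 100)
    X <- matrix(runif(300 * 2), 300, dimnames = list(NULL, c("x1", "x2")))
    y <- sin(4 * pi * X[, 1]) + 2 * X[, 2] + rnorm(300, 0, 0.01)
    fit <- llm_select(X, y, n_starts = 1, seed = s)
    ok <- ok + (fit$indicator["x1"] == "gp" && fit$indicator["x2"] == "linear")
  }
  expect_gte(ok, 8)
})

test_that("laGP with m = n reduces to the full GP and interpolates", {
  set.seed(20)
  X <- matrix(runif(60 * 2), 60)
  y <- sin(12 * X[, 1]) + cos(11 * X[, 2])
  pr_lagp <- lagp_predict(X, y, X[1:5, ], m = 60, nugget = 0)
  expect_lt(max(abs(pr_lagp$mean - y[1:5])), 1e-6)
  pr_site <- lagp_predict(X, y, X[7, , drop = FALSE], m = 30, nugget = 0)
  expect_lt(abs(pr_site$mean - y[7]), 1e-6)
})

test_that("laGP rejects too-small neighborhoods", {
  X <- matrix(runif(50 * 6), 50)
  expect_error(lagp_predict(X, rnorm(50), X[1:2, ], m = 5), "d \\+ 2")
  expect_error(lagp_predict(X, rnorm(50), X[1:2, ], m = 60), "exceed")
})

test_that("laGP stays within 2x of the full GP on a smooth surface", {
  set.seed(8)
  X <- matrix(runif(600 * 2), 600)
  y <- sin(3 * X[, 1]) + cos(2 * X[, 2])
  Xt <- matrix(runif(100 * 2), 100)
  yt <- sin(3 * Xt[, 1]) + cos(2 * Xt[, 2])
  r_lagp <- rmse(lagp_predict(X, y, Xt, m = 50)$mean, yt)
  full <- gp_fit(X, y, n_starts = 2)
  r_full <- rmse(predict(full, Xt)$mean, yt)
  expect_lt(r_lagp, 2 * max(r_full, 1e-4))
})

test_that("the treed model finds a step breakpoint within 5%", {
  set.seed(4)
  X <- matrix(runif(400 * 2), 400, dimnames = list(NULL, c("x1", "x2")))
  y <- ifelse(X[, 1] > 0.63, 5, 0)
  fit <- treed_fit(X, y, max_depth = 2, leaf_model = "linear")
  sp <- treed_splits(fit)
  expect_equal(sp$dim[1], "x1")
  expect_lt(abs(sp$cut[1] - 0.63), 0.05)
})

test_that("depth zero reduces the treed model to its leaf model", {
  set.seed(5)
  X <- matrix(runif(80 * 2), 80)
  y <- X[, 1] + 2 * X[, 2] + rnorm(80, 0, 0.01)
  tr <- treed_fit(X, y, max_depth = 0, leaf_model = "linear")
  expect_equal(nrow(treed_splits(tr)), 0)
  lm_fit <- lm(y ~ X)
  expect_equal(predict(tr, X)$mean, unname(fitted(lm_fit)), tolerance = 1e-10)
})

test_that("the treed model captures a bi-modal two-regime response", {
  set.seed(7)
  X <- matrix(runif(500 * 3), 500, dimnames = list(NULL, paste0("x", 1:3)))
  y <- ifelse(X[, 1] > 0.5, 30 + 2 * X[, 2], -30 + X[, 3]) + rnorm(500, 0, 0.5)
  fit <- treed_fit(X[1:400, ], y[1:400], max_depth = 3, leaf_model = "linear")
  r <- rmse(predict(fit, X[401:500, ])$mean, y[401:500])
  expect_lt(r, 0.25 * sd(y[401:500]))
})

test_that("infeasible treed configurations are rejected", {
  X <- matrix(runif(20 * 3), 20)
  expect_error(treed_fit(X, rnorm(20), min_leaf = 30), "infeasible")
  expect_error(treed_fit(X, rnorm(20), min_leaf = 4, leaf_model = "gp"),
               "d \\+ 2")
})

test_that("every emulator honours the shared prediction contract", {
  set.seed(30)
  X <- matrix(runif(80 * 3), 80, dimnames = list(NULL, c("a", "b", "c")))
  y <- X[, 1] + sin(2 * X[, 2]) + rnorm(80, 0, 0.05)
  Xn <- matrix(runif(6 * 3), 6, dimnames = list(NULL, c("a", "b", "c")))
  for (m in c("gp", "gpllm", "lagp", "tree", "rf", "nn", "lm", "mean")) {
    spec <- if (m == "lagp") emulator_spec(m, m = 40)
            else if (m == "gp") emulator_spec(m, n_starts = 1, maxit = 30)
            else emulator_spec(m)
    fit <- fit_emulator(spec, X, y, seed = 1)
    pr <- predict(fit, Xn)
    expect_identical(names(pr), c("mean", "sd", "q05", "q95"))
    expect_equal(nrow(pr), 6)
    expect_true(all(is.finite(pr$mean)), info = m)
    if (m %in% c("rf", "nn")) expect_true(all(is.na(pr$sd)), info = m)
    else expect_true(all(pr$sd >= 0), info = m)
  }
})

test_that("the benchmark reports RMSE, SD ratio and isolates failures", {
  set.seed(31)
  X <- matrix(runif(120 * 3), 120, dimnames = list(NULL, c("a", "b", "c")))
  y <- 2 * X[, 1] + rnorm(120, 0, 0.05)
  tr <- 1:90; te <- 91:120
  specs <- list(null = emulator_spec("mean"),
                lin = emulator_spec("lm"),
                bad = emulator_spec("lagp", m = 2))  # infeasible: m < d + 2
  tab <- benchmark(specs, X[tr, ], y[tr], X[te, ], y[te], sort_by = NULL)
  expect_equal(tab$method, c("null", "lin", "bad"))
  # null model: RMSE equals test SD about the train mean
  expect_equal(tab$rmse[1], sqrt(mean((mean(y[tr]) - y[te])^2)),
               tolerance = 1e-12)
  expect_equal(tab$test_sd, rep(sd(y[te]), 3))
  expect_lt(tab$rmse_over_sd[2], 0.2)   # linear truth: near-oracle
  expect_true(is.na(tab$rmse[3]) && !is.na(tab$error[3]))
})
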