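test_that("the squared-exponential kernel matches its closed form", {
  h <- list(signal_variance = 2.5, lengthscales = c(1, 1, 1))
  x <- c(0.3, 0.4, 0.5)
  expect_equal(se_kernel(x, x, h), 2.5)
  h1 <- list(signal_variance = 1, lengthscales = 1)
  # unit distance, unit lengthscale -> exp(-1/2)
  expect_equal(se_kernel(c(0, 0), c(0.6, 0.8), h1), exp(-0.5),
               tolerance = 1e-12)
  expect_identical(se_kernel(c(0.1, 0.9), c(0.7, 0.2), h1),
                   se_kernel(c(0.7, 0.2), c(0.1, 0.9), h1))
  expect_error(se_kernel(x, x, list(signal_variance = 1,
                                    lengthscales = c(1, -1, 1))),
               "positive")
  # 1000 random pairs against direct evaluation
  set.seed(31)
  ls <- runif(4, 0.2, 3)
  sf2 <- 1.7
  hh <- list(signal_variance = sf2, lengthscales = ls)
  for (i in 1:1000) {
    a <- runif(4); b <- runif(4)
    expect_equal(se_kernel(a, b, hh),
                 sf2 * exp(-0.5 * sum((a - b)^2 / ls^2)),
                 tolerance = 1e-12)
  }
})

test_that("GP posterior matches a dense brute-force computation for n <= 10", {
  set.seed(1)
  n <- 8; d <- 3
  X <- matrix(runif(n * d), n)
  y <- sin(2 * X[, 1]) + X[, 2]^2 + rnorm(n, 0, 0.01)
  fit <- gp_fit(X, y, nugget = 1e-6, n_starts = 2, maxit = 50)
  h <- fit$hyper; ts <- fit$train
  K <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    K[i, j] <- se_kernel(ts$Xs[i, ], ts$Xs[j, ], h)
  K <- K + diag(n) * (h$nugget + fit$jitter)
  Xnew <- matrix(runif(5 * d), 5)
  Xs_new <- sweep(sweep(Xnew, 2, ts$lo, "-"), 2, ts$span, "/")
  ks <- matrix(0, 5, n)
  for (i in 1:5) for (j in 1:n)
    ks[i, j] <- se_kernel(Xs_new[i, ], ts$Xs[j, ], h)
  H <- matrix(1, n, 1)
  Kinv <- solve(K)
  beta <- solve(t(H) %*% Kinv %*% H, t(H) %*% Kinv %*% ts$yz)
  alpha <- Kinv %*% (ts$yz - H %*% beta)
  mu <- (as.numeric(beta) + ks %*% alpha) * ts$y_sd + ts$y_mean
  A <- t(H) %*% Kinv %*% H
  vv <- vapply(1:5, function(i) {
    u <- 1 - t(H) %*% Kinv %*% ks[i, ]
    drop(h$signal_variance - t(ks[i, ]) %*% Kinv %*% ks[i, ] +
           t(u) %*% solve(A) %*% u)
  }, numeric(1))
  pr <- predict(fit, Xnew)
  expect_lt(max(abs(pr$mean - mu)), 1e-8)
  expect_lt(max(abs(pr$sd - sqrt(pmax(vv, 0)) * ts$y_sd)), 1e-8)
})

test_that("a zero-nugget GP interpolates its training data", {
  set.seed(2)
  X <- matrix(runif(200 * 5), 200)
  y <- apply(X, 1, function(r) sum(sin(pi * r)))
  fit <- gp_fit(X, y, nugget = 0, n_starts = 2)
  pr <- predict(fit, X)
  expect_lt(max(abs(pr$mean - y)), 1e-6)
  expect_lt(max(pr$sd), 1e-3 * sqrt(fit$hyper$signal_variance) * fit$train$y_sd)
})

test_that("quantiles obey the Gaussian identity q95 - q05 = 2 z sd", {
  set.seed(3)
  X <- matrix(runif(40 * 2), 40)
  fit <- gp_fit(X, X[, 1] + rnorm(40, 0, 0.1), n_starts = 1, maxit = 30)
  pr <- predict(fit, matrix(runif(20 * 2), 20))
  expect_equal(pr$q95 - pr$q05, 2 * qnorm(0.95) * pr$sd, tolerance = 1e-10)
  expect_true(all(pr$q05 <= pr$mean & pr$mean <= pr$q95))
})

test_that("far from all data the posterior reverts to trend and prior variance", {
  set.seed(3)
  X <- matrix(runif(60 * 2, 0, 0.1), 60)
  y <- 2 * X[, 1] + rnorm(60, 0, 0.05)
  fit <- gp_fit(X, y, n_starts = 2)
  pr <- predict(fit, matrix(c(50, 50), 1))
  ts <- fit$train
  expect_equal(pr$mean, fit$beta[1] * ts$y_sd + ts$y_mean, tolerance = 1e-6)
  expect_equal(pr$sd, sqrt(fit$hyper$signal_variance) * ts$y_sd,
               tolerance = 0.05)
})

test_that("a constant response yields constant predictions", {
  X <- matrix(runif(30 * 2), 30)
  fit <- gp_fit(X, rep(3.5, 30), n_starts = 1, maxit = 20)
  pr <- predict(fit, matrix(runif(10 * 2), 10))
  expect_equal(pr$mean, rep(3.5, 10), tolerance = 1e-8)
})

test_that("duplicated inputs with conflicting responses and zero nugget error", {
  X <- matrix(runif(20 * 2), 20)
  X[2, ] <- X[1, ]
  y <- rnorm(20)
  expect_error(gp_fit(X, y, nugget = 0), "conditioning")
})

test_that("n < d + 2 is rejected", {
  expect_error(gp_fit(matrix(runif(10 * 9), 10), rnorm(10)), "d \\+ 2")
})

test_that("known-GP draws recover lengthscales within a factor of two", {
  true_ls <- c(0.3, 0.6, 1.2)
  ok <- 0
  for (s in 1:10) {
    set.seed(s)
    X <- matrix(runif(200 * 3), 200)
    K <- neuremu:::se_cross_cov(X, X, true_ls, 1)
    K <- (K + t(K)) / 2 + diag(200) * 1e-6
    y <- drop(crossprod(chol(K), rnorm(200)))
    fit <- gp_fit(X, y, nugget = 1e-6, n_starts = 5, seed = s)
    rat <- fit$hyper$lengthscales / true_ls
    ok <- ok + all(rat > 0.5 & rat < 2)
  }
  expect_gte(ok, 8)
})

test_that("conditioning on more data never inflates posterior sd (fixed hyper)", {
  set.seed(6)
  X <- matrix(runif(80 * 2), 80)
  y <- sin(3 * X[, 1]) + X[, 2]
  xstar <- matrix(c(0.5, 0.5), 1)
  ls <- c(0.4, 0.4)
  sd_at <- function(idx) {
    H <- matrix(1, length(idx), 1)
    p <- neuremu:::gp_posterior(X[idx, , drop = FALSE], y[idx], H, xstar,
                                matrix(1, 1, 1), ls, 1, 1e-8, 0)
    sqrt(p$var)
  }
  sds <- vapply(c(20, 40, 60, 80), function(k) sd_at(seq_len(k)), numeric(1))
  expect_true(all(diff(sds) <= 1e-8))
})
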