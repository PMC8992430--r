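#' Fit a Gaussian-process emulator
#'
#' Regression-plus-GP model \code{f(x) = sum_i beta_i g_i(x) + Z(x)} with a
#' constant trend by default (optionally linear terms for selected inputs) and
#' a zero-mean GP \code{Z} under the ARD squared-exponential kernel
#' ([se_kernel()]). Inputs are scaled to the unit cube through the parameter
#' space bounds (observed ranges when no space is given); the response is
#' standardized before fitting and de-standardized at prediction.
#' Hyperparameters maximize the beta-profiled log marginal likelihood by
#' multi-start L-BFGS-B in log space with analytic gradients (empirical-Bayes
#' conditioning). With \code{nugget = 0} the fitted model interpolates its
#' training data.
#'
#' @param X numeric matrix of inputs (rows = training runs).
#' @param y numeric response, no missing values.
#' @param space optional [parameter_space()] used for unit-cube scaling.
#' @param linear_dims character/integer columns acting through the linear
#'   trend rather than the kernel (the limiting-linear-model structure).
#' @param nugget \code{"estimate"} (default; bounded in \code{[1e-8, 1]} on
#'   the standardized scale — guards conditioning even for deterministic
#'   simulators) or a fixed nonnegative number (\code{0} = interpolating GP).
#' @param n_starts number of optimizer starts (first deterministic, rest
#'   seeded).
#' @param maxit L-BFGS-B iteration cap per start.
#' @param seed integer seed for the optimizer restarts.
#' @return Object of class \code{c("gp_emulator", "emulator")} with the
#'   fitted hyperparameters (\code{$hyper}: signal variance, per-dimension
#'   lengthscales on the unit cube, nugget — standardized-response scale),
#'   trend coefficients \code{$beta} and the negative log marginal likelihood
#'   \code{$nll}.
#' @seealso [predict.gp_emulator()], [llm_select()], [lagp_predict()]
#' @export
gp_fit <- function(X, y, space = NULL, linear_dims = NULL,
                   nugget = "estimate", n_starts = 3L, maxit = 100L,
                   seed = 1L) {
  ts <- new_train_set(X, y, space)
  if (ts$n < ts$d + 2)
    stop("GP fit requires n >= d + 2 training rows (n = ", ts$n,
         ", d = ", ts$d, ")")
  all_dims <- colnames(ts$Xs)
  if (is.numeric(linear_dims)) linear_dims <- all_dims[linear_dims]
  linear_dims <- as.character(linear_dims %||% character())
  gp_dims <- setdiff(all_dims, linear_dims)
  if (length(gp_dims) == 0)
    stop("no GP dimensions left; use the linear emulator instead")

  Xk <- ts$Xs[, gp_dims, drop = FALSE]
  H <- cbind(const = 1, ts$Xs[, linear_dims, drop = FALSE])

  fixed_nugget <- is.numeric(nugget)
  if (fixed_nugget && nugget < 0) stop("nugget must be >= 0")
  if (fixed_nugget && nugget <= 1e-10 && anyDuplicated(Xk)) {
    dup <- duplicated(Xk) | duplicated(Xk, fromLast = TRUE)
    if (stats::var(ts$yz[dup]) > 0 ||
        length(unique(ts$yz[dup])) > nrow(unique(Xk[dup, , drop = FALSE])))
      stop("conditioning error: duplicated training inputs with conflicting ",
           "responses and nugget = 0")
  }
  dg <- length(gp_dims)
  log_nug_fixed <- if (fixed_nugget) log(max(nugget / ts$y_sd^2, 1e-300)) else NA
  n_free <- dg + 1L + if (fixed_nugget) 0L else 1L

  lower <- c(rep(log(1e-3), dg), log(1e-4), if (!fixed_nugget) log(1e-8))
  upper <- c(rep(log(1e3), dg), log(1e4), if (!fixed_nugget) log(1))

  full_theta <- function(th) if (fixed_nugget) c(th, log_nug_fixed) else th
  cache <- new.env(parent = emptyenv())
  eval_pt <- function(th) {
    key <- paste(format(th, digits = 17), collapse = ",")
    if (!is.null(cache$key) && identical(cache$key, key)) return(cache$val)
    r <- gp_nll_grad(Xk, ts$yz, H, full_theta(th), TRUE)
    if (!isTRUE(r$ok)) r <- list(ok = FALSE, nll = 1e10,
                                 grad = rep(0, length(full_theta(th))))
    cache$key <- key
    cache$val <- r
    r
  }
  fn <- function(th) eval_pt(th)$nll
  gr <- function(th) eval_pt(th)$grad[seq_len(n_free)]

  set.seed(derive_seed(seed, 0L))
  starts <- vector("list", n_starts)
  starts[[1]] <- c(rep(log(0.5), dg), log(1), if (!fixed_nugget) log(1e-4))
  if (n_starts > 1) for (s in 2:n_starts)
    starts[[s]] <- c(log(10^stats::runif(dg, -1.3, 0.7)),
                     log(10^stats::runif(1, -0.7, 0.7)),
                     if (!fixed_nugget) log(10^stats::runif(1, -7, -2)))

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, fn, gr, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = maxit)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || best$value >= 1e10)
    stop("conditioning error: covariance factorization failed for every ",
         "optimizer start")

  theta <- full_theta(best$par)
  final <- gp_nll_grad(Xk, ts$yz, H, theta, FALSE)
  ls <- exp(theta[seq_len(dg)])
  structure(list(
    train = ts, gp_dims = gp_dims, linear_dims = linear_dims,
    hyper = new_kernel_hyper(signal_variance = exp(theta[dg + 1]),
                             lengthscales = stats::setNames(ls, gp_dims),
                             nugget = if (fixed_nugget) nugget / ts$y_sd^2
                                      else exp(theta[dg + 2])),
    beta = as.numeric(final$beta), jitter = final$jitter,
    nll = final$nll,
    config = list(nugget = nugget, n_starts = n_starts, maxit = maxit,
                  seed = seed)),
    class = c("gp_emulator", "emulator"))
}

#' Predict from a Gaussian-process emulator
#'
#' Standard universal-kriging posterior: mean and latent predictive SD
#' (including the trend-estimation correction, excluding the nugget), plus
#' central predictive quantiles from the Gaussian posterior. At a training
#' site with zero nugget the mean reproduces the training response.
#'
#' @param object a fitted \code{gp_emulator}.
#' @param Xnew matrix of prediction inputs (raw scale).
#' @param level central interval level for the reported quantiles
#'   (default 0.90, giving \code{q05}/\code{q95}).
#' @param ... unused.
#' @return \code{data.frame} with columns \code{mean}, \code{sd}, \code{q05},
#'   \code{q95} (response units).
#' @export
predict.gp_emulator <- function(object, Xnew, level = 0.90, ...) {
  ts <- object$train
  Xs <- scale_newdata(ts, Xnew)
  Xk_new <- Xs[, object$gp_dims, drop = FALSE]
  H_new <- cbind(const = 1, Xs[, object$linear_dims, drop = FALSE])
  Xk <- ts$Xs[, object$gp_dims, drop = FALSE]
  H <- cbind(const = 1, ts$Xs[, object$linear_dims, drop = FALSE])
  h <- object$hyper
  post <- gp_posterior(Xk, ts$yz, H, Xk_new, H_new,
                       h$lengthscales, h$signal_variance,
                       max(h$nugget, 1e-300), object$jitter)
  z <- stats::qnorm(1 - (1 - level) / 2)
  mean_raw <- post$mean * ts$y_sd + ts$y_mean
  sd_raw <- sqrt(pmax(post$var, 0)) * ts$y_sd
  data.frame(mean = mean_raw, sd = sd_raw,
             q05 = mean_raw - z * sd_raw, q95 = mean_raw + z * sd_raw)
}

#' @export
print.gp_emulator <- function(x, ...) {
  cat(sprintf("gp_emulator: n = %d, %d kernel dim(s), %d linear dim(s)\n",
              x$train$n, length(x$gp_dims), length(x$linear_dims)))
  cat(sprintf("  signal variance %.3g, nugget %.3g (standardized scale), nll %.3f\n",
              x$hyper$signal_variance, x$hyper$nugget, x$nll))
  invisible(x)
}
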