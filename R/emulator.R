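#' Specify an emulator method
#'
#' Light-weight recipe naming one of the supported emulation methods with
#' method options; [fit_emulator()] turns it into a fitted model. All fitted
#' emulators share one prediction contract: \code{predict()} returns a
#' \code{data.frame} with columns \code{mean}, \code{sd}, \code{q05},
#' \code{q95}. Methods providing only a point prediction (random forest,
#' neural network) report \code{sd = NA} and are excluded from coverage
#' analysis.
#'
#' @param method one of \code{"gp"}, \code{"gpllm"}, \code{"lagp"},
#'   \code{"tree"}, \code{"rf"}, \code{"nn"}, \code{"lm"}, or
#'   \code{"mean"} (the null model predicting the training mean — the
#'   benchmark's reference point: its RMSE equals the test SD about the
#'   training mean).
#' @param ... method options forwarded to the fitting routine (e.g.
#'   \code{n_starts}, \code{maxit}, \code{nugget} for GP-family methods;
#'   \code{max_depth}, \code{min_leaf}, \code{leaf_model} for the treed
#'   model; \code{ntree} for the forest; \code{size}, \code{decay} for the
#'   neural net).
#' @param m laGP neighbor count (named formal so it is matched exactly).
#' @return Object of class \code{emulator_spec}.
#' @export
emulator_spec <- function(method = c("gp", "gpllm", "lagp", "tree", "rf",
                                     "nn", "lm", "mean"), ..., m = NULL) {
  method <- match.arg(method)
  opts <- list(...)
  if (!is.null(m)) opts$m <- m   # post-dots formal: exact match only, so the
                                 # laGP neighbor count can never partially
                                 # match 'method'
  structure(list(method = method, opts = opts), class = "emulator_spec")
}

#' @export
print.emulator_spec <- function(x, ...) {
  cat("emulator_spec:", x$method, "\n")
  invisible(x)
}

#' Fit an emulator from a specification
#'
#' @param spec an [emulator_spec()].
#' @param X input matrix (raw parameter scale).
#' @param y numeric response without missing values.
#' @param space optional [parameter_space()] for unit-cube input scaling.
#' @param seed integer seed (forwarded to stochastic methods and optimizer
#'   restarts).
#' @return A fitted emulator (class \code{"emulator"} plus a method class).
#' @export
fit_emulator <- function(spec, X, y, space = NULL, seed = 1L) {
  stopifnot(inherits(spec, "emulator_spec"))
  o <- spec$opts
  fit <- switch(spec$method,
    gp    = do.call(gp_fit, c(list(X = X, y = y, space = space, seed = seed), o)),
    gpllm = do.call(llm_select, c(list(X = X, y = y, space = space, seed = seed), o)),
    lagp  = do.call(lagp_emulator, c(list(X = X, y = y, space = space, seed = seed), o)),
    tree  = do.call(treed_fit, c(list(X = X, y = y, space = space, seed = seed), o)),
    rf    = do.call(rf_emulator, c(list(X = X, y = y, seed = seed), o)),
    nn    = do.call(nn_emulator, c(list(X = X, y = y, space = space, seed = seed), o)),
    lm    = do.call(lm_emulator, c(list(X = X, y = y), o)),
    mean  = mean_emulator(y))
  attr(fit, "spec") <- spec
  fit
}

#' Methods forming the GP family (full predictive distributions)
#' @return Character vector of method names whose predictions carry
#'   quantiles.
#' @export
gp_family_methods <- function() c("gp", "gpllm", "lagp", "tree", "lm")

prediction_frame <- function(mean, sd = NA_real_, level = 0.90) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  sd <- rep_len(sd, length(mean))
  data.frame(mean = mean, sd = sd, q05 = mean - z * sd, q95 = mean + z * sd)
}

# ---- null model: train mean ------------------------------------------------

mean_emulator <- function(y) {
  structure(list(value = mean(y), sd = stats::sd(y)),
            class = c("mean_emulator", "emulator"))
}

#' @export
predict.mean_emulator <- function(object, Xnew, level = 0.90, ...) {
  n <- if (is.matrix(Xnew) || is.data.frame(Xnew)) nrow(Xnew) else 1L
  prediction_frame(rep(object$value, n), object$sd, level)
}

# ---- degenerate constant response ------------------------------------------

constant_emulator <- function(value) {
  structure(list(value = value), class = c("constant_emulator", "emulator"))
}

#' @export
predict.constant_emulator <- function(object, Xnew, level = 0.90, ...) {
  n <- if (is.matrix(Xnew) || is.data.frame(Xnew)) nrow(Xnew) else 1L
  prediction_frame(rep(object$value, n), 0, level)
}

# ---- linear baseline -------------------------------------------------------

lm_emulator <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  df <- data.frame(.y = y, X, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = df)
  structure(list(fit = fit, xnames = colnames(X)),
            class = c("lm_emulator", "emulator"))
}

#' @export
predict.lm_emulator <- function(object, Xnew, level = 0.90, ...) {
  Xnew <- as.matrix(Xnew)
  colnames(Xnew) <- object$xnames
  pr <- stats::predict(object$fit, newdata = as.data.frame(Xnew),
                       se.fit = TRUE)
  sd <- sqrt(pr$se.fit^2 + pr$residual.scale^2)
  prediction_frame(as.numeric(pr$fit), sd, level)
}

# ---- random forest (point predictions only) --------------------------------

rf_emulator <- function(X, y, ntree = 500, mtry = NULL, seed = 1L) {
  set.seed(derive_seed(seed, 0L))
  X <- as.matrix(X)
  args <- list(x = X, y = y, ntree = ntree)
  if (!is.null(mtry)) args$mtry <- mtry
  fit <- do.call(randomForest::randomForest, args)
  structure(list(fit = fit), class = c("rf_emulator", "emulator"))
}

#' @export
predict.rf_emulator <- function(object, Xnew, level = 0.90, ...) {
  prediction_frame(as.numeric(stats::predict(object$fit, as.matrix(Xnew))),
                   NA_real_, level)
}

# ---- neural network (point predictions only) -------------------------------

nn_emulator <- function(X, y, space = NULL, size = 10, decay = 1e-3,
                        maxit = 500, seed = 1L) {
  ts <- new_train_set(X, y, space)
  set.seed(derive_seed(seed, 0L))
  fit <- nnet::nnet(ts$Xs, ts$yz, size = size, decay = decay, maxit = maxit,
                    linout = TRUE, trace = FALSE)
  structure(list(fit = fit, train = ts), class = c("nn_emulator", "emulator"))
}

#' @export
predict.nn_emulator <- function(object, Xnew, level = 0.90, ...) {
  ts <- object$train
  yz <- as.numeric(stats::predict(object$fit, scale_newdata(ts, Xnew)))
  prediction_frame(yz * ts$y_sd + ts$y_mean, NA_real_, level)
}
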