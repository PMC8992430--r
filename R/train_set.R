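# Internal training-set container: inputs scaled to the unit cube (via
# parameter-space bounds when available, observed ranges otherwise), response
# standardized to zero mean / unit SD. All emulators share this scaler.
new_train_set <- function(X, y, space = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X and y sizes disagree")
  if (anyNA(y)) stop("y contains missing values; exclude missing rows upstream")
  if (anyNA(X)) stop("X contains missing values")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!is.null(space)) {
    nm <- colnames(X)
    known <- nm %in% space$names
    lo <- hi <- numeric(ncol(X))
    lo[known] <- space$lower[nm[known]]
    hi[known] <- space$upper[nm[known]]
    # columns outside the space (e.g. appended noise controls): observed range
    lo[!known] <- apply(X[, !known, drop = FALSE], 2, min)
    hi[!known] <- apply(X[, !known, drop = FALSE], 2, max)
  } else {
    lo <- apply(X, 2, min)
    hi <- apply(X, 2, max)
  }
  span <- hi - lo
  span[span <= 0] <- 1
  Xs <- sweep(sweep(X, 2, lo, "-"), 2, span, "/")
  y_mean <- mean(y)
  y_sd <- stats::sd(y)
  if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
  list(X = X, Xs = Xs, y = y, yz = (y - y_mean) / y_sd,
       lo = stats::setNames(lo, colnames(X)), span = stats::setNames(span, colnames(X)),
       y_mean = y_mean, y_sd = y_sd, n = nrow(X), d = ncol(X))
}

scale_newdata <- function(ts, Xnew) {
  Xnew <- as.matrix(Xnew)
  storage.mode(Xnew) <- "double"
  if (ncol(Xnew) != ts$d) stop("dimension mismatch: expected ", ts$d,
                               " input columns, got ", ncol(Xnew))
  if (is.null(colnames(Xnew))) colnames(Xnew) <- names(ts$lo)
  else if (!identical(colnames(Xnew), names(ts$lo)) &&
           all(names(ts$lo) %in% colnames(Xnew)))
    Xnew <- Xnew[, names(ts$lo), drop = FALSE]
  sweep(sweep(Xnew, 2, ts$lo, "-"), 2, ts$span, "/")
}
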