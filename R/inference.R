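#' Predictive-interval coverage report
#'
#' Coverage is the fraction of held-out true values falling inside the
#' emulator's central predictive interval \code{[q05, q95]} (closed
#' interval). At the nominal 90\% level, empirical coverage near 0.90
#' indicates both a good fit and an honest uncertainty assessment. Interval
#' widths are also reported in units of the test-set SD — well-calibrated
#' GP emulators typically produce intervals one to two SDs wide.
#'
#' @param predictions \code{data.frame} with \code{q05}/\code{q95} columns
#'   (GP-family emulators only; point-prediction methods carry \code{NA}
#'   quantiles and are rejected).
#' @param y_true numeric held-out responses, nonempty.
#' @param level nominal central level of the intervals (default 0.90).
#' @return List of class \code{coverage_report}: \code{nominal},
#'   \code{coverage}, \code{n}, \code{mean_width}, \code{sd_width},
#'   \code{mean_width_sd_units}.
#' @export
coverage <- function(predictions, y_true, level = 0.90) {
  if (length(y_true) == 0) stop("empty test set")
  if (nrow(predictions) != length(y_true))
    stop("predictions and y_true sizes disagree")
  if (anyNA(predictions$q05) || anyNA(predictions$q95))
    stop("unsupported emulator: predictions carry no quantiles ",
         "(point-prediction method)")
  inside <- y_true >= predictions$q05 & y_true <= predictions$q95
  w <- predictions$q95 - predictions$q05
  s <- stats::sd(y_true)
  structure(list(nominal = level, coverage = mean(inside),
                 n = length(y_true), mean_width = mean(w),
                 sd_width = stats::sd(w),
                 mean_width_sd_units = if (is.finite(s) && s > 0) mean(w) / s
                                       else NA_real_),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf(
    "coverage %.3f (nominal %.2f, n = %d); mean width %.3g (%.2f test SDs)\n",
    x$coverage, x$nominal, x$n, x$mean_width, x$mean_width_sd_units))
  invisible(x)
}

#' Append standard-normal noise-control columns
#'
#' Adds two columns of independent standard-normal draws to an input matrix.
#' The controls are, by construction, unrelated to the response; in
#' sensitivity analyses their indices frame the noise floor — any mechanistic
#' parameter whose index falls at or below the controls' is
#' indistinguishable from noise (a negative control).
#'
#' @param X input matrix.
#' @param seed integer seed.
#' @param names names of the appended columns.
#' @return List with \code{X} (augmented matrix, original columns untouched)
#'   and \code{controls} (the control column names).
#' @export
add_noise_controls <- function(X, seed = 1L,
                               names = c("noise_1", "noise_2")) {
  X <- as.matrix(X)
  set.seed(derive_seed(seed, 5L))
  N <- matrix(stats::rnorm(nrow(X) * length(names)), nrow(X),
              dimnames = list(NULL, names))
  list(X = cbind(X, N), controls = names)
}

# uniform-box sampler over a parameter space, with standard-normal control
# columns appended; returns raw-scale draws
box_sampler <- function(space, controls = character()) {
  function(n) {
    U <- matrix(stats::runif(n * space$d), n, dimnames = list(NULL, space$names))
    X <- unscale_params(space, U)
    if (length(controls)) {
      N <- matrix(stats::rnorm(n * length(controls)), n,
                  dimnames = list(NULL, controls))
      X <- cbind(X, N)
    }
    X
  }
}

#' Monte-Carlo Sobol sensitivity indices through an emulator
#'
#' First-order indices \code{S_j} (share of output variance explained by
#' input \code{j} alone) and total indices \code{T_j} (share involving
#' \code{j} in any interaction), estimated by Saltelli-scheme paired sampling
#' with the Jansen estimators, applied to the emulator's posterior mean.
#' Inputs are drawn uniformly over the parameter box; noise-control columns
#' (standard normal) can be included as negative controls. Deterministic
#' given the seed; uses \code{n_base * (d + 2)} emulator evaluations.
#'
#' @param object a fitted emulator (its \code{predict()} mean is the model
#'   output) or a plain function \code{f(X) -> numeric}.
#' @param space a [parameter_space()] describing the mechanistic inputs.
#' @param n_base Monte-Carlo base sample size (power of 2 recommended,
#'   \code{>= 256}).
#' @param seed integer seed.
#' @param controls names of standard-normal control columns appended after
#'   the space's parameters (must match the emulator's training layout).
#' @return \code{data.frame} of class \code{sensitivity_result} with columns
#'   \code{parameter}, \code{S}, \code{T} (clipped at 0), \code{S_raw},
#'   \code{T_raw}; attributes \code{n_base} and \code{seed}.
#' @export
sobol_indices <- function(object, space, n_base = 1024L, seed = 1L,
                          controls = character()) {
  if (n_base < 256) stop("n_base must be >= 256")
  f <- if (is.function(object)) object
       else function(X) stats::predict(object, X)$mean
  sampler <- box_sampler(space, controls)
  set.seed(derive_seed(seed, 7L))
  A <- sampler(n_base)
  B <- sampler(n_base)
  nms <- colnames(A)
  D <- ncol(A)
  fA <- f(A)
  fB <- f(B)
  if (anyNA(fA) || anyNA(fB)) stop("emulator returned missing predictions")
  V <- stats::var(c(fA, fB))
  S <- T_ <- numeric(D)
  for (j in seq_len(D)) {
    ABj <- A
    ABj[, j] <- B[, j]
    fABj <- f(ABj)
    # Jansen estimators
    S[j] <- (V - mean((fB - fABj)^2) / 2) / V
    T_[j] <- mean((fA - fABj)^2) / 2 / V
  }
  structure(data.frame(parameter = nms, S = pmax(S, 0), T = pmax(T_, 0),
                       S_raw = S, T_raw = T_, stringsAsFactors = FALSE),
            class = c("sensitivity_result", "data.frame"),
            n_base = n_base, seed = seed)
}

#' Main-effect curve of one parameter
#'
#' Fixes the chosen parameter at each value of an equispaced grid and
#' averages the emulator's mean prediction over Monte-Carlo draws of the
#' remaining inputs (uniform over the box; standard normal for control
#' columns). Common random numbers are used across the grid, so the curve's
#' shape is not obscured by resampling noise.
#'
#' @inheritParams sobol_indices
#' @param parameter name of the parameter to profile.
#' @param grid either the number of equispaced grid points (default 25) or a
#'   numeric vector of values, all within the parameter's bounds.
#' @param n_mc Monte-Carlo draws of the remaining inputs.
#' @return \code{data.frame} with columns \code{value} and \code{effect}.
#' @export
main_effects <- function(object, space, parameter, grid = 25L, n_mc = 200L,
                         seed = 1L, controls = character()) {
  if (!parameter %in% c(space$names, controls))
    stop("unknown parameter: ", parameter)
  f <- if (is.function(object)) object
       else function(X) stats::predict(object, X)$mean
  if (length(grid) == 1L) {
    lo <- space$lower[parameter]
    hi <- space$upper[parameter]
    grid <- seq(lo, hi, length.out = grid)
  } else if (parameter %in% space$names &&
             (min(grid) < space$lower[parameter] ||
              max(grid) > space$upper[parameter]))
    stop("grid outside the bounds of ", parameter)
  set.seed(derive_seed(seed, 9L))
  X <- box_sampler(space, controls)(n_mc)
  effect <- vapply(grid, function(v) {
    X[, parameter] <- v
    mean(f(X))
  }, numeric(1))
  data.frame(value = as.numeric(grid), effect = effect)
}
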