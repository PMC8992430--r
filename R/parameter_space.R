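#' Define a bounded, tagged parameter space
#'
#' The parameter space is the shared coordinate frame of the simulator, the
#' emulators and the genetic algorithm: named bounded inputs, each tagged with
#' a region (\code{"somatic"}, \code{"basal"}, \code{"axonal"}) or marked
#' \code{"inert"}. Inert parameters are provably ignored by the simulator and
#' double as built-in negative controls for sensitivity analysis.
#'
#' @param names character vector of unique parameter names.
#' @param lower,upper numeric bounds, elementwise \code{lower < upper}.
#' @param region character vector of region tags, one per parameter.
#' @return An object of class \code{parameter_space} with fields
#'   \code{names}, \code{lower}, \code{upper}, \code{region}, \code{d}.
#' @seealso [default_parameter_space()]
#' @export
parameter_space <- function(names, lower, upper, region) {
  names <- as.character(names)
  if (anyDuplicated(names)) stop("parameter names must be unique")
  if (length(lower) != length(names) || length(upper) != length(names) ||
      length(region) != length(names))
    stop("names, lower, upper and region must have equal length")
  if (!all(is.finite(lower)) || !all(is.finite(upper)) || !all(lower < upper))
    stop("bounds must be finite with lower < upper elementwise")
  structure(list(names = names,
                 lower = stats::setNames(as.numeric(lower), names),
                 upper = stats::setNames(as.numeric(upper), names),
                 region = stats::setNames(as.character(region), names),
                 d = length(names)),
            class = "parameter_space")
}

# the 12 mechanistic membrane parameters of the stand-in simulator
mechanistic_bounds <- function() {
  data.frame(
    name   = c("C_m", "g_L", "E_L", "V_T", "Delta_T", "a_w", "b_w", "tau_w",
               "V_reset", "V_peak", "t_ref", "i_gain"),
    lower  = c(0.03, 0.0025, -85, -55, 0.5, 0,     0,    20,  -70, 10, 0.5, 0.5),
    upper  = c(0.15, 0.01,   -65, -40, 4,   0.005, 0.15, 300, -50, 30, 5,   2),
    region = c("somatic", "somatic", "somatic", "axonal", "axonal", "somatic",
               "somatic", "somatic", "axonal", "axonal", "axonal", "basal"),
    stringsAsFactors = FALSE)
}

#' Default parameter space of the stand-in neuron
#'
#' Twelve mechanistic adaptive-exponential membrane parameters (capacitance,
#' leak conductance and reversal, spike threshold and slope factor, adaptation
#' coupling/increment/time constant, reset, spike cutoff, refractory period,
#' input gain) padded with \code{d - 12} inert parameters on \code{[0, 1]}.
#' The default dimension is 31, the size typical of conductance-based neuron
#' fitting problems.
#'
#' @param d total number of parameters, \code{d >= 12}.
#' @return A [parameter_space()].
#' @export
default_parameter_space <- function(d = 31L) {
  mech <- mechanistic_bounds()
  if (d < nrow(mech)) stop("d must be at least ", nrow(mech))
  n_in <- d - nrow(mech)
  inert <- if (n_in > 0) sprintf("inert_%02d", seq_len(n_in)) else character()
  parameter_space(
    names  = c(mech$name, inert),
    lower  = c(mech$lower, rep(0, n_in)),
    upper  = c(mech$upper, rep(1, n_in)),
    region = c(mech$region, rep("inert", n_in)))
}

#' @export
print.parameter_space <- function(x, ...) {
  cat(sprintf("parameter_space: %d parameters (%d inert)\n",
              x$d, sum(x$region == "inert")))
  invisible(x)
}

#' Check a parameter vector (or matrix rows) against the bounds
#'
#' @param space a [parameter_space()].
#' @param params named numeric vector or a matrix with columns matching
#'   \code{space$names}.
#' @return Invisibly \code{TRUE}; errors naming the offending parameter
#'   otherwise.
#' @export
check_bounds <- function(space, params) {
  m <- if (is.matrix(params)) params else matrix(params, nrow = 1,
                                                 dimnames = list(NULL, names(params)))
  if (is.null(colnames(m))) {
    if (ncol(m) != space$d) stop("unnamed parameters must have length d")
    colnames(m) <- space$names
  }
  missing_p <- setdiff(space$names, colnames(m))
  if (length(missing_p))
    stop("missing parameter(s): ", paste(missing_p, collapse = ", "))
  for (nm in space$names) {
    bad <- which(m[, nm] < space$lower[nm] | m[, nm] > space$upper[nm])
    if (length(bad))
      stop(sprintf("parameter '%s' out of bounds [%g, %g] (row %d, value %g)",
                   nm, space$lower[nm], space$upper[nm], bad[1], m[bad[1], nm]))
  }
  invisible(TRUE)
}

#' Scale parameters to the unit cube and back
#'
#' Emulators operate on inputs scaled to \code{[0, 1]^d} via the parameter
#' space bounds.
#'
#' @param space a [parameter_space()].
#' @param X matrix of raw parameter rows (or a vector).
#' @return Matrix on the unit cube (or raw scale for `unscale_params`).
#' @export
scale_params <- function(space, X) {
  X <- as_param_matrix(space, X)
  sweep(sweep(X, 2, space$lower[colnames(X)], "-"),
        2, (space$upper - space$lower)[colnames(X)], "/")
}

#' @rdname scale_params
#' @export
unscale_params <- function(space, X) {
  X <- as_param_matrix(space, X)
  sweep(sweep(X, 2, (space$upper - space$lower)[colnames(X)], "*"),
        2, space$lower[colnames(X)], "+")
}

as_param_matrix <- function(space, X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1, dimnames = list(NULL, names(X)))
  if (is.null(colnames(X))) {
    if (ncol(X) != space$d) stop("unnamed parameter matrix must have d columns")
    colnames(X) <- space$names
  }
  X
}

#' Draw a space-filling population of parameter vectors
#'
#' Generates a GA-like first generation: a seeded Latin hypercube over the
#' parameter box, mimicking the random initial generation of a feature-based
#' multi-objective fit.
#'
#' @param space a [parameter_space()].
#' @param n number of individuals.
#' @param seed integer seed.
#' @return An \code{n x d} named matrix of raw-scale parameters.
#' @export
sample_population <- function(space, n, seed = 1L) {
  set.seed(as.integer(seed))
  U <- lhs::randomLHS(n, space$d)
  colnames(U) <- space$names
  unscale_params(space, U)
}
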