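#' Generate a synthetic GA-like population with simulated features
#'
#' Produces the study dataset used throughout the package: a seeded
#' space-filling population over the default (or supplied) parameter space,
#' evaluated through the stand-in simulator under the default protocols. The
#' result mirrors the structure of a first GA generation in feature-based
#' neuron fitting: a 31-dimensional input with 12 mechanistic and 19 inert
#' dimensions, ~20 output features per individual, structural missingness in
#' spike-dependent features, and a bi-modal inter-spike voltage feature.
#'
#' @param n number of individuals (default 1000, one GA generation).
#' @param d input dimension (default 31).
#' @param seed integer seed.
#' @param protocols list of [stimulus_protocol()].
#' @param dt Euler step (ms).
#' @param space optional [parameter_space()] overriding the default.
#' @return List with \code{space}, \code{params} (n x d matrix) and
#'   \code{features} (a \code{feature_table}).
#' @export
make_synthetic <- function(n = 1000L, d = 31L, seed = 1L,
                           protocols = default_protocols(), dt = 0.1,
                           space = NULL) {
  space <- space %||% default_parameter_space(d)
  params <- sample_population(space, n, seed = seed)
  features <- batch_evaluate(params, protocols, dt = dt)
  list(space = space, params = params, features = features)
}
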