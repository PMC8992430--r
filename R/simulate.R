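#' Define a current-injection stimulus protocol
#'
#' @param name protocol identifier, used to prefix feature names.
#' @param amplitude injected current (nA).
#' @param onset stimulus onset (ms).
#' @param duration stimulus duration (ms), \code{> 0}.
#' @param total_time total simulated time (ms), \code{>= onset + duration}.
#' @return An object of class \code{stimulus_protocol}.
#' @export
stimulus_protocol <- function(name, amplitude, onset, duration, total_time) {
  stop_if_not_scalar_num(amplitude, "amplitude")
  stop_if_not_scalar_num(duration, "duration")
  if (duration <= 0) stop("duration must be > 0")
  if (onset + duration > total_time)
    stop("onset + duration must not exceed total_time")
  structure(list(name = as.character(name), amplitude = amplitude,
                 onset = onset, duration = duration, total_time = total_time),
            class = "stimulus_protocol")
}

#' Default stimulus protocols
#'
#' Two protocols spanning the regimes of interest: a weak subthreshold step
#' (`IVf_3`, 0.04 nA for 1000 ms) probing passive membrane properties, and a
#' long suprathreshold step (`IDRest_7`, 0.27 nA for 2000 ms) that elicits
#' repetitive firing in part of the parameter box — the source of structural
#' missingness in spike-dependent features.
#'
#' @return Named list of [stimulus_protocol()] objects.
#' @export
default_protocols <- function() {
  list(
    IVf_3    = stimulus_protocol("IVf_3",    0.04, 250, 1000, 1500),
    IDRest_7 = stimulus_protocol("IDRest_7", 0.27, 250, 2000, 2500))
}

#' Simulate the stand-in neuron
#'
#' Deterministic adaptive-exponential integrate-and-fire dynamics under a
#' current step, integrated with fixed-step explicit Euler. A spike is
#' registered when the membrane reaches the cutoff \code{V_peak}; the voltage
#' sample at that step is recorded at \code{V_peak}, then the membrane resets
#' to \code{V_reset}, the adaptation current jumps by \code{b_w} and the cell
#' is clamped for \code{t_ref} ms. Parameters tagged inert in the space are
#' ignored, so perturbing them leaves the trace bit-identical.
#'
#' @param params named parameter vector (must contain the 12 mechanistic
#'   names; extra inert entries are allowed and ignored).
#' @param protocol a [stimulus_protocol()].
#' @param dt Euler step (ms), default 0.1.
#' @param space optional [parameter_space()]; when given, bounds are checked.
#' @return An object of class \code{voltage_trace}: list with \code{dt},
#'   \code{voltage} (mV, sampled at \code{0, dt, ...}), \code{spike_times}
#'   (ms, strictly increasing) and the protocol.
#' @export
simulate_neuron <- function(params, protocol, dt = 0.1, space = NULL) {
  if (dt <= 0) stop("dt must be > 0")
  if (!inherits(protocol, "stimulus_protocol")) stop("protocol must be a stimulus_protocol")
  if (!is.null(space)) check_bounds(space, params)
  need <- mechanistic_bounds()$name
  if (is.null(names(params))) {
    if (length(params) < length(need)) stop("parameter vector too short")
    names(params) <- c(need, sprintf("inert_%02d", seq_len(length(params) - length(need))))[seq_along(params)]
  }
  miss <- setdiff(need, names(params))
  if (length(miss)) stop("missing mechanistic parameter(s): ",
                         paste(miss, collapse = ", "))
  p <- as.list(params[need])
  out <- adex_integrate(p$C_m, p$g_L, p$E_L, p$V_T, p$Delta_T, p$a_w, p$b_w,
                        p$tau_w, p$V_reset, p$V_peak, p$t_ref, p$i_gain,
                        protocol$amplitude, protocol$onset, protocol$duration,
                        protocol$total_time, dt)
  structure(list(dt = dt, voltage = out$voltage,
                 spike_times = out$spike_times, protocol = protocol),
            class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("voltage_trace: %s, %d samples at dt = %g ms, %d spike(s)\n",
              x$protocol$name, length(x$voltage), x$dt, length(x$spike_times)))
  invisible(x)
}
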