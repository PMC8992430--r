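#' Extract electrophysiology features from a voltage trace
#'
#' Computes a fixed catalog of electrical features with explicit structural
#' missingness: a feature whose defining event did not occur (no spike, or
#' fewer than two spikes) has no value and is reported as \code{NA}. This is
#' structural missingness — nothing is imputed, and downstream emulation
#' treats the missingness indicator as a modeling target of its own.
#'
#' Feature catalog and missingness contract:
#' \itemize{
#'   \item never missing: \code{voltage_base} (mean over the
#'     \code{base_window} ms before onset), \code{steady_state_voltage_stimend}
#'     (mean over the final \code{steady_frac} of the stimulus),
#'     \code{voltage_after_stimulation} (mean over the last
#'     \code{after_window} ms of the trace), \code{spikecount};
#'   \item missing iff \code{spikecount == 0}: \code{peak_voltage},
#'     \code{AP_amplitude} (spike peak minus the pre-upswing minimum over the
#'     preceding 5 ms, averaged over spikes), \code{AHP_depth_absolute}
#'     (post-spike voltage minimum, averaged over spikes);
#'   \item missing iff \code{spikecount < 2}: \code{time_to_second_spike}
#'     (second spike time minus onset), \code{min_voltage_between_spikes}
#'     (minimum sampled voltage strictly between consecutive spikes),
#'     \code{AP2_AP1_peak_difference}, \code{mean_ISI}.
#' }
#' All windows are half-open \code{[start, end)} over 0-based samples at
#' times \code{i * dt}.
#'
#' @param trace a \code{voltage_trace} from [simulate_neuron()].
#' @param protocol the [stimulus_protocol()] the trace was produced for.
#' @param base_window,steady_frac,after_window window configuration (ms, ms,
#'   and a fraction of the stimulus duration).
#' @return Named numeric vector (a feature vector); missing features are
#'   \code{NA}. The missing set is \code{names(which(is.na(x)))}.
#' @export
extract_features <- function(trace, protocol = trace$protocol,
                             base_window = 100, steady_frac = 0.1,
                             after_window = 100) {
  v <- trace$voltage
  dt <- trace$dt
  tmax <- (length(v) - 1) * dt
  if (tmax + dt / 2 < protocol$total_time)
    stop("trace shorter than protocol total_time: trace/protocol mismatch")
  tt <- (seq_along(v) - 1) * dt
  win_mean <- function(t0, t1) {
    idx <- tt >= t0 & tt < t1
    if (!any(idx)) return(NA_real_)
    mean(v[idx])
  }
  onset <- protocol$onset
  stim_end <- onset + protocol$duration
  sp <- trace$spike_times
  sp <- sp[sp >= onset & sp < stim_end]
  nsp <- length(sp)

  out <- c(
    voltage_base = win_mean(max(0, onset - base_window), onset),
    steady_state_voltage_stimend =
      win_mean(stim_end - steady_frac * protocol$duration, stim_end),
    voltage_after_stimulation =
      win_mean(protocol$total_time - after_window, protocol$total_time),
    spikecount = as.numeric(nsp),
    peak_voltage = NA_real_, AP_amplitude = NA_real_,
    AHP_depth_absolute = NA_real_,
    time_to_second_spike = NA_real_, min_voltage_between_spikes = NA_real_,
    AP2_AP1_peak_difference = NA_real_, mean_ISI = NA_real_)

  spike_idx <- as.integer(round(sp / dt)) + 1L
  peak_v <- v[spike_idx]

  if (nsp >= 1) {
    out["peak_voltage"] <- max(peak_v)
    amp <- vapply(seq_len(nsp), function(k) {
      i0 <- max(1L, spike_idx[k] - as.integer(round(5 / dt)))
      peak_v[k] - min(v[i0:(spike_idx[k] - 1L)])
    }, numeric(1))
    out["AP_amplitude"] <- mean(amp)
    ahp <- vapply(seq_len(nsp), function(k) {
      i1 <- if (k < nsp) spike_idx[k + 1L] - 1L else
        min(length(v), spike_idx[k] + as.integer(round(50 / dt)))
      min(v[(spike_idx[k] + 1L):i1])
    }, numeric(1))
    out["AHP_depth_absolute"] <- mean(ahp)
  }
  if (nsp >= 2) {
    out["time_to_second_spike"] <- sp[2] - onset
    between <- unlist(lapply(seq_len(nsp - 1L), function(k) {
      lo <- spike_idx[k] + 1L
      hi <- spike_idx[k + 1L] - 1L
      if (hi >= lo) v[lo:hi] else numeric()
    }))
    out["min_voltage_between_spikes"] <- min(between)
    out["AP2_AP1_peak_difference"] <- peak_v[2] - peak_v[1]
    out["mean_ISI"] <- mean(diff(sp))
  }
  out
}

#' Names of features that can be structurally missing
#'
#' @return Named list: \code{spike} (missing iff no spike) and \code{isi}
#'   (missing iff fewer than two spikes).
#' @export
missingness_classes <- function() {
  list(spike = c("peak_voltage", "AP_amplitude", "AHP_depth_absolute"),
       isi = c("time_to_second_spike", "min_voltage_between_spikes",
               "AP2_AP1_peak_difference", "mean_ISI"))
}

#' Evaluate a population through the simulator
#'
#' Runs every row of a parameter matrix through [simulate_neuron()] under each
#' protocol and assembles a feature table: one row per individual, columns
#' named \code{<protocol>.<feature>}, missing values encoded as \code{NA}.
#'
#' @param population matrix of parameter rows (named columns).
#' @param protocols list of [stimulus_protocol()] (default [default_protocols()]).
#' @param dt Euler step (ms).
#' @param space optional [parameter_space()] for bounds checking.
#' @param ... window configuration forwarded to [extract_features()].
#' @return A \code{data.frame} of class \code{feature_table}; attribute
#'   \code{missing_counts} holds per-feature missing-value counts.
#' @export
batch_evaluate <- function(population, protocols = default_protocols(),
                           dt = 0.1, space = NULL, ...) {
  if (!is.matrix(population)) population <- t(as.matrix(population))
  if (!is.null(space)) check_bounds(space, population)
  rows <- lapply(seq_len(nrow(population)), function(i) {
    fv <- tryCatch(
      unlist(lapply(unname(protocols), function(pr) {
        f <- extract_features(simulate_neuron(population[i, ], pr, dt = dt), pr, ...)
        stats::setNames(f, paste(pr$name, names(f), sep = "."))
      })),
      error = function(e) stop(sprintf("row %d: %s", i, conditionMessage(e)),
                               call. = FALSE))
    fv
  })
  tab <- as.data.frame(do.call(rbind, rows))
  attr(tab, "missing_counts") <- colSums(is.na(tab))
  class(tab) <- c("feature_table", class(tab))
  tab
}

#' Per-feature missing-value counts of a feature table
#'
#' @param tab a feature table from [batch_evaluate()] or [read_feature_table()].
#' @return Named integer vector of missing counts per feature column.
#' @export
missing_counts <- function(tab) colSums(is.na(tab))
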