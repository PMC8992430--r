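# Shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# small synthetic GA-like population with simulated features (d = 31)
fix_synth <- function() fixture("synth300", function() {
  make_synthetic(n = 300, d = 31, seed = 42)
})

# reference individual and its self-consistent targets
fix_targets <- function() fixture("targets", function() {
  sp <- default_parameter_space(31)
  set.seed(99)
  ref <- sp$lower + stats::runif(sp$d) * (sp$upper - sp$lower)
  names(ref) <- sp$names
  list(space = sp, ref = ref, targets = targets_from_params(ref))
})

# a hand-built voltage trace with spikes at chosen times (for feature tests)
make_trace <- function(spike_times, dt = 0.1, total = 1500, onset = 250,
                       duration = 1000, base = -70, peak = 20) {
  n <- total / dt + 1
  v <- rep(base, n)
  tt <- (seq_len(n) - 1) * dt
  v[tt >= onset & tt < onset + duration] <- base + 5
  for (s in spike_times) {
    i <- round(s / dt) + 1
    v[i] <- peak
    v[i - (5:1)] <- base - 2 + (1:5)  # pre-spike upswing from a local dip
    v[i + 1] <- -65                   # post-spike reset sample
  }
  structure(list(dt = dt, voltage = v, spike_times = spike_times,
                 protocol = stimulus_protocol("T", 0.1, onset, duration,
                                              total)),
            class = "voltage_trace")
}

rmse <- function(a, b) sqrt(mean((a - b)^2))
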