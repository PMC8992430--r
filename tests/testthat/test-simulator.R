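quiet_params <- function() {
  sp <- default_parameter_space(31)
  p <- sample_population(sp, 1, seed = 5)[1, ]
  # adaptation off, threshold far above rest: pure leaky membrane
  p["a_w"] <- 0; p["b_w"] <- 0; p["V_T"] <- -40; p["Delta_T"] <- 0.5
  p["E_L"] <- -80; p["g_L"] <- 0.008; p["i_gain"] <- 1; p["C_m"] <- 0.1
  p
}

test_that("zero stimulus leaves the cell at its leak reversal", {
  p <- quiet_params()
  pr <- stimulus_protocol("null", 0, 250, 1000, 1500)
  tr <- simulate_neuron(p, pr)
  expect_length(tr$spike_times, 0)
  expect_lt(abs(tail(tr$voltage, 1) - p["E_L"]), 0.5)
})

test_that("subthreshold steady state matches the leak closed form E_L + I/g_L", {
  p <- quiet_params()
  pr <- default_protocols()$IVf_3
  f <- extract_features(simulate_neuron(p, pr), pr)
  expect_lt(abs(f["steady_state_voltage_stimend"] -
                  (p["E_L"] + pr$amplitude / p["g_L"])), 0.5)
})

test_that("simulation is deterministic", {
  sp <- default_parameter_space(31)
  p <- sample_population(sp, 1, seed = 11)[1, ]
  a <- simulate_neuron(p, default_protocols()$IDRest_7)
  b <- simulate_neuron(p, default_protocols()$IDRest_7)
  expect_identical(a$voltage, b$voltage)
  expect_identical(a$spike_times, b$spike_times)
})

test_that("inert parameters leave the trace bit-identical", {
  sp <- default_parameter_space(31)
  p <- sample_population(sp, 1, seed = 12)[1, ]
  base <- simulate_neuron(p, default_protocols()$IDRest_7)
  for (nm in c("inert_01", "inert_10", "inert_19")) {
    q <- p
    q[nm] <- if (p[nm] < 0.5) 0.99 else 0.01
    alt <- simulate_neuron(q, default_protocols()$IDRest_7)
    expect_identical(base$voltage, alt$voltage)
    expect_identical(base$spike_times, alt$spike_times)
  }
})

test_that("out-of-bounds parameters raise an error naming the parameter", {
  sp <- default_parameter_space(31)
  p <- sample_population(sp, 1, seed = 13)[1, ]
  p["tau_w"] <- 1e6
  expect_error(simulate_neuron(p, default_protocols()$IVf_3, space = sp),
               "tau_w")
})

test_that("spike events reach the cutoff and reset below it", {
  sp <- default_parameter_space(31)
  pop <- sample_population(sp, 40, seed = 14)
  found <- FALSE
  for (i in seq_len(nrow(pop))) {
    tr <- simulate_neuron(pop[i, ], default_protocols()$IDRest_7)
    if (length(tr$spike_times) >= 2) {
      found <- TRUE
      idx <- round(tr$spike_times / tr$dt) + 1
      expect_equal(tr$voltage[idx],
                   rep(unname(pop[i, "V_peak"]), length(idx)))
      expect_true(all(diff(tr$spike_times) > 0))
      break
    }
  }
  expect_true(found)
})

test_that("subthreshold response is affine in stimulus amplitude", {
  p <- quiet_params()
  amps <- seq(-0.05, 0.05, length.out = 5)
  ss <- vapply(amps, function(a) {
    pr <- stimulus_protocol("sweep", a, 250, 1000, 1500)
    extract_features(simulate_neuron(p, pr), pr)["steady_state_voltage_stimend"]
  }, numeric(1))
  r2 <- summary(stats::lm(ss ~ amps))$r.squared
  expect_gt(r2, 0.999)
})

test_that("halving the step changes features by < 1% or < 0.5 mV", {
  # Euler error is first order, so the convergence check halves from a step
  # already inside the asymptotic regime (0.05 ms -> 0.025 ms)
  sp <- default_parameter_space(31)
  pop <- sample_population(sp, 4, seed = 15)
  for (i in seq_len(nrow(pop))) {
    pr <- default_protocols()$IDRest_7
    f1 <- extract_features(simulate_neuron(pop[i, ], pr, dt = 0.05), pr)
    f2 <- extract_features(simulate_neuron(pop[i, ], pr, dt = 0.025), pr)
    both <- !is.na(f1) & !is.na(f2)
    dif <- abs(f1[both] - f2[both])
    rel <- dif / pmax(abs(f1[both]), 1e-12)
    expect_true(all(rel < 0.01 | dif < 0.5),
                info = paste("row", i, ":",
                             paste(names(dif)[!(rel < 0.01 | dif < 0.5)],
                                   collapse = ", ")))
  }
})
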