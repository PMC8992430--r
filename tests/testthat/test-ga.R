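test_that("ga_step is seeded, elitist and respects zero-rate operators", {
  sp <- default_parameter_space(31)
  pop <- sample_population(sp, 40, seed = 1)
  scores <- seq_len(40) / 10
  cfg <- ga_config(pop_size = 40, elitism = 2, seed = 1)
  set.seed(5); a <- ga_step(pop, scores, sp, cfg)
  set.seed(5); b <- ga_step(pop, scores, sp, cfg)
  expect_identical(a, b)
  expect_equal(a[1, ], pop[1, ])       # elite copied unchanged
  expect_equal(a[2, ], pop[2, ])
  # no crossover, no mutation: every offspring is a copy of a parent
  cfg0 <- ga_config(pop_size = 40, cx_rate = 0, mut_rate = 0)
  set.seed(6); kids <- ga_step(pop, scores, sp, cfg0)
  in_pop <- apply(kids, 1, function(k)
    any(apply(pop, 1, function(p) all(p == k))))
  expect_true(all(in_pop))
  expect_silent(check_bounds(sp, a))
  expect_error(ga_step(pop, c(NA, scores[-1]), sp, cfg), "scored")
})

test_that("config invariants are enforced", {
  expect_error(ga_config(pop_size = 2, elitism = 2), "elitism")
  expect_error(ga_config(cx_rate = 1.5), "rates")
  expect_error(strategy_config(train_frac = 1), "train_frac")
})

test_that("drift check flags a constant emulator and trusts a perfect one", {
  set.seed(9)
  sim <- data.frame(f1 = rnorm(40), f2 = rnorm(40, 5, 2))
  sds <- c(f1 = sd(sim$f1), f2 = sd(sim$f2))
  same <- drift_check(sim, sim, sds, threshold = 0.5)
  expect_equal(unname(same$rmse_ratio), c(0, 0))
  expect_false(same$refit)
  const <- data.frame(f1 = rep(mean(sim$f1), 40), f2 = rep(mean(sim$f2), 40))
  dc <- drift_check(const, sim, sds, threshold = 0.5)
  expect_equal(unname(dc$rmse_ratio), rep(sqrt(39 / 40), 2), tolerance = 1e-10)
  expect_true(dc$refit)
  expect_false(drift_check(const, sim, sds, threshold = Inf)$refit)
  # all-missing feature skipped
  sim$f3 <- NA_real_
  const$f3 <- 1
  sds <- c(sds, f3 = 1)
  expect_true(is.na(drift_check(const, sim, sds)$rmse_ratio["f3"]))
})

test_that("split mode accounts calls exactly at the train fraction", {
  fx <- fix_targets()
  ga <- ga_config(pop_size = 100, generations = 2, seed = 3)
  run <- run_moo(fx$space, fx$targets, ga, strategy_config("split"),
                 emulator_specs = list(emulator_spec("lm")), seed = 3)
  expect_equal(run$history$sim_calls, c(80, 80))
  expect_equal(run$history$emu_calls, c(20, 20))
  expect_equal(run$history$sim_calls + run$history$emu_calls, c(100, 100))
})

test_that("screen mode simulates only the kept fraction after generation one", {
  fx <- fix_targets()
  ga <- ga_config(pop_size = 100, generations = 3, seed = 4)
  run <- run_moo(fx$space, fx$targets, ga,
                 strategy_config("screen", keep_frac = 0.3),
                 emulator_specs = list(emulator_spec("lm")), seed = 4)
  h <- run$history
  expect_equal(h$sim_calls[1], 100)
  expect_equal(h$sim_calls[2:3], c(30, 30))
  expect_equal(h$emu_calls[2:3], c(100, 100))
})

test_that("emulate_gens refreshes on schedule and logs drift", {
  fx <- fix_targets()
  ga <- ga_config(pop_size = 80, generations = 4, seed = 5)
  run <- run_moo(fx$space, fx$targets, ga,
                 strategy_config("emulate_gens", refresh_every = 3,
                                 drift_n = 15, drift_threshold = Inf),
                 emulator_specs = list(emulator_spec("lm")), seed = 5)
  h <- run$history
  expect_equal(h$sim_calls[1], 80)              # refresh generation
  expect_equal(h$sim_calls[2:3], c(15, 15))     # drift samples only
  expect_equal(h$sim_calls[4], 80)              # periodic refresh
  expect_true(all(is.finite(h$drift_rmse[2:3])))
  expect_false(any(h$refit))
})

test_that("elitism never lets the best score regress under full simulation", {
  fx <- fix_targets()
  ga <- ga_config(pop_size = 60, generations = 5, seed = 6)
  run <- run_moo(fx$space, fx$targets, ga, strategy_config("full_sim"),
                 seed = 6)
  expect_true(all(diff(run$history$best_score) <= 1e-9))
})
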