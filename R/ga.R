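#' Genetic-algorithm configuration
#'
#' Standard real-coded GA operators: tournament selection (minimizing the
#' global score), blend (BLX-alpha) crossover, per-gene Gaussian mutation
#' with bound clipping, and elitism.
#'
#' @param pop_size individuals per generation (default 1000).
#' @param generations number of generations.
#' @param tournament tournament size (default 4).
#' @param cx_rate crossover probability per offspring (default 0.9).
#' @param cx_alpha blend-crossover expansion factor (default 0.5).
#' @param mut_rate per-gene mutation probability (default \code{NULL} =
#'   \code{1/d}, resolved at run time).
#' @param mut_sd_frac mutation SD as a fraction of each parameter's range
#'   (default 0.1).
#' @param mut_anneal geometric decay of the mutation SD per generation
#'   (default 0.90): early generations explore, late generations fine-tune.
#'   Set to 1 for a constant mutation scale.
#' @param elitism number of best individuals copied unchanged (default 1).
#' @param seed integer seed.
#' @return List of class \code{ga_config}.
#' @export
ga_config <- function(pop_size = 1000L, generations = 30L, tournament = 4L,
                      cx_rate = 0.9, cx_alpha = 0.5, mut_rate = NULL,
                      mut_sd_frac = 0.1, mut_anneal = 0.90, elitism = 1L,
                      seed = 1L) {
  if (pop_size < 2 * elitism) stop("pop_size must be >= 2 * elitism")
  for (r in c(cx_rate, mut_rate %||% 0.5))
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 tournament = as.integer(tournament), cx_rate = cx_rate,
                 cx_alpha = cx_alpha, mut_rate = mut_rate,
                 mut_sd_frac = mut_sd_frac, mut_anneal = mut_anneal,
                 elitism = as.integer(elitism), seed = as.integer(seed)),
            class = "ga_config")
}

#' Emulation-strategy configuration for the GA
#'
#' Four execution modes: \code{"full_sim"} (every individual simulated),
#' \code{"split"} (each generation a seeded train fraction is simulated,
#' per-feature emulators are fitted on it and the remaining individuals'
#' features are predicted — the 80/20 strategy), \code{"emulate_gens"}
#' (refresh generations are fully simulated and used to refit; intermediate
#' generations are fully emulated except a simulated drift-check sample) and
#' \code{"screen"} (the emulator scores all offspring; only the best
#' keep-fraction is simulated, the rest are discarded unsimulated).
#'
#' @param mode one of \code{"full_sim"}, \code{"split"},
#'   \code{"emulate_gens"}, \code{"screen"}.
#' @param train_frac fraction of each generation simulated for emulator
#'   training in \code{"split"} mode (default 0.8).
#' @param refresh_every full-simulation refresh period (generations) in
#'   \code{"emulate_gens"} mode.
#' @param drift_n drift-check sample size per emulated generation.
#' @param drift_threshold refit when any feature's drift RMSE exceeds this
#'   multiple of the feature's current-generation SD (default 0.5 — the
#'   "RMSE below half an SD" accuracy bar).
#' @param keep_frac fraction of offspring simulated in \code{"screen"} mode.
#' @return List of class \code{strategy_config}.
#' @export
strategy_config <- function(mode = c("full_sim", "split", "emulate_gens",
                                     "screen"),
                            train_frac = 0.8, refresh_every = 5L,
                            drift_n = 20L, drift_threshold = 0.5,
                            keep_frac = 0.3) {
  mode <- match.arg(mode)
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0, 1)")
  if (refresh_every < 1) stop("refresh_every must be >= 1")
  structure(list(mode = mode, train_frac = train_frac,
                 refresh_every = as.integer(refresh_every),
                 drift_n = as.integer(drift_n),
                 drift_threshold = drift_threshold, keep_frac = keep_frac),
            class = "strategy_config")
}

#' One GA step: produce offspring from a scored population
#'
#' Elitism copies the best (lowest-score) individuals unchanged; the
#' remaining offspring come from tournament selection followed, with
#' probability \code{cx_rate}, by per-gene blend crossover, then per-gene
#' Gaussian mutation and clipping to the parameter bounds. Selection
#' minimizes the score (the global score is a distance; lower is better).
#' Reproducible given the R RNG state.
#'
#' @param params matrix of parameter rows (the current generation).
#' @param scores numeric global scores, no missing values.
#' @param space a [parameter_space()].
#' @param config a [ga_config()].
#' @param mut_scale multiplier on the mutation SD (used by [run_moo()] to
#'   anneal mutation over generations; default 1).
#' @return Matrix of \code{config$pop_size} offspring rows.
#' @export
ga_step <- function(params, scores, space, config, mut_scale = 1) {
  if (anyNA(scores)) stop("all individuals must be scored before selection")
  n <- nrow(params)
  d <- ncol(params)
  mut_rate <- config$mut_rate %||% (1 / d)
  lo <- space$lower[colnames(params)]
  hi <- space$upper[colnames(params)]
  rng <- hi - lo
  pick <- function() {
    cand <- sample.int(n, config$tournament, replace = TRUE)
    cand[which.min(scores[cand])]
  }
  n_child <- config$pop_size - config$elitism
  kids <- matrix(NA_real_, n_child, d, dimnames = list(NULL, colnames(params)))
  for (i in seq_len(n_child)) {
    p1 <- params[pick(), ]
    if (stats::runif(1) < config$cx_rate) {
      p2 <- params[pick(), ]
      lo_g <- pmin(p1, p2)
      hi_g <- pmax(p1, p2)
      span <- hi_g - lo_g
      kid <- stats::runif(d, lo_g - config$cx_alpha * span,
                          hi_g + config$cx_alpha * span)
    } else kid <- p1
    mut <- stats::runif(d) < mut_rate
    if (any(mut))
      kid[mut] <- kid[mut] + stats::rnorm(sum(mut), 0,
                                          mut_scale * config$mut_sd_frac *
                                            rng[mut])
    kids[i, ] <- clamp(kid, lo, hi)
  }
  elite <- params[utils::head(order(scores), config$elitism), , drop = FALSE]
  rbind(elite, kids)
}

#' Drift check: does the emulator still mimic the simulator?
#'
#' Compares emulated and simulated feature values on a small sample of the
#' current generation. Each feature's RMSE is expressed in units of that
#' feature's current-generation SD; the refit flag raises when any ratio
#' exceeds the threshold. Features missing for every sampled individual are
#' skipped.
#'
#' @param emulated data.frame/matrix of emulator-predicted features (sample
#'   rows).
#' @param simulated matching simulated features.
#' @param feature_sds named per-feature SDs of the current generation.
#' @param threshold refit threshold in SD units (default 0.5;
#'   \code{Inf} = never refit).
#' @return List with \code{rmse_ratio} (named vector, \code{NA} for skipped
#'   features) and logical \code{refit}.
#' @export
drift_check <- function(emulated, simulated, feature_sds, threshold = 0.5) {
  feats <- intersect(colnames(simulated), names(feature_sds))
  ratio <- sapply(feats, function(f) {
    e <- emulated[[f]]
    s <- simulated[[f]]
    ok <- !is.na(e) & !is.na(s)
    if (!any(ok)) return(NA_real_)
    sqrt(mean((e[ok] - s[ok])^2)) / feature_sds[[f]]
  })
  list(rmse_ratio = ratio,
       refit = isTRUE(any(ratio > threshold, na.rm = TRUE)))
}

# fit one emulator per feature on simulated rows; candidates selected by a
# seeded internal validation split when more than one spec is given
fit_feature_emulators <- function(X, feats, feature_names, specs, space,
                                  seed, min_rows) {
  ems <- list()
  for (f in feature_names) {
    y <- feats[[f]]
    ok <- !is.na(y)
    if (sum(ok) < min_rows) next
    if (stats::sd(y[ok]) == 0) {
      ems[[f]] <- constant_emulator(y[ok][1])
      next
    }
    Xo <- X[ok, , drop = FALSE]
    yo <- y[ok]
    spec <- specs[[1]]
    if (length(specs) > 1) {
      set.seed(derive_seed(seed, 17L))
      idx <- sample.int(length(yo), max(2, round(0.25 * length(yo))))
      rmse <- vapply(specs, function(sp) {
        tryCatch({
          fit <- fit_emulator(sp, Xo[-idx, , drop = FALSE], yo[-idx],
                              space = space, seed = seed)
          sqrt(mean((stats::predict(fit, Xo[idx, , drop = FALSE])$mean -
                       yo[idx])^2))
        }, error = function(e) Inf)
      }, numeric(1))
      spec <- specs[[which.min(rmse)]]
    }
    ems[[f]] <- tryCatch(
      fit_emulator(spec, Xo, yo, space = space, seed = seed),
      error = function(e) NULL)
  }
  ems
}

predict_feature_table <- function(ems, X, feature_names) {
  out <- as.data.frame(matrix(NA_real_, nrow(X), length(feature_names),
                              dimnames = list(NULL, feature_names)))
  for (f in feature_names)
    if (!is.null(ems[[f]]))
      out[[f]] <- stats::predict(ems[[f]], X)$mean
  out
}

#' Run the surrogate-assisted multi-objective optimization
#'
#' Evolves a population toward the experimental targets under one of the
#' four execution strategies, logging per generation the best and median
#' global score and the exact simulator/emulator call counts (plus the drift
#' RMSE when checked). On emulator fit failure mid-run the affected
#' generation falls back to full simulation and the event is logged.
#' Emulator-evaluated individuals are never used as emulator training data.
#'
#' @param space a [parameter_space()].
#' @param targets a [target_stats()] table; feature names must match the
#'   prefixed names produced by [batch_evaluate()] under \code{protocols}.
#' @param ga a [ga_config()].
#' @param strategy a [strategy_config()].
#' @param emulator_specs list of candidate [emulator_spec()]s for per-feature
#'   emulation (default a single GPllm spec); ignored in \code{"full_sim"}.
#' @param protocols list of [stimulus_protocol()].
#' @param missing_penalty score for a missing feature (SD units).
#' @param dt Euler step (ms).
#' @param seed integer master seed (fans out via [derive_seed()]).
#' @return List of class \code{moo_run}: \code{history} (data.frame with
#'   columns generation, best_score, median_score, sim_calls, emu_calls,
#'   drift_rmse, refit), \code{best_params}, \code{best_score},
#'   \code{population}, \code{scores}, and the configs.
#' @export
run_moo <- function(space, targets, ga, strategy = strategy_config("full_sim"),
                    emulator_specs = list(emulator_spec("gpllm")),
                    protocols = default_protocols(), missing_penalty = 20,
                    dt = 0.1, seed = 1L) {
  if (inherits(emulator_specs, "emulator_spec"))
    emulator_specs <- list(emulator_specs)
  mode <- strategy$mode
  feature_names <- targets$feature
  min_rows <- space$d + 2L

  pop <- sample_population(space, ga$pop_size, seed = derive_seed(seed, 1L))
  history <- NULL
  best <- list(score = Inf, params = NULL)
  ems <- NULL          # current emulator set (emulate_gens / screen)
  hist_row <- function(g, scores, sim, emu, drift = NA_real_, refit = FALSE)
    data.frame(generation = g, best_score = min(scores),
               median_score = stats::median(scores), sim_calls = sim,
               emu_calls = emu, drift_rmse = drift, refit = refit)

  for (g in seq_len(ga$generations)) {
    gseed <- derive_seed(seed, 100L + g)
    sim_calls <- 0L
    emu_calls <- 0L
    drift_rmse <- NA_real_
    refit_flag <- FALSE
    n <- nrow(pop)

    if (mode == "full_sim") {
      feats <- batch_evaluate(pop, protocols, dt = dt)
      sim_calls <- n
    } else if (mode == "split") {
      set.seed(gseed)
      n_train <- round(strategy$train_frac * n)
      idx <- sample.int(n, n_train)
      feats_tr <- batch_evaluate(pop[idx, , drop = FALSE], protocols, dt = dt)
      sim_calls <- n_train
      ems_g <- fit_feature_emulators(pop[idx, , drop = FALSE], feats_tr,
                                     feature_names, emulator_specs, space,
                                     gseed, min_rows)
      rest <- setdiff(seq_len(n), idx)
      if (length(ems_g) < length(feature_names)) {
        # fallback: features without a usable emulator are simulated
        feats_rest <- batch_evaluate(pop[rest, , drop = FALSE], protocols,
                                     dt = dt)
        sim_calls <- n
      } else {
        feats_rest <- predict_feature_table(ems_g, pop[rest, , drop = FALSE],
                                            feature_names)
        emu_calls <- length(rest)
      }
      feats <- as.data.frame(matrix(NA_real_, n,
                                    ncol(feats_tr),
                                    dimnames = list(NULL, colnames(feats_tr))))
      feats[idx, ] <- feats_tr
      feats[rest, colnames(feats_rest)] <- feats_rest
    } else if (mode == "emulate_gens") {
      due <- is.null(ems) || ((g - 1L) %% strategy$refresh_every == 0L)
      if (due) {
        feats <- batch_evaluate(pop, protocols, dt = dt)
        sim_calls <- n
        ems <- fit_feature_emulators(pop, feats, feature_names,
                                     emulator_specs, space, gseed, min_rows)
        if (length(ems) == 0) ems <- NULL
      } else {
        feats <- predict_feature_table(ems, pop, feature_names)
        emu_calls <- n
        set.seed(gseed)
        chk <- sample.int(n, min(strategy$drift_n, n))
        sim_chk <- batch_evaluate(pop[chk, , drop = FALSE], protocols,
                                  dt = dt)
        sim_calls <- length(chk)
        sds <- vapply(feature_names, function(f)
          stats::sd(feats[[f]], na.rm = TRUE), numeric(1))
        dc <- drift_check(feats[chk, , drop = FALSE], sim_chk,
                          sds, strategy$drift_threshold)
        drift_rmse <- max(dc$rmse_ratio, na.rm = TRUE)
        if (dc$refit) {
          refit_flag <- TRUE
          feats <- batch_evaluate(pop, protocols, dt = dt)
          sim_calls <- n + length(chk)
          emu_calls <- 0L
          ems <- fit_feature_emulators(pop, feats, feature_names,
                                       emulator_specs, space, gseed, min_rows)
        } else {
          feats[chk, colnames(sim_chk)] <- sim_chk
          emu_calls <- n - length(chk)   # emulated values actually kept
        }
      }
    } else { # screen
      if (is.null(ems)) {
        feats <- batch_evaluate(pop, protocols, dt = dt)
        sim_calls <- n
      } else {
        pred <- predict_feature_table(ems, pop, feature_names)
        emu_calls <- n
        pred_scores <- score_table(pred, targets, missing_penalty)
        keep <- utils::head(order(pred_scores),
                            max(2L, round(strategy$keep_frac * n)))
        pop <- pop[keep, , drop = FALSE]
        n <- nrow(pop)
        feats <- batch_evaluate(pop, protocols, dt = dt)
        sim_calls <- n
      }
      ems_new <- fit_feature_emulators(pop, feats, feature_names,
                                       emulator_specs, space, gseed, min_rows)
      # a kept set smaller than the training minimum yields no new emulators;
      # the previous generation's emulators stay in service
      if (is.null(ems)) ems <- if (length(ems_new)) ems_new else NULL
      else if (length(ems_new)) ems[names(ems_new)] <- ems_new
    }

    scores <- score_table(feats, targets, missing_penalty)
    # the run-level best tracks simulator-verified individuals only, so an
    # optimistic emulated score can never be reported as the optimum
    sim_rows <- if (mode == "full_sim" || sim_calls >= n) seq_len(n)
                else if (mode == "split") idx else integer()
    if (length(sim_rows) && min(scores[sim_rows]) < best$score) {
      b <- sim_rows[which.min(scores[sim_rows])]
      best$score <- scores[b]
      best$params <- pop[b, ]
    }
    history <- rbind(history, hist_row(g, scores, sim_calls, emu_calls,
                                       drift_rmse, refit_flag))
    if (g < ga$generations) {
      set.seed(derive_seed(seed, 200L + g))
      pop <- ga_step(pop, scores, space, ga,
                     mut_scale = (ga$mut_anneal %||% 1)^(g - 1L))
    }
  }
  structure(list(history = history, best_params = best$params,
                 best_score = best$score, population = pop, scores = scores,
                 ga = ga, strategy = strategy, seed = seed),
            class = "moo_run")
}

#' @export
print.moo_run <- function(x, ...) {
  h <- x$history
  cat(sprintf("moo_run (%s): %d generations, best score %.4f\n",
              x$strategy$mode, nrow(h), x$best_score))
  cat(sprintf("  simulator calls %d, emulator predictions %d\n",
              sum(h$sim_calls), sum(h$emu_calls)))
  invisible(x)
}
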