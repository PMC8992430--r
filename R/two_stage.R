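#' Forest configuration for the missingness classifier
#'
#' @param n_trees number of trees (default 1200, the tuned value reported
#'   for an action-potential amplitude classifier).
#' @param mtry candidate features per split (default 15).
#' @param seed integer seed.
#' @return List of class \code{forest_config}.
#' @export
forest_config <- function(n_trees = 1200L, mtry = 15L, seed = 1L) {
  if (n_trees < 1) stop("n_trees must be >= 1")
  structure(list(n_trees = as.integer(n_trees), mtry = as.integer(mtry),
                 seed = as.integer(seed)), class = "forest_config")
}

#' Fit the two-stage missingness classifier + value regressor
#'
#' For a feature that is structurally missing in some simulations, fits (1) a
#' random-forest classifier predicting whether the feature will be observed,
#' trained on the binary missingness indicator over all rows, and (2) a value
#' emulator trained on the observed rows only. At prediction time, rows
#' classified missing receive the missing token (\code{NA}) without a
#' regressor call.
#'
#' When the minority missingness class has fewer than \code{skip_below}
#' training rows, no classifier is fitted (skip-classifier mode) and every
#' row is passed to the regressor — the right behaviour for features that
#' are almost always observed.
#'
#' @param X input matrix (rows = individuals).
#' @param y feature values with \code{NA} marking structural missingness.
#' @param clf a [forest_config()]; set \code{mtry} to \code{NULL} to use the
#'   forest default.
#' @param reg an [emulator_spec()] for the value regressor.
#' @param threshold decision threshold on the forest's observed-class
#'   probability (default 0.5); lowering it predicts "observed" more often,
#'   raising sensitivity.
#' @param tune if \code{TRUE}, tunes \code{n_trees} over
#'   \code{c(500, 800, 1100, 1200)} and \code{mtry} over
#'   \code{c(ceiling(sqrt(d)), 15, 24)} by out-of-bag accuracy before the
#'   final fit.
#' @param skip_below minority-class size below which the classifier is
#'   skipped (default 10).
#' @param space optional [parameter_space()] passed to the regressor.
#' @param seed integer seed.
#' @return Object of class \code{two_stage_emulator}.
#' @export
fit_two_stage <- function(X, y, clf = forest_config(),
                          reg = emulator_spec("gpllm"), threshold = 0.5,
                          tune = FALSE, skip_below = 10L, space = NULL,
                          seed = 1L) {
  X <- as.matrix(X)
  obs <- !is.na(y)
  n_min <- min(sum(obs), sum(!obs))
  classifier <- NULL
  tuned <- NULL
  if (n_min >= skip_below) {
    lab <- factor(ifelse(obs, "observed", "missing"),
                  levels = c("observed", "missing"))
    d <- ncol(X)
    if (tune) {
      grid <- expand.grid(n_trees = c(500L, 800L, 1100L, 1200L),
                          mtry = unique(pmin(c(ceiling(sqrt(d)), 15L, 24L), d)))
      oob <- vapply(seq_len(nrow(grid)), function(i) {
        set.seed(derive_seed(seed, 30L + i))
        f <- randomForest::randomForest(X, lab, ntree = grid$n_trees[i],
                                        mtry = grid$mtry[i])
        1 - f$err.rate[grid$n_trees[i], "OOB"]
      }, numeric(1))
      bi <- which.max(oob)
      clf <- forest_config(grid$n_trees[bi], grid$mtry[bi], seed = clf$seed)
      tuned <- data.frame(grid, oob_accuracy = oob)
    }
    set.seed(derive_seed(seed, 2L))
    classifier <- randomForest::randomForest(
      X, lab, ntree = clf$n_trees,
      mtry = min(clf$mtry %||% max(floor(sqrt(d)), 1L), d),
      importance = TRUE)
  }
  if (sum(obs) < 2) stop("too few observed rows to train the regressor")
  regressor <- fit_emulator(reg, X[obs, , drop = FALSE], y[obs],
                            space = space, seed = derive_seed(seed, 3L))
  structure(list(classifier = classifier, regressor = regressor,
                 threshold = threshold, clf_config = clf, tuned = tuned,
                 skip_classifier = is.null(classifier)),
            class = "two_stage_emulator")
}

#' Predict through the two-stage pipeline
#'
#' @param object a \code{two_stage_emulator}.
#' @param Xnew matrix of prediction inputs.
#' @param ... forwarded to the regressor's \code{predict()}.
#' @return \code{data.frame} with \code{prob_observed}, logical
#'   \code{predicted_missing}, and \code{value} (\code{NA} for rows
#'   classified missing — the missing token; no regressor call is made for
#'   them).
#' @export
predict.two_stage_emulator <- function(object, Xnew, ...) {
  Xnew <- as.matrix(Xnew)
  n <- nrow(Xnew)
  if (object$skip_classifier) {
    p_obs <- rep(1, n)
    pred_missing <- rep(FALSE, n)
  } else {
    p_obs <- stats::predict(object$classifier, Xnew,
                            type = "prob")[, "observed"]
    pred_missing <- p_obs < object$threshold
  }
  value <- rep(NA_real_, n)
  if (any(!pred_missing))
    value[!pred_missing] <-
      stats::predict(object$regressor, Xnew[!pred_missing, , drop = FALSE],
                     ...)$mean
  data.frame(prob_observed = as.numeric(p_obs),
             predicted_missing = pred_missing, value = value)
}

#' Confusion matrix of a missingness classifier
#'
#' 2x2 table of predicted vs observed missingness, laid out with predicted
#' status in rows (non-missing first) and observed status in columns.
#'
#' @param predicted_missing logical vector (or factor) of predictions.
#' @param observed_missing logical vector of truth.
#' @return Integer matrix of class \code{confusion_matrix}.
#' @export
confusion_matrix <- function(predicted_missing, observed_missing) {
  cm <- matrix(c(sum(!predicted_missing & !observed_missing),
                 sum(!predicted_missing & observed_missing),
                 sum(predicted_missing & !observed_missing),
                 sum(predicted_missing & observed_missing)),
               nrow = 2, byrow = TRUE,
               dimnames = list(predicted = c("non-missing", "missing"),
                               observed = c("non-missing", "missing")))
  structure(cm, class = c("confusion_matrix", class(cm)))
}

#' Build a confusion matrix from its four counts
#'
#' @param nm_nm predicted non-missing, observed non-missing.
#' @param nm_m predicted non-missing, observed missing.
#' @param m_nm predicted missing, observed non-missing.
#' @param m_m predicted missing, observed missing.
#' @return A \code{confusion_matrix}.
#' @export
confusion_counts <- function(nm_nm, nm_m, m_nm, m_m) {
  cm <- matrix(c(nm_nm, nm_m, m_nm, m_m), nrow = 2, byrow = TRUE,
               dimnames = list(predicted = c("non-missing", "missing"),
                               observed = c("non-missing", "missing")))
  if (any(cm < 0)) stop("counts must be nonnegative")
  structure(cm, class = c("confusion_matrix", class(cm)))
}

#' Accuracy, sensitivity and specificity of a missingness classifier
#'
#' Accuracy is the fraction of correct classifications. Sensitivity is the
#' fraction of truly observed (non-missing) rows predicted non-missing —
#' the critical quantity for the pipeline, since rows misclassified as
#' missing are discarded without emulation. Specificity is the fraction of
#' truly missing rows predicted missing. Values are exact proportions;
#' rounding happens only at display.
#'
#' @param cm a [confusion_matrix()].
#' @return List of class \code{class_metrics} with \code{accuracy},
#'   \code{sensitivity}, \code{specificity}; a metric whose conditioning
#'   column is empty is \code{NA} (undefined).
#' @export
metrics <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) stop("cm must be a confusion_matrix")
  total <- sum(cm)
  if (total == 0) stop("confusion matrix has no observations")
  obs_nm <- sum(cm[, "non-missing"])
  obs_m <- sum(cm[, "missing"])
  structure(list(
    accuracy = (cm[1, 1] + cm[2, 2]) / total,
    sensitivity = if (obs_nm > 0) cm["non-missing", "non-missing"] / obs_nm
                  else NA_real_,
    specificity = if (obs_m > 0) cm["missing", "missing"] / obs_m
                  else NA_real_),
    class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
              100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' Gini variable importance of the missingness classifier
#'
#' Ranks inputs by the forest's mean decrease in Gini impurity over all
#' splits — the standard forest importance measure, used to identify which
#' parameters drive whether a feature's defining event occurs.
#'
#' @param object a \code{two_stage_emulator} (with a fitted classifier) or a
#'   \code{randomForest} classification fit.
#' @param top return only the leading entries (default all).
#' @return \code{data.frame} with \code{parameter} and \code{importance}
#'   (nonnegative), sorted descending.
#' @export
variable_importance <- function(object, top = Inf) {
  rf <- if (inherits(object, "two_stage_emulator")) object$classifier
        else object
  if (is.null(rf)) stop("no classifier fitted (skip-classifier mode)")
  imp <- randomForest::importance(rf, type = 2)[, 1]
  out <- data.frame(parameter = names(imp), importance = as.numeric(imp))
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  utils::head(out, top)
}
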