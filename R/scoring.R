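#' Experimental target statistics
#'
#' Per-feature experimental mean and standard deviation against which
#' simulated features are scored. Every scored feature's deviation is
#' expressed in units of its experimental SD, so features of different
#' magnitudes contribute comparably.
#'
#' @param feature character vector of feature names.
#' @param mean experimental means (feature units).
#' @param sd experimental SDs, strictly positive.
#' @return \code{data.frame} of class \code{target_stats}.
#' @export
target_stats <- function(feature, mean, sd) {
  if (any(!is.finite(sd)) || any(sd <= 0))
    stop("target sd must be strictly positive for every scored feature")
  if (anyDuplicated(feature)) stop("duplicate target feature names")
  structure(data.frame(feature = as.character(feature), mean = as.numeric(mean),
                       sd = as.numeric(sd), stringsAsFactors = FALSE),
            class = c("target_stats", "data.frame"))
}

#' Build target statistics from a reference parameter vector
#'
#' Simulates the reference individual and uses its feature values as target
#' means, with SDs set to a configured fraction of each mean's magnitude
#' (floored to avoid degenerate targets). Features that are missing for the
#' reference individual are dropped.
#'
#' @param params named reference parameter vector.
#' @param protocols list of [stimulus_protocol()].
#' @param features feature names to target (default: all non-missing).
#' @param sd_frac SD as a fraction of \code{|mean|} (default 0.1).
#' @param sd_floor lower floor on the SD (feature units, default 0.5).
#' @param dt Euler step (ms).
#' @return A [target_stats()] table.
#' @export
targets_from_params <- function(params, protocols = default_protocols(),
                                features = NULL, sd_frac = 0.1,
                                sd_floor = 0.5, dt = 0.1) {
  ft <- batch_evaluate(params, protocols, dt = dt)
  vals <- unlist(ft[1, , drop = TRUE])
  vals <- vals[!is.na(vals)]
  if (!is.null(features)) {
    miss <- setdiff(features, names(vals))
    if (length(miss)) stop("reference individual is missing target feature(s): ",
                           paste(miss, collapse = ", "))
    vals <- vals[features]
  }
  target_stats(names(vals), vals, pmax(sd_frac * abs(vals), sd_floor))
}

#' Per-feature objective scores
#'
#' \code{score_j = |f_j - mu_j| / sigma_j} for observed features; a feature
#' in the missing set receives the configured missing-feature penalty (in SD
#' units). The penalty default of 20 is a package design choice, not an
#' experimental quantity — it must dominate typical observed deviations so
#' that individuals lacking a defining event are strongly disfavoured, and it
#' is exposed for tuning.
#'
#' @param features named numeric feature vector (missing features \code{NA}).
#' @param targets a [target_stats()] table covering all scored features.
#' @param missing_penalty score assigned to a missing feature (SD units).
#' @return Named numeric vector of nonnegative per-feature scores.
#' @export
objective_scores <- function(features, targets, missing_penalty = 20) {
  if (!inherits(targets, "target_stats")) stop("targets must be target_stats")
  absent <- setdiff(targets$feature, names(features))
  if (length(absent))
    stop("feature vector lacks scored feature(s): ",
         paste(absent, collapse = ", "))
  f <- features[targets$feature]
  s <- abs(f - targets$mean) / targets$sd
  s[is.na(f)] <- missing_penalty
  stats::setNames(as.numeric(s), targets$feature)
}

#' Global score of an individual
#'
#' Sum over scored features of the per-feature objective scores: the summed
#' distance, in experimental SD units, between the individual's simulated
#' features and the experimental targets. Lower is better; a perfect match
#' scores 0.
#'
#' @inheritParams objective_scores
#' @return Single nonnegative number.
#' @export
global_score <- function(features, targets, missing_penalty = 20) {
  sum(objective_scores(features, targets, missing_penalty))
}

#' Global scores for a feature table
#'
#' @param tab a feature table (rows = individuals).
#' @inheritParams objective_scores
#' @return Numeric vector of global scores, one per row.
#' @export
score_table <- function(tab, targets, missing_penalty = 20) {
  apply(as.matrix(tab[, targets$feature, drop = FALSE]), 1, function(r)
    global_score(r, targets, missing_penalty))
}
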