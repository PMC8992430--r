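#' Benchmark emulator methods on a train/test split
#'
#' Fits every requested method on the training data, predicts the held-out
#' test inputs, and reports the root mean squared prediction error together
#' with fit-plus-predict wall time. The test-response SD is reported so the
#' RMSE/SD ratio — the accuracy yardstick "RMSE below half the response SD" —
#' can be read off directly. Timings are hardware-dependent and are reported
#' for orientation only.
#'
#' @param specs named list of [emulator_spec()] objects (names label the
#'   rows; unnamed lists are labelled by method).
#' @param X_train,y_train training inputs/response.
#' @param X_test,y_test disjoint test inputs/response.
#' @param space optional [parameter_space()].
#' @param seed integer seed fanned out per method.
#' @param sort_by column to sort the table by (default \code{"rmse"};
#'   \code{NULL} preserves input order).
#' @return \code{data.frame} with columns \code{method}, \code{rmse},
#'   \code{test_sd}, \code{rmse_over_sd}, \code{seconds}, \code{error}
#'   (\code{NA} unless the method failed; failures leave other rows
#'   unaffected).
#' @export
benchmark <- function(specs, X_train, y_train, X_test, y_test, space = NULL,
                      seed = 1L, sort_by = "rmse") {
  if (inherits(specs, "emulator_spec")) specs <- list(specs)
  nm <- names(specs) %||% vapply(specs, `[[`, "", "method")
  nm[nm == ""] <- vapply(specs[nm == ""], `[[`, "", "method")
  test_sd <- stats::sd(y_test)
  rows <- lapply(seq_along(specs), function(i) {
    t0 <- proc.time()["elapsed"]
    res <- tryCatch({
      fit <- fit_emulator(specs[[i]], X_train, y_train, space = space,
                          seed = derive_seed(seed, i))
      pr <- stats::predict(fit, X_test)
      sqrt(mean((pr$mean - y_test)^2))
    }, error = function(e) conditionMessage(e))
    secs <- as.numeric(proc.time()["elapsed"] - t0)
    if (is.character(res))
      data.frame(method = nm[i], rmse = NA_real_, test_sd = test_sd,
                 rmse_over_sd = NA_real_, seconds = secs, error = res)
    else
      data.frame(method = nm[i], rmse = res, test_sd = test_sd,
                 rmse_over_sd = res / test_sd, seconds = secs,
                 error = NA_character_)
  })
  out <- do.call(rbind, rows)
  if (!is.null(sort_by) && sort_by %in% names(out))
    out <- out[order(out[[sort_by]]), ]
  rownames(out) <- NULL
  out
}
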