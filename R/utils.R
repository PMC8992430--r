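#' Derive a stage seed from a master seed
#'
#' One global seed fans out to per-stage seeds through a fixed affine counter
#' scheme, so any stage can be re-run in isolation from the run manifest.
#'
#' @param master integer master seed.
#' @param stage integer stage counter (>= 0).
#' @return An integer seed, strictly below 2^31.
#' @export
derive_seed <- function(master, stage = 0L) {
  master <- as.integer(master)
  stopifnot(is.finite(master), stage >= 0)
  as.integer((as.double(master) * 7919 + as.double(stage) * 104729 + 1) %%
               2147483629)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
}
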