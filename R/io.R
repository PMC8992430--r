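#' Read and write feature tables
#'
#' Feature tables are plain CSV: header row of feature names, one row per
#' individual, missing values encoded as the literal \code{NA}. Parsing is
#' locale-independent (dot decimal separator).
#'
#' @param path file path.
#' @return For \code{read_feature_table}, a \code{feature_table} data.frame
#'   with the missingness mask as \code{NA} entries and per-column missing
#'   counts in \code{attr(, "missing_counts")}.
#' @export
read_feature_table <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (anyDuplicated(names(raw)))
    stop("duplicate column names in ", path, ": ",
         paste(unique(names(raw)[duplicated(names(raw))]), collapse = ", "))
  for (j in seq_along(raw)) {
    x <- raw[[j]]
    is_na <- x == "NA" | x == ""
    num <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(num) & !is_na)
    if (length(bad))
      stop(sprintf("parse error at row %d, column '%s': '%s' is not numeric",
                   bad[1], names(raw)[j], x[bad[1]]))
    num[is_na] <- NA_real_
    raw[[j]] <- num
  }
  attr(raw, "missing_counts") <- colSums(is.na(raw))
  class(raw) <- c("feature_table", class(raw))
  raw
}

#' @param tab a feature table (or any data.frame/matrix).
#' @rdname read_feature_table
#' @export
write_feature_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read and write experimental target statistics
#'
#' Targets may be stored as CSV (columns \code{feature}, \code{mean},
#' \code{sd}) or JSON (array of objects with those fields); the extension
#' decides. SDs must be strictly positive.
#'
#' @param path file path (\code{.csv} or \code{.json}).
#' @return A [target_stats()] table.
#' @export
read_targets <- function(path) {
  df <- if (grepl("\\.json$", path, ignore.case = TRUE))
    as.data.frame(jsonlite::fromJSON(path))
  else utils::read.csv(path, check.names = FALSE)
  need <- c("feature", "mean", "sd")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("targets file lacks column(s): ",
                         paste(miss, collapse = ", "))
  target_stats(df$feature, df$mean, df$sd)
}

#' @param targets a [target_stats()] table.
#' @rdname read_targets
#' @export
write_targets <- function(targets, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(as.data.frame(unclass(targets)), path,
                         auto_unbox = TRUE, digits = NA)
  else utils::write.csv(as.data.frame(unclass(targets)), path,
                        row.names = FALSE)
  invisible(path)
}

#' Write a parameter table
#'
#' @param params matrix of parameter rows (named columns).
#' @param path file path.
#' @export
write_params <- function(params, path) {
  utils::write.csv(as.data.frame(params), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  as.matrix(utils::read.csv(path, check.names = FALSE))
}

#' Assemble and write a run manifest
#'
#' The manifest records everything needed to re-run a stage: the
#' configuration snapshot, every seed, the package version, call counts and
#' a timestamp. Deterministic stages are bit-reproducible from it; stochastic
#' stages are re-seedable.
#'
#' @param command the command or stage name.
#' @param config named list: the full configuration snapshot.
#' @param seeds named list or vector of all seeds used.
#' @param counts optional named list of per-stage call counts.
#' @return List of class \code{run_manifest}.
#' @export
run_manifest <- function(command, config = list(), seeds = list(),
                         counts = list()) {
  structure(list(command = command, config = config, seeds = seeds,
                 counts = counts,
                 package_version =
                   as.character(utils::packageVersion("neuremu")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            class = "run_manifest")
}

#' @param manifest a [run_manifest()].
#' @param path output JSON path.
#' @rdname run_manifest
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
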