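#' Greedy treed emulator with linear or GP leaves
#'
#' Recursive binary axis-aligned partitioning of the input space, each split
#' chosen to maximize the reduction in residual (about-the-mean) variance,
#' with an independent leaf model — linear, GP, or GPllm — fitted in each
#' partition. This is a deterministic greedy approximation to Bayesian treed
#' GP models: it keeps their two mechanisms (regime changes across the space,
#' flexible within-regime response) while replacing the MCMC search over tree
#' structures with a single greedy tree.
#'
#' @inheritParams gp_fit
#' @param max_depth maximum split depth (0 = no splits: the plain leaf model
#'   on all data).
#' @param min_leaf minimum rows per leaf; must be \code{>= d + 2} for GP
#'   leaves.
#' @param leaf_model \code{"linear"}, \code{"gp"} or \code{"gpllm"}.
#' @param n_cuts candidate cut points per dimension (quantile grid).
#' @param ... options forwarded to the leaf fitting routine.
#' @return Object of class \code{c("treed_emulator", "emulator")}.
#' @export
treed_fit <- function(X, y, space = NULL, max_depth = 3L,
                      min_leaf = NULL, leaf_model = c("linear", "gp", "gpllm"),
                      n_cuts = 40L, seed = 1L, ...) {
  leaf_model <- match.arg(leaf_model)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  d <- ncol(X)
  min_leaf <- min_leaf %||% max(d + 2L, 10L)
  if (leaf_model != "linear" && min_leaf < d + 2)
    stop("min_leaf must be >= d + 2 for GP leaves")
  if (nrow(X) < min_leaf)
    stop("infeasible configuration: fewer than min_leaf training rows")
  leaf_opts <- list(...)

  fit_leaf <- function(rows) {
    Xi <- X[rows, , drop = FALSE]
    yi <- y[rows]
    switch(leaf_model,
      linear = lm_emulator(Xi, yi),
      gp     = do.call(gp_fit, c(list(X = Xi, y = yi, space = space,
                                      seed = seed), leaf_opts)),
      gpllm  = do.call(llm_select, c(list(X = Xi, y = yi, space = space,
                                          seed = seed), leaf_opts)))
  }

  best_split <- function(rows) {
    yi <- y[rows]
    sse0 <- sum((yi - mean(yi))^2)
    best <- NULL
    for (j in seq_len(d)) {
      xj <- X[rows, j]
      cuts <- unique(stats::quantile(xj, probs = seq_len(n_cuts) / (n_cuts + 1),
                                     names = FALSE, type = 1))
      for (cc in cuts) {
        left <- xj <= cc
        nl <- sum(left)
        if (nl < min_leaf || length(rows) - nl < min_leaf) next
        yl <- yi[left]; yr <- yi[!left]
        sse <- sum((yl - mean(yl))^2) + sum((yr - mean(yr))^2)
        if (is.null(best) || sse < best$sse)
          best <- list(dim = j, cut = cc, sse = sse, gain = sse0 - sse)
      }
    }
    if (!is.null(best) && best$gain > 0) best else NULL
  }

  grow <- function(rows, depth) {
    sp <- if (depth < max_depth) best_split(rows) else NULL
    if (is.null(sp))
      return(list(leaf = TRUE, n = length(rows), model = fit_leaf(rows)))
    left <- rows[X[rows, sp$dim] <= sp$cut]
    right <- setdiff(rows, left)
    list(leaf = FALSE, dim = sp$dim, cut = sp$cut,
         left = grow(left, depth + 1L), right = grow(right, depth + 1L))
  }

  structure(list(tree = grow(seq_len(nrow(X)), 0L), xnames = colnames(X),
                 leaf_model = leaf_model, max_depth = max_depth,
                 min_leaf = min_leaf),
            class = c("treed_emulator", "emulator"))
}

#' @export
predict.treed_emulator <- function(object, Xnew, level = 0.90, ...) {
  Xnew <- as.matrix(Xnew)
  route <- function(node, idx) {
    if (node$leaf) {
      pr <- stats::predict(node$model, Xnew[idx, , drop = FALSE],
                           level = level)
      pr$.row <- idx
      return(list(pr))
    }
    go_left <- Xnew[idx, node$dim] <= node$cut
    c(if (any(go_left)) route(node$left, idx[go_left]),
      if (any(!go_left)) route(node$right, idx[!go_left]))
  }
  parts <- do.call(rbind, route(object$tree, seq_len(nrow(Xnew))))
  parts <- parts[order(parts$.row), ]
  parts$.row <- NULL
  rownames(parts) <- NULL
  parts
}

#' Splits of a fitted treed emulator
#'
#' @param object a \code{treed_emulator}.
#' @return \code{data.frame} with columns \code{depth}, \code{dim} (name) and
#'   \code{cut}; zero rows when the tree has no splits.
#' @export
treed_splits <- function(object) {
  rec <- function(node, depth) {
    if (node$leaf) return(NULL)
    rbind(data.frame(depth = depth, dim = object$xnames[node$dim],
                     cut = node$cut),
          rec(node$left, depth + 1L), rec(node$right, depth + 1L))
  }
  out <- rec(object$tree, 0L)
  out %||% data.frame(depth = integer(), dim = character(), cut = numeric())
}
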