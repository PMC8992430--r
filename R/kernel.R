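#' Squared-exponential (ARD) covariance between two input vectors
#'
#' \code{k(x, x') = sigma_f^2 exp(-1/2 sum_j (x_j - x'_j)^2 / l_j^2)}, the
#' automatic-relevance-determination form in which each input dimension
#' carries its own length scale; large length scales flag unimportant inputs.
#'
#' @param xp,xq numeric vectors of equal length (unit-cube scale).
#' @param hyper list with \code{signal_variance} (\code{sigma_f^2}),
#'   \code{lengthscales} (vector \code{l_j}, all \code{> 0}) and optionally
#'   \code{nugget} (ignored here; the nugget enters only on the diagonal of a
#'   covariance matrix).
#' @return Scalar covariance value; symmetric in its arguments.
#' @export
se_kernel <- function(xp, xq, hyper) {
  ls <- rep_len(hyper$lengthscales, length(xp))
  if (any(ls <= 0)) stop("lengthscales must be strictly positive")
  if (length(xp) != length(xq)) stop("xp and xq must have equal length")
  hyper$signal_variance * exp(-0.5 * sum((xp - xq)^2 / ls^2))
}

new_kernel_hyper <- function(signal_variance, lengthscales, nugget = 0) {
  if (signal_variance <= 0) stop("signal_variance must be > 0")
  if (any(lengthscales <= 0)) stop("lengthscales must be > 0")
  if (nugget < 0) stop("nugget must be >= 0")
  list(signal_variance = signal_variance, lengthscales = lengthscales,
       nugget = nugget)
}
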