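#' Empirical quantiles by linear interpolation of order statistics
#'
#' Estimates `F^{-1}(p)` for each probability in `probs` from a numeric
#' sample, interpolating linearly between order statistics at position
#' `h = (m - 1) p + 1` (the continuous estimator used throughout the
#' package, identical to [stats::quantile()] type 7).
#'
#' @param values Numeric sample (length >= 1, all finite).
#' @param probs Probabilities, each strictly inside (0, 1).
#' @return Numeric vector of quantile estimates, one per probability,
#'   monotone non-decreasing when `probs` is increasing.
#' @examples
#' estimate_quantiles(1:5, c(0.25, 0.5, 0.75))
#' @export
estimate_quantiles <- function(values, probs) {
  if (length(values) == 0L) stop("no observations")
  if (anyNA(values) || !all(is.finite(values))) stop("sample contains non-finite values")
  check_probs(probs)
  stats::quantile(values, probs = probs, names = FALSE, type = 7)
}

check_probs <- function(probs) {
  if (length(probs) == 0L || anyNA(probs) || any(probs <= 0) || any(probs >= 1)) {
    stop("probabilities must lie strictly inside (0, 1)")
  }
  if (is.unsorted(probs, strictly = TRUE)) {
    stop("probabilities must be strictly increasing")
  }
  invisible(probs)
}

check_weights <- function(weights, probs) {
  if (length(weights) != length(probs)) stop("weights must match probs in length")
  if (anyNA(weights) || any(weights <= 0)) stop("weights must be positive")
  weights / sum(weights)
}

# Row-wise type-7 quantiles of a genes x samples matrix, vectorised across
# genes: each quantile is a fixed linear combination of two sorted columns.
row_quantiles <- function(m, probs) {
  m <- as.matrix(m)
  n <- ncol(m)
  if (n == 0L) stop("no observations")
  srt <- matrix(0, nrow(m), n)
  for (i in seq_len(nrow(m))) srt[i, ] <- sort.int(m[i, ], method = "quick")
  h <- (n - 1) * probs + 1
  lo <- pmin(floor(h), n)
  hi <- pmin(lo + 1, n)
  g <- h - lo
  out <- srt[, lo, drop = FALSE] * rep(1 - g, each = nrow(m)) +
    srt[, hi, drop = FALSE] * rep(g, each = nrow(m))
  dimnames(out) <- list(rownames(m), NULL)
  out
}

#' Per-gene quantile-difference vectors
#'
#' For each gene `g`, computes `v_gp = F_hat_X^{-1}(p) - F_hat_Y^{-1}(p)` over
#' the probability set: the difference between the condition-1 and
#' condition-2 empirical quantiles. Genes whose expression distribution is
#' identical under both conditions give rows near zero; differentially
#' expressed genes stand out as outlying rows.
#'
#' @param cond1,cond2 Numeric matrices (genes x samples), identical gene
#'   count and ordering.
#' @param probs Probability set (default quartiles `c(0.25, 0.5, 0.75)`).
#' @return A genes x `length(probs)` matrix; row names carry gene labels.
#' @examples
#' m1 <- matrix(rnorm(30), 5, 6)
#' m2 <- matrix(rnorm(30), 5, 6)
#' quantile_differences(m1, m2)
#' @export
quantile_differences <- function(cond1, cond2, probs = c(0.25, 0.5, 0.75)) {
  check_probs(probs)
  cond1 <- as.matrix(cond1)
  cond2 <- as.matrix(cond2)
  if (nrow(cond1) != nrow(cond2)) stop("condition matrices must have the same gene count")
  row_quantiles(cond1, probs) - row_quantiles(cond2, probs)
}

# Column scale factors: sample sd of each column of the ORIGINAL-data
# quantile-difference matrix. Shared between original and permuted cases so
# both live in one coordinate system; no centering (0 keeps meaning "no
# difference").
column_scale_factors <- function(reference, enabled = TRUE) {
  if (!enabled) return(rep(1, ncol(reference)))
  sds <- apply(reference, 2, stats::sd)
  if (any(!is.finite(sds)) || any(sds == 0)) stop("degenerate quantile column")
  sds
}

#' Scale quantile-difference columns by reference standard deviations
#'
#' Divides each column by the sample standard deviation of the corresponding
#' column of `reference` (normally the original-data matrix, so that original
#' genes and permuted null cases share one scale). Columns are never
#' centered: zero must keep meaning "no difference between conditions".
#'
#' @param v Quantile-difference matrix to scale.
#' @param reference Matrix supplying the per-column standard deviations
#'   (defaults to `v` itself).
#' @param enabled If `FALSE`, returns `v` unchanged (scale factors 1).
#' @return Matrix of the same shape with attribute `scale_factors`.
#' @export
scale_columns <- function(v, reference = v, enabled = TRUE) {
  if (ncol(reference) != ncol(v)) stop("reference must have the same column count")
  sf <- column_scale_factors(reference, enabled)
  out <- sweep(v, 2, sf, "/")
  attr(out, "scale_factors") <- sf
  out
}

#' Weighted Euclidean distances between quantile-difference vectors
#'
#' `d(u, v) = sqrt(sum_p w_p (u_p - v_p)^2)` with weights normalised to sum
#' one. This is the metric used for the outlier ratio and for the
#' false-positive neighbourhood counts.
#'
#' @param points Numeric matrix, cases in rows.
#' @param weights Positive weights, one per column (normalised internally).
#' @return A [stats::dist] object over all unordered case pairs.
#' @export
weighted_distances <- function(points, weights = rep(1, ncol(points))) {
  points <- as.matrix(points)
  if (length(weights) != ncol(points)) stop("weights must match the number of columns")
  if (any(weights <= 0)) stop("weights must be positive")
  w <- weights / sum(weights)
  stats::dist(sweep(points, 2, sqrt(w), "*"))
}
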