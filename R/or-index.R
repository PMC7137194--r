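#' Outlier-ratio (OR) scores for a set of quantile-difference vectors
#'
#' For each case i, OR(i) is the mean weighted distance from i to every
#' other case of the set, divided by the mean over all pairwise distances.
#' Typical cases score near 1; outlying cases — candidate differentially
#' expressed genes — score well above 1. The ratio is invariant to global
#' rescaling of the coordinates and to duplicating the whole case set, and
#' grows without bound as a case moves away from the rest.
#'
#' @param points Numeric matrix (cases x quantiles), at least 3 rows.
#' @param weights Per-quantile weights (normalised internally).
#' @return Numeric vector of non-negative OR values, one per case.
#' @export
or_scores <- function(points, weights = rep(1, ncol(points))) {
  points <- as.matrix(points)
  m <- nrow(points)
  if (m < 3L) stop("at least 3 cases are required")
  d <- weighted_distances(points, weights)
  overall <- mean(d)
  if (overall == 0) stop("degenerate case set")
  dm <- as.matrix(d)
  # mean distance to the other m-1 cases (the diagonal self-zero drops out)
  unname(rowSums(dm) / (m - 1)) / overall
}

# One permutation replicate: pool the s1+s2 sample columns, permute them with
# a single permutation shared by all genes, re-split into pseudo-conditions
# of the original sizes. Emulates genes with no condition effect.
permute_replicate <- function(cond1, cond2) {
  s1 <- ncol(cond1)
  pooled <- cbind(cond1, cond2)
  perm <- sample.int(ncol(pooled))
  list(
    cond1 = pooled[, perm[seq_len(s1)], drop = FALSE],
    cond2 = pooled[, perm[-seq_len(s1)], drop = FALSE]
  )
}

#' Permutation null of OR values
#'
#' Generates `B` label-permuted replicates of the data, recomputes scaled
#' quantile-difference vectors and OR scores within each replicate, pools the
#' `n * B` null OR values, and records the empirical `(1 - alpha)` quantile
#' as the potential-DEG threshold. Null cases strictly above the threshold
#' ("retained" cases) are known false positives, kept with their replicate id
#' for the neighbourhood calibration step.
#'
#' Replicate b draws its random permutation from a seed derived
#' deterministically from (`seed`, b), so results are identical for any
#' `workers` count and execution order.
#'
#' @param cond1,cond2 Expression matrices (genes x samples).
#' @param probs,weights Quantile probabilities and their weights.
#' @param alpha Tail level for the null percentile (default 0.05).
#' @param B Number of permutation replicates (default 100).
#' @param scale_factors Per-column divisors from the original-data
#'   quantile-difference matrix (see [scale_columns()]); `NULL` disables
#'   scaling.
#' @param seed Integer master seed.
#' @param workers Number of parallel processes (forked; results do not
#'   depend on it).
#' @return List with elements `or_values` (length `n * B`), `replicate_id`,
#'   `threshold`, `retained` (indices into the pooled null cases),
#'   `retained_cases` (their scaled quantile-difference vectors),
#'   `retained_replicate` (their replicate ids), `n`, and `B`.
#' @export
build_null_set <- function(cond1, cond2, probs = c(0.25, 0.5, 0.75),
                           weights = c(0.25, 0.5, 0.25), alpha = 0.05,
                           B = 100, scale_factors = NULL, seed = 0,
                           workers = 1) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie strictly inside (0, 1)")
  if (B < 1L) stop("B must be at least 1")
  weights <- check_weights(weights, probs)
  n <- nrow(cond1)
  rep_seeds <- derive_seeds(seed, B + 1L)[seq_len(B)]

  one_replicate <- function(b) {
    set.seed(rep_seeds[b])
    perm <- permute_replicate(cond1, cond2)
    v <- quantile_differences(perm$cond1, perm$cond2, probs)
    if (!is.null(scale_factors)) v <- sweep(v, 2, scale_factors, "/")
    list(cases = v, or = or_scores(v, weights))
  }
  reps <- if (workers > 1L) {
    parallel::mclapply(seq_len(B), one_replicate, mc.cores = workers)
  } else {
    lapply(seq_len(B), one_replicate)
  }

  or_values <- unlist(lapply(reps, `[[`, "or"), use.names = FALSE)
  replicate_id <- rep(seq_len(B), each = n)
  threshold <- stats::quantile(or_values, probs = 1 - alpha, names = FALSE, type = 7)
  retained <- which(or_values > threshold)
  cases <- do.call(rbind, lapply(reps, `[[`, "cases"))[retained, , drop = FALSE]
  rownames(cases) <- NULL
  list(
    or_values = or_values,
    replicate_id = replicate_id,
    threshold = threshold,
    retained = retained,
    retained_cases = cases,
    retained_replicate = replicate_id[retained],
    n = n,
    B = B
  )
}

# Deterministic child seeds derived from one master seed; keeps replicate
# RNG streams independent of worker count and execution order.
derive_seeds <- function(seed, k) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  sample.int(.Machine$integer.max, k)
}

#' Flag potential differentially expressed genes
#'
#' A gene is a potential DEG when its OR score is strictly greater than the
#' `(1 - alpha)` percentile of the pooled permutation-null OR values.
#'
#' @param original_or OR values of the original genes.
#' @param threshold Null percentile from [build_null_set()].
#' @return Integer indices of flagged genes (possibly empty, with a warning).
#' @export
flag_potential <- function(original_or, threshold) {
  if (!is.finite(threshold) && !is.infinite(threshold)) stop("threshold must not be NA")
  idx <- which(original_or > threshold)
  if (length(idx) == 0L) warning("no potential differentially expressed genes found")
  idx
}
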