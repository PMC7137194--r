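#' Partition permutation replicates into folds
#'
#' Randomly assigns the `B` replicates to `fold` balanced groups. Each
#' fold's retained null cases later form an independent calibration set for
#' the K-nearest-neighbour false-positive counts.
#'
#' @param B Number of permutation replicates.
#' @param fold Number of folds (1 <= fold <= B).
#' @param seed Integer seed making the partition reproducible.
#' @return Integer vector of length `B`: the fold of each replicate.
#' @export
assign_folds <- function(B, fold, seed = 0) {
  if (fold < 1L || fold > B) stop("fold must lie between 1 and B")
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
  sample(rep_len(seq_len(fold), B))
}

#' False-positive neighbourhood scores (FP and dFP)
#'
#' For each potential DEG g and each fold f, ranks the candidate set —
#' every other potential DEG plus fold f's retained null cases — by weighted
#' distance to g. `FP_f(g)` counts the retained null cases among the K
#' nearest candidates; `dFP_f(g)` sums `1 / max(d, eps)` over those null
#' neighbours, an inverse-distance density. Both are averaged over folds.
#' Distance ties are broken by candidate ordinal (potential DEGs first, then
#' null cases, each in input order); a gene is never its own neighbour.
#'
#' @param potentials Scaled quantile-difference vectors of the potential
#'   DEGs (rows).
#' @param null_cases Retained null-case vectors (rows, same columns).
#' @param null_fold Fold id of each null case.
#' @param K Neighbourhood size.
#' @param weights Per-quantile weights.
#' @param eps Floor applied to distances inside dFP (default 1e-10).
#' @return A tibble with one row per potential DEG: `fp` and `dfp` (means
#'   over folds) plus matrix columns `fp_fold` and `dfp_fold` holding the
#'   per-fold values.
#' @export
fp_dfp <- function(potentials, null_cases, null_fold, K = 10,
                   weights = rep(1, ncol(potentials)), eps = 1e-10) {
  potentials <- as.matrix(potentials)
  null_cases <- as.matrix(null_cases)
  np <- nrow(potentials)
  if (np < 1L) stop("no potential DEGs supplied")
  folds <- sort(unique(null_fold))
  w <- weights / sum(weights)
  pw <- sweep(potentials, 2, sqrt(w), "*")
  nw <- sweep(null_cases, 2, sqrt(w), "*")

  # all-pairs distances among potentials, reused by every fold
  dpot <- as.matrix(stats::dist(pw))

  fp_f <- matrix(0, np, length(folds))
  dfp_f <- matrix(0, np, length(folds))
  for (fi in seq_along(folds)) {
    in_fold <- null_fold == folds[fi]
    nf <- sum(in_fold)
    if (np - 1L + nf < K) stop("neighbourhood undersized")
    dnull <- cross_dist(pw, nw[in_fold, , drop = FALSE])
    for (g in seq_len(np)) {
      d <- c(dpot[g, -g], dnull[g, ])
      is_null <- c(rep(FALSE, np - 1L), rep(TRUE, nf))
      nn <- order(d, method = "radix")[seq_len(K)]  # stable: ties by ordinal
      null_nn <- nn[is_null[nn]]
      fp_f[g, fi] <- length(null_nn)
      dfp_f[g, fi] <- sum(1 / pmax(d[null_nn], eps))
    }
  }
  tibble::tibble(
    fp = rowMeans(fp_f),
    dfp = rowMeans(dfp_f),
    fp_fold = fp_f,
    dfp_fold = dfp_f
  )
}

# Euclidean cross-distance matrix between row sets a and b
cross_dist <- function(a, b) {
  if (nrow(b) == 0L) return(matrix(0, nrow(a), 0))
  sq <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(sq, 0))
}

#' Expected false-positive neighbours under uniform mixing
#'
#' The reference value for the relaxed selection: if potential DEGs and a
#' fold's retained null cases were spatially indistinguishable, a size-K
#' neighbourhood would contain `K * P_f / (P_f + n_potential)` null cases on
#' average, where `P_f` is the fold's retained-case count. Reported as the
#' mean over folds, together with the corresponding null-case proportion.
#'
#' @param K Neighbourhood size.
#' @param fold_counts Retained null-case count per fold.
#' @param n_potential Number of potential DEGs.
#' @return List with `expected` (neighbours) and `proportion` (percent).
#' @export
expected_fp <- function(K, fold_counts, n_potential) {
  if (n_potential < 1L) stop("n_potential must be at least 1")
  prop <- mean(fold_counts / (fold_counts + n_potential))
  list(expected = K * prop, proportion = 100 * prop)
}
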