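#' Identify differentially expressed genes by quantile-difference outlier scoring
#'
#' Runs the full two-step procedure. Step one represents each gene by its
#' vector of condition-1 minus condition-2 empirical quantiles, scores genes
#' with the outlier ratio (OR) against `B` label-permuted replicates, and
#' keeps genes above the `(1 - alpha)` null percentile as *potential* DEGs.
#' Step two measures, for each potential DEG, the contamination of its
#' K-nearest neighbourhood by above-threshold permuted cases (FP, and its
#' inverse-distance density dFP) using fold-partitioned null cases, applies
#' the strong (`FP == 0`) and relaxed (`FP` below the uniform-mixing
#' expectation) selection rules, and clusters the potential DEGs on their
#' z-scored (OR, FP, dFP) indexes with PAM and silhouette-chosen k.
#'
#' The run is fully deterministic given `seed`, regardless of `workers`.
#'
#' @param cond1 Either a genes x samples matrix / data frame for condition 1,
#'   or a `degor_sim` tibble from [simulate_study()] (then `cond2` is
#'   ignored).
#' @param cond2 Genes x samples matrix for condition 2 (same genes, same
#'   order). Values are assumed already normalised / transformed; no
#'   pre-processing is applied.
#' @param probs Quantile probabilities (default `c(0.25, 0.5, 0.75)`).
#' @param weights Weights given to the quantiles (default
#'   `c(0.25, 0.5, 0.25)`, normalised to sum 1).
#' @param alpha Tail level defining the potential-DEG threshold (default
#'   0.05).
#' @param B Number of permutation replicates (default 100).
#' @param K Neighbourhood size for FP / dFP (default 10).
#' @param fold Number of folds the replicates are split into (default 10).
#' @param scale If `TRUE` (default), quantile-difference columns are divided
#'   by the original-data column standard deviations (shared with the
#'   permuted cases).
#' @param numclustoseek Largest cluster count tried by the silhouette search
#'   (default 10).
#' @param k Fixed cluster count; `NULL` (default) selects it by silhouette.
#' @param seed Integer master seed (default 0).
#' @param workers Parallel processes for the permutation loop (default 1;
#'   results are identical for any value).
#' @return An object of class `degor_fit`: a list with
#'   \describe{
#'     \item{genes}{tibble of potential DEGs: `gene`, `or`, `fp`, `dfp`,
#'       `strong`, `relaxed`, `cluster`, sorted by decreasing OR.}
#'     \item{clusters}{per-cluster summary tibble (see
#'       [summarize_clusters()]).}
#'     \item{expected_fp}{uniform-mixing expected false-positive neighbours.}
#'     \item{null_proportion}{percentage of permuted cases among candidates.}
#'     \item{threshold}{the `(1 - alpha)` null OR percentile.}
#'     \item{k}{number of clusters used; `silhouette` the candidate table.}
#'     \item{config}{echo of all parameters, including the seed.}
#'   }
#' @examples
#' sim <- simulate_study(n_genes = 120, n_de = 12, s1 = 10, s2 = 10, seed = 3)
#' fit <- find_degs(sim, B = 20, seed = 3)
#' fit
#' @export
find_degs <- function(cond1, cond2 = NULL, probs = c(0.25, 0.5, 0.75),
                      weights = c(0.25, 0.5, 0.25), alpha = 0.05, B = 100,
                      K = 10, fold = 10, scale = TRUE, numclustoseek = 10,
                      k = NULL, seed = 0, workers = 1) {
  if (inherits(cond1, "degor_sim")) {
    mats <- study_matrices(cond1)
    cond1 <- mats$cond1
    cond2 <- mats$cond2
  }
  cond1 <- as.matrix(cond1)
  cond2 <- as.matrix(cond2)
  validate_pair(cond1, cond2)
  check_probs(probs)
  weights <- check_weights(weights, probs)
  if (fold < 1 || fold > B) stop("fold must lie between 1 and B")
  if (K < 1) stop("numneighbours must be at least 1")
  if (numclustoseek < 2) stop("numclustoseek must be at least 2")
  labels <- rownames(cond1)
  if (is.null(labels)) labels <- paste0("Gene", seq_len(nrow(cond1)))

  config <- list(probs = probs, weights = weights, alpha = alpha, B = B,
                 K = K, fold = fold, scale = scale,
                 numclustoseek = numclustoseek, k = k, seed = seed,
                 workers = workers)
  seeds <- derive_seeds(seed, 2L)

  # step 1: original OR scores vs permutation-null threshold
  v0 <- quantile_differences(cond1, cond2, probs)
  sf <- column_scale_factors(v0, enabled = scale)
  v <- sweep(v0, 2, sf, "/")
  null <- build_null_set(cond1, cond2, probs, weights, alpha, B,
                         scale_factors = if (scale) sf else NULL,
                         seed = seeds[1], workers = workers)
  or_orig <- or_scores(v, weights)
  pot <- suppressWarnings(flag_potential(or_orig, null$threshold))
  if (length(pot) == 0L) {
    warning("no potential differentially expressed genes found")
    return(empty_fit(config, null$threshold, nrow(cond1)))
  }

  # step 2: neighbourhood false-positive calibration, selection, clustering
  fold_of_rep <- assign_folds(B, fold, seed = seeds[2])
  null_fold <- fold_of_rep[null$retained_replicate]
  scores <- fp_dfp(v[pot, , drop = FALSE], null$retained_cases, null_fold,
                   K = K, weights = weights)
  fold_counts <- tabulate(null_fold, nbins = fold)
  efp <- expected_fp(K, fold_counts, length(pot))
  flags <- strong_relaxed_flags(scores$fp, efp$expected)

  genes <- tibble::tibble(
    gene = labels[pot],
    or = or_orig[pot],
    fp = scores$fp,
    dfp = scores$dfp,
    strong = flags$strong,
    relaxed = flags$relaxed
  )
  if (nrow(genes) > 3L) {
    cl <- cluster_scores(genes, k = k, numclustoseek = numclustoseek)
    genes$cluster <- cl$cluster
    kk <- cl$k
    sil <- cl$silhouette
  } else {
    genes$cluster <- 1L
    kk <- 1L
    sil <- NULL
  }
  genes <- dplyr::arrange(genes, dplyr::desc(.data$or))

  structure(list(
    genes = genes,
    clusters = summarize_clusters(genes),
    expected_fp = efp$expected,
    null_proportion = efp$proportion,
    threshold = null$threshold,
    n_retained = length(null$retained),
    fold_counts = fold_counts,
    k = kk,
    silhouette = sil,
    n_genes = nrow(cond1),
    config = config
  ), class = "degor_fit")
}

validate_pair <- function(cond1, cond2) {
  if (nrow(cond1) != nrow(cond2)) stop("condition matrices must have the same gene count")
  if (ncol(cond1) < 3 || ncol(cond2) < 3) stop("at least 3 samples per condition are required")
  if (!all(is.finite(cond1)) || !all(is.finite(cond2))) stop("expression values must be finite")
  l1 <- rownames(cond1)
  if (!is.null(l1) && anyDuplicated(l1)) stop("gene labels must be unique")
  l2 <- rownames(cond2)
  if (!is.null(l1) && !is.null(l2) && !identical(l1, l2)) {
    stop("gene labels differ between conditions")
  }
  invisible(TRUE)
}

empty_fit <- function(config, threshold, n_genes = NA_integer_) {
  structure(list(
    genes = tibble::tibble(gene = character(), or = numeric(), fp = numeric(),
                           dfp = numeric(), strong = logical(),
                           relaxed = logical(), cluster = integer()),
    clusters = tibble::tibble(),
    expected_fp = NA_real_, null_proportion = NA_real_,
    threshold = threshold, n_retained = NA_integer_,
    fold_counts = integer(), k = NA_integer_, silhouette = NULL,
    n_genes = n_genes, config = config
  ), class = "degor_fit")
}

#' @export
print.degor_fit <- function(x, ...) {
  cat("Quantile-difference outlier DEG analysis\n")
  cat(sprintf("  potential DEGs: %d (OR > %.3f, alpha = %g, B = %d)\n",
              nrow(x$genes), x$threshold, x$config$alpha, x$config$B))
  if (nrow(x$genes) > 0) {
    cat(sprintf("  relaxed selection: %d genes; strong selection: %d genes\n",
                sum(x$genes$relaxed), sum(x$genes$strong)))
    cat(sprintf("  expected false-positive neighbours: %.2f (null proportion %.2f%%)\n",
                x$expected_fp, x$null_proportion))
    cat(sprintf("  clusters: %d (sizes %s)\n", x$k,
                paste(x$clusters$n_genes, collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.degor_fit <- function(object, ...) {
  print(object)
  if (nrow(object$clusters) > 0) {
    cat("\nCluster characteristics (ordered by decreasing mean OR):\n")
    print(dplyr::select(object$clusters, -"genes"))
  }
  invisible(object$clusters)
}
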