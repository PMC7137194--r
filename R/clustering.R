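#' Strong and relaxed selection flags
#'
#' Strong selection takes potential DEGs whose neighbourhoods contain no
#' retained null case at all (`mean FP == 0`, and hence `dFP == 0`). Relaxed
#' selection takes those whose mean FP falls strictly below the
#' uniform-mixing reference from [expected_fp()]. Strong genes are always a
#' subset of the relaxed set.
#'
#' @param fp Mean FP per potential DEG.
#' @param expected The expected false-positive-neighbour reference value.
#' @return A tibble with logical columns `strong` and `relaxed`.
#' @export
strong_relaxed_flags <- function(fp, expected) {
  if (length(fp) == 0L) stop("no scores supplied")
  tibble::tibble(strong = fp == 0, relaxed = fp < expected)
}

#' Partitioning around medoids on a score table
#'
#' Classic PAM (BUILD initialisation followed by SWAP local search, as
#' implemented in [cluster::pam()]) on Euclidean distances. Deterministic:
#' no random restarts.
#'
#' @param points Numeric matrix, cases in rows (already scaled as desired).
#' @param k Number of clusters, `2 <= k < nrow(points)`.
#' @return List with `assignment` (cluster id per case), `medoids` (row
#'   indices), `cost` (total distance of cases to their medoids), and
#'   `build_cost` (the same total after BUILD only; SWAP never exceeds it).
#' @export
pam_cluster <- function(points, k) {
  points <- as.matrix(points)
  m <- nrow(points)
  if (k < 2L || k >= m) stop("k must satisfy 2 <= k < number of cases")
  fit <- cluster::pam(points, k = k, metric = "euclidean", keep.diss = FALSE,
                      keep.data = FALSE, do.swap = TRUE, cluster.only = FALSE)
  medoids <- fit$id.med
  dm <- as.matrix(stats::dist(points))
  assignment <- apply(dm[, medoids, drop = FALSE], 1, which.min)
  cost <- sum(dm[cbind(seq_len(m), medoids[assignment])])
  list(assignment = as.integer(assignment), medoids = as.integer(medoids),
       cost = cost, build_cost = unname(fit$objective["build"]) * m)
}

#' Mean silhouette width of a clustering
#'
#' `s(i) = (b_i - a_i) / max(a_i, b_i)` with `a_i` the mean distance to the
#' other members of i's cluster and `b_i` the smallest mean distance to any
#' other cluster; members of singleton clusters score 0.
#'
#' @param points Numeric matrix, cases in rows.
#' @param assignment Integer cluster labels (at least two distinct).
#' @return Mean silhouette width over all cases.
#' @export
mean_silhouette <- function(points, assignment) {
  if (length(unique(assignment)) < 2L) stop("at least two clusters are required")
  sil <- cluster::silhouette(as.integer(factor(assignment)), stats::dist(as.matrix(points)))
  mean(sil[, "sil_width"])
}

#' Choose the number of clusters by silhouette analysis
#'
#' Runs [pam_cluster()] for `k = 2, ..., min(numclustoseek, m - 1)` and
#' returns the k maximising the mean silhouette width (smallest k on ties).
#'
#' @param points Numeric matrix, cases in rows (`m > 3`).
#' @param numclustoseek Largest k considered (default 10).
#' @return List with `k`, and `silhouette`: a tibble of candidate k and
#'   mean silhouette widths.
#' @export
choose_k <- function(points, numclustoseek = 10) {
  m <- nrow(points)
  if (m <= 3L) stop("too few cases to select a cluster count")
  ks <- 2:min(numclustoseek, m - 1L)
  widths <- purrr::map_dbl(ks, function(k) {
    mean_silhouette(points, pam_cluster(points, k)$assignment)
  })
  list(k = ks[which.max(widths)],
       silhouette = tibble::tibble(k = ks, avg_width = widths))
}

# z-score columns; constant columns map to 0 so they carry no weight in the
# clustering distance
zscore_columns <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  sds[!is.finite(sds) | sds == 0] <- 1
  out <- sweep(sweep(x, 2, mu, "-"), 2, sds, "/")
  out
}

#' Cluster potential DEGs on their (OR, FP, dFP) indexes
#'
#' z-scores the three index columns, clusters with PAM, selects k by
#' silhouette when not supplied, and renumbers clusters by decreasing mean
#' OR so cluster 1 always holds the most differentially expressed genes.
#'
#' @param scores Data frame with columns `or`, `fp`, `dfp` (one row per
#'   potential DEG).
#' @param k Number of clusters; `NULL` (default) selects it by silhouette.
#' @param numclustoseek Largest k considered during selection.
#' @return List with `cluster` (renumbered assignment), `k`, and the
#'   silhouette tibble (`NULL` when k was supplied).
#' @export
cluster_scores <- function(scores, k = NULL, numclustoseek = 10) {
  pts <- zscore_columns(as.matrix(scores[, c("or", "fp", "dfp")]))
  sil <- NULL
  if (is.null(k)) {
    sel <- choose_k(pts, numclustoseek)
    k <- sel$k
    sil <- sel$silhouette
  }
  raw <- pam_cluster(pts, k)$assignment
  # renumber by decreasing within-cluster mean OR
  means <- purrr::map_dbl(seq_len(k), function(cl) mean(scores$or[raw == cl]))
  relabel <- match(seq_len(k), order(means, decreasing = TRUE))
  list(cluster = relabel[raw], k = k, silhouette = sil)
}

#' Per-cluster summary of potential DEGs
#'
#' @param genes Tibble with columns `gene`, `or`, `fp`, `dfp`, `cluster`.
#' @return Tibble with one row per cluster (ordered by cluster number, i.e.
#'   decreasing mean OR): gene count, mean and sd of each index, and a
#'   list-column of member gene labels.
#' @export
summarize_clusters <- function(genes) {
  genes |>
    dplyr::group_by(cluster) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      or_mean = mean(or), or_sd = stats::sd(or),
      fp_mean = mean(fp), fp_sd = stats::sd(fp),
      dfp_mean = mean(dfp), dfp_sd = stats::sd(dfp),
      genes = list(gene),
      .groups = "drop"
    ) |>
    dplyr::arrange(cluster)
}
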