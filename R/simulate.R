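#' Simulate a two-condition expression study with known ground truth
#'
#' Generates the benchmark design used throughout the package: `n_genes`
#' genes measured in `s1` + `s2` samples. Non-DE genes draw every sample
#' from N(0, 1) in both conditions. Each DE gene g draws condition 1 from
#' N(0, 1) and condition 2 from N(mu_g, 1) with `|mu_g| = Delta_g` and a
#' random sign; Delta sets the effect size. DE genes are spread as evenly as
#' possible over the Delta set (remainders to the smaller values first)
#' unless explicit per-Delta counts are given, and are placed at random
#' gene positions.
#'
#' @param n_genes Total genes (default 1000).
#' @param n_de Number of DE genes (default 100).
#' @param deltas Effect sizes available (default `c(1.5, 2, 3)`).
#' @param delta_counts Optional integer vector (same length as `deltas`)
#'   giving the exact number of DE genes per Delta; must sum to `n_de`.
#' @param s1,s2 Samples per condition (default 30 each; at least 3).
#' @param seed Integer seed.
#' @return A tibble of class `degor_sim`, one row per gene: `gene`, `de`
#'   (0/1 truth flag), `delta`, `mu` (signed shift), then the `s1` condition-1
#'   columns (`C1_*`) and `s2` condition-2 columns (`C2_*`). Attributes `s1`,
#'   `s2`, and `seed` record the design.
#' @examples
#' sim <- simulate_study(n_genes = 50, n_de = 5, s1 = 10, s2 = 10, seed = 1)
#' table(sim$delta)
#' @export
simulate_study <- function(n_genes = 1000, n_de = 100, deltas = c(1.5, 2, 3),
                           delta_counts = NULL, s1 = 30, s2 = 30, seed = 0) {
  if (n_de > n_genes || n_de < 0) stop("n_de must lie between 0 and n_genes")
  if (s1 < 3 || s2 < 3) stop("at least 3 samples per condition are required")
  if (is.null(delta_counts)) {
    base <- n_de %/% length(deltas)
    extra <- n_de %% length(deltas)
    delta_counts <- rep(base, length(deltas)) + (seq_along(deltas) <= extra)
  }
  if (length(delta_counts) != length(deltas) || sum(delta_counts) != n_de) {
    stop("delta_counts must match deltas and sum to n_de")
  }
  set.seed(seed)
  de_idx <- sort(sample.int(n_genes, n_de))
  delta <- numeric(n_genes)
  delta[de_idx] <- sample(rep(deltas, delta_counts))
  mu <- delta * sample(c(-1, 1), n_genes, replace = TRUE)
  mu[delta == 0] <- 0

  cond1 <- matrix(stats::rnorm(n_genes * s1), n_genes, s1)
  cond2 <- matrix(stats::rnorm(n_genes * s2, mean = rep(mu, s2)), n_genes, s2)
  labels <- paste0("Gene", seq_len(n_genes))

  out <- tibble::tibble(
    gene = labels,
    de = as.integer(delta > 0),
    delta = delta,
    mu = mu
  )
  colnames(cond1) <- paste0("C1_", seq_len(s1))
  colnames(cond2) <- paste0("C2_", seq_len(s2))
  out <- dplyr::bind_cols(out, tibble::as_tibble(cond1), tibble::as_tibble(cond2))
  attr(out, "s1") <- s1
  attr(out, "s2") <- s2
  attr(out, "seed") <- seed
  class(out) <- c("degor_sim", class(out))
  out
}

#' Extract the two condition matrices from a simulated study
#'
#' @param sim A `degor_sim` tibble from [simulate_study()].
#' @return List with matrices `cond1` and `cond2` (genes x samples, gene
#'   labels as row names).
#' @export
study_matrices <- function(sim) {
  s1 <- attr(sim, "s1")
  c1 <- as.matrix(sim[, grep("^C1_", names(sim)), drop = FALSE])
  c2 <- as.matrix(sim[, grep("^C2_", names(sim)), drop = FALSE])
  stopifnot(ncol(c1) == s1)
  rownames(c1) <- rownames(c2) <- sim$gene
  list(cond1 = c1, cond2 = c2)
}

#' Write / read a simulated study in the flat benchmark layout
#'
#' The file layout is: gene labels as row names, column 1 the DE truth flag,
#' column 2 Delta, columns `3..(2+s1)` the condition-1 expressions and the
#' remaining `s2` columns the condition-2 expressions (tab-separated, with
#' header).
#'
#' @param sim A `degor_sim` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_study <- function(sim, path) {
  df <- as.data.frame(sim[, setdiff(names(sim), "mu")])
  rownames(df) <- df$gene
  df$gene <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_study
#' @param s1 Number of condition-1 columns in the file being read.
#' @export
read_study <- function(path, s1 = 30) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  s2 <- ncol(df) - 2L - s1
  if (s2 < 1L) stop("file has too few expression columns for the given s1")
  out <- tibble::tibble(
    gene = rownames(df),
    de = as.integer(df[[1]]),
    delta = as.numeric(df[[2]]),
    mu = NA_real_
  )
  expr <- as.matrix(df[, -(1:2), drop = FALSE])
  colnames(expr) <- c(paste0("C1_", seq_len(s1)), paste0("C2_", seq_len(s2)))
  out <- dplyr::bind_cols(out, tibble::as_tibble(expr))
  attr(out, "s1") <- s1
  attr(out, "s2") <- s2
  class(out) <- c("degor_sim", class(out))
  out
}

#' Score a detection result against simulated ground truth
#'
#' Cross-tabulates a fitted result's selected genes against the simulator's
#' DE flags: overall true/false positives and false negatives, plus the
#' per-Delta, per-cluster distribution of identified DEGs with their
#' strong/relaxed breakdown.
#'
#' @param sim The `degor_sim` study the result was fitted on.
#' @param result A `degor_fit` from [find_degs()].
#' @param selection `"relaxed"` (default) or `"strong"`: which selection
#'   defines "identified as DE".
#' @return List with `totals` (one-row tibble: tp, fp, fn, sensitivity) and
#'   `strata` (tibble: delta x cluster counts of identified DEGs, with
#'   strong/relaxed splits and the true gene count `n` per Delta stratum).
#' @export
detection_table <- function(sim, result, selection = c("relaxed", "strong")) {
  selection <- match.arg(selection)
  genes <- result$genes
  if (!all(genes$gene %in% sim$gene)) stop("gene labels do not match the simulated study")
  truth <- sim[, c("gene", "de", "delta")]
  joined <- dplyr::left_join(truth, genes, by = "gene") |>
    dplyr::mutate(
      selected = dplyr::coalesce(.data[[selection]], FALSE),
      strong = dplyr::coalesce(.data$strong, FALSE),
      relaxed = dplyr::coalesce(.data$relaxed, FALSE)
    )
  tp <- sum(joined$selected & joined$de == 1)
  fp <- sum(joined$selected & joined$de == 0)
  fn <- sum(!joined$selected & joined$de == 1)
  totals <- tibble::tibble(tp = tp, fp = fp, fn = fn,
                           sensitivity = tp / max(tp + fn, 1L))
  n_per_delta <- truth |>
    dplyr::filter(.data$de == 1) |>
    dplyr::count(.data$delta, name = "n_true")
  list(totals = totals,
       strata = joined |>
         dplyr::filter(.data$selected) |>
         dplyr::group_by(.data$delta, .data$cluster) |>
         dplyr::summarise(identified = dplyr::n(),
                          strong = sum(.data$strong),
                          relaxed = sum(.data$relaxed),
                          .groups = "drop") |>
         dplyr::left_join(n_per_delta, by = "delta"))
}
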