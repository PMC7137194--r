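#' Read a genes x samples expression matrix from delimited text
#'
#' Accepts TSV or CSV with a header row; if the first column is
#' non-numeric it is taken as gene labels, otherwise genes are auto-labelled
#' `Gene1 ... Genen`. Every body cell must be a finite number; the first
#' offending cell is reported by gene and column.
#'
#' @param path File path.
#' @param format `"tsv"` or `"csv"`; default guesses from the extension.
#' @return Numeric matrix with unique gene row names.
#' @export
read_expression_matrix <- function(path, format = c("auto", "tsv", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) == 0L) stop("empty table: ", path)
  first_numeric <- suppressWarnings(as.numeric(df[[1]]))
  if (all(!is.na(first_numeric))) {
    labels <- paste0("Gene", seq_len(nrow(df)))
  } else {
    labels <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
  }
  if (anyDuplicated(labels)) {
    stop("duplicate gene labels: ", paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  m <- matrix(NA_real_, nrow(df), ncol(df),
              dimnames = list(labels, colnames(df)))
  for (j in seq_len(ncol(df))) {
    col <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(col) | !is.finite(col))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric or missing value at gene '%s', column '%s'",
                   labels[bad[1]], colnames(df)[j]))
    }
    m[, j] <- col
  }
  m
}

#' Write the results of a DEG analysis to a directory
#'
#' Emits `potential_degs.tsv` (gene, or, fp, dfp, strong, relaxed, cluster),
#' `summary.json` (configuration echo, expected false-positive neighbours,
#' null proportion, threshold, and per-cluster characteristics), and
#' `run.log`.
#'
#' @param fit A `degor_fit` from [find_degs()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_results <- function(fit, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2) != 0) stop("directory not writable: ", dir)
  readr::write_tsv(fit$genes, file.path(dir, "potential_degs.tsv"))
  summary <- list(
    config = fit$config,
    n_genes = fit$n_genes,
    n_potential = nrow(fit$genes),
    n_relaxed = sum(fit$genes$relaxed),
    n_strong = sum(fit$genes$strong),
    expected_fp = fit$expected_fp,
    null_proportion = fit$null_proportion,
    threshold = fit$threshold,
    k = fit$k,
    clusters = if (nrow(fit$clusters) > 0) {
      dplyr::select(fit$clusters, -"genes")
    } else {
      list()
    }
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(c(
    sprintf("degor %s", as.character(utils::packageVersion("degor"))),
    sprintf("seed: %s", fit$config$seed),
    sprintf("potential DEGs: %d of %s genes", nrow(fit$genes), fit$n_genes),
    sprintf("written: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  ), file.path(dir, "run.log"))
  invisible(dir)
}

#' Re-read a results directory written by [write_results()]
#'
#' @param dir Results directory.
#' @return List with `genes` (tibble) and `summary` (parsed JSON list).
#' @export
read_results <- function(dir) {
  genes <- readr::read_tsv(file.path(dir, "potential_degs.tsv"),
                           show_col_types = FALSE)
  summary <- jsonlite::read_json(file.path(dir, "summary.json"),
                                 simplifyVector = TRUE)
  list(genes = genes, summary = summary)
}
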