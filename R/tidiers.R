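#' Tidy a fitted DEG analysis
#'
#' Returns the per-gene score table: one row per potential DEG with its
#' outlier ratio, neighbourhood false-positive indexes, selection flags and
#' cluster.
#'
#' @param x A `degor_fit`.
#' @param ... Ignored.
#' @return A tibble with columns `gene`, `or`, `fp`, `dfp`, `strong`,
#'   `relaxed`, `cluster`.
#' @export
tidy.degor_fit <- function(x, ...) {
  x$genes
}

#' One-row summary of a fitted DEG analysis
#'
#' @param x A `degor_fit`.
#' @param ... Ignored.
#' @return A one-row tibble: gene counts at each stage, the selection
#'   reference values, the OR threshold and the cluster count.
#' @export
glance.degor_fit <- function(x, ...) {
  tibble::tibble(
    n_genes = x$n_genes,
    n_potential = nrow(x$genes),
    n_relaxed = sum(x$genes$relaxed),
    n_strong = sum(x$genes$strong),
    expected_fp = x$expected_fp,
    null_proportion = x$null_proportion,
    threshold = x$threshold,
    k = x$k
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
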