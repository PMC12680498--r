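#' Quality-control filter for nuclei
#'
#' Keeps nuclei with a detected-gene count between `min_genes` and
#' `max_genes` (inclusive) and fewer than `max_umi` total UMIs (strict
#' bound). Genes with zero total count across the retained nuclei are then
#' dropped. The filter is idempotent.
#'
#' @param m A [cell_matrix()].
#' @param min_genes,max_genes Inclusive detected-gene bounds.
#' @param max_umi Exclusive UMI bound.
#' @return Filtered [cell_matrix()].
#' @export
qc_filter <- function(m, min_genes = 200, max_genes = 7500, max_umi = 15000) {
  stopifnot(inherits(m, "cell_matrix"))
  detected <- Matrix::colSums(m$counts > 0)
  umi <- Matrix::colSums(m$counts)
  keep <- detected >= min_genes & detected <= max_genes & umi < max_umi
  if (!any(keep)) stop("quality control removed every cell")
  counts <- m$counts[, keep, drop = FALSE]
  counts <- counts[Matrix::rowSums(counts) > 0, , drop = FALSE]
  cell_matrix(counts, m$samples[keep])
}

#' Log-normalize a count matrix
#'
#' Per-cell library normalization followed by a natural-log transform:
#' `ln(1 + count * scale / cell_total)`. Zeros stay zero, so sparsity is
#' preserved; values depend only on within-cell proportions.
#'
#' @param m A [cell_matrix()] (after [qc_filter()]).
#' @param scale Scale factor (default 1e4).
#' @return A sparse `dgCMatrix` of normalized values with the input
#'   dimnames; the per-cell sample labels are kept in
#'   `attr(,"samples")`.
#' @export
log_normalize <- function(m, scale = 10000) {
  stopifnot(inherits(m, "cell_matrix"))
  counts <- m$counts
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) stop("cell with zero total count; run qc_filter first")
  norm <- counts
  per_entry <- rep.int(totals, diff(norm@p))
  norm@x <- log1p(norm@x * scale / per_entry)
  attr(norm, "samples") <- m$samples
  norm
}
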