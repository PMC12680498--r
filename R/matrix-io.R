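#' Construct a gene-by-cell count container
#'
#' @param counts Sparse (or dense) non-negative integer matrix, genes in
#'   rows and cells in columns, with unique dimnames.
#' @param samples Sample-of-origin label per cell. If `NULL`, labels are
#'   taken from the barcode suffix after the last `-`.
#' @return An object of class `"cell_matrix"`: a list with elements `counts`
#'   (a `dgCMatrix`), and `samples` (named character vector, one per cell).
#' @export
cell_matrix <- function(counts, samples = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene and barcode dimnames")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate cell barcodes")
  if (any(counts@x < 0)) stop("negative counts are not allowed")
  if (any(counts@x != round(counts@x))) stop("counts must be integers")
  if (is.null(samples)) {
    samples <- sub("^.*-", "", colnames(counts))
  }
  samples <- stats::setNames(as.character(samples), colnames(counts))
  if (length(samples) != ncol(counts)) {
    stop("one sample label per cell is required")
  }
  structure(list(counts = counts, samples = samples), class = "cell_matrix")
}

#' @exportS3Method print cell_matrix
print.cell_matrix <- function(x, ...) {
  cat("cell_matrix: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " cells (", format(length(x$counts@x), big.mark = ","),
      " nonzero); samples: ",
      paste(names(table(x$samples)), table(x$samples),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read a MatrixMarket gene-by-cell matrix directory
#'
#' Expects the droplet-pipeline layout: `matrix.mtx` (triplet MatrixMarket),
#' `features.tsv` (gene ids in column 1) and `barcodes.tsv` (one barcode per
#' line). The per-cell sample label comes from the barcode suffix after the
#' last `-` unless a `samples.tsv` file (barcode TAB sample) is present.
#'
#' @param dir Directory holding the three files.
#' @return A [cell_matrix()].
#' @export
read_cell_matrix <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  feats <- utils::read.table(file.path(dir, "features.tsv"), sep = "\t",
                             header = FALSE, stringsAsFactors = FALSE)
  bcs <- readLines(file.path(dir, "barcodes.tsv"))
  if (nrow(m) != nrow(feats) || ncol(m) != length(bcs)) {
    stop("dimension mismatch: matrix is ", nrow(m), " x ", ncol(m),
         " but features/barcodes give ", nrow(feats), " x ", length(bcs))
  }
  dimnames(m) <- list(feats[[1L]], bcs)
  samples_file <- file.path(dir, "samples.tsv")
  samples <- NULL
  if (file.exists(samples_file)) {
    st <- utils::read.table(samples_file, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    samples <- st[[2L]][match(bcs, st[[1L]])]
  }
  cell_matrix(m, samples)
}

#' Write a cell_matrix as a MatrixMarket directory
#'
#' @param x A [cell_matrix()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cell_matrix <- function(x, dir) {
  stopifnot(inherits(x, "cell_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(x$counts), file.path(dir, "features.tsv"))
  writeLines(colnames(x$counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(
    data.frame(barcode = colnames(x$counts), sample = unname(x$samples)),
    file.path(dir, "samples.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(dir)
}

#' Merge cell matrices from several samples on their shared genes
#'
#' @param ... Two or more [cell_matrix()] objects with disjoint barcodes.
#' @return A single [cell_matrix()] restricted to the genes present in all
#'   inputs.
#' @export
merge_cell_matrices <- function(...) {
  xs <- list(...)
  stopifnot(length(xs) >= 2L, all(vapply(xs, inherits, TRUE, "cell_matrix")))
  genes <- Reduce(intersect, lapply(xs, function(x) rownames(x$counts)))
  if (!length(genes)) stop("no shared genes between samples")
  counts <- do.call(cbind, lapply(xs, function(x) x$counts[genes, , drop = FALSE]))
  samples <- do.call(c, lapply(xs, function(x) x$samples))
  cell_matrix(counts, samples)
}
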