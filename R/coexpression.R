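#' Intersect SV-proximal genes with differentially expressed genes
#'
#' The final candidate-gene step: genes that both lie near (or in) a
#' focal-unique SV and are differentially expressed between the cultivars.
#' Counting is over deduplicated gene ids; when the full evidence tables are
#' supplied, each candidate is annotated with its supporting SVs/distances
#' and DEG statistics.
#'
#' @param sv_genes Character vector of SV-linked gene ids, or a links table
#'   from [link_genes_to_svs()].
#' @param degs Character vector of DEG ids, a [find_group_degs()] result, or
#'   its `genes` summary table.
#' @return `data.frame` sorted by gene id with column `gene` plus evidence
#'   columns (`sv_ids`, `min_distance`, `avg_log2FC`, `direction`) where the
#'   inputs carry them.
#' @export
intersect_candidates <- function(sv_genes, degs) {
  links <- NULL
  if (is.data.frame(sv_genes)) {
    links <- sv_genes
    sv_genes <- unique(links$gene_id)
  }
  deg_tab <- NULL
  if (inherits(degs, "deg_result")) degs <- degs$genes
  if (is.data.frame(degs)) {
    deg_tab <- degs
    degs <- unique(deg_tab$gene)
  }
  genes <- sort(intersect(unique(sv_genes), unique(degs)))
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  if (!is.null(links) && nrow(out)) {
    per <- split(links, links$gene_id)
    out$sv_ids <- vapply(out$gene, function(g)
      paste(sort(unique(per[[g]]$sv_id)), collapse = ","), character(1))
    out$min_distance <- vapply(out$gene, function(g)
      min(per[[g]]$distance), numeric(1))
  }
  if (!is.null(deg_tab) && nrow(out)) {
    i <- match(out$gene, deg_tab$gene)
    if ("avg_log2FC" %in% names(deg_tab)) out$avg_log2FC <- deg_tab$avg_log2FC[i]
    if ("direction" %in% names(deg_tab)) out$direction <- deg_tab$direction[i]
  }
  out
}

#' Transcripts-per-million normalization
#'
#' Per sample: reads-per-kilobase `count / (length/1000)` scaled so the
#' column sums to one million. Length-normalizes within gene and
#' depth-normalizes within sample; invariant to scaling all counts of a
#' sample by a constant.
#'
#' @param counts Genes-by-samples matrix of raw counts.
#' @param lengths Gene lengths in bp (named, or aligned with the rows).
#' @return Genes-by-samples TPM matrix.
#' @export
tpm_normalize <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths))) lengths <- lengths[rownames(counts)]
  if (length(lengths) != nrow(counts) || anyNA(lengths)) {
    stop("one length per gene is required")
  }
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  rpk <- counts / (lengths / 1000)
  totals <- colSums(rpk)
  if (any(totals == 0)) {
    stop("sample with zero total count: ",
         colnames(counts)[which(totals == 0)[1L]])
  }
  sweep(rpk, 2L, totals, "/") * 1e6
}

#' Drop expression rows containing zeros
#'
#' @param table Genes-by-samples expression matrix.
#' @param policy `"any_zero"` (default; drop a gene if any sample is zero)
#'   or `"all_zero"` (drop only genes that are zero everywhere).
#' @return The filtered matrix.
#' @export
filter_zero_rows <- function(table, policy = c("any_zero", "all_zero")) {
  policy <- match.arg(policy)
  keep <- if (policy == "any_zero") {
    rowSums(table == 0) == 0
  } else {
    rowSums(table != 0) > 0
  }
  if (!any(keep)) stop("zero-row filtering removed every gene")
  table[keep, , drop = FALSE]
}

#' Pairwise Spearman correlation of expression profiles
#'
#' Rank correlation across samples with average ranks for ties. Genes with a
#' constant profile have an undefined coefficient; their entries are
#' reported as `NA` with a warning, and the diagonal stays 1.
#'
#' @param table Genes-by-samples expression matrix (e.g. TPM).
#' @param genes Optional gene subset.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(table, genes = NULL) {
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(table))
    if (length(missing)) stop("genes absent from table: ",
                              paste(utils::head(missing, 5), collapse = ", "))
    table <- table[genes, , drop = FALSE]
  }
  if (ncol(table) < 3L) stop("at least 3 samples are required")
  constant <- apply(table, 1L, function(r) length(unique(r)) == 1L)
  if (any(constant)) {
    warning(sum(constant), " constant profile(s): coefficients reported as NA")
  }
  rho <- suppressWarnings(stats::cor(t(table), method = "spearman"))
  diag(rho) <- 1
  rho
}

#' Hierarchical leaf ordering of a correlation matrix
#'
#' Average-linkage agglomeration on the distance `1 - rho`; the dendrogram
#' leaf order groups co-expressed genes for display. Missing coefficients
#' are imputed as 0 with a warning.
#'
#' @param corr Correlation matrix from [spearman_matrix()].
#' @return Character vector of gene ids in leaf order (attribute `hclust`
#'   carries the tree).
#' @export
hierarchical_order <- function(corr) {
  corr <- as.matrix(corr)
  if (nrow(corr) == 1L) return(rownames(corr))
  if (anyNA(corr)) {
    warning("missing correlations imputed as 0 for ordering")
    corr[is.na(corr)] <- 0
  }
  hc <- stats::hclust(stats::as.dist(1 - corr), method = "average")
  structure(rownames(corr)[hc$order], hclust = hc)
}
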