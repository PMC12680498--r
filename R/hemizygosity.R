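#' Filter long-read deletion calls for hemizygosity detection
#'
#' Retains calls that are DEL type, have an END coordinate, precise
#' breakpoints, length of at least `min_len` bp, quality of at least
#' `min_qual`, and read support of at least `min_support`. All bounds are
#' inclusive. Records with missing quality or support fail the corresponding
#' bound.
#'
#' @param calls SV-call table from [as_sv_calls()].
#' @param min_len Minimum |SVLEN| in bp.
#' @param min_qual Minimum QUAL.
#' @param min_support Minimum supporting reads.
#' @return The retained subset of `calls`, original order preserved.
#' @export
filter_deletion_calls <- function(calls, min_len = 50, min_qual = 60,
                                  min_support = 4) {
  if (nrow(calls) && anyNA(calls$svtype)) {
    stop("SV call without SVTYPE at row ", which(is.na(calls$svtype))[1L])
  }
  ok <- calls$svtype == "DEL" &
    !is.na(calls$end) &
    calls$precise %in% TRUE &
    !is.na(calls$svlen) & abs(calls$svlen) >= min_len &
    !is.na(calls$qual) & calls$qual >= min_qual &
    !is.na(calls$support) & calls$support >= min_support
  calls[which(ok), , drop = FALSE]
}

#' Call hemizygous genes from filtered deletion intervals
#'
#' A gene present on only one haplotype of a diploid sits inside a
#' heterozygous deletion on the other haplotype. In the default mode a gene
#' is called hemizygous when some deletion interval fully contains the gene
#' body (same chromosome; boundary-equal intervals count). The alternative
#' mode `"deletion_in_gene"` applies the literal converse -- the deletion
#' fully inside the gene -- and is exposed for comparison.
#'
#' @param dels Filtered deletion calls ([filter_deletion_calls()]).
#' @param genes Gene table ([read_gff3()]).
#' @param mode `"gene_in_deletion"` (default) or `"deletion_in_gene"`.
#' @return Sorted character vector of hemizygous gene ids (each once).
#' @export
call_hemizygous_genes <- function(dels, genes,
                                  mode = c("gene_in_deletion",
                                           "deletion_in_gene")) {
  mode <- match.arg(mode)
  if (!nrow(dels) || !nrow(genes)) return(character(0))
  dgr <- GenomicRanges::GRanges(dels$chrom,
                                IRanges::IRanges(dels$pos, dels$end))
  ggr <- genes_as_granges(genes)
  hits <- if (mode == "gene_in_deletion") {
    GenomicRanges::findOverlaps(ggr, dgr, type = "within", ignore.strand = TRUE)
  } else {
    GenomicRanges::findOverlaps(dgr, ggr, type = "within", ignore.strand = TRUE)
  }
  idx <- if (mode == "gene_in_deletion") S4Vectors::queryHits(hits)
         else S4Vectors::subjectHits(hits)
  sort(unique(genes$id[idx]))
}

#' Fraction of genes that are hemizygous
#'
#' @param n_hemi Number of hemizygous genes.
#' @param n_genes Total number of annotated genes.
#' @return `n_hemi / n_genes`.
#' @export
hemizygosity_rate <- function(n_hemi, n_genes) {
  if (n_genes <= 0) stop("n_genes must be positive")
  if (n_hemi > n_genes) stop("n_hemi cannot exceed n_genes")
  n_hemi / n_genes
}
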