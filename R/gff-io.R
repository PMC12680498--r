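#' Read gene models from a GFF3 file
#'
#' Imports a GFF3 annotation through `rtracklayer` and keeps only features of
#' type `gene`, the unit every downstream stage (hemizygosity, SV linking,
#' expression) works with. Coordinates stay 1-based inclusive as on disk.
#'
#' @param path Path to a GFF3 file.
#' @return A `data.frame` with columns `id`, `chrom`, `start`, `end`,
#'   `strand` (one row per gene).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  ids <- if (is.null(gr$ID)) rep(NA_character_, length(gr)) else
    as.character(gr$ID)
  if (length(gr) && (any(is.na(ids)) | any(!nzchar(ids)))) {
    bad <- which(is.na(ids) | !nzchar(ids))
    stop("gene feature without ID attribute (gene feature number ",
         paste(utils::head(bad, 5), collapse = ", "), ")")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate gene IDs in ", path, ": ",
         paste(utils::head(unique(ids[duplicated(ids)]), 5), collapse = ", "))
  }
  df <- data.frame(
    id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  if (any(df$start > df$end)) {
    stop("gene with start > end: ", df$id[which(df$start > df$end)[1L]])
  }
  df
}

#' Write gene models as GFF3
#'
#' @param genes Gene table as returned by [read_gff3()].
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path, source = "panvine") {
  lines <- c(
    "##gff-version 3",
    sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
            genes$chrom, source, genes$start, genes$end,
            ifelse(genes$strand %in% c("+", "-"), genes$strand, "."),
            genes$id)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Convert a gene table to GRanges
#' @param genes Gene table (`id`, `chrom`, `start`, `end`, `strand`).
#' @return A `GRanges` with the gene ids as names.
#' @keywords internal
genes_as_granges <- function(genes) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = ifelse(genes$strand %in% c("+", "-"), genes$strand, "*")
  )
  names(gr) <- genes$id
  gr
}
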