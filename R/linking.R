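#' Link genes to unique SVs within a proximity window
#'
#' Emits one link per (SV, gene) pair whose end-to-end gap is at most
#' `window` bp (inclusive at exactly `window`; bedtools-window semantics).
#' Overlapping or bookended intervals have distance 0 and relation
#' `"overlapping"`; otherwise the relation is `"upstream"`/`"downstream"`
#' relative to the gene's strand. Strand affects only the relation label,
#' never eligibility.
#'
#' @param svs SV interval table with columns `id`, `chrom`, `start`, `end`
#'   (e.g. the output of [find_unique_svs()]).
#' @param genes Gene table ([read_gff3()]).
#' @param window Maximum gap in bp (default 5000).
#' @return `data.frame` with columns `sv_id`, `gene_id`, `distance`,
#'   `relation`.
#' @export
link_genes_to_svs <- function(svs, genes, window = 5000) {
  if (window < 0) stop("window must be non-negative")
  empty <- data.frame(sv_id = character(0), gene_id = character(0),
                      distance = integer(0), relation = character(0),
                      stringsAsFactors = FALSE)
  if (!nrow(svs) || !nrow(genes)) return(empty)
  sgr <- GenomicRanges::GRanges(svs$chrom, IRanges::IRanges(svs$start, svs$end))
  ggr <- genes_as_granges(genes)
  hits <- GenomicRanges::findOverlaps(sgr, ggr, maxgap = window,
                                      ignore.strand = TRUE)
  if (!length(hits)) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  dist <- GenomicRanges::distance(sgr[qi], ggr[si], ignore.strand = TRUE)
  keep <- !is.na(dist) & dist <= window
  qi <- qi[keep]; si <- si[keep]; dist <- dist[keep]
  sv_after_gene <- svs$start[qi] > genes$end[si]
  plus <- genes$strand[si] != "-"
  relation <- ifelse(dist == 0, "overlapping",
                     ifelse(sv_after_gene == plus, "downstream", "upstream"))
  data.frame(sv_id = svs$id[qi], gene_id = genes$id[si],
             distance = as.integer(dist), relation = relation,
             stringsAsFactors = FALSE)
}

#' Hypergeometric over-representation test of a gene set
#'
#' For every annotation term, tests whether the study set contains more
#' term-annotated genes than expected by drawing `n = |study|` genes from
#' the population: upper-tail hypergeometric p-value `P(X >= k)` with
#' Benjamini-Hochberg adjustment across tested terms.
#'
#' @param study Character vector of study gene ids (subset of `population`).
#' @param population Character vector of background gene ids.
#' @param term_map `data.frame` with columns `gene`, `term` (one row per
#'   annotation); genes outside the population are ignored.
#' @param alpha Significance level used for the `significant` flag.
#' @return `data.frame` sorted by adjusted p (ties by raw p then term) with
#'   columns `term`, `k`, `n`, `K`, `N`, `p`, `p_adj`, `significant`.
#' @export
hypergeometric_enrichment <- function(study, population, term_map,
                                      alpha = 0.05) {
  study <- unique(study)
  population <- unique(population)
  if (!all(study %in% population)) {
    stop("study set must be a subset of the population")
  }
  term_map <- term_map[term_map$gene %in% population, , drop = FALSE]
  terms <- sort(unique(term_map$term))
  N <- length(population)
  n <- length(study)
  res <- lapply(terms, function(tm) {
    g <- unique(term_map$gene[term_map$term == tm])
    K <- length(g)
    k <- sum(study %in% g)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, n = n, K = K, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0))
  }
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < alpha
  out[order(out$p_adj, out$p, out$term), , drop = FALSE]
}
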