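# In-code fixture builders and independent brute-force oracles shared
# across test files.

# Write a small VCF text file from parallel vectors; returns the path.
write_vcf_text <- function(records, samples = character(0),
                           path = tempfile(fileext = ".vcf")) {
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (length(samples)) cols <- c(cols, "FORMAT", samples)
  writeLines(c("##fileformat=VCFv4.2",
               paste(cols, collapse = "\t"),
               records), path)
  path
}

# One data line for write_vcf_text.
vcf_line <- function(chrom = "chr01", pos = 100, id = ".", ref = "A",
                     alt = "T", qual = ".", filter = ".", info = ".",
                     gt = NULL) {
  fields <- c(chrom, pos, id, ref, alt, qual, filter, info)
  if (!is.null(gt)) fields <- c(fields, "GT", gt)
  paste(fields, collapse = "\t")
}

# Build an in-memory pan_vcf from a record data.frame (chrom, pos, id, ref,
# alt, gt list-column) -- mirrors the generator's internal constructor.
make_pan_vcf <- function(df, samples) {
  df$qual <- df$qual %||% "."
  df$filter <- "."
  df$info <- df$info %||% "."
  df$format <- "GT"
  attr(df, "samples") <- samples
  attr(df, "header") <- c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  class(df) <- c("pan_vcf", "data.frame")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force all-pairs gene-in-deletion containment.
bf_hemizygous <- function(dels, genes) {
  hit <- logical(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(dels))) {
      if (genes$chrom[i] == dels$chrom[j] &&
          dels$pos[j] <= genes$start[i] && dels$end[j] >= genes$end[i]) {
        hit[i] <- TRUE
        break
      }
    }
  }
  sort(unique(genes$id[hit]))
}

# Brute-force end-to-end gap between two 1-based inclusive intervals
# (0 when they overlap or touch).
bf_gap <- function(s1, e1, s2, e2) {
  if (e1 < s2) return(max(0L, s2 - e1 - 1L))
  if (e2 < s1) return(max(0L, s1 - e2 - 1L))
  0L
}

# Exact two-sided Wilcoxon p by enumerating every assignment of the pooled
# values into groups of the observed sizes.
bf_wilcox_enum <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  splits <- utils::combn(length(pooled), nx)
  us <- apply(splits, 2L, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * length(y) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Exact upper-tail hypergeometric P(X >= k) by direct tail summation.
bf_hyper_tail <- function(k, K, N, n) {
  kk <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Rank-then-Pearson Spearman oracle with average ranks.
bf_spearman <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  num <- sum((ra - mean(ra)) * (rb - mean(rb)))
  den <- sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  num / den
}

# Small deterministic single-cell dataset used by several expression tests.
# min_genes scales the QC bound down for reduced gene catalogs.
sc_fixture <- function(seed = 11, min_genes = 200, ...) {
  sim <- simulate_single_cell(seed = seed, ...)
  m <- merge_cell_matrices(sim$matrices[[1]], sim$matrices[[2]])
  q <- qc_filter(m, min_genes = min_genes)
  list(sim = sim, merged = m, qc = q, norm = log_normalize(q))
}
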