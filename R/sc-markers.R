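#' Wilcoxon rank-sum test
#'
#' Rank-sum test with average ranks for ties. The p-value is exact
#' (Mann-Whitney null distribution) when both groups are tie-free and the
#' smaller group has at most 8 observations; otherwise a normal
#' approximation with tie-corrected variance, continuity correction, and an
#' Edgeworth kurtosis term is used (the higher-order term keeps the
#' approximation within |dp| <= 0.01 of the exact tail even at n = m = 8).
#'
#' @param x,y Numeric value vectors for the two groups (non-empty).
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact branch;
#'   `NULL` (default) chooses automatically. The exact branch is undefined
#'   in the presence of ties.
#' @return List with `statistic` (Mann-Whitney U for `x`), `p.value` and
#'   `method`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact = NULL) {
  nx <- length(x); ny <- length(y)
  if (!nx || !ny) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- if (is.null(exact)) !ties && min(nx, ny) <= 8L else isTRUE(exact)
  if (use_exact && ties) stop("exact p-value is undefined with ties")
  if (use_exact) {
    p <- min(1, 2 * min(stats::pwilcox(u, nx, ny),
                        stats::pwilcox(u - 1, nx, ny, lower.tail = FALSE)))
    return(list(statistic = u, p.value = p, method = "exact"))
  }
  n <- nx + ny
  mu <- nx * ny / 2
  tie_tab <- table(r)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 == 0) return(list(statistic = u, p.value = 1, method = "approx"))
  s <- sqrt(sigma2)
  g2 <- -(6 / 5) * (nx^2 + ny^2 + nx * ny + n) / (nx * ny * (n + 1))
  lower_tail <- function(q) {
    z <- (q + 0.5 - mu) / s
    stats::pnorm(z) - stats::dnorm(z) * (z^3 - 3 * z) * g2 / 24
  }
  p <- min(1, max(0, 2 * min(lower_tail(u), 1 - lower_tail(u - 1))))
  list(statistic = u, p.value = p, method = "approx")
}

# Shared mechanics of the marker and DEG tests: expression-fraction screen,
# back-transformed log2 fold change, Wilcoxon p, Bonferroni over tested genes.
.test_two_groups <- function(norm, cells_in, cells_out, min_pct, logfc_min,
                             two_sided) {
  sub_in <- norm[, cells_in, drop = FALSE]
  sub_out <- norm[, cells_out, drop = FALSE]
  pct1 <- Matrix::rowMeans(sub_in > 0)
  pct2 <- Matrix::rowMeans(sub_out > 0)
  tested <- pmax(pct1, pct2) >= min_pct
  n_tested <- sum(tested)
  mean_in <- Matrix::rowMeans(expm1(sub_in))
  mean_out <- Matrix::rowMeans(expm1(sub_out))
  log2fc <- log2((mean_in + 1) / (mean_out + 1))
  keep <- tested & if (two_sided) abs(log2fc) >= logfc_min else
    log2fc >= logfc_min
  idx <- which(keep)
  if (!length(idx)) {
    return(data.frame(gene = character(0), avg_log2FC = numeric(0),
                      pct.1 = numeric(0), pct.2 = numeric(0),
                      p_val = numeric(0), p_val_adj = numeric(0),
                      stringsAsFactors = FALSE))
  }
  dense_in <- as.matrix(sub_in[idx, , drop = FALSE])
  dense_out <- as.matrix(sub_out[idx, , drop = FALSE])
  p <- vapply(seq_along(idx), function(j) {
    wilcoxon_rank_sum(dense_in[j, ], dense_out[j, ])$p.value
  }, numeric(1))
  data.frame(gene = rownames(norm)[idx],
             avg_log2FC = log2fc[idx],
             pct.1 = pct1[idx], pct.2 = pct2[idx],
             p_val = p,
             p_val_adj = pmin(1, p * n_tested),
             stringsAsFactors = FALSE)
}

#' Find cluster marker genes (one-vs-rest)
#'
#' For every cluster, compares its cells against all other cells. A gene is
#' tested when it is expressed (count > 0) in at least `min_pct` of either
#' group; retained markers must reach `logfc_min` average log2 fold change
#' (positive-only by default). Fold change is computed on back-transformed
#' normalized means with a pseudocount of 1; adjusted p-values are
#' Bonferroni over the genes tested in the comparison.
#'
#' @param norm Normalized matrix ([log_normalize()]).
#' @param labels Cluster label per cell (same order as columns).
#' @param only_positive Keep only positively enriched markers.
#' @param min_pct Expression-fraction screen (default 0.25).
#' @param logfc_min Fold-change threshold (default 0.25).
#' @return `data.frame` with columns `gene`, `cluster`, `avg_log2FC`,
#'   `pct.1`, `pct.2`, `p_val`, `p_val_adj`.
#' @export
find_markers <- function(norm, labels, only_positive = TRUE, min_pct = 0.25,
                         logfc_min = 0.25) {
  labels <- as.vector(labels)
  stopifnot(length(labels) == ncol(norm))
  clusters <- sort(unique(labels))
  if (length(clusters) < 2L) stop("marker detection needs >= 2 clusters")
  out <- lapply(clusters, function(cl) {
    cells_in <- which(labels == cl)
    if (length(cells_in) < 3L) {
      warning("cluster ", cl, " has fewer than 3 cells; skipped")
      return(NULL)
    }
    res <- .test_two_groups(norm, cells_in, which(labels != cl),
                            min_pct, logfc_min, two_sided = !only_positive)
    if (nrow(res)) res$cluster <- cl
    res
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(out) <- NULL
  out[, c("gene", "cluster", "avg_log2FC", "pct.1", "pct.2",
          "p_val", "p_val_adj")]
}

#' Cross-sample differential expression per cluster
#'
#' Within each cluster, tests sample A versus sample B with the marker
#' mechanics but two-sided retention (`|avg_log2FC| >= logfc_min`), where A
#' is the alphabetically first sample label; `pct.1`/`pct.2` and the fold
#' change refer to A over B, and `direction` records which sample the gene
#' is up in. Clusters missing either sample (or with < 3 cells of one) are
#' skipped with a warning. The result carries both the per-cluster rows and
#' a deduplicated gene-level summary whose direction comes from the
#' largest-|log2FC| cluster.
#'
#' @param norm Normalized matrix ([log_normalize()]).
#' @param labels Cluster label per cell.
#' @param sample_of_cell Sample label per cell (exactly two levels overall).
#' @param min_pct Expression-fraction screen (default 0.1).
#' @param logfc_min Fold-change retention threshold (default 0.25); 0 keeps
#'   every tested gene, which is how the null calibration of the test is
#'   examined.
#' @return List of class `"deg_result"`: `table` (per cluster-gene rows:
#'   `gene`, `cluster`, `avg_log2FC`, `pct.1`, `pct.2`, `p_val`,
#'   `p_val_adj`, `direction`) and `genes` (deduplicated summary).
#' @export
find_group_degs <- function(norm, labels, sample_of_cell, min_pct = 0.1,
                            logfc_min = 0.25) {
  labels <- as.vector(labels)
  sample_of_cell <- as.character(sample_of_cell)
  stopifnot(length(labels) == ncol(norm),
            length(sample_of_cell) == ncol(norm))
  lev <- sort(unique(sample_of_cell))
  if (length(lev) != 2L) stop("exactly two samples are required")
  out <- lapply(sort(unique(labels)), function(cl) {
    in_cl <- labels == cl
    a <- which(in_cl & sample_of_cell == lev[1L])
    b <- which(in_cl & sample_of_cell == lev[2L])
    if (length(a) < 3L || length(b) < 3L) {
      warning("cluster ", cl, " lacks enough cells of both samples; skipped")
      return(NULL)
    }
    res <- .test_two_groups(norm, a, b, min_pct, logfc_min, two_sided = TRUE)
    if (nrow(res)) {
      res$cluster <- cl
      res$direction <- ifelse(res$avg_log2FC > 0,
                              paste0("up_in_", lev[1L]),
                              paste0("up_in_", lev[2L]))
    }
    res
  })
  tab <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(tab)) stop("no cluster contained both samples")
  rownames(tab) <- NULL
  tab <- tab[, c("gene", "cluster", "avg_log2FC", "pct.1", "pct.2",
                 "p_val", "p_val_adj", "direction")]
  best <- tab[order(-abs(tab$avg_log2FC), tab$p_val), ]
  best <- best[!duplicated(best$gene), ]
  genes <- data.frame(gene = best$gene, avg_log2FC = best$avg_log2FC,
                      direction = best$direction, cluster = best$cluster,
                      p_val = best$p_val, p_val_adj = best$p_val_adj,
                      n_clusters = as.vector(table(tab$gene)[best$gene]),
                      stringsAsFactors = FALSE)
  genes <- genes[order(genes$gene), ]
  rownames(genes) <- NULL
  structure(list(table = tab, genes = genes), class = "deg_result")
}

#' Top-n markers per cluster by average log2 fold change
#'
#' Stable sort by decreasing `avg_log2FC`, ties broken by ascending raw p
#' then gene id; at most `n` rows are kept per cluster.
#'
#' @param records Marker table from [find_markers()].
#' @param n Markers to keep per cluster (10, 20 and 50 are the usual report
#'   sizes).
#' @return Subset of `records`, grouped by cluster.
#' @export
rank_top_markers <- function(records, n = 10) {
  parts <- split(records, records$cluster)
  out <- lapply(parts, function(df) {
    df <- df[order(-df$avg_log2FC, df$p_val, df$gene), , drop = FALSE]
    utils::head(df, n)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
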