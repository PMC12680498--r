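#' Standardized per-gene variance after mean-variance trend removal
#'
#' Fits a loess trend of log10 variance on log10 mean across expressed
#' genes, standardizes each gene's values by the trend-expected standard
#' deviation (clipped at sqrt(number of cells)), and returns the variance of
#' the standardized values. Genes with zero variance get 0. With too few
#' variable genes to fit a trend the raw variance is used.
#'
#' @param mat Genes-by-cells matrix (counts or normalized values).
#' @param loess_span Span of the mean-variance trend fit.
#' @return Named numeric vector of standardized variances.
#' @keywords internal
standardized_variance <- function(mat, loess_span = 0.3) {
  mat <- methods::as(mat, "CsparseMatrix")
  n <- ncol(mat)
  mu <- Matrix::rowMeans(mat)
  ex2 <- Matrix::rowMeans(mat^2)
  v <- (ex2 - mu^2) * n / max(n - 1, 1)
  out <- stats::setNames(numeric(nrow(mat)), rownames(mat))
  use <- v > 0 & mu > 0
  if (sum(use) < 5L) {
    out[use] <- v[use]
    return(out)
  }
  fit <- try(stats::loess(log10(v[use]) ~ log10(mu[use]), span = loess_span,
                          degree = 2), silent = TRUE)
  if (inherits(fit, "try-error")) {
    out[use] <- v[use]
    return(out)
  }
  sd_exp <- sqrt(10^stats::fitted(fit))
  clip <- sqrt(n)
  dense <- as.matrix(mat[use, , drop = FALSE])
  z <- (dense - mu[use]) / sd_exp
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  out[use] <- apply(z, 1L, stats::var)
  out
}

#' Select highly variable genes across samples
#'
#' Ranks genes per sample by standardized variance (highest first) and
#' combines samples by the best (minimum) rank, so a gene highly variable in
#' either cultivar is eligible; ties are broken by mean rank, then gene id.
#'
#' @param mats Named list of genes-by-cells matrices sharing a gene
#'   namespace (one per sample), or a single matrix.
#' @param n Number of genes to return (default 3000).
#' @return Character vector of the selected gene ids.
#' @export
select_variable_genes <- function(mats, n = 3000) {
  if (!is.list(mats)) mats <- list(mats)
  genes <- Reduce(intersect, lapply(mats, rownames))
  if (!length(genes)) stop("samples share no genes")
  ranks <- vapply(mats, function(m) {
    sv <- standardized_variance(m[genes, , drop = FALSE])
    rank(-sv, ties.method = "min")
  }, numeric(length(genes)))
  ranks <- matrix(ranks, nrow = length(genes))
  best <- apply(ranks, 1L, min)
  mean_rank <- rowMeans(ranks)
  ord <- order(best, mean_rank, genes)
  if (n > length(genes)) {
    warning("requested ", n, " variable genes but only ", length(genes),
            " are available; returning all")
    n <- length(genes)
  }
  genes[ord][seq_len(n)]
}

#' Principal-component analysis of normalized expression
#'
#' Centers and unit-scales each selected gene across cells, then computes
#' the decomposition. Variance fractions are the component variances over
#' the total variance of the scaled matrix (the number of genes used), so
#' they are comparable across runs and non-increasing.
#'
#' @param norm Genes-by-cells normalized matrix ([log_normalize()]).
#' @param genes Genes to use (default: all rows).
#' @param n_components Number of components to retain.
#' @return List of class `"pca_result"`: `scores` (cells x components),
#'   `fractions` (variance fraction per retained component), `rotation`,
#'   `genes` (genes actually used; zero-variance genes are dropped with a
#'   warning).
#' @export
run_pca <- function(norm, genes = NULL, n_components = 50) {
  if (is.null(genes)) genes <- rownames(norm)
  x <- t(as.matrix(norm[genes, , drop = FALSE]))          # cells x genes
  if (nrow(x) < 2L) stop("PCA needs at least 2 cells")
  if (n_components > min(dim(x))) {
    stop("n_components exceeds min(cells, genes) = ", min(dim(x)))
  }
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance gene(s) dropped before PCA")
    x <- x[, sds > 0, drop = FALSE]
    genes <- colnames(x)
    if (n_components > min(dim(x))) n_components <- min(dim(x))
  }
  x <- scale(x)
  fit <- stats::prcomp(x, center = FALSE, scale. = FALSE, rank. = n_components)
  k <- ncol(fit$x)
  fractions <- fit$sdev[seq_len(k)]^2 / ncol(x)
  structure(list(scores = fit$x, fractions = fractions,
                 rotation = fit$rotation, genes = genes),
            class = "pca_result")
}

#' Choose the number of principal components
#'
#' Applies two rules jointly: take the smallest `j` whose cumulative
#' variance fraction exceeds `cum_threshold` while the next component
#' explains less than `indiv_threshold` (the fraction after the last
#' component is taken as 0). If no `j` qualifies -- possible when the
#' retained components do not reach the cumulative bound -- fall back to the
#' smallest `j` where the drop between consecutive fractions falls below
#' `delta_threshold` (the point where the variance decay stabilizes);
#' otherwise use all components.
#'
#' @param fractions Non-increasing positive variance fractions (or a
#'   `"pca_result"`).
#' @param cum_threshold Cumulative-variance rule (default 0.90).
#' @param indiv_threshold Next-component variance rule (default 0.05).
#' @param delta_threshold Successive-difference stabilization rule
#'   (default 0.001).
#' @return Integer cutoff `k` with an attribute `criterion` naming the rule
#'   that fired (`"cumulative+individual"`, `"delta"`, or `"all"`).
#' @export
select_pc_cutoff <- function(fractions, cum_threshold = 0.90,
                             indiv_threshold = 0.05,
                             delta_threshold = 0.001) {
  if (inherits(fractions, "pca_result")) fractions <- fractions$fractions
  if (!length(fractions)) stop("empty variance-fraction vector")
  if (any(fractions <= 0) || is.unsorted(rev(fractions), strictly = FALSE)) {
    stop("fractions must be positive and non-increasing")
  }
  p <- length(fractions)
  cum <- cumsum(fractions)
  nxt <- c(fractions[-1L], 0)
  ok <- cum > cum_threshold & nxt < indiv_threshold
  if (any(ok)) {
    k <- which(ok)[1L]
    attr(k, "criterion") <- "cumulative+individual"
    return(k)
  }
  drops <- -diff(fractions)
  stable <- which(drops < delta_threshold)
  if (length(stable)) {
    k <- stable[1L]
    attr(k, "criterion") <- "delta"
    return(k)
  }
  k <- p
  attr(k, "criterion") <- "all"
  k
}
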