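#' Joint embedding of two samples without anchor integration
#'
#' A deliberately simple cross-sample embedding: each sample's normalized
#' matrix is restricted to the shared variable genes and gene-scaled within
#' the sample (removing per-sample location/scale shifts), the scaled cells
#' are concatenated, and a single PCA is run on the pooled matrix. A
#' precomputed embedding can be supplied downstream instead, so externally
#' integrated coordinates plug into [cluster_cells()] unchanged.
#'
#' @param norm_list Named list of genes-by-cells normalized matrices.
#' @param genes Genes to embed (e.g. from [select_variable_genes()]).
#' @param n_components Number of components.
#' @return A `"pca_result"` whose scores carry all cells (rownames are the
#'   barcodes, in list order).
#' @export
joint_pca <- function(norm_list, genes, n_components = 50) {
  scaled <- lapply(norm_list, function(m) {
    x <- t(as.matrix(m[genes, , drop = FALSE]))
    sds <- apply(x, 2L, stats::sd)
    sds[sds == 0] <- 1
    scale(x, scale = sds)
  })
  x <- do.call(rbind, scaled)
  if (n_components > min(dim(x))) n_components <- min(dim(x))
  fit <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  fractions <- fit$sdev[seq_len(ncol(fit$x))]^2 / sum(fit$sdev^2)
  structure(list(scores = fit$x, fractions = fractions,
                 rotation = fit$rotation, genes = genes),
            class = "pca_result")
}

.snn_graph <- function(scores, k_neighbors, prune = 1 / 15) {
  n <- nrow(scores)
  d <- as.matrix(stats::dist(scores))
  # k-nearest neighborhood of each cell, the cell itself included
  nn <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    idx <- order(d[i, ])[seq_len(k_neighbors)]
    nn[i, idx] <- 1L
  }
  shared <- nn %*% t(nn)
  jac <- shared / (2 * k_neighbors - shared)
  jac[jac < prune] <- 0
  diag(jac) <- 0
  jac
}

#' Cluster cells on a shared-nearest-neighbor graph
#'
#' Builds a Euclidean k-nearest-neighbor graph on the embedding (each cell's
#' neighborhood includes itself), weights edges by the Jaccard overlap of
#' neighborhoods, prunes weights below 1/15, and partitions the graph by
#' modularity optimization (Louvain) at the given resolution. Labels are
#' `0 .. C-1`, ordered by decreasing cluster size; results are deterministic
#' under a fixed seed.
#'
#' @param scores Cells-by-components embedding (a `"pca_result"` is
#'   accepted), typically restricted to `1:k` components from
#'   [select_pc_cutoff()].
#' @param k_neighbors Neighborhood size (reduced with a warning when there
#'   are fewer cells).
#' @param resolution Modularity resolution (default 0.4).
#' @param seed Integer seed.
#' @return Integer vector of cluster labels named by cell barcode.
#' @export
cluster_cells <- function(scores, k_neighbors = 20, resolution = 0.4,
                          seed = 1L) {
  if (inherits(scores, "pca_result")) scores <- scores$scores
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n < 2L) stop("clustering needs at least 2 cells")
  if (k_neighbors > n) {
    warning("k_neighbors reduced from ", k_neighbors, " to ", n)
    k_neighbors <- n
  }
  adj <- .snn_graph(scores, k_neighbors)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  raw <- igraph::membership(comm)
  sizes <- sort(table(raw), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  labels <- unname(relabel[as.character(raw)])
  stats::setNames(as.integer(labels), rownames(scores))
}
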