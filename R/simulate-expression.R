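#' Simulate two-cultivar single-nucleus count matrices with known truth
#'
#' Negative-binomial droplet-style counts with planted structure: cell types
#' with elevated marker genes, cross-sample DEGs shifted between the two
#' cultivars, log-normal library-size variation, and planted low-quality
#' cells that each violate exactly one quality-control bound. Marker genes
#' are elevated `2^marker_log2fc`-fold in their type in both samples; DEG
#' genes are shifted `2^deg_log2fc`-fold between samples (random direction)
#' in every cell type, so the per-cluster tests see a consistent signal.
#'
#' @param n_genes Number of genes.
#' @param cells_per_sample Good-quality cells per sample (default 400, a
#'   desk-scale stand-in for the tens of thousands of nuclei a droplet run
#'   yields).
#' @param n_types Number of cell types (>= 2), equal proportions.
#' @param markers_per_type Marker genes planted per type.
#' @param n_degs Cross-sample DEG genes planted.
#' @param marker_log2fc Marker elevation (log2; default 2).
#' @param deg_log2fc Cross-sample shift (log2; default 1).
#' @param nb_dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param n_bad_cells Planted QC-violating cells per sample; they cycle over
#'   the feasible bounds (fewer than 200 detected genes; at least 15 000
#'   UMIs; more than 7500 detected genes when `n_genes` allows it).
#' @param base_mean Mean of the log-normal gene-level expression means.
#' @param samples Two sample (cultivar) labels.
#' @param seed Integer seed.
#' @param gene_ids Optional explicit gene identifiers (overrides `n_genes`);
#'   used when the expression stage must share a namespace with a simulated
#'   gene catalog.
#' @param deg_genes Optional explicit genes to plant as cross-sample DEGs
#'   (overrides `n_degs`); lets integration tests plant DEGs on genes that
#'   also sit near planted SVs.
#' @param dir Optional directory; writes one MatrixMarket subdirectory per
#'   sample.
#' @return List with `matrices` (named list of [cell_matrix()]), `truth`
#'   (list: `cell_type` named vector over all barcodes, `markers` table
#'   (gene, type, log2fc), `degs` table (gene, direction, log2fc),
#'   `bad_cells` table (barcode, violation)), and `paths` when written.
#' @export
simulate_single_cell <- function(n_genes = 1000, cells_per_sample = 400,
                                 n_types = 3, markers_per_type = 20,
                                 n_degs = 100, marker_log2fc = 2,
                                 deg_log2fc = 1, nb_dispersion = 0.5,
                                 n_bad_cells = 3, base_mean = 0.8,
                                 samples = c("JA", "MH"), seed = 1L,
                                 gene_ids = NULL, deg_genes = NULL,
                                 dir = NULL) {
  stopifnot(n_types >= 2, marker_log2fc > 0, deg_log2fc > 0,
            length(samples) == 2L)
  if (is.null(gene_ids)) {
    gene_ids <- sprintf("Gene%04d", seq_len(n_genes))
  } else {
    n_genes <- length(gene_ids)
  }
  if (!is.null(deg_genes)) {
    stopifnot(all(deg_genes %in% gene_ids))
    n_degs <- length(deg_genes)
  }
  if (n_degs + n_types * markers_per_type > n_genes) {
    stop("more planted genes than genes available")
  }
  set.seed(seed)
  mu0 <- stats::rlnorm(n_genes, meanlog = log(base_mean), sdlog = 1)
  if (is.null(deg_genes)) {
    special <- sample(n_genes, n_types * markers_per_type + n_degs)
    marker_idx <- special[seq_len(n_types * markers_per_type)]
    deg_idx <- special[-seq_len(n_types * markers_per_type)]
  } else {
    deg_idx <- match(deg_genes, gene_ids)
    marker_idx <- sample(setdiff(seq_len(n_genes), deg_idx),
                         n_types * markers_per_type)
    special <- c(marker_idx, deg_idx)
  }
  # planted effects live on expressed genes: a fold change on a gene the
  # assay cannot detect encodes no recoverable truth
  mu0[special] <- stats::rlnorm(length(special),
                                meanlog = log(4 * base_mean), sdlog = 0.4)
  marker_type <- rep(seq_len(n_types) - 1L, each = markers_per_type)
  deg_dir <- sample(c(1, -1), n_degs, replace = TRUE)  # +1: up in sample 1

  # per-type mean matrix (genes x types)
  mu_type <- matrix(mu0, n_genes, n_types)
  for (j in seq_along(marker_idx)) {
    mu_type[marker_idx[j], marker_type[j] + 1L] <-
      mu0[marker_idx[j]] * 2^marker_log2fc
  }

  sample_one <- function(sample_name, deg_sign) {
    types <- rep_len(seq_len(n_types) - 1L, cells_per_sample)
    lib <- stats::rlnorm(cells_per_sample, 0, 0.1)
    mu <- mu_type[, types + 1L, drop = FALSE]
    if (length(deg_idx)) {
      mu[deg_idx, ] <- mu[deg_idx, ] * 2^(deg_sign * deg_dir * deg_log2fc / 2)
    }
    mu <- sweep(mu, 2L, lib, "*")
    counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                    size = 1 / nb_dispersion),
                     n_genes, cells_per_sample)
    # planted QC failures, one bound each
    bad_kinds <- c("low_genes", "high_umi",
                   if (n_genes > 7500) "high_genes")
    bads <- character(0)
    if (n_bad_cells > 0) {
      bad <- matrix(0L, n_genes, n_bad_cells)
      bads <- rep_len(bad_kinds, n_bad_cells)
      for (b in seq_len(n_bad_cells)) {
        if (bads[b] == "low_genes") {
          n_on <- min(150L, n_genes)
          on <- sample(n_genes, n_on)
          bad[on, b] <- 1L + stats::rpois(n_on, 1)
        } else if (bads[b] == "high_umi") {
          cell <- stats::rnbinom(n_genes, mu = mu_type[, 1L] * 30,
                                 size = 1 / nb_dispersion)
          deficit <- 15000L - sum(cell)
          if (deficit > 0) cell <- cell + ceiling(deficit / n_genes) + 1L
          bad[, b] <- cell
        } else {                                   # high_genes
          bad[, b] <- 1L + stats::rpois(n_genes, 1)
        }
      }
      counts <- cbind(counts, bad)
      types <- c(types, rep(NA_integer_, n_bad_cells))
    }
    barcodes <- sprintf("C%04d-%s", seq_len(ncol(counts)), sample_name)
    dimnames(counts) <- list(gene_ids, barcodes)
    list(m = cell_matrix(counts, rep(sample_name, ncol(counts))),
         types = stats::setNames(types, barcodes),
         bad = if (n_bad_cells > 0)
           data.frame(barcode = barcodes[cells_per_sample + seq_len(n_bad_cells)],
                      violation = bads, stringsAsFactors = FALSE)
         else data.frame(barcode = character(0), violation = character(0)))
  }

  s1 <- sample_one(samples[1L], +1)
  s2 <- sample_one(samples[2L], -1)
  truth <- list(
    cell_type = c(s1$types, s2$types),
    markers = data.frame(gene = gene_ids[marker_idx], type = marker_type,
                         log2fc = marker_log2fc, stringsAsFactors = FALSE),
    degs = data.frame(gene = gene_ids[deg_idx],
                      direction = ifelse(deg_dir > 0,
                                         paste0("up_in_", samples[1L]),
                                         paste0("up_in_", samples[2L])),
                      log2fc = deg_dir * deg_log2fc,
                      stringsAsFactors = FALSE),
    bad_cells = rbind(s1$bad, s2$bad)
  )
  out <- list(matrices = stats::setNames(list(s1$m, s2$m), samples),
              truth = truth)
  if (!is.null(dir)) {
    out$paths <- lapply(samples, function(s)
      write_cell_matrix(out$matrices[[s]], file.path(dir, s)))
    names(out$paths) <- samples
  }
  out
}

#' Simulate bulk stage-profile counts with planted correlated gene pairs
#'
#' Each planted pair shares a latent stage profile: both genes' counts are
#' integer multiples of the same strictly varying profile, perturbed by
#' multiplicative log-normal noise of standard deviation `noise_sd`. With
#' `noise_sd = 0` the pair members are exactly proportional, so their TPM
#' values are a monotone transform of each other and their Spearman
#' correlation is exactly 1 regardless of the other genes' library
#' contribution. Remaining genes are independent.
#'
#' @param genes Gene table (ids are reused for the count rows) or an
#'   integer number of genes.
#' @param n_stages Number of stages/samples (>= 4).
#' @param n_corr_pairs Planted correlated pairs.
#' @param noise_sd Log-normal noise standard deviation.
#' @param seed Integer seed.
#' @param stage_labels Sample labels; defaults to the study design of five
#'   fruit development stages, inflorescences, leaves and buds.
#' @return List with `counts` (genes x stages integer matrix), `lengths`
#'   (named bp vector, >= 150), `truth` (`pairs`: gene1, gene2), `stages`.
#' @export
simulate_bulk_stages <- function(genes, n_stages = 8, n_corr_pairs = 5,
                                 noise_sd = 0.1, seed = 1L,
                                 stage_labels = NULL) {
  stopifnot(n_stages >= 4)
  set.seed(seed)
  ids <- if (is.data.frame(genes)) genes$id else
    sprintf("Gene%03d", seq_len(genes))
  n <- length(ids)
  stopifnot(2 * n_corr_pairs <= n)
  if (is.null(stage_labels)) {
    stage_labels <- c(paste0("F", 1:5), "F6", "L", "buds")
  }
  stage_labels <- rep_len(stage_labels, n_stages)
  stage_labels <- make.unique(stage_labels)
  counts <- matrix(stats::rnbinom(n * n_stages,
                                  mu = stats::rlnorm(n, log(200), 1),
                                  size = 2),
                   n, n_stages)
  pair_idx <- matrix(sample(n, 2 * n_corr_pairs), ncol = 2L)
  for (p in seq_len(nrow(pair_idx))) {
    # geometric spacing keeps successive stage values well separated, so
    # moderate multiplicative noise does not reorder ranks
    profile <- round(cumprod(c(stats::runif(1, 20, 60),
                               stats::runif(n_stages - 1L, 1.35, 1.6))))
    mult <- sample(1:5, 2L, replace = TRUE)
    for (j in 1:2) {
      noise <- if (noise_sd > 0) exp(stats::rnorm(n_stages, 0, noise_sd)) else 1
      counts[pair_idx[p, j], ] <- round(mult[j] * profile * noise)
    }
  }
  dimnames(counts) <- list(ids, stage_labels)
  lengths <- stats::setNames(sample(300:3000, n, replace = TRUE), ids)
  list(counts = counts, lengths = lengths,
       truth = list(pairs = data.frame(gene1 = ids[pair_idx[, 1L]],
                                       gene2 = ids[pair_idx[, 2L]],
                                       stringsAsFactors = FALSE)),
       stages = stage_labels)
}
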