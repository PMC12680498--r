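#' Pipeline configuration with the study defaults
#'
#' Collects every tunable threshold of the pipeline in one validated list.
#' Defaults are the values the analysis is defined with: 50 bp to call a
#' structural variant, a 5 kb gene-linking window, quality-control bounds of
#' 200--7500 detected genes and fewer than 15 000 UMIs per nucleus, the top
#' 3000 variable genes, clustering resolution 0.4, marker screening at
#' min.pct 0.25 / log2FC 0.25, cross-cultivar DEG screening at min.pct 0.1 /
#' log2FC 0.25, and the 90 % cumulative / 5 % individual variance rules for
#' the principal-component cutoff.
#'
#' @param seed Integer seed recorded alongside every derived result.
#' @param sv_min_len Minimum allele-length difference (bp) for an SV.
#' @param window Gene-to-SV linking window (bp).
#' @param qc_min_genes,qc_max_genes Detected-gene bounds per nucleus
#'   (inclusive).
#' @param qc_max_umi UMI bound per nucleus (exclusive: "fewer than").
#' @param n_variable_genes Number of variable genes used for embedding.
#' @param resolution Modularity resolution for clustering.
#' @param k_neighbors Neighborhood size of the SNN graph.
#' @param marker_min_pct,marker_logfc Marker screening parameters.
#' @param deg_min_pct,deg_logfc Cross-cultivar DEG screening parameters.
#' @param pc_cum_threshold,pc_indiv_threshold,pc_delta_threshold
#'   Component-cutoff rules (cumulative variance, next-component variance,
#'   successive-difference stabilization).
#' @param hemi_min_len,hemi_min_qual,hemi_min_support Deletion-call filter
#'   thresholds for hemizygous-gene detection.
#' @return A named list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L,
                            sv_min_len = 50,
                            window = 5000,
                            qc_min_genes = 200,
                            qc_max_genes = 7500,
                            qc_max_umi = 15000,
                            n_variable_genes = 3000,
                            resolution = 0.4,
                            k_neighbors = 20,
                            marker_min_pct = 0.25,
                            marker_logfc = 0.25,
                            deg_min_pct = 0.1,
                            deg_logfc = 0.25,
                            pc_cum_threshold = 0.90,
                            pc_indiv_threshold = 0.05,
                            pc_delta_threshold = 0.001,
                            hemi_min_len = 50,
                            hemi_min_qual = 60,
                            hemi_min_support = 4) {
  cfg <- list(
    seed = as.integer(seed), sv_min_len = sv_min_len, window = window,
    qc_min_genes = qc_min_genes, qc_max_genes = qc_max_genes,
    qc_max_umi = qc_max_umi, n_variable_genes = n_variable_genes,
    resolution = resolution, k_neighbors = k_neighbors,
    marker_min_pct = marker_min_pct, marker_logfc = marker_logfc,
    deg_min_pct = deg_min_pct, deg_logfc = deg_logfc,
    pc_cum_threshold = pc_cum_threshold,
    pc_indiv_threshold = pc_indiv_threshold,
    pc_delta_threshold = pc_delta_threshold,
    hemi_min_len = hemi_min_len, hemi_min_qual = hemi_min_qual,
    hemi_min_support = hemi_min_support
  )
  num <- cfg[setdiff(names(cfg), "seed")]
  if (any(!vapply(num, is.numeric, TRUE)) || any(unlist(num) <= 0)) {
    stop("all configuration thresholds must be strictly positive numbers")
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}
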