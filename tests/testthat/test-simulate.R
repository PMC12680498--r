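test_that("reference simulation is deterministic with non-overlapping genes", {
  r1 <- simulate_reference(2, 100000, 50, seed = 7)
  r2 <- simulate_reference(2, 100000, 50, seed = 7)
  expect_equal(as.character(r1$seqs), as.character(r2$seqs))
  expect_equal(r1$genes, r2$genes)
  expect_equal(length(r1$seqs), 2L)
  expect_equal(nrow(r1$genes), 50L)
  g <- r1$genes
  for (i in seq_len(nrow(g) - 1)) {
    same <- which(g$chrom == g$chrom[i]); same <- same[same > i]
    for (j in same) {
      expect_false(g$start[i] <= g$end[j] && g$end[i] >= g$start[j])
    }
  }
  expect_error(simulate_reference(1, 1000, 50, seed = 1), "cannot place")
})

test_that("panel truth matches the requested composition", {
  ref <- simulate_reference(2, 100000, 50, seed = 2)
  pan <- simulate_pangenome_vcf(ref, 8, 8, 8, seed = 2)
  expect_equal(nrow(pan$truth$planted), 8L)
  expect_equal(sum(pan$truth$planted$direction == "insertion"), 4L)
  expect_equal(table(pan$truth$decoys$category)[["sub_threshold"]], 8L)
  expect_equal(nrow(pan$vcf), 8L + 5L * 8L)
  # disjoint ids, all present in the file
  expect_length(intersect(pan$truth$planted$id, pan$truth$decoys$id), 0)
  expect_true(all(c(pan$truth$planted$id, pan$truth$decoys$id) %in% pan$vcf$id))
  # records are position-sorted within chromosome
  for (ch in unique(pan$vcf$chrom)) {
    expect_false(is.unsorted(pan$vcf$pos[pan$vcf$chrom == ch]))
  }
})

test_that("a panel with nothing planted yields no unique SVs", {
  ref <- simulate_reference(2, 100000, 50, seed = 3)
  pan <- simulate_pangenome_vcf(ref, 6, 0, 6, seed = 3)
  expect_equal(nrow(find_unique_svs(pan$vcf)), 0L)
})

test_that("planted unique records satisfy their own invariants", {
  ref <- simulate_reference(2, 100000, 50, seed = 4)
  pan <- simulate_pangenome_vcf(ref, 10, 12, 4, seed = 4)
  planted_rows <- pan$vcf[match(pan$truth$planted$id, pan$vcf$id), ]
  for (i in seq_len(nrow(planted_rows))) {
    expect_true(all(planted_rows$gt[[i]] == "1|1"))
    delta <- abs(nchar(planted_rows$ref[i]) - nchar(planted_rows$alt[i]))
    expect_gte(delta, 50)
  }
  ins <- pan$truth$planted$direction == "insertion"
  expect_true(all(nchar(planted_rows$ref[ins]) > nchar(planted_rows$alt[ins])))
})

test_that("SV-call decoys each fail for their stated single reason", {
  ref <- simulate_reference(2, 100000, 40, seed = 5)
  sv <- simulate_sv_calls(ref, 10, 6, seed = 5)
  calls <- sv$calls
  expect_equal(nrow(calls), 16L)
  expect_true(all(calls$svtype == "DEL"))
  miss <- calls[grepl("^miss", calls$id), ]
  qual59 <- miss[miss$qual == 59, ]
  expect_equal(nrow(qual59), 1L)
  expect_false(qual59$id %in% filter_deletion_calls(calls)$id)
  sup3 <- miss[miss$support == 3, ]
  expect_equal(nrow(sup3), 1L)
  expect_false(sup3$id %in% filter_deletion_calls(calls)$id)
})

test_that("single-cell truth marks a low-complexity cell the QC bound removes", {
  sim <- simulate_single_cell(n_genes = 500, cells_per_sample = 50,
                              markers_per_type = 5, n_degs = 20,
                              n_bad_cells = 2, seed = 6)
  bad <- sim$truth$bad_cells
  low <- bad$barcode[bad$violation == "low_genes"][1]
  sample_of_low <- sub("^.*-", "", low)
  counts <- sim$matrices[[sample_of_low]]$counts
  expect_equal(unname(Matrix::colSums(counts > 0)[low]), 150)
  merged <- merge_cell_matrices(sim$matrices[[1]], sim$matrices[[2]])
  expect_false(low %in% colnames(qc_filter(merged)$counts))
})

test_that("single-cell simulation is deterministic under a fixed seed", {
  a <- simulate_single_cell(n_genes = 200, cells_per_sample = 30,
                            markers_per_type = 5, n_degs = 10, seed = 9)
  b <- simulate_single_cell(n_genes = 200, cells_per_sample = 30,
                            markers_per_type = 5, n_degs = 10, seed = 9)
  expect_equal(as.matrix(a$matrices[[1]]$counts),
               as.matrix(b$matrices[[1]]$counts))
  expect_equal(a$truth, b$truth)
})

test_that("noise-free bulk pairs are perfectly rank-correlated after TPM", {
  ref <- simulate_reference(2, 100000, 50, seed = 7)
  b <- simulate_bulk_stages(ref$genes, noise_sd = 0, seed = 10)
  expect_true(all(b$lengths >= 150))
  tpm <- tpm_normalize(b$counts, b$lengths)
  rho <- suppressWarnings(spearman_matrix(tpm))
  for (i in seq_len(nrow(b$truth$pairs))) {
    expect_equal(rho[b$truth$pairs$gene1[i], b$truth$pairs$gene2[i]], 1)
  }
})

test_that("independent bulk genes stay weakly correlated on average", {
  ref <- simulate_reference(2, 100000, 50, seed = 7)
  b <- simulate_bulk_stages(ref$genes, n_stages = 8, noise_sd = 0.1, seed = 11)
  tpm <- tpm_normalize(b$counts, b$lengths)
  rho <- suppressWarnings(spearman_matrix(tpm))
  others <- setdiff(rownames(tpm), unlist(b$truth$pairs))
  half <- length(others) %/% 2
  bg <- rho[others[seq_len(half)], others[(half + 1):(2 * half)]]
  expect_lt(mean(abs(bg)), 0.5)
  b2 <- simulate_bulk_stages(ref$genes, n_stages = 8, noise_sd = 0.1, seed = 11)
  expect_equal(b$counts, b2$counts)
})

test_that("pipeline results are reproducible end to end under one seed", {
  run_once <- function() {
    fx <- sc_fixture(seed = 13, min_genes = 50, cells_per_sample = 80,
                     n_genes = 300, markers_per_type = 5, n_degs = 20)
    per <- lapply(split(colnames(fx$qc$counts), fx$qc$samples),
                  function(cc) fx$norm[, cc, drop = FALSE])
    vg <- select_variable_genes(per, 100)
    emb <- joint_pca(per, vg, n_components = 20)
    labels <- cluster_cells(emb$scores[, 1:5], seed = 13)
    find_group_degs(fx$norm, labels, fx$qc$samples)$genes
  }
  expect_identical(run_once(), run_once())
})
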