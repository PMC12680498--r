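test_that("candidate intersection is a deduplicated, commutative set operation", {
  expect_equal(nrow(intersect_candidates(c("a", "b"), c("c", "d"))), 0L)
  expect_equal(intersect_candidates(c("a", "b", "c"), c("b", "c", "d"))$gene,
               c("b", "c"))
  expect_equal(intersect_candidates(c("b", "c", "b"), c("c", "b"))$gene,
               intersect_candidates(c("c", "b"), c("b", "c", "b"))$gene)
})

test_that("candidates carry SV and DEG evidence when tables are supplied", {
  links <- data.frame(sv_id = c("s1", "s2", "s1"),
                      gene_id = c("gA", "gA", "gB"),
                      distance = c(100L, 0L, 4000L),
                      relation = c("upstream", "overlapping", "downstream"),
                      stringsAsFactors = FALSE)
  degs <- data.frame(gene = c("gA", "gC"), avg_log2FC = c(1.5, -2),
                     direction = c("up_in_JA", "up_in_MH"),
                     stringsAsFactors = FALSE)
  out <- intersect_candidates(links, degs)
  expect_equal(out$gene, "gA")
  expect_equal(out$sv_ids, "s1,s2")
  expect_equal(out$min_distance, 0)
  expect_equal(out$avg_log2FC, 1.5)
  expect_equal(out$direction, "up_in_JA")
})

test_that("TPM follows the per-kilobase formula and conserves one million per sample", {
  counts <- matrix(c(10, 10, 20, 20), 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  tpm <- tpm_normalize(counts, c(g1 = 1000, g2 = 1000))
  expect_equal(unname(tpm[, 1]), c(5e5, 5e5))
  # doubling one gene's length halves its per-kilobase share
  tpm2 <- tpm_normalize(counts, c(g1 = 2000, g2 = 1000))
  expect_equal(unname(tpm2["g1", 1] / tpm2["g2", 1]), 0.5)
  set.seed(2)
  rnd <- matrix(rpois(300, 40), 30, 10,
                dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:10)))
  lens <- setNames(sample(200:3000, 30), rownames(rnd))
  t3 <- tpm_normalize(rnd, lens)
  expect_true(all(abs(colSums(t3) - 1e6) < 1e6 * 1e-6))
  # scale invariance per sample
  rnd2 <- rnd; rnd2[, 3] <- rnd2[, 3] * 7L
  expect_equal(tpm_normalize(rnd2, lens), t3)
  expect_error(tpm_normalize(rnd * 0L, lens), "zero total")
})

test_that("zero-row policies differ exactly on partially-zero genes", {
  x <- matrix(c(0, 5, 7,  1, 2, 3,  0, 0, 0), 3, byrow = TRUE,
              dimnames = list(c("gz", "gp", "g0"), c("a", "b", "c")))
  expect_equal(rownames(filter_zero_rows(x)), "gp")
  expect_setequal(rownames(filter_zero_rows(x, "all_zero")), c("gz", "gp"))
  expect_error(filter_zero_rows(x["g0", , drop = FALSE]), "every gene")
})

test_that("Spearman matrix is symmetric, monotone-invariant, and matches the rank oracle", {
  set.seed(15)
  x <- matrix(sample(0:20, 8 * 10, replace = TRUE), 8, 10,
              dimnames = list(sprintf("g%d", 1:8), sprintf("s%d", 1:10)))
  rho <- spearman_matrix(x)
  expect_equal(rho, t(rho))
  expect_equal(unname(diag(rho)), rep(1, 8))
  for (i in 1:7) for (j in (i + 1):8) {
    expect_equal(rho[i, j], bf_spearman(x[i, ], x[j, ]), tolerance = 1e-12)
  }
  # invariance under strictly monotone transforms
  y <- x
  y[1, ] <- exp(x[1, ] / 3) + 5
  expect_equal(spearman_matrix(y)[1, ], rho[1, ], tolerance = 1e-12)
  # perfectly concordant / reversed profiles
  z <- rbind(a = 1:6, b = (1:6)^3, c = 6:1)
  rz <- spearman_matrix(z)
  expect_equal(rz["a", "b"], 1)
  expect_equal(rz["a", "c"], -1)
})

test_that("constant profiles are reported as missing with a warning", {
  x <- rbind(g1 = c(1, 1, 1, 1), g2 = c(1, 2, 3, 4), g3 = c(2, 4, 1, 3))
  expect_warning(rho <- spearman_matrix(x), "constant")
  expect_true(is.na(rho["g1", "g2"]))
  expect_equal(rho["g1", "g1"], 1)
  expect_error(spearman_matrix(x[, 1:2]), "3 samples")
})

test_that("the Spearman matrix is positive semi-definite when complete", {
  set.seed(16)
  x <- matrix(rnorm(60), 6, 10,
              dimnames = list(sprintf("g%d", 1:6), sprintf("s%d", 1:10)))
  ev <- eigen(spearman_matrix(x), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10)
})

test_that("hierarchical ordering puts correlated pairs on adjacent leaves", {
  set.seed(17)
  base1 <- sort(runif(10)); base2 <- sample(10)
  x <- rbind(p1a = base1, p1b = base1 * 3 + 1,
             out = runif(10),
             p2a = base2, p2b = base2 * 2)
  colnames(x) <- sprintf("s%d", 1:10)
  ord <- hierarchical_order(spearman_matrix(x))
  pos <- match(c("p1a", "p1b", "p2a", "p2b"), ord)
  expect_equal(abs(pos[1] - pos[2]), 1L)
  expect_equal(abs(pos[3] - pos[4]), 1L)
  expect_equal(hierarchical_order(matrix(1, 1, 1,
                                         dimnames = list("g1", "g1"))), "g1")
})

test_that("leaf adjacency is invariant to input gene order", {
  set.seed(18)
  base <- sort(runif(8))
  x <- rbind(a1 = base, a2 = base + 0.01, b = runif(8), c = runif(8))
  colnames(x) <- sprintf("s%d", 1:8)
  rho <- spearman_matrix(x)
  perm <- c(3, 1, 4, 2)
  o1 <- hierarchical_order(rho)
  o2 <- hierarchical_order(rho[perm, perm])
  neighbors <- function(ord, g) {
    i <- match(g, ord)
    sort(c(if (i > 1) ord[i - 1], if (i < length(ord)) ord[i + 1]))
  }
  expect_true("a2" %in% neighbors(o1, "a1"))
  expect_true("a2" %in% neighbors(o2, "a1"))
})

test_that("missing correlations are imputed as zero with a warning for ordering", {
  rho <- matrix(c(1, NA, NA, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_warning(ord <- hierarchical_order(rho), "imputed")
  expect_setequal(ord, c("a", "b"))
})

test_that("planted SV-adjacent DEG genes come out as the exact candidate set", {
  ref <- simulate_reference(2, 400000, 60, seed = 8)
  pan <- simulate_pangenome_vcf(ref, 12, 10, 5, seed = 8,
                                near_gene_window = 1500)
  u <- find_unique_svs(pan$vcf)
  links <- link_genes_to_svs(u, ref$genes, window = 5000)
  # plant DEGs on half of the SV-adjacent genes plus unrelated genes
  linked_genes <- sort(unique(links$gene_id))
  target <- linked_genes[seq(1, length(linked_genes), by = 2)]
  others <- setdiff(ref$genes$id, linked_genes)[1:10]
  sim <- simulate_single_cell(cells_per_sample = 300, n_types = 2,
                              markers_per_type = 10,
                              gene_ids = ref$genes$id, n_bad_cells = 0,
                              deg_genes = c(target, others), seed = 8)
  m <- merge_cell_matrices(sim$matrices[[1]], sim$matrices[[2]])
  q <- qc_filter(m, min_genes = 10)   # desk-scale catalog: 60 genes
  norm <- log_normalize(q)
  labels <- sim$truth$cell_type[colnames(q$counts)]
  deg <- find_group_degs(norm, labels, q$samples)
  sig <- deg$genes[deg$genes$p_val_adj < 0.05, ]
  cand <- intersect_candidates(links, sig)
  expect_setequal(cand$gene, target)
})
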