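gene_row <- function(id, start, end, chrom = "chr1", strand = "+") {
  data.frame(id = id, chrom = chrom, start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}
sv_row <- function(id, start, end, chrom = "chr1") {
  data.frame(id = id, chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

test_that("the 5 kb window is inclusive at exactly 5000 bp", {
  g <- gene_row("g1", 1, 100)
  expect_equal(link_genes_to_svs(sv_row("s1", 5101, 5101), g)$distance, 5000L)
  expect_equal(nrow(link_genes_to_svs(sv_row("s1", 5102, 5102), g)), 0L)
})

test_that("overlap gives distance zero and strand only labels the relation", {
  g <- gene_row("g1", 1000, 2000)
  inside <- link_genes_to_svs(sv_row("s1", 1500, 1600), g)
  expect_equal(inside$distance, 0L)
  expect_equal(inside$relation, "overlapping")
  after <- link_genes_to_svs(sv_row("s1", 2500, 2600), g)
  expect_equal(after$relation, "downstream")
  g_minus <- gene_row("g1", 1000, 2000, strand = "-")
  after_minus <- link_genes_to_svs(sv_row("s1", 2500, 2600), g_minus)
  expect_equal(after_minus$relation, "upstream")
  expect_equal(after$distance, after_minus$distance)  # eligibility unchanged
  expect_error(link_genes_to_svs(sv_row("s1", 1, 2), g, window = -1),
               "non-negative")
})

test_that("linking matches a brute-force all-pairs gap computation", {
  set.seed(12)
  svs <- sv_row(sprintf("s%03d", 1:80),
                start = sample(1:60000, 80),
                end = 0, chrom = sample(c("chr1", "chr2"), 80, TRUE))
  svs$end <- svs$start + sample(0:800, 80, TRUE)
  genes <- gene_row(sprintf("g%03d", 1:80),
                    start = sample(1:60000, 80), end = 0,
                    chrom = sample(c("chr1", "chr2"), 80, TRUE))
  genes$end <- genes$start + sample(100:3000, 80, TRUE)
  links <- link_genes_to_svs(svs, genes, window = 5000)
  expected <- list()
  for (i in seq_len(nrow(svs))) for (j in seq_len(nrow(genes))) {
    if (svs$chrom[i] != genes$chrom[j]) next
    gap <- bf_gap(svs$start[i], svs$end[i], genes$start[j], genes$end[j])
    if (gap <= 5000) {
      expected[[length(expected) + 1L]] <-
        data.frame(sv_id = svs$id[i], gene_id = genes$id[j],
                   distance = gap, stringsAsFactors = FALSE)
    }
  }
  expected <- do.call(rbind, expected)
  key <- function(d) sort(paste(d$sv_id, d$gene_id, d$distance))
  expect_equal(key(links), key(expected))
})

test_that("linking is symmetric in interval roles", {
  set.seed(13)
  svs <- sv_row(sprintf("s%02d", 1:30), start = sample(1:40000, 30), end = 0)
  svs$end <- svs$start + sample(0:500, 30, TRUE)
  genes <- gene_row(sprintf("g%02d", 1:30), start = sample(1:40000, 30), end = 0)
  genes$end <- genes$start + sample(100:2000, 30, TRUE)
  fwd <- link_genes_to_svs(svs, genes)
  swapped <- link_genes_to_svs(
    data.frame(id = genes$id, chrom = genes$chrom, start = genes$start,
               end = genes$end, stringsAsFactors = FALSE),
    data.frame(id = svs$id, chrom = svs$chrom, start = svs$start,
               end = svs$end, strand = "+", stringsAsFactors = FALSE))
  expect_setequal(paste(fwd$sv_id, fwd$gene_id, fwd$distance),
                  paste(swapped$gene_id, swapped$sv_id, swapped$distance))
})

test_that("unique SVs planted next to chosen genes link exactly those genes", {
  # sparse catalog so no bystander gene falls inside the window
  ref <- simulate_reference(2, 500000, 8, seed = 6)
  pan <- simulate_pangenome_vcf(ref, 10, 6, 4, seed = 6,
                                near_gene_window = 1500)
  u <- find_unique_svs(pan$vcf)
  links <- link_genes_to_svs(u, ref$genes, window = 5000)
  expect_setequal(unique(links$gene_id), unique(pan$truth$planted$gene_id))
})

test_that("hypergeometric enrichment reproduces exact tail probabilities", {
  # N=10, K=5, n=5, k=5: a single fully loaded draw
  e <- hypergeometric_enrichment(letters[1:5], letters[1:10],
                                 data.frame(gene = letters[1:5], term = "T"))
  expect_equal(e$p, 1 / choose(10, 5))
  expect_equal(e$k, 5L)
  # k = 0
  e0 <- hypergeometric_enrichment(letters[6:10], letters[1:10],
                                  data.frame(gene = letters[1:5], term = "T"))
  expect_equal(e0$p, 1)
  # study = population: p = 1 for every term
  tm <- data.frame(gene = rep(letters[1:10], 2),
                   term = rep(c("A", "B"), each = 10))
  efull <- hypergeometric_enrichment(letters[1:10], letters[1:10], tm)
  expect_true(all(efull$p == 1))
  expect_true(all(efull$p_adj >= efull$p - 1e-12))
  expect_error(hypergeometric_enrichment(c("a", "zz"), letters[1:5],
                                         data.frame(gene = "a", term = "T")),
               "subset")
})

test_that("enrichment p-values equal enumerated tail sums on random gene sets", {
  set.seed(3)
  for (rep in 1:20) {
    N <- sample(5:30, 1)
    pop <- sprintf("G%02d", seq_len(N))
    n <- sample(1:N, 1)
    K <- sample(1:N, 1)
    study <- sample(pop, n)
    tm <- data.frame(gene = sample(pop, K), term = "T",
                     stringsAsFactors = FALSE)
    e <- hypergeometric_enrichment(study, pop, tm)
    expect_equal(e$p, bf_hyper_tail(e$k, K, N, n), tolerance = 1e-12)
  }
})
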