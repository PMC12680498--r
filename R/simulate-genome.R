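#' Simulate a reference genome with a gene catalog
#'
#' Random nucleotide sequences plus non-overlapping, roughly uniformly
#' placed genes with unique ids (`Gene001`, ...). Each chromosome is divided
#' into equal slots and one gene is placed at a random offset inside its
#' slot, which guarantees non-overlap by construction.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_len Length of each chromosome in bp.
#' @param n_genes Total genes across chromosomes.
#' @param seed Integer seed.
#' @param gene_len_range Min/max gene length in bp.
#' @param dir Optional directory; when given, `ref.fa` and `genes.gff3` are
#'   written there.
#' @return List with `seqs` (a `DNAStringSet`), `genes` (gene table as from
#'   [read_gff3()]), and `paths` when `dir` was given.
#' @export
simulate_reference <- function(n_chroms = 2, chrom_len = 100000, n_genes = 50,
                               seed = 1L, gene_len_range = c(300, 1500),
                               dir = NULL) {
  set.seed(seed)
  per_chrom <- diff(round(seq(0, n_genes, length.out = n_chroms + 1L)))
  slot_margin <- 2L
  for (i in seq_len(n_chroms)) {
    slot <- chrom_len %/% max(per_chrom[i], 1L)
    if (per_chrom[i] > 0 && slot < gene_len_range[2L] + 2 * slot_margin) {
      stop("cannot place ", per_chrom[i], " genes of up to ",
           gene_len_range[2L], " bp on a ", chrom_len, " bp chromosome")
    }
  }
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(n_chroms), function(i) {
    paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
          collapse = "")
  }, character(1)))
  names(seqs) <- sprintf("chr%02d", seq_len(n_chroms))
  rows <- list()
  gi <- 0L
  for (ci in seq_len(n_chroms)) {
    ng <- per_chrom[ci]
    if (ng == 0) next
    slot <- chrom_len %/% ng
    for (s in seq_len(ng)) {
      gi <- gi + 1L
      len <- sample(gene_len_range[1L]:gene_len_range[2L], 1L)
      lo <- (s - 1L) * slot + slot_margin
      hi <- s * slot - len - slot_margin
      start <- sample(lo:hi, 1L)
      rows[[gi]] <- data.frame(
        id = sprintf("Gene%03d", gi),
        chrom = names(seqs)[ci],
        start = start, end = start + len - 1L,
        strand = sample(c("+", "-"), 1L),
        stringsAsFactors = FALSE
      )
    }
  }
  genes <- do.call(rbind, rows)
  out <- list(seqs = seqs, genes = genes)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fa <- file.path(dir, "ref.fa")
    gff <- file.path(dir, "genes.gff3")
    Biostrings::writeXStringSet(seqs, fa)
    write_gff3(genes, gff)
    out$paths <- list(fasta = fa, gff3 = gff)
  }
  out
}

.rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.make_pan_vcf <- function(df, samples) {
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  df$qual <- "."
  df$filter <- "."
  df$info <- "."
  df$format <- "GT"
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  attr(df, "samples") <- samples
  attr(df, "header") <- header
  class(df) <- c("pan_vcf", "data.frame")
  df
}

#' Simulate a pan-genome multi-sample VCF with planted focal-unique SVs
#'
#' Plants `n_planted_unique` focal-specific SV records -- allele-length
#' difference of at least 50 bp and every haplotype genotype `1|1` -- among
#' decoys that each fail the uniqueness rule for exactly one reason:
#' `shared` (some haplotypes carry the reference allele, `0|0`),
#' `partial` (heterozygous `0|1` tokens), `missing` (a `.|.` token),
#' `non11` (multi-allelic record whose tokens are `2|2`), and
#' `sub_threshold` (all `1|1` but an allele difference of
#' `sv_min_len - 1`). Planted SVs alternate insertion/deletion shape and are
#' placed within `near_gene_window` bp of distinct genes, so the
#' linking-stage truth (which genes sit near focal-unique SVs) is known.
#'
#' @param reference Output of [simulate_reference()].
#' @param n_haplotype_samples Haplotype columns in the panel (>= 2).
#' @param n_planted_unique Number of planted focal-unique SVs.
#' @param n_decoys_per_category Decoys per category (5 categories).
#' @param sv_len_range Allele-length difference range for SV-scale records.
#' @param seed Integer seed.
#' @param sv_min_len SV threshold (bp).
#' @param near_gene_window Maximum gap between a planted SV and its target
#'   gene.
#' @param dir Optional directory; writes `panel.vcf` there.
#' @return List with `vcf` (a `pan_vcf`), `truth` (list `planted`: id,
#'   direction, delta, gene_id; `decoys`: id, category), and `path` when
#'   written.
#' @export
simulate_pangenome_vcf <- function(reference, n_haplotype_samples = 30,
                                   n_planted_unique = 20,
                                   n_decoys_per_category = 40,
                                   sv_len_range = c(60, 500), seed = 1L,
                                   sv_min_len = 50, near_gene_window = 2000,
                                   dir = NULL) {
  stopifnot(n_haplotype_samples >= 2)
  set.seed(seed)
  genes <- reference$genes
  chrom_len <- Biostrings::width(reference$seqs)
  chroms <- names(reference$seqs)
  samples <- sprintf("hap%02d", seq_len(n_haplotype_samples))
  categories <- c("shared", "partial", "missing", "non11", "sub_threshold")
  n_dec <- n_decoys_per_category * length(categories)
  if (n_planted_unique > nrow(genes)) {
    stop("more planted unique SVs than genes available to anchor them")
  }

  # planted records: next to distinct target genes, alternating direction
  target <- genes[sample(nrow(genes), n_planted_unique), , drop = FALSE]
  planted <- vector("list", n_planted_unique)
  used <- list()
  for (i in seq_len(n_planted_unique)) {
    g <- target[i, ]
    len <- sample(sv_len_range[1L]:sv_len_range[2L], 1L)
    gap <- sample(0:near_gene_window, 1L)
    pos <- g$end + gap + 1L
    L <- chrom_len[match(g$chrom, chroms)]
    if (pos + len + 1L > L) pos <- max(1L, g$start - gap - len - 2L)
    dirn <- if (i %% 2L == 1L) "insertion" else "deletion"
    if (dirn == "insertion") {
      ref <- .rand_seq(len + 1L); alt <- substr(ref, 1L, 1L)
    } else {
      ref <- .rand_seq(1L); alt <- paste0(ref, .rand_seq(len))
    }
    planted[[i]] <- data.frame(
      chrom = g$chrom, pos = pos, id = sprintf("usv%03d", i),
      ref = ref, alt = alt, direction = dirn, delta = len,
      gene_id = g$id, stringsAsFactors = FALSE
    )
  }
  planted <- do.call(rbind, planted)
  planted_gt <- rep(list(rep("1|1", n_haplotype_samples)), n_planted_unique)

  # decoys: anywhere on the genome
  dec_chrom <- sample(chroms, n_dec, replace = TRUE)
  dec_pos <- vapply(dec_chrom, function(ch)
    sample.int(chrom_len[match(ch, chroms)] - max(sv_len_range) - 2L, 1L),
    integer(1))
  dec_cat <- rep(categories, each = n_decoys_per_category)
  decoys <- vector("list", n_dec)
  decoy_gt <- vector("list", n_dec)
  for (i in seq_len(n_dec)) {
    cat_i <- dec_cat[i]
    len <- if (cat_i == "sub_threshold") sv_min_len - 1L else
      sample(sv_len_range[1L]:sv_len_range[2L], 1L)
    ref <- .rand_seq(len + 1L)
    alt <- substr(ref, 1L, 1L)
    gt <- rep("1|1", n_haplotype_samples)
    if (cat_i == "shared") {
      gt[sample(n_haplotype_samples, max(1L, n_haplotype_samples %/% 3L))] <-
        "0|0"
    } else if (cat_i == "partial") {
      gt[sample(n_haplotype_samples, max(1L, n_haplotype_samples %/% 4L))] <-
        "0|1"
    } else if (cat_i == "missing") {
      gt[sample(n_haplotype_samples, 1L)] <- ".|."
    } else if (cat_i == "non11") {
      alt <- paste0(alt, ",", .rand_seq(len + 5L))
      gt <- rep("2|2", n_haplotype_samples)
    }
    decoys[[i]] <- data.frame(
      chrom = dec_chrom[i], pos = dec_pos[i], id = sprintf("dcy%03d", i),
      ref = ref, alt = alt, stringsAsFactors = FALSE
    )
    decoy_gt[[i]] <- gt
  }
  decoys <- do.call(rbind, decoys)

  df <- rbind(planted[, c("chrom", "pos", "id", "ref", "alt")], decoys)
  df$gt <- c(planted_gt, decoy_gt)
  vcf <- .make_pan_vcf(df, samples)
  truth <- list(
    planted = planted[, c("id", "direction", "delta", "gene_id")],
    decoys = data.frame(id = decoys$id, category = dec_cat,
                        stringsAsFactors = FALSE)
  )
  out <- list(vcf = vcf, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out$path <- write_vcf(vcf, file.path(dir, "panel.vcf"))
  }
  out
}

#' Simulate long-read SV deletion calls with planted hemizygous genes
#'
#' Each truth gene is fully contained in a DEL record passing every filter
#' bound (QUAL >= 60, support >= 4, precise, length >= 50, END present);
#' each near-miss decoy violates exactly one criterion: QUAL 59, support 3,
#' imprecise breakpoints, length 49, absent END, or only partial overlap
#' with a gene.
#'
#' @param reference Output of [simulate_reference()].
#' @param n_hemi_genes Number of genes planted as hemizygous.
#' @param n_near_miss_decoys Number of single-violation decoys.
#' @param seed Integer seed.
#' @param dir Optional directory; writes `sv_calls.vcf` there.
#' @return List with `vcf` (a `pan_vcf`), `calls` (typed [as_sv_calls()]
#'   table), `truth` (character vector of hemizygous gene ids), and `path`
#'   when written.
#' @export
simulate_sv_calls <- function(reference, n_hemi_genes = 10,
                              n_near_miss_decoys = 6, seed = 1L, dir = NULL) {
  set.seed(seed)
  genes <- reference$genes
  stopifnot(n_hemi_genes + n_near_miss_decoys <= nrow(genes))
  picked <- sample(nrow(genes), n_hemi_genes + n_near_miss_decoys)
  hemi <- genes[picked[seq_len(n_hemi_genes)], , drop = FALSE]
  dec_genes <- genes[picked[-seq_len(n_hemi_genes)], , drop = FALSE]
  violations <- rep(c("qual", "support", "imprecise", "length", "no_end",
                      "partial"), length.out = n_near_miss_decoys)
  mk <- function(chrom, start, end, id, qual, support, precise, with_end,
                 svlen = end - start + 1L) {
    info <- c(
      "SVTYPE=DEL",
      if (with_end) sprintf("END=%d", end),
      sprintf("SVLEN=%d", -svlen),
      sprintf("SUPPORT=%d", support),
      if (precise) "PRECISE" else "IMPRECISE"
    )
    data.frame(chrom = chrom, pos = start, id = id, ref = "N", alt = "<DEL>",
               qual = as.character(qual), filter = "PASS",
               info = paste(info, collapse = ";"), stringsAsFactors = FALSE)
  }
  rows <- list()
  for (i in seq_len(n_hemi_genes)) {
    g <- hemi[i, ]
    pad <- sample(10:200, 2L)
    rows[[length(rows) + 1L]] <- mk(
      g$chrom, max(1L, g$start - pad[1L]), g$end + pad[2L],
      sprintf("hemi%03d", i), qual = sample(60:99, 1L),
      support = sample(4:20, 1L), precise = TRUE, with_end = TRUE
    )
  }
  for (i in seq_len(n_near_miss_decoys)) {
    g <- dec_genes[i, ]
    v <- violations[i]
    pad <- sample(10:200, 2L)
    start <- max(1L, g$start - pad[1L]); end <- g$end + pad[2L]
    qual <- sample(60:99, 1L); support <- sample(4:20, 1L)
    precise <- TRUE; with_end <- TRUE
    if (v == "qual") qual <- 59
    if (v == "support") support <- 3
    if (v == "imprecise") precise <- FALSE
    if (v == "no_end") with_end <- FALSE
    if (v == "length") { start <- g$start + 1L; end <- start + 48L }
    if (v == "partial") { start <- g$start + 5L }   # starts inside the gene
    rows[[length(rows) + 1L]] <- mk(g$chrom, start, end,
                                    sprintf("miss%03d", i), qual, support,
                                    precise, with_end)
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  df$format <- "GT"
  df$gt <- rep(list("0/1"), nrow(df))
  header <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End position">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length">',
    '##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description="Supporting reads">',
    '##INFO=<ID=PRECISE,Number=0,Type=Flag,Description="Precise breakpoints">',
    '##INFO=<ID=IMPRECISE,Number=0,Type=Flag,Description="Imprecise breakpoints">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "focal"), collapse = "\t")
  )
  attr(df, "samples") <- "focal"
  attr(df, "header") <- header
  class(df) <- c("pan_vcf", "data.frame")
  out <- list(vcf = df, calls = as_sv_calls(df), truth = sort(hemi$id))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out$path <- write_vcf(df, file.path(dir, "sv_calls.vcf"))
  }
  out
}
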