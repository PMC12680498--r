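#' Classify one pan-genome variant record
#'
#' Classification follows the maximal allele-length difference across ALT
#' alleles: zero difference is a SNP (1 bp REF) or an MNP (longer REF),
#' a difference below `sv_min_len` is an indel, and a difference of at least
#' `sv_min_len` (default 50 bp) is a structural variant.
#'
#' @param ref REF allele string.
#' @param alts Character vector of ALT allele strings (a comma-joined ALT
#'   field is accepted and split).
#' @param sv_min_len SV length threshold in bp.
#' @return One of `"SNP"`, `"MNP"`, `"INDEL"`, `"SV"`.
#' @export
classify_variant <- function(ref, alts, sv_min_len = 50) {
  if (length(alts) == 1L && grepl(",", alts, fixed = TRUE)) {
    alts <- split_alts(alts)
  }
  if (!length(alts) || !all(nzchar(alts)) || !nzchar(ref)) {
    stop("record must have a non-empty REF and at least one ALT allele")
  }
  d <- max(abs(nchar(ref) - nchar(alts)))
  if (d == 0) {
    if (nchar(ref) == 1L) "SNP" else "MNP"
  } else if (d < sv_min_len) {
    "INDEL"
  } else {
    "SV"
  }
}

#' Count variant classes across a record table
#'
#' @param vcf A `pan_vcf` record table from [read_vcf()].
#' @param sv_min_len SV length threshold in bp.
#' @return Named integer vector with entries `SNP`, `MNP`, `INDEL`, `SV`
#'   summing to `nrow(vcf)`.
#' @export
summarize_variant_classes <- function(vcf, sv_min_len = 50) {
  classes <- vapply(seq_len(nrow(vcf)), function(i) {
    classify_variant(vcf$ref[i], vcf$alt[i], sv_min_len)
  }, character(1))
  out <- c(SNP = 0L, MNP = 0L, INDEL = 0L, SV = 0L)
  tab <- table(classes)
  out[names(tab)] <- as.integer(tab)
  out
}

.gt_tokens_check <- function(tokens, row) {
  if (!length(tokens)) stop("record ", row, " has no genotype columns")
  sep <- grepl("[|/]", tokens)
  if (!all(sep)) {
    stop("haploid genotype token '", tokens[!sep][1L], "' at record ", row,
         ": the panel must contain haplotype-resolved diploid tokens")
  }
  invisible(TRUE)
}

#' Call focal-cultivar unique structural variants
#'
#' Implements the uniqueness rule for a pan-genome VCF decomposed against the
#' focal cultivar: a record is a unique SV when (a) its allele-length
#' difference reaches `sv_min_len`, (b) no genotype carries a reference (0)
#' allele and none is missing, and (c) every genotype token is homozygous
#' alternate `1|1` (or unphased `1/1`). Because coordinates are on the focal
#' genome, direction is focal-centric and inverted relative to a naive VCF
#' reading: a REF allele longer than the ALT means sequence present only in
#' the focal cultivar, i.e. a focal **insertion**; a longer ALT is a focal
#' **deletion** (see [classify_sv_direction()]).
#'
#' @param vcf A `pan_vcf` record table.
#' @param sv_min_len SV length threshold in bp.
#' @return A `data.frame` (one row per unique SV, input order preserved) with
#'   columns `id`, `chrom`, `start`, `end` (REF footprint on the focal
#'   genome), `direction` (`"insertion"`/`"deletion"`), `delta` (bp), and
#'   `row` (index into `vcf`).
#' @export
find_unique_svs <- function(vcf, sv_min_len = 50) {
  keep <- logical(nrow(vcf))
  for (i in seq_len(nrow(vcf))) {
    if (classify_variant(vcf$ref[i], vcf$alt[i], sv_min_len) != "SV") next
    tokens <- vcf$gt[[i]]
    .gt_tokens_check(tokens, i)
    alleles <- strsplit(tokens, "[|/]")
    flat <- unlist(alleles)
    if (any(flat == ".") || any(flat == "0")) next          # missing / ref allele
    if (!all(vapply(alleles, function(a)
      length(a) == 2L && all(a == "1"), TRUE))) next        # strictly 1|1 / 1/1
    keep[i] <- TRUE
  }
  rows <- which(keep)
  if (!length(rows)) {
    return(data.frame(id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      direction = character(0), delta = numeric(0),
                      row = integer(0), stringsAsFactors = FALSE))
  }
  dir <- vapply(rows, function(i) classify_sv_direction(vcf$ref[i], vcf$alt[i]),
                character(1))
  delta <- vapply(rows, function(i) {
    max(abs(nchar(vcf$ref[i]) - nchar(split_alts(vcf$alt[i]))))
  }, numeric(1))
  data.frame(
    id = vcf$id[rows],
    chrom = vcf$chrom[rows],
    start = vcf$pos[rows],
    end = vcf$pos[rows] + nchar(vcf$ref[rows]) - 1L,
    direction = dir,
    delta = delta,
    row = rows,
    stringsAsFactors = FALSE
  )
}

#' Direction of a unique SV from the focal cultivar's perspective
#'
#' The pan-genome VCF is decomposed against the focal genome, so its REF
#' allele is focal sequence and the ALT allele is the panel (query) sequence.
#' A REF longer than the query therefore is sequence the focal cultivar
#' carries and the panel lacks -- a focal-specific insertion; a shorter REF
#' is a focal-specific deletion. The longest-delta ALT allele is used as the
#' query for multi-allelic records.
#'
#' @param ref REF allele string.
#' @param alts ALT allele(s); comma-joined string accepted.
#' @return `"insertion"` or `"deletion"`.
#' @export
classify_sv_direction <- function(ref, alts) {
  if (length(alts) == 1L && grepl(",", alts, fixed = TRUE)) {
    alts <- split_alts(alts)
  }
  d <- abs(nchar(ref) - nchar(alts))
  alt <- alts[which.max(d)]
  if (nchar(ref) > nchar(alt)) {
    "insertion"
  } else if (nchar(ref) < nchar(alt)) {
    "deletion"
  } else {
    stop("undefined direction: REF and query allele have equal length")
  }
}
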