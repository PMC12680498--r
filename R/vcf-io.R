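#' Read a VCF file into a record table
#'
#' Light text reader for both VCF dialects the pipeline consumes: the
#' pan-genome multi-sample VCF produced by decomposing a pan-genome graph
#' against the focal cultivar, and single-sample long-read SV-caller VCFs.
#' All fields are kept verbatim as strings so that [write_vcf()] reproduces
#' the data lines byte-identically; typed accessors interpret positions,
#' qualities and INFO keys on demand.
#'
#' @param path Path to a VCF 4.x text file (plain or gzip-compressed).
#' @return A `data.frame` of class `"pan_vcf"` with columns `chrom`, `pos`
#'   (integer, 1-based), `id`, `ref`, `alt` (comma-joined as on disk), `qual`,
#'   `filter`, `info`, `format` and a list-column `gt` holding the per-sample
#'   genotype tokens verbatim. Sample names are stored in
#'   `attr(x, "samples")`, header lines in `attr(x, "header")`.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty VCF file: ", path)
  is_meta <- startsWith(lines, "##")
  is_chrom <- startsWith(lines, "#CHROM")
  if (!startsWith(lines[1L], "##fileformat")) {
    stop("malformed VCF header at line 1: expected '##fileformat' in ", path)
  }
  chrom_idx <- which(is_chrom)
  if (length(chrom_idx) != 1L) {
    stop("malformed VCF: expected exactly one #CHROM line in ", path)
  }
  header <- lines[seq_len(chrom_idx)]
  cols <- strsplit(lines[chrom_idx], "\t", fixed = TRUE)[[1L]]
  if (length(cols) < 8L) {
    stop("malformed #CHROM line at line ", chrom_idx, ": fewer than 8 columns")
  }
  samples <- if (length(cols) > 9L) cols[-(1:9)] else character(0)
  n_expect <- if (length(cols) > 8L) 9L + length(samples) else 8L

  body_idx <- setdiff(seq_along(lines), seq_len(chrom_idx))
  body_idx <- body_idx[nzchar(lines[body_idx])]
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != n_expect)
  if (length(bad)) {
    stop("VCF parse error at line ", body_idx[bad[1L]], ": expected ",
         n_expect, " fields, found ", nf[bad[1L]])
  }
  m <- if (length(fields)) do.call(rbind, fields) else
    matrix(character(0), 0, n_expect)
  pos <- suppressWarnings(as.integer(m[, 2L]))
  if (anyNA(pos) && nrow(m)) {
    stop("VCF parse error at line ", body_idx[which(is.na(pos))[1L]],
         ": POS is not an integer")
  }
  out <- data.frame(
    chrom = if (nrow(m)) m[, 1L] else character(0),
    pos = pos,
    id = if (nrow(m)) m[, 3L] else character(0),
    ref = if (nrow(m)) m[, 4L] else character(0),
    alt = if (nrow(m)) m[, 5L] else character(0),
    qual = if (nrow(m)) m[, 6L] else character(0),
    filter = if (nrow(m)) m[, 7L] else character(0),
    info = if (nrow(m)) m[, 8L] else character(0),
    stringsAsFactors = FALSE
  )
  out$format <- if (n_expect > 8L && nrow(m)) m[, 9L] else
    rep(NA_character_, nrow(m))
  out$gt <- if (length(samples) && nrow(m)) {
    lapply(seq_len(nrow(m)), function(i) unname(m[i, -(1:9)]))
  } else {
    rep(list(character(0)), nrow(m))
  }
  attr(out, "samples") <- samples
  attr(out, "header") <- header
  class(out) <- c("pan_vcf", "data.frame")
  out
}

#' Write a VCF record table back to disk
#'
#' Reconstructs data lines from the verbatim fields stored by [read_vcf()],
#' so `write_vcf(read_vcf(f))` reproduces every non-header data line of `f`
#' byte-identically.
#'
#' @param x A `pan_vcf` object from [read_vcf()] or built by a generator.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "pan_vcf"))
  header <- attr(x, "header")
  body <- vapply(seq_len(nrow(x)), function(i) {
    fixed <- c(x$chrom[i], as.character(x$pos[i]), x$id[i], x$ref[i],
               x$alt[i], x$qual[i], x$filter[i], x$info[i])
    if (!is.na(x$format[i])) fixed <- c(fixed, x$format[i], x$gt[[i]])
    paste(fixed, collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Split comma-joined ALT alleles of one record
#' @param alt ALT field string.
#' @return Character vector of alleles.
#' @keywords internal
split_alts <- function(alt) strsplit(alt, ",", fixed = TRUE)[[1L]]

#' Parse a VCF INFO field into a named list
#'
#' Flags (keys without `=`) become `TRUE`; `"."` yields an empty list.
#' @param info INFO field string.
#' @return Named list of character values / logical flags.
#' @keywords internal
parse_info <- function(info) {
  if (is.na(info) || info == "." || !nzchar(info)) return(list())
  parts <- strsplit(info, ";", fixed = TRUE)[[1L]]
  out <- list()
  for (p in parts) {
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq > 0) {
      out[[substr(p, 1L, eq - 1L)]] <- substr(p, eq + 1L, nchar(p))
    } else {
      out[[p]] <- TRUE
    }
  }
  out
}

#' Interpret a VCF record table as long-read SV calls
#'
#' Extracts the typed fields the hemizygosity filter consumes from INFO:
#' `SVTYPE`, `END`, `SVLEN` (absolute value), the precision flag, and read
#' support. The precision flag is read as: `PRECISE` present, otherwise
#' `IMPRECISE` absent (a record stating neither is treated as precise).
#' Read support is taken from the first available of the INFO keys `SUPPORT`,
#' `RE`, `DV`, covering SV-caller dialect drift.
#'
#' @param x A `pan_vcf` object.
#' @return A `data.frame` with columns `chrom`, `pos`, `end` (NA when the
#'   record has no END key), `svtype`, `svlen`, `qual`, `support`, `precise`,
#'   `id`.
#' @export
as_sv_calls <- function(x) {
  stopifnot(inherits(x, "pan_vcf"))
  infos <- lapply(x$info, parse_info)
  get1 <- function(key) {
    vapply(infos, function(z) {
      v <- z[[key]]
      if (is.null(v)) NA_character_ else as.character(v)
    }, character(1))
  }
  svtype <- get1("SVTYPE")
  if (anyNA(svtype) && nrow(x)) {
    stop("SV record without SVTYPE at row ", which(is.na(svtype))[1L])
  }
  support <- suppressWarnings(as.integer(get1("SUPPORT")))
  re <- suppressWarnings(as.integer(get1("RE")))
  dv <- suppressWarnings(as.integer(get1("DV")))
  support[is.na(support)] <- re[is.na(support)]
  support[is.na(support)] <- dv[is.na(support)]
  precise <- vapply(infos, function(z) {
    if (isTRUE(z[["PRECISE"]])) TRUE else !isTRUE(z[["IMPRECISE"]])
  }, logical(1))
  data.frame(
    chrom = x$chrom,
    pos = x$pos,
    end = suppressWarnings(as.integer(get1("END"))),
    svtype = svtype,
    svlen = abs(suppressWarnings(as.numeric(get1("SVLEN")))),
    qual = suppressWarnings(as.numeric(x$qual)),
    support = support,
    precise = precise,
    id = x$id,
    stringsAsFactors = FALSE
  )
}
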