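# CIGAR arithmetic on plain strings (vectorized): total length of the given
# operation classes
cigar_op_sum <- function(cigar, ops) {
  out <- numeric(length(cigar))
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)
  tok <- regmatches(cigar, m)
  lens <- lapply(tok, function(t) as.integer(sub("[MIDNSHP=X]$", "", t)))
  opch <- lapply(tok, function(t) substr(t, nchar(t), nchar(t)))
  for (i in seq_along(cigar)) {
    sel <- opch[[i]] %in% ops
    out[i] <- sum(lens[[i]][sel])
  }
  out
}

#' Load barcode-tagged alignments from SAM/BAM
#'
#' Reads a SAM or BAM file carrying per-read `BX:Z:` barcode tags and returns
#' one row per mapped alignment record (primary, secondary and supplementary;
#' unmapped records are never yielded). Uniqueness is assessed per
#' (read, mate): a mate reported at more than one location -- or on more than
#' one reference -- across primary/secondary/supplementary records has
#' `is_unique = FALSE` on all of its rows. Mapped records lacking a `BX` tag
#' are skipped; their count is reported in a warning and in the
#' `skipped_no_bx` attribute.
#'
#' @param path SAM or BAM file (SAM is converted on the fly via
#'   [Rsamtools::asBam()]).
#' @return a `data.table` with columns `read_id`, `mate`, `barcode`, `rname`,
#'   `pos`, `end`, `mapq`, `aligned_bases`, `is_primary`, `is_reverse`,
#'   `is_proper`, `mate_rname`, `mate_pos`, `isize`, `n_hits`, `is_unique`.
#' @export
load_barcoded_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = FALSE)
  } else {
    bam <- path
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar",
             "mrnm", "mpos", "isize"),
    tag = "BX"
  )
  b <- Rsamtools::scanBam(bam, param = param)[[1L]]
  dt <- data.table(
    read_id = b$qname,
    flag = b$flag,
    rname = as.character(b$rname),
    pos = b$pos,
    mapq = b$mapq,
    cigar = b$cigar,
    mate_rname = as.character(b$mrnm),
    mate_pos = b$mpos,
    isize = b$isize,
    barcode = b$tag$BX %||% rep(NA_character_, length(b$qname))
  )
  dt <- dt[bitwAnd(flag, 4L) == 0L]                  # drop unmapped
  n_nobx <- sum(is.na(dt$barcode))
  if (n_nobx > 0L) {
    warning(n_nobx, " mapped record(s) without a BX tag were skipped")
    dt <- dt[!is.na(barcode)]
  }
  if (nrow(dt) == 0L) {
    dt <- data.table(read_id = character(), mate = integer(),
                     barcode = character(), rname = character(),
                     pos = integer(), end = integer(), mapq = integer(),
                     aligned_bases = numeric(), is_primary = logical(),
                     is_reverse = logical(), is_proper = logical(),
                     mate_rname = character(), mate_pos = integer(),
                     isize = integer(), n_hits = integer(),
                     is_unique = logical())
    setattr(dt, "skipped_no_bx", n_nobx)
    return(dt)
  }
  dt[, mate := fifelse(bitwAnd(flag, 128L) > 0L, 2L, 1L)]
  dt[, is_primary := bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L]
  dt[, is_reverse := bitwAnd(flag, 16L) > 0L]
  dt[, is_proper := bitwAnd(flag, 2L) > 0L]
  dt[, aligned_bases := cigar_op_sum(cigar, c("M", "=", "X", "I"))]
  dt[, end := pos + cigar_op_sum(cigar, c("M", "=", "X", "D", "N")) - 1L]
  if (any(dt$aligned_bases < 1)) {
    stop("invalid alignment: mapped record with no aligned bases")
  }
  dt[, n_hits := .N, by = .(read_id, mate)]
  dt[, is_unique := n_hits == 1L]
  dt[, c("flag", "cigar") := NULL]
  setattr(dt, "skipped_no_bx", n_nobx)
  dt[]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write alignments as SAM
#'
#' Minimal SAM writer used to emit simulator truth alignments. `aln` needs
#' columns `read_id`, `flag`, `rname`, `pos`, `mapq`, `cigar`, `mate_rname`,
#' `mate_pos`, `isize`, `barcode`, and optionally `seq` and `qual`
#' (defaulting to `*`).
#'
#' @param aln alignment `data.table` (1-based positions).
#' @param ref_lengths named vector of reference sequence lengths for the
#'   `@SQ` header lines.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, ref_lengths, path) {
  aln <- as.data.table(aln)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", names(ref_lengths), "\tLN:",
                  as.integer(ref_lengths)))
  seqs <- if ("seq" %in% names(aln)) aln$seq else rep("*", nrow(aln))
  quals <- if ("qual" %in% names(aln)) aln$qual else rep("*", nrow(aln))
  rnext <- fifelse(aln$mate_rname == aln$rname, "=", aln$mate_rname)
  int_fmt <- function(x) formatC(x, format = "d")  # never scientific notation
  body <- paste(aln$read_id, aln$flag, aln$rname, int_fmt(aln$pos), aln$mapq,
                aln$cigar, rnext, int_fmt(aln$mate_pos), int_fmt(aln$isize),
                seqs, quals,
                paste0("BX:Z:", aln$barcode),
                sep = "\t")
  write_text_lines(c(hdr, body), path)
}
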