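#' Write unified barcoded FASTQ
#'
#' Serializes unified records to FASTQ. The barcode is carried as a single
#' whitespace-separated `BX:Z:<barcode>` token in the FASTQ comment field --
#' the same convention as the SAM `BX` tag, so aligner-propagated tags stay
#' byte-identical downstream. Records with the [NULL_BARCODE] sentinel omit
#' the token. The mate is encoded as a `/1` or `/2` suffix on the read name.
#'
#' @param records a `data.table` as returned by [convert_to_unified()]
#'   (columns `read_id`, `mate`, `sequence`, `qualities`, `barcode`).
#' @param path output path (`.gz` for gzip).
#' @return `path`, invisibly.
#' @export
write_unified_fastq <- function(records, path) {
  records <- as.data.table(records)
  stopifnot(all(c("read_id", "mate", "sequence", "qualities", "barcode") %in%
                  names(records)))
  if (any(nchar(records$sequence) != nchar(records$qualities))) {
    stop("invalid record: sequence and qualities differ in length")
  }
  bx <- ifelse(is_null_barcode(records$barcode), "",
               paste0(" BX:Z:", records$barcode))
  lines <- as.vector(rbind(
    paste0("@", records$read_id, "/", records$mate, bx),
    records$sequence,
    "+",
    records$qualities
  ))
  write_text_lines(lines, path)
}

#' Read unified barcoded FASTQ
#'
#' Parses a FASTQ file in the unified representation, recovering the barcode
#' from the `BX:Z:` comment token. Headers lacking the token yield
#' [NULL_BARCODE]. `read(write(x))` is the identity on the record stream.
#'
#' @param path FASTQ path (gzip allowed).
#' @param platform platform label to stamp on the records.
#' @return a `data.table` of unified records.
#' @export
read_unified_fastq <- function(path, platform = NA_character_) {
  fq <- parse_fastq(path)
  m <- regmatches(fq$comment, regexpr("(?:^| )BX:Z:\\S*", fq$comment))
  has_bx <- grepl("(^| )BX:Z:", fq$comment)
  barcode <- rep(NULL_BARCODE, nrow(fq))
  if (any(has_bx)) {
    val <- sub("^ ?BX:Z:", "", m)
    bad <- which(val == "" | grepl("[^ACGTN]", val))
    if (length(bad)) {
      stop("format error: malformed BX token at line ",
           (which(has_bx)[bad[1L]] - 1L) * 4L + 1L, " of '", path, "'")
    }
    barcode[has_bx] <- val
  }
  mate <- rep(1L, nrow(fq))
  suffixed <- grepl("/[12]$", fq$read_id)
  mate[suffixed] <- as.integer(sub("^.*/", "", fq$read_id[suffixed]))
  data.table(read_id = sub("/[12]$", "", fq$read_id),
             mate = mate,
             sequence = fq$sequence,
             qualities = fq$qualities,
             barcode = barcode,
             platform = platform)
}
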