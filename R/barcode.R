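#' Read a barcode whitelist
#'
#' One barcode per line, plain text (optionally gzipped). Entries must be of
#' uniform length and are deduplicated.
#'
#' @param path whitelist file.
#' @return character vector of class `whitelist`.
#' @export
read_whitelist <- function(path) {
  wl <- read_text_lines(path)
  wl <- wl[nzchar(wl)]
  as_whitelist(wl)
}

#' @rdname read_whitelist
#' @param entries character vector of barcodes.
#' @export
as_whitelist <- function(entries) {
  entries <- unique(entries)
  if (length(entries) == 0L) stop("empty whitelist")
  if (length(unique(nchar(entries))) != 1L) {
    stop("whitelist entries must all have the same length")
  }
  structure(entries, class = "whitelist")
}

#' Whitelist-based barcode correction
#'
#' Corrects observed barcodes against a whitelist under Hamming distance
#' (substitutions only; barcodes are fixed-length codes, indels are not
#' modelled; `N` counts as a mismatch at its position):
#'
#' * an exact whitelist member is returned unchanged (`exact`);
#' * a barcode at distance exactly 1 from exactly one entry is rewritten to
#'   that entry (`corrected`);
#' * distance 1 to two or more entries is left unresolved and nulled
#'   (`ambiguous`) -- resolving by entry abundance would systematically merge
#'   barcodes, sacrificing the specificity the technology exists to provide;
#' * distance >= 2 from every entry is nulled (`uncorrectable`).
#'
#' @param barcodes character vector of observed barcodes (length must equal
#'   the whitelist entry length).
#' @param whitelist a [as_whitelist()] object or character vector.
#' @return `data.table(barcode, corrected, status)` with `corrected` either a
#'   whitelist member or [NULL_BARCODE] and `status` in
#'   `{exact, corrected, ambiguous, uncorrectable}`.
#' @export
correct_with_whitelist <- function(barcodes, whitelist) {
  if (!inherits(whitelist, "whitelist")) whitelist <- as_whitelist(whitelist)
  L <- nchar(whitelist[1L])
  if (any(nchar(barcodes) != L)) {
    stop("input error: barcode length differs from whitelist entry length ", L)
  }
  uq <- unique(barcodes)
  res <- data.table(barcode = uq,
                    corrected = NULL_BARCODE,
                    status = "uncorrectable")
  exact <- which(uq %chin% whitelist)
  res[exact, `:=`(corrected = barcode, status = "exact")]
  todo <- which(!(uq %chin% whitelist))
  if (length(todo)) {
    nb <- hamming1_neighbors(uq[todo])
    nb <- nb[neighbor %chin% whitelist]
    if (nrow(nb)) {
      hits <- nb[, .(n = .N, hit = neighbor[1L]), by = idx]
      one <- hits[n == 1L]
      amb <- hits[n > 1L]
      res[todo[one$idx], `:=`(corrected = one$hit, status = "corrected")]
      res[todo[amb$idx], `:=`(corrected = NULL_BARCODE, status = "ambiguous")]
    }
  }
  res[match(barcodes, uq)][]
}

#' Count-based barcode correction (whitelist-free)
#'
#' TELL-seq has no manufacturer whitelist; instead, the supporting-read count
#' of every observed barcode is tallied, and a barcode seen on a single read
#' that lies at Hamming distance exactly 1 from exactly one multi-read
#' barcode (count >= 2) is treated as a sequencing error of that barcode.
#' Every other barcode -- including all multi-read barcodes -- maps to
#' itself; singletons with zero or several distance-1 multi-read partners are
#' left unchanged.
#'
#' @param counts named integer vector (or [table()]) mapping barcode to
#'   supporting read count; counts must be >= 1 and keys of uniform length.
#' @return `data.table(barcode, corrected)` covering every input barcode.
#' @export
correct_without_whitelist <- function(counts) {
  counts <- unlist(as.list(counts))
  if (length(counts) == 0L) stop("input error: empty barcode count table")
  if (any(counts < 1)) stop("input error: barcode counts must be >= 1")
  codes <- names(counts)
  if (length(unique(nchar(codes))) != 1L) {
    stop("input error: barcode keys must have uniform length")
  }
  res <- data.table(barcode = codes, corrected = codes)
  singles <- which(counts == 1L)
  multis <- codes[counts >= 2L]
  if (length(singles) && length(multis)) {
    nb <- hamming1_neighbors(codes[singles])
    nb <- nb[neighbor %chin% multis]
    if (nrow(nb)) {
      hits <- nb[, .(n = .N, hit = neighbor[1L]), by = idx]
      one <- hits[n == 1L]
      res[singles[one$idx], corrected := one$hit]
    }
  }
  res[]
}

#' Fraction of corrected barcodes on the whitelist
#'
#' The whitelist-match rate: number of reads whose barcode is a whitelist
#' member after correction, over the number of reads that carried any raw
#' barcode. Reads whose correction failed (nulled barcodes) count in the
#' denominator but not the numerator.
#'
#' @param corrected character vector of post-correction barcodes (may contain
#'   [NULL_BARCODE]).
#' @param raw character vector of pre-correction barcodes, parallel to
#'   `corrected`.
#' @param whitelist whitelist object or character vector.
#' @return fraction in `[0, 1]`, or `NA` when no read has a raw barcode.
#' @export
whitelist_rate <- function(corrected, raw = corrected, whitelist) {
  if (!inherits(whitelist, "whitelist")) whitelist <- as_whitelist(whitelist)
  denom <- sum(!is_null_barcode(raw))
  if (denom == 0L) return(NA_real_)
  num <- sum(!is_null_barcode(raw) & corrected %chin% whitelist)
  num / denom
}

#' Correct the barcodes of a unified record stream
#'
#' Applies [correct_with_whitelist()] (when a whitelist is given) or
#' [correct_without_whitelist()] (count-based, TELL-seq style) to a unified
#' record table and reports correction statistics.
#'
#' @param records unified records (`data.table` with a `barcode` column).
#' @param whitelist optional whitelist; when `NULL`, count-based correction
#'   is used.
#' @return list with `records` (barcodes replaced by their corrections) and
#'   `stats` (counts of exact/corrected/ambiguous/uncorrectable reads and,
#'   with a whitelist, `whitelist_rate`).
#' @export
correct_records <- function(records, whitelist = NULL) {
  records <- copy(as.data.table(records))
  has_bc <- !is_null_barcode(records$barcode)
  raw <- copy(records$barcode)   # := below would otherwise mutate this alias
  if (!is.null(whitelist)) {
    cw <- correct_with_whitelist(raw[has_bc], whitelist)
    records[has_bc == TRUE, barcode := cw$corrected]
    stats <- as.list(table(factor(cw$status, levels = c(
      "exact", "corrected", "ambiguous", "uncorrectable"))))
    stats <- lapply(stats, as.integer)
    stats$whitelist_rate <- whitelist_rate(records$barcode, raw, whitelist)
  } else {
    counts <- table(raw[has_bc])
    map <- correct_without_whitelist(counts)
    new <- map$corrected[match(raw[has_bc], map$barcode)]
    stats <- list(
      exact = sum(new == raw[has_bc]),
      corrected = sum(new != raw[has_bc]),
      ambiguous = 0L, uncorrectable = 0L,
      whitelist_rate = NA_real_
    )
    records[has_bc == TRUE, barcode := new]
  }
  list(records = records[], stats = stats)
}
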