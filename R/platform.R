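#' Platform specification for a linked-read technology
#'
#' Describes where the partition barcode lives inside the raw reads of one
#' linked-read platform. The built-in presets are:
#'
#' * `tenx` -- 16 bp barcode carried inline as the first 16 bases of R1
#'   (removed from the payload on conversion);
#' * `stlfr` -- 30 bp barcode split into three 10 bp segments at the tail of
#'   R2 (removed from the payload on conversion);
#' * `tellseq` -- 18 bp barcode carried on the separate index read I1
#'   (payload reads untouched). TELL-seq has no manufacturer whitelist.
#'
#' The barcode layout is a table of `(source, offset, length, trim)` segments.
#' `source` is one of `"R1"`, `"R2"`, `"I1"`; `offset` is the 1-based start of
#' the segment within its source read, with negative values counted from the
#' read end (`-30` = 30th base from the end); `trim` marks segments whose
#' bases are part of the payload read and must be removed on conversion.
#' Segments are concatenated in table order to form the barcode. Offsets are
#' configurable because stLFR libraries differ in whether linkers separate
#' the three barcode segments.
#'
#' @param name platform name: `"tenx"`, `"stlfr"` or `"tellseq"`.
#' @param barcode_length total barcode length in bases; defaults to the
#'   platform preset (16/30/18).
#' @param layout optional `data.frame(source, offset, length, trim)`
#'   overriding the preset segment layout.
#' @param whitelist_available logical; whether a manufacturer whitelist
#'   exists for the platform.
#' @return an object of class `platform_spec`.
#' @examples
#' platform_spec("tenx")$barcode_length   # 16
#' platform_spec("stlfr")$barcode_length  # 30
#' @export
platform_spec <- function(name = c("tenx", "stlfr", "tellseq"),
                          barcode_length = NULL,
                          layout = NULL,
                          whitelist_available = NULL) {
  name <- match.arg(name)
  presets <- list(
    tenx = list(
      barcode_length = 16L,
      layout = data.table(source = "R1", offset = 1L, length = 16L, trim = TRUE),
      whitelist_available = TRUE
    ),
    stlfr = list(
      barcode_length = 30L,
      layout = data.table(source = "R2", offset = c(-30L, -20L, -10L),
                          length = 10L, trim = TRUE),
      whitelist_available = TRUE
    ),
    tellseq = list(
      barcode_length = 18L,
      layout = data.table(source = "I1", offset = 1L, length = 18L, trim = FALSE),
      whitelist_available = FALSE
    )
  )
  p <- presets[[name]]
  if (!is.null(barcode_length)) p$barcode_length <- as.integer(barcode_length)
  if (!is.null(layout)) {
    layout <- as.data.table(layout)
    if (!"trim" %in% names(layout)) layout[, trim := FALSE]
    stopifnot(all(c("source", "offset", "length") %in% names(layout)))
    p$layout <- layout[, .(source = as.character(source),
                           offset = as.integer(offset),
                           length = as.integer(length),
                           trim = as.logical(trim))]
  }
  if (!is.null(whitelist_available)) p$whitelist_available <- whitelist_available
  if (sum(p$layout$length) != p$barcode_length) {
    stop("layout error: segment lengths sum to ", sum(p$layout$length),
         " but barcode_length is ", p$barcode_length)
  }
  structure(list(name = name,
                 barcode_length = p$barcode_length,
                 layout = p$layout,
                 whitelist_available = p$whitelist_available),
            class = "platform_spec")
}

#' @export
print.platform_spec <- function(x, ...) {
  cat("platform_spec:", x$name, "| barcode", x$barcode_length, "bp |",
      if (x$whitelist_available) "whitelist" else "no whitelist", "\n")
  print(x$layout)
  invisible(x)
}

# parse one FASTQ file into a data.table(read_id, comment, sequence, qualities)
parse_fastq <- function(path) {
  lines <- read_text_lines(path)
  if (length(lines) %% 4L != 0L) {
    stop("parse error: truncated FASTQ in '", path, "' at record ",
         length(lines) %/% 4L + 1L)
  }
  n <- length(lines) %/% 4L
  hdr <- lines[seq(1L, length(lines), by = 4L)]
  seqs <- lines[seq(2L, length(lines), by = 4L)]
  quals <- lines[seq(4L, length(lines), by = 4L)]
  bad <- which(substr(hdr, 1L, 1L) != "@")
  if (length(bad)) {
    stop("parse error: malformed FASTQ header in '", path, "' at record ", bad[1L])
  }
  hdr <- sub("^@", "", hdr)
  sp <- regexpr(" ", hdr, fixed = TRUE)
  id <- ifelse(sp > 0L, substr(hdr, 1L, sp - 1L), hdr)
  comment <- ifelse(sp > 0L, substr(hdr, sp + 1L, nchar(hdr)), "")
  if (any(nchar(seqs) != nchar(quals))) {
    stop("parse error: sequence/quality length mismatch in '", path, "' at record ",
         which(nchar(seqs) != nchar(quals))[1L])
  }
  data.table(read_id = id, comment = comment, sequence = seqs, qualities = quals)
}

# resolve (possibly negative) segment offsets against actual read lengths;
# errors when a segment falls outside its source read
segment_bounds <- function(offset, seg_len, read_len, source) {
  start <- ifelse(offset < 0L, read_len + offset + 1L, offset)
  stop_ <- start + seg_len - 1L
  bad <- which(start < 1L | stop_ > read_len)
  if (length(bad)) {
    stop("layout error: barcode segment (", source, ", offset ", offset,
         ", length ", seg_len, ") out of range for read ", bad[1L],
         " (read length ", read_len[bad[1L]], ")")
  }
  list(start = start, stop = stop_)
}

#' Convert raw platform reads to the unified barcoded representation
#'
#' Assembles the partition barcode of each read pair by concatenating the
#' platform's layout segments in order, strips inline barcode bases from the
#' payload, and returns records in the unified representation in which both
#' mates of a pair carry the identical (raw, uncorrected) barcode. A layout
#' with zero total segment length yields [NULL_BARCODE] and leaves the
#' payload untouched.
#'
#' @param r1,r2 paths to the raw R1/R2 FASTQ files (gzip allowed).
#' @param spec a [platform_spec()].
#' @param i1 path to the index read FASTQ, required when the layout draws
#'   from `I1` (TELL-seq).
#' @return a `data.table` of unified records with columns `read_id`, `mate`
#'   (1 or 2), `sequence`, `qualities`, `barcode`, `platform`.
#' @seealso [write_unified_fastq()], [read_unified_fastq()]
#' @export
convert_to_unified <- function(r1, r2, spec, i1 = NULL) {
  stopifnot(inherits(spec, "platform_spec"))
  reads <- list(R1 = parse_fastq(r1), R2 = parse_fastq(r2))
  if (!is.null(i1)) reads$I1 <- parse_fastq(i1)
  n <- nrow(reads$R1)
  if (nrow(reads$R2) != n) {
    stop("parse error: R1 has ", n, " records but R2 has ", nrow(reads$R2))
  }
  layout <- spec$layout[length > 0L]
  if (nrow(layout) > 0L && any(!layout$source %in% names(reads))) {
    missing_src <- setdiff(layout$source, names(reads))
    stop("layout error: layout requires read(s) ", paste(missing_src, collapse = ", "),
         " but no such file was supplied")
  }
  if (!is.null(reads$I1) && nrow(reads$I1) != n) {
    stop("parse error: I1 has ", nrow(reads$I1), " records but R1 has ", n)
  }

  if (nrow(layout) == 0L) {
    barcode <- rep(NULL_BARCODE, n)
  } else {
    parts <- vector("list", nrow(layout))
    for (i in seq_len(nrow(layout))) {
      src <- reads[[layout$source[i]]]
      rl <- nchar(src$sequence)
      b <- segment_bounds(layout$offset[i], layout$length[i], rl, layout$source[i])
      parts[[i]] <- substr(src$sequence, b$start, b$stop)
    }
    barcode <- do.call(paste0, parts)
  }

  # strip inline barcode bases from payload reads (right-to-left per source
  # so earlier cuts do not shift later coordinates)
  payload <- list(R1 = reads$R1, R2 = reads$R2)
  trim_segs <- layout[trim == TRUE & source %in% c("R1", "R2")]
  for (src_name in unique(trim_segs$source)) {
    segs <- trim_segs[source == src_name]
    src <- payload[[src_name]]
    rl <- nchar(src$sequence)
    starts <- lapply(seq_len(nrow(segs)), function(i) {
      segment_bounds(segs$offset[i], segs$length[i], rl, src_name)
    })
    ord <- order(vapply(starts, function(b) b$start[1L], numeric(1)), decreasing = TRUE)
    for (i in ord) {
      b <- starts[[i]]
      src[, sequence := paste0(substr(sequence, 1L, b$start - 1L),
                               substr(sequence, b$stop + 1L, nchar(sequence)))]
      src[, qualities := paste0(substr(qualities, 1L, b$start - 1L),
                                substr(qualities, b$stop + 1L, nchar(qualities)))]
    }
    payload[[src_name]] <- src
  }

  strip_mate <- function(id) sub("/[12]$", "", id)
  rec <- rbindlist(list(
    data.table(read_id = strip_mate(payload$R1$read_id), mate = 1L,
               sequence = payload$R1$sequence, qualities = payload$R1$qualities),
    data.table(read_id = strip_mate(payload$R2$read_id), mate = 2L,
               sequence = payload$R2$sequence, qualities = payload$R2$qualities)
  ))
  rec[, barcode := rep(barcode, 2L)]
  rec[, platform := spec$name]
  setkey(rec, NULL)
  rec[]
}
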