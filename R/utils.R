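#' Sentinel for a missing barcode
#'
#' Reads whose barcode could not be determined (absent in the raw layout, or
#' uncorrectable/ambiguous after error correction) carry this literal value.
#' They are kept in the read stream but excluded from every barcode-grouped
#' computation.
#'
#' @export
NULL_BARCODE <- "NA"

#' Test for the null barcode
#'
#' @param x character vector of barcodes.
#' @return logical vector: `TRUE` where the barcode is absent.
#' @export
is_null_barcode <- function(x) {
  is.na(x) | x == NULL_BARCODE
}

# read a text file, transparently handling gzip by extension
read_text_lines <- function(path) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    readLines(con)
  } else {
    readLines(path)
  }
}

write_text_lines <- function(lines, path) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "wt")
    on.exit(close(con))
    writeLines(lines, con)
  } else {
    writeLines(lines, path)
  }
  invisible(path)
}

# reverse complement for plain character vectors
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate distinct random barcode sequences
#'
#' Used by the simulator when no whitelist is supplied.
#'
#' @param n number of barcodes.
#' @param barcode_length length in bases.
#' @return character vector of `n` distinct barcodes.
#' @export
random_barcodes <- function(n, barcode_length) {
  stopifnot(n >= 1, barcode_length >= 1)
  draw <- function(k) {
    m <- matrix(sample(c("A", "C", "G", "T"), k * barcode_length, replace = TRUE),
                nrow = k)
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  }
  codes <- unique(draw(n))
  while (length(codes) < n) {
    codes <- unique(c(codes, draw(n - length(codes) + 16L)))
  }
  codes[seq_len(n)]
}

# all Hamming-distance-1 neighbours of each barcode (substitutions over ACGT).
# Returns a data.table(idx, neighbor); neighbours equal to the input string
# are dropped, so every neighbour differs at exactly one position.
hamming1_neighbors <- function(codes) {
  L <- nchar(codes[1L])
  stopifnot(all(nchar(codes) == L))
  bases <- c("A", "C", "G", "T")
  n <- length(codes)
  out <- vector("list", L * 4L)
  k <- 0L
  for (p in seq_len(L)) {
    pre <- substr(codes, 1L, p - 1L)
    post <- substr(codes, p + 1L, L)
    cur <- substr(codes, p, p)
    for (b in bases) {
      k <- k + 1L
      nb <- paste0(pre, b, post)
      keep <- cur != b
      out[[k]] <- data.table(idx = which(keep), neighbor = nb[keep])
    }
  }
  rbindlist(out)
}

# zero-truncated Poisson draws (Poisson(lambda) conditioned on >= 1)
rztpois <- function(n, lambda) {
  if (n == 0L) return(integer(0))
  p0 <- dpois(0, lambda)
  qpois(runif(n, p0, 1), lambda)
}

# population standard deviation (divide by n)
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}
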