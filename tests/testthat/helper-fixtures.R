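# fixtures are built in code at test time -- nothing binary ships with the
# package

# write a raw FASTQ file from parallel vectors
write_raw_fastq <- function(ids, seqs, path, quals = NULL) {
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), path)
  path
}

rand_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# minimal coordinate-sorted-agnostic SAM file writer for hand-built records;
# each record is a list(qname, flag, rname, pos, mapq, cigar, rnext, pnext,
# tlen, seq, qual, tags)
write_tiny_sam <- function(records, ref_lengths, path) {
  hdr <- c("@HD\tVN:1.6",
           paste0("@SQ\tSN:", names(ref_lengths), "\tLN:", ref_lengths))
  body <- vapply(records, function(r) {
    paste(c(r$qname, r$flag, r$rname, r$pos, r$mapq %||% 60,
            r$cigar %||% "100M", r$rnext %||% "*", r$pnext %||% 0,
            r$tlen %||% 0, r$seq %||% "*", r$qual %||% "*",
            r$tags %||% character(0)),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force single-linkage clustering of seed intervals at a gap cutoff:
# repeatedly merge any two clusters containing intervals whose gap <= cutoff
oracle_single_linkage <- function(start, end, cutoff) {
  n <- length(start)
  lab <- seq_len(n)
  gap <- function(i, j) {
    max(0, max(start[i], start[j]) - min(end[i], end[j]))
  }
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (lab[i] != lab[j] && gap(i, j) <= cutoff) {
          lab[lab == lab[j]] <- lab[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  as.integer(factor(lab))
}

# brute-force Hamming distance between equal-length strings
oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# hand-rolled per-read multimapping tally used as the exhaustive oracle for
# window_counts mass bookkeeping
oracle_window_tally <- function(aln, ref_lengths, l) {
  aln <- as.data.frame(aln)
  if (is.null(aln$genome_id)) aln$genome_id <- aln$rname
  hits <- split(aln$genome_id, aln$read_id)
  u_counts <- table(unlist(lapply(hits, function(h) {
    if (length(unique(h)) == 1L) unique(h) else character(0)
  })))
  mass <- list()
  for (rid in names(hits)) {
    rows <- aln[aln$read_id == rid, ]
    gs <- unique(rows$genome_id)
    if (length(gs) == 1L) {
      w <- stats::setNames(1, gs)
    } else {
      u <- vapply(gs, function(g) {
        if (g %in% names(u_counts)) as.numeric(u_counts[[g]]) else 0
      }, numeric(1))
      w <- if (sum(u) == 0) stats::setNames(rep(1 / length(gs), length(gs)), gs)
           else stats::setNames(u / sum(u), gs)
    }
    for (g in gs) {
      p <- rows$pos[rows$genome_id == g][1]
      key <- paste(g, (p - 1) %/% l + 1, sep = ":")
      mass[[key]] <- (mass[[key]] %||% 0) + w[[g]]
    }
  }
  unlist(mass)
}
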