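# normalize a quantification alignment table: one row per (read, genome),
# columns read_id, genome_id, pos (+ aligned_bases). `genome_of` maps
# reference names to genome ids when references are not themselves genomes.
as_quant_alignments <- function(aln, genome_of = NULL, read_length = 150L) {
  aln <- as.data.table(aln)
  stopifnot(all(c("read_id", "rname", "pos") %in% names(aln)))
  if (!"aligned_bases" %in% names(aln)) {
    aln <- copy(aln)[, aligned_bases := read_length]
  }
  if (!is.null(genome_of)) {
    aln[, genome_id := genome_of[rname]]
  } else if (!"genome_id" %in% names(aln)) {
    aln[, genome_id := rname]
  }
  # one row per (read, genome): several loci on the same genome collapse to
  # the primary/first hit, so uniqueness is assessed across genomes
  if ("is_primary" %in% names(aln)) setorder(aln, -is_primary)
  unique(aln, by = c("read_id", "genome_id"))
}

#' Per-genome coverage from first-pass alignments
#'
#' Computes, for every genome, the number of bases covered by at least one
#' read and the coverage rate (covered fraction of the genome). All mapped
#' reads contribute, including multimapped ones -- the first-pass filter runs
#' before any multimapping deconvolution.
#'
#' @param aln alignment table (`read_id`, `rname`, `pos`, optionally
#'   `aligned_bases`).
#' @param ref_lengths named vector of genome lengths.
#' @param genome_of optional named map from `rname` to genome id.
#' @return `data.table(genome_id, genome_length, covered_bases,
#'   coverage_rate)` including genomes with zero coverage.
#' @export
genome_coverage <- function(aln, ref_lengths, genome_of = NULL) {
  q <- as_quant_alignments(aln, genome_of)
  if (is.null(genome_of)) {
    glen <- data.table(genome_id = names(ref_lengths),
                       genome_length = as.numeric(ref_lengths))
  } else {
    glen <- data.table(genome_id = genome_of[names(ref_lengths)],
                       len = as.numeric(ref_lengths))[
                         , .(genome_length = sum(len)), by = genome_id]
  }
  cov <- q[, {
    ir <- IRanges::reduce(IRanges::IRanges(start = pos,
                                           end = pos + aligned_bases - 1))
    .(covered_bases = sum(IRanges::width(ir)))
  }, by = genome_id]
  out <- merge(glen, cov, by = "genome_id", all.x = TRUE)
  out[is.na(covered_bases), covered_bases := 0]
  out[, coverage_rate := covered_bases / genome_length]
  out[]
}

#' First-pass genome filter
#'
#' Keeps a genome iff its coverage rate is strictly greater than `min_rate`
#' and its covered bases strictly exceed `min_bases` (defaults: rate > 40%
#' and > 500 kb covered).
#'
#' @param coverages table from [genome_coverage()].
#' @param min_rate minimum coverage rate (strict, default 0.40).
#' @param min_bases minimum covered bases (strict, default 500000).
#' @return character vector of candidate genome ids.
#' @export
first_pass_filter <- function(coverages, min_rate = 0.40, min_bases = 500000) {
  coverages <- as.data.table(coverages)
  coverages[coverage_rate > min_rate & covered_bases > min_bases,
            sort(genome_id)]
}

#' Multimapping weights
#'
#' A read aligned to `N >= 2` genomes is split across them with weights
#' proportional to the genomes' unique-read counts:
#' `omega_j = U_j / sum(U)`; when every hit genome has zero unique reads the
#' weight degenerates to the uniform `1/N`. Weights always sum to exactly 1,
#' so each multiread distributes one read of mass.
#'
#' @param unique_counts numeric vector of the unique-read counts `U_j` of the
#'   read's hit genomes.
#' @return numeric vector of weights, same order, summing to 1.
#' @export
multiread_weights <- function(unique_counts) {
  n <- length(unique_counts)
  stopifnot(n >= 1, all(unique_counts >= 0))
  tot <- sum(unique_counts)
  if (tot == 0) rep(1 / n, n) else unique_counts / tot
}

#' Windowed read counts with multimapping deconvolution
#'
#' Partitions every candidate genome into windows of `l` bases (the final
#' window keeps its true, shorter length) and assigns each mapped read to the
#' window containing its leftmost aligned base. Unique reads (hitting a
#' single genome) increment the window's `U`; each multiread contributes
#' weight `omega_j` (see [multiread_weights()], computed from genome-level
#' unique-read counts over the read's hit set within `aln`) to one window per
#' hit genome. Per-window rates are `RC_U = U/l`, `RC_M = M_contrib/l`,
#' `RC_W = RC_U + RC_M`.
#'
#' @param aln second-pass alignment table restricted to candidate genomes
#'   (one row per read x genome; hit sets -- and hence weights -- are taken
#'   over this restricted set, i.e. renormalized).
#' @param ref_lengths named vector of genome lengths for the candidates.
#' @param l window size in bases (default 10 kb).
#' @param genome_of optional named map from `rname` to genome id.
#' @return `data.table(genome_id, window_index, window_start, l, U,
#'   M_contrib, RC_U, RC_M, RC_W)` covering all windows of all candidate
#'   genomes, including empty ones.
#' @export
window_counts <- function(aln, ref_lengths, l = 10000, genome_of = NULL) {
  q <- as_quant_alignments(aln, genome_of)
  glen <- data.table(genome_id = names(ref_lengths),
                     genome_length = as.numeric(ref_lengths))
  stopifnot(all(q$genome_id %in% glen$genome_id))
  q <- merge(q, glen, by = "genome_id")
  if (any(q$pos < 1 | q$pos > q$genome_length)) {
    stop("input error: read position outside genome bounds")
  }
  q[, n_hits_g := uniqueN(genome_id), by = read_id]
  u_counts <- q[n_hits_g == 1L, .(U_genome = .N), by = genome_id]
  q <- merge(q, u_counts, by = "genome_id", all.x = TRUE)
  q[is.na(U_genome), U_genome := 0]
  q[, omega := fifelse(n_hits_g == 1L, 1, NA_real_)]
  multi <- q$n_hits_g > 1L
  if (any(multi)) {
    q[multi == TRUE, omega := {
      tot <- sum(U_genome)
      if (tot == 0) rep(1 / .N, .N) else U_genome / tot
    }, by = read_id]
  }
  q[, window_index := (pos - 1) %/% l + 1L]

  # full window scaffold, short final window keeps its true length
  wins <- glen[, {
    nw <- as.integer(ceiling(genome_length / l))
    wi <- seq_len(nw)
    .(window_index = wi,
      window_start = (wi - 1) * l + 1,
      l = fifelse(wi == nw, genome_length - (nw - 1) * l, as.numeric(l)))
  }, by = genome_id]

  tallies <- q[, .(U = sum(n_hits_g == 1L),
                   M_contrib = sum(omega[n_hits_g > 1L])),
               by = .(genome_id, window_index)]
  out <- merge(wins, tallies, by = c("genome_id", "window_index"), all.x = TRUE)
  out[is.na(U), U := 0]
  out[is.na(M_contrib), M_contrib := 0]
  out[, RC_U := U / l]
  out[, RC_M := M_contrib / l]
  out[, RC_W := RC_U + RC_M]
  setorder(out, genome_id, window_index)
  out[]
}

#' Trimmed average depth of one genome
#'
#' Removes windows with an extreme read count before averaging: under the
#' default `"percentile"` rule, windows whose `RC_W` falls outside the
#' \[`lo`, `hi`\] percentile range of the genome's nonzero-window `RC_W`
#' distribution are dropped; under `"sd"`, windows outside
#' mean +/- 3 standard deviations are dropped. The depth is the mean `RC_W`
#' of the surviving windows; if trimming removes everything, the untrimmed
#' mean is returned.
#'
#' @param windows window table of a single genome (from [window_counts()]).
#' @param trim_rule `"percentile"` (default) or `"sd"`.
#' @param lo,hi percentile bounds for the percentile rule.
#' @return scalar depth (mean reads per base over retained windows).
#' @export
genome_depth <- function(windows, trim_rule = c("percentile", "sd"),
                         lo = 0.05, hi = 0.95) {
  trim_rule <- match.arg(trim_rule)
  windows <- as.data.table(windows)
  stopifnot(nrow(windows) >= 1L, uniqueN(windows$genome_id) <= 1L)
  rc <- windows$RC_W
  nz <- rc[rc > 0]
  if (length(nz) == 0L) return(0)
  bounds <- if (trim_rule == "percentile") {
    quantile(nz, c(lo, hi), names = FALSE)
  } else {
    c(mean(nz) - 3 * sd(nz), mean(nz) + 3 * sd(nz))
  }
  kept <- rc[rc >= bounds[1] & rc <= bounds[2]]
  if (length(kept) == 0L) mean(rc) else mean(kept)
}

#' Relative abundances from per-genome depths
#'
#' @param depths named numeric vector of average depths (or a
#'   `data.table(genome_id, depth)`).
#' @return `data.table(genome_id, depth, relative_abundance)`; abundances
#'   are `depth / sum(depth)` and sum to 1.
#' @export
relative_abundance <- function(depths) {
  if (is.data.frame(depths)) {
    dt <- as.data.table(depths)[, .(genome_id, depth)]
  } else {
    dt <- data.table(genome_id = names(depths), depth = as.numeric(depths))
  }
  if (all(dt$depth == 0)) stop("quantification error: all depths are zero")
  dt[, relative_abundance := depth / sum(depth)]
  dt[]
}

#' Tiered metagenomic quantification
#'
#' Full pipeline: first-pass coverage filter, second-pass windowed counting
#' with multimapping weights, per-genome trimmed depth, relative abundances.
#'
#' @param aln_pass1 first-pass alignments against the full reference set.
#' @param aln_pass2 second-pass alignments; defaults to `aln_pass1`
#'   restricted to the candidate genomes.
#' @param ref_lengths named vector of genome lengths.
#' @param window window size in bases.
#' @param min_rate,min_bases first-pass thresholds, see
#'   [first_pass_filter()].
#' @param genome_of optional named map from `rname` to genome id.
#' @return list with `coverage`, `candidates`, `windows`, `abundance`.
#' @export
quantify_metagenome <- function(aln_pass1, aln_pass2 = NULL, ref_lengths,
                                window = 10000, min_rate = 0.40,
                                min_bases = 500000, genome_of = NULL) {
  cov <- genome_coverage(aln_pass1, ref_lengths, genome_of)
  cand <- first_pass_filter(cov, min_rate, min_bases)
  if (length(cand) == 0L) {
    stop("quantification error: no genome passes the first-pass filter")
  }
  if (is.null(aln_pass2)) aln_pass2 <- aln_pass1
  q2 <- as_quant_alignments(aln_pass2, genome_of)[genome_id %in% cand]
  gid <- if (is.null(genome_of)) names(ref_lengths) else genome_of[names(ref_lengths)]
  glen <- tapply(as.numeric(ref_lengths), gid, sum)
  keep_len <- glen[names(glen) %in% cand]
  wins <- window_counts(q2, keep_len, l = window)
  depths <- wins[, .(depth = genome_depth(.SD)), by = genome_id]
  ab <- relative_abundance(depths)
  ab <- merge(ab, cov, by = "genome_id", all.x = TRUE)
  list(coverage = cov, candidates = cand, windows = wins, abundance = ab[])
}
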