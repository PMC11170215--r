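#' Estimate the paired-end insert-size model
#'
#' The insert ("outer distance") of a pair is the span from the leftmost
#' aligned base of one mate to the rightmost aligned base of the other,
#' inclusive -- the magnitude of the SAM template length. The model is fit on
#' unique-mapped proper pairs only; sizes above the 99.5th percentile (order
#' statistic) are discarded before computing the mean and the population
#' standard deviation (divide by n).
#'
#' @param x either a numeric vector of insert sizes, or an alignment
#'   `data.table` from [load_barcoded_alignments()] (unique proper pairs are
#'   extracted via [build_pairs()]), or a pair table from [build_pairs()].
#' @return list of class `insert_model` with `mu_pe`, `sigma_pe`,
#'   `n_pairs_used`.
#' @export
estimate_insert_model <- function(x) {
  if (is.data.frame(x)) {
    x <- as.data.table(x)
    if (!"span" %in% names(x)) x <- build_pairs(x)
    x <- x[is_unique == TRUE & is_proper == TRUE & same_ref == TRUE, span]
  }
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("model error: no usable unique-mapped proper pairs")
  cut <- quantile(x, 0.995, type = 1, names = FALSE)
  kept <- x[x <= cut]
  structure(list(mu_pe = mean(kept),
                 sigma_pe = pop_sd(kept),
                 n_pairs_used = length(kept)),
            class = "insert_model")
}

#' @export
print.insert_model <- function(x, ...) {
  cat(sprintf("insert_model: mu_PE = %.1f, sigma_PE = %.1f (n = %d pairs)\n",
              x$mu_pe, x$sigma_pe, x$n_pairs_used))
  invisible(x)
}

#' Collapse per-mate alignments into read-pair seeds
#'
#' Joins the primary alignments of the two mates of each read into one
#' pair-level row spanning both mates. Pairs whose mates map to different
#' references keep both reference names (`same_ref = FALSE`) and a missing
#' span.
#'
#' @param aln alignment table from [load_barcoded_alignments()].
#' @return `data.table(read_id, barcode, rname, rname2, start, end, span,
#'   aligned_bases, is_unique, is_proper, same_ref)`; single-ended reads are
#'   kept with their own extent.
#' @export
build_pairs <- function(aln) {
  aln <- as.data.table(aln)
  prim <- aln[is_primary == TRUE]
  setorder(prim, read_id, mate)
  pairs <- prim[, .(
    barcode = barcode[1L],
    rname = rname[1L],
    rname2 = rname[.N],
    start = min(pos),
    end = max(end),
    aligned_bases = sum(aligned_bases),
    is_unique = all(is_unique),
    is_proper = all(is_proper),
    same_ref = uniqueN(rname) == 1L,
    n_mates = .N
  ), by = read_id]
  pairs[, span := fifelse(same_ref, end - start + 1, NA_real_)]
  pairs[]
}

#' Remove discordant read pairs
#'
#' A pair is removed iff its R1--R2 outer distance exceeds
#' `mu_PE + 3 * sigma_PE` (strictly) or its mates map to different
#' references. Surviving pairs are returned unchanged.
#'
#' @param pairs pair table from [build_pairs()] (or any table with `span` and
#'   `same_ref` columns).
#' @param model an [estimate_insert_model()] fit.
#' @return the filtered pair table.
#' @export
filter_pairs <- function(pairs, model) {
  stopifnot(inherits(model, "insert_model"))
  pairs <- as.data.table(pairs)
  thr <- model$mu_pe + 3 * model$sigma_pe
  pairs[same_ref == TRUE & span <= thr]
}

#' Convert simulator truth pairs to reconstruction seeds
#'
#' @param pairs truth pair table from [simulate_read_pairs()].
#' @param read_length read length used in the simulation.
#' @return seed table with the columns [reconstruct_fragments()] expects.
#' @export
pairs_to_seeds <- function(pairs, read_length) {
  pairs <- as.data.table(pairs)
  data.table(read_id = pairs$read_id,
             barcode = pairs$barcode,
             rname = pairs$rname,
             start = pairs$pos1,
             end = pairs$pos2 + read_length - 1,
             aligned_bases = 2 * read_length)
}

#' Reconstruct long DNA fragments from co-barcoded seeds
#'
#' Within each (barcode, reference) group, seeds (read pairs) sorted by
#' coordinate are greedily extended: a seed joins the current fragment when
#' the gap between the fragment's rightmost aligned base and the seed's
#' leftmost base is at most `max_gap`, otherwise it opens a new fragment.
#' The result is identical to single-linkage clustering of the seed
#' intervals at gap cutoff `max_gap`. Fragments never cross references.
#'
#' @param seeds seed table with columns `barcode`, `rname`, `start`, `end`
#'   and optionally `aligned_bases` (defaults to the seed width); rows with
#'   a null barcode are ignored.
#' @param max_gap maximum extension distance in bases (default 200 kb).
#' @return `data.table(barcode, rname, start, end, length, n_read_pairs,
#'   aligned_read_bases)`, one row per reconstructed fragment.
#' @export
reconstruct_fragments <- function(seeds, max_gap = 200000) {
  seeds <- as.data.table(seeds)
  stopifnot(all(c("barcode", "rname", "start", "end") %in% names(seeds)))
  if (!"aligned_bases" %in% names(seeds)) {
    seeds <- copy(seeds)[, aligned_bases := end - start + 1]
  }
  seeds <- seeds[!is_null_barcode(barcode)]
  setorder(seeds, barcode, rname, start, end)
  # a new fragment opens where the gap to the running rightmost end exceeds
  # max_gap; cummax handles seeds nested inside earlier ones
  seeds[, frag := {
    run_end <- shift(cummax(as.numeric(end)), fill = NA)
    cumsum(is.na(run_end) | start - run_end > max_gap)
  }, by = .(barcode, rname)]
  frags <- seeds[, .(
    start = min(start),
    end = max(end),
    n_read_pairs = .N,
    aligned_read_bases = sum(aligned_bases)
  ), by = .(barcode, rname, frag)]
  frags[, frag := NULL]
  frags[, length := end - start + 1]
  setcolorder(frags, c("barcode", "rname", "start", "end", "length",
                       "n_read_pairs", "aligned_read_bases"))
  frags[]
}

#' Library-quality statistics of a fragment set
#'
#' The five linked-read library metrics:
#' * `c_r` -- short-read coverage within fragments. The default (`"pooled"`)
#'   is the ratio of total aligned read bases to total fragment length; the
#'   `"per_fragment_mean"` alternative averages the per-fragment ratio
#'   `aligned_read_bases / length` (unstable for single-pair fragments, whose
#'   reconstructed length collapses to the insert size -- see the package
#'   vignette).
#' * `c_f` -- physical coverage: total fragment length over genome length.
#' * `n_fp` -- mean number of fragments per barcode.
#' * `mu_fl` -- unweighted mean fragment length (bases).
#' * `wmu_fl` -- length-weighted mean fragment length, `sum(L^2) / sum(L)`
#'   (bases); always `>= mu_fl`.
#'
#' @param frags fragment table from [reconstruct_fragments()].
#' @param genome_length scalar genome length, or a named vector of reference
#'   lengths -- in which case the genome length is the summed length of the
#'   references that carry at least one fragment.
#' @param min_pairs_per_fragment drop fragments supported by fewer read
#'   pairs before computing statistics (default 1 = keep all; singleton
#'   seeds are legitimate fragments but inflate `n_fp`).
#' @param cr_mode `"pooled"` (default) or `"per_fragment_mean"`, see above.
#' @return list of class `library_stats` with fields `c_r`, `c_f`, `n_fp`,
#'   `mu_fl`, `wmu_fl`, `n_fragments`, `n_barcodes`.
#' @export
compute_library_stats <- function(frags, genome_length,
                                  min_pairs_per_fragment = 1,
                                  cr_mode = c("pooled", "per_fragment_mean")) {
  cr_mode <- match.arg(cr_mode)
  frags <- as.data.table(frags)
  frags <- frags[n_read_pairs >= min_pairs_per_fragment]
  if (nrow(frags) == 0L) {
    stop("stats error: no fragments survive the min_pairs filter")
  }
  if (length(genome_length) > 1L || !is.null(names(genome_length))) {
    genome_length <- sum(genome_length[names(genome_length) %in% frags$rname])
  }
  stopifnot(genome_length > 0)
  c_r <- switch(cr_mode,
                pooled = sum(frags$aligned_read_bases) / sum(frags$length),
                per_fragment_mean = mean(frags$aligned_read_bases / frags$length))
  structure(list(
    c_r = c_r,
    c_f = sum(frags$length) / genome_length,
    n_fp = nrow(frags) / uniqueN(frags$barcode),
    mu_fl = mean(frags$length),
    wmu_fl = sum(frags$length^2) / sum(frags$length),
    n_fragments = nrow(frags),
    n_barcodes = uniqueN(frags$barcode)
  ), class = "library_stats")
}

#' @export
print.library_stats <- function(x, ...) {
  cat(sprintf(paste0(
    "library_stats over %d fragments / %d barcodes:\n",
    "  C_R    = %.3f\n  C_F    = %.2f\n  N_F/P  = %.2f\n",
    "  mu_FL  = %.2f kb\n  Wmu_FL = %.2f kb\n"),
    x$n_fragments, x$n_barcodes, x$c_r, x$c_f, x$n_fp,
    x$mu_fl / 1000, x$wmu_fl / 1000))
  invisible(x)
}

#' Simulator/reconstruction parameter-recovery experiment
#'
#' Closes the loop between the simulator and the fragment module: samples
#' ground-truth fragments and read-pair placements under `config`,
#' reconstructs fragments from the truth alignments with
#' [reconstruct_fragments()], and measures the library statistics of the
#' reconstruction. On references large relative to
#' `n_fp * max_gap` the recovered `c_r`, `n_fp` and `mu_fl` approach the
#' configured values (see the package vignette for the co-barcode collision
#' analysis that governs this).
#'
#' @param refs reference description (see [sample_fragments()]).
#' @param config a [sim_config()].
#' @param max_gap extension distance for reconstruction (default 200 kb).
#' @param abundances optional abundances forwarded to [sample_fragments()].
#' @return list with `stats` (a `library_stats`), `fragments_truth`,
#'   `fragments_reconstructed`, `n_pairs`.
#' @export
parameter_recovery <- function(refs, config, max_gap = 200000,
                               abundances = NULL) {
  refs <- as_ref_table(refs)
  frags <- sample_fragments(refs, config, abundances)
  pairs <- simulate_read_pairs(frags, config)
  seeds <- pairs_to_seeds(pairs, config$read_length)
  rec <- reconstruct_fragments(seeds, max_gap = max_gap)
  stats <- compute_library_stats(rec, sum(refs$length))
  list(stats = stats, fragments_truth = frags,
       fragments_reconstructed = rec, n_pairs = nrow(pairs))
}
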