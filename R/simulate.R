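#' Simulator configuration
#'
#' Parameters of the linked-read library generator. Defaults are the 10x
#' Genomics simulation preset `C_F = 500, C_R = 0.2, N_F/P = 16, mu_FL = 20`;
#' the stLFR preset differs only in `n_fp = 1`.
#'
#' @param c_f target physical coverage of each genome by long fragments
#'   (fold). On a metagenome, genome g receives physical coverage
#'   `c_f * n_genomes * a_g` where `a_g` are relative abundances summing to
#'   1, so equal abundances give every genome coverage `c_f`.
#' @param c_r target short-read coverage within a fragment (fold).
#' @param n_fp mean number of long fragments per partition (barcode). Drawn
#'   zero-truncated Poisson(`n_fp`); `n_fp = 1` is treated as deterministic
#'   (exactly one fragment per barcode, the stLFR ideal).
#' @param mu_fl mean fragment length in kilobases. Fragment lengths are drawn
#'   from the chosen `fragment_length_model` and truncated to
#'   `[1 kb, replicon length]`.
#' @param read_length read length in bases.
#' @param insert_mean,insert_sd paired-end insert size model (bases); inserts
#'   are Normal, truncated to `[2 * read_length, fragment length]`.
#' @param error_rate per-base substitution probability in read payloads.
#' @param barcode_error_rate per-base substitution probability applied to the
#'   barcode as observed in the FASTQ output (the truth SAM always carries
#'   the true barcode).
#' @param platform platform preset used for the barcode length of generated
#'   pools.
#' @param fragment_length_model `"exponential"` (default) or `"fixed"`.
#' @param barcode_pool optional character vector of barcodes to draw
#'   partitions from; generated at random when `NULL`.
#' @param seed integer seed; fixing it makes all simulator output
#'   reproducible.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(c_f = 500, c_r = 0.2, n_fp = 16, mu_fl = 20,
                       read_length = 150L, insert_mean = 350, insert_sd = 35,
                       error_rate = 0.001, barcode_error_rate = 0,
                       platform = c("tenx", "stlfr", "tellseq"),
                       fragment_length_model = c("exponential", "fixed"),
                       barcode_pool = NULL, seed = 1L) {
  platform <- match.arg(platform)
  fragment_length_model <- match.arg(fragment_length_model)
  stopifnot(c_f >= 0, c_r > 0, n_fp >= 1, mu_fl > 0, read_length > 0,
            insert_mean > 0, insert_sd >= 0, error_rate >= 0,
            barcode_error_rate >= 0)
  structure(list(c_f = c_f, c_r = c_r, n_fp = n_fp, mu_fl = mu_fl,
                 read_length = as.integer(read_length),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 error_rate = error_rate,
                 barcode_error_rate = barcode_error_rate,
                 platform = platform,
                 fragment_length_model = fragment_length_model,
                 barcode_pool = barcode_pool,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw lognormal community abundances
#'
#' Relative abundances for a set of genomes are drawn i.i.d.
#' lognormal(`mu_ln`, `sigma_ln`) and normalized to sum to exactly 1.
#' `sigma_ln = 0` degenerates to equal abundances.
#'
#' @param genome_ids character vector of genome identifiers.
#' @param mu_ln,sigma_ln log-scale mean and standard deviation.
#' @param seed optional seed applied before drawing.
#' @return named numeric vector of relative abundances summing to 1.
#' @export
sample_abundances <- function(genome_ids, mu_ln = 0, sigma_ln = 1, seed = NULL) {
  if (length(genome_ids) < 1L) stop("need at least one genome")
  if (sigma_ln < 0) stop("parameter error: sigma_ln must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  x <- rlnorm(length(genome_ids), mu_ln, sigma_ln)
  ab <- x / sum(x)
  names(ab) <- genome_ids
  ab
}

# normalize the reference description into data.table(genome_id, rname, length)
as_ref_table <- function(refs) {
  if (is.numeric(refs) && !is.null(names(refs))) {
    refs <- data.table(genome_id = names(refs), rname = names(refs),
                       length = as.numeric(refs))
  } else {
    refs <- as.data.table(refs)
    if (!"genome_id" %in% names(refs)) refs[, genome_id := rname]
  }
  stopifnot(all(c("genome_id", "rname", "length") %in% names(refs)),
            all(refs$length > 0))
  refs[, .(genome_id = as.character(genome_id), rname = as.character(rname),
           length = as.numeric(length))]
}

#' Sample ground-truth long fragments
#'
#' Draws long DNA fragments genome by genome: the fragment count per genome
#' is `round(cov_g * G_g / (mu_fl * 1000))` with `cov_g` the genome's target
#' physical coverage (see [sim_config()]), lengths follow the configured
#' length model truncated to `[1 kb, replicon length]`, and start positions
#' are uniform. Fragments are then pooled, shuffled, and grouped into
#' partitions of zero-truncated Poisson(`n_fp`) size; each partition receives
#' one distinct barcode.
#'
#' @param refs either a named numeric vector of replicon lengths or a
#'   `data.table(genome_id, rname, length)`; multiple replicons per
#'   `genome_id` are allowed and weighted by length.
#' @param config a [sim_config()].
#' @param abundances optional named relative abundances per `genome_id`
#'   (default: equal).
#' @return `data.table(fragment_id, barcode, genome_id, rname, start, end,
#'   length, n_read_pairs)` (`n_read_pairs` is filled by
#'   [simulate_read_pairs()]).
#' @export
sample_fragments <- function(refs, config, abundances = NULL) {
  stopifnot(inherits(config, "sim_config"))
  refs <- as_ref_table(refs)
  set.seed(config$seed)
  genomes <- refs[, .(g_len = sum(length)), by = genome_id]
  if (is.null(abundances)) {
    abundances <- stats::setNames(rep(1 / nrow(genomes), nrow(genomes)),
                                  genomes$genome_id)
  }
  stopifnot(all(genomes$genome_id %in% names(abundances)))
  ab <- abundances[genomes$genome_id] / sum(abundances[genomes$genome_id])
  cov_g <- config$c_f * nrow(genomes) * ab
  mu_bp <- config$mu_fl * 1000

  frag_list <- vector("list", nrow(genomes))
  for (i in seq_len(nrow(genomes))) {
    gid <- genomes$genome_id[i]
    n_g <- round(cov_g[i] * genomes$g_len[i] / mu_bp)
    if (n_g < 1) next
    reps <- refs[genome_id == gid]
    # replicon per fragment, proportional to replicon length
    rep_idx <- sample.int(nrow(reps), n_g, replace = TRUE,
                          prob = reps$length)
    rep_len <- reps$length[rep_idx]
    len <- switch(config$fragment_length_model,
                  exponential = rexp(n_g, rate = 1 / mu_bp),
                  fixed = rep(mu_bp, n_g))
    len <- pmin(pmax(round(len), 1000), rep_len)
    start <- floor(runif(n_g, 1, rep_len - len + 1 + 1))
    frag_list[[i]] <- data.table(genome_id = gid,
                                 rname = reps$rname[rep_idx],
                                 start = start,
                                 end = start + len - 1,
                                 length = len)
  }
  frags <- rbindlist(frag_list)
  if (nrow(frags) == 0L) {
    return(data.table(fragment_id = character(), barcode = character(),
                      genome_id = character(), rname = character(),
                      start = numeric(), end = numeric(), length = numeric(),
                      n_read_pairs = integer()))
  }
  frags <- frags[sample.int(.N)]

  # partition sizes: zero-truncated Poisson, deterministic when n_fp == 1
  n <- nrow(frags)
  if (config$n_fp == 1) {
    sizes <- rep(1L, n)
  } else {
    sizes <- integer(0)
    while (sum(sizes) < n) {
      sizes <- c(sizes, rztpois(ceiling((n - sum(sizes)) / config$n_fp) + 8L,
                                config$n_fp))
    }
    sizes <- sizes[cumsum(sizes) - sizes < n]   # partitions that receive >= 1 fragment
  }
  part <- rep(seq_along(sizes), times = sizes)[seq_len(n)]
  n_part <- max(part)
  pool <- config$barcode_pool
  if (is.null(pool)) {
    bl <- platform_spec(config$platform)$barcode_length
    pool <- random_barcodes(n_part, bl)
  } else if (length(pool) < n_part) {
    stop("simulation error: barcode pool exhausted (need ", n_part,
         " barcodes, have ", length(pool), "); supply a larger pool")
  } else {
    pool <- sample(pool, n_part)
  }
  frags[, barcode := pool[part]]
  frags[, fragment_id := sprintf("F%07d", seq_len(.N))]
  frags[, n_read_pairs := 0L]
  setcolorder(frags, c("fragment_id", "barcode", "genome_id", "rname",
                       "start", "end", "length", "n_read_pairs"))
  frags[]
}

#' Place ground-truth read pairs on fragments
#'
#' Each fragment of length `L` receives
#' `round(c_r * L / (2 * read_length))` read pairs. Inserts are Normal
#' (`insert_mean`, `insert_sd`), rounded and truncated to
#' `[2 * read_length, L]`; the pair's leftmost base is uniform within the
#' fragment. Positions are true alignment coordinates; no errors are applied
#' at this stage.
#'
#' @param frags fragment table from [sample_fragments()] (updated by
#'   reference with the realized `n_read_pairs`).
#' @param config a [sim_config()].
#' @return `data.table(read_id, barcode, fragment_id, genome_id, rname,
#'   pos1, pos2, insert)` where `pos1`/`pos2` are the 1-based leftmost
#'   aligned bases of the forward (R1) and reverse (R2) mates.
#' @export
simulate_read_pairs <- function(frags, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  rl <- config$read_length
  k <- round(config$c_r * frags$length / (2 * rl))
  frags[, n_read_pairs := as.integer(k)]
  use <- which(k > 0)
  if (length(use) == 0L) {
    return(data.table(read_id = character(), barcode = character(),
                      fragment_id = character(), genome_id = character(),
                      rname = character(), pos1 = numeric(), pos2 = numeric(),
                      insert = numeric()))
  }
  fi <- rep(use, times = k[use])
  n <- length(fi)
  L <- frags$length[fi]
  insert <- round(rnorm(n, config$insert_mean, config$insert_sd))
  insert <- pmin(pmax(insert, 2 * rl), L)
  start <- floor(runif(n, frags$start[fi], frags$end[fi] - insert + 1 + 1))
  pairs <- data.table(
    read_id = paste0(frags$fragment_id[fi], ":",
                     sequence_within(fi)),
    barcode = frags$barcode[fi],
    fragment_id = frags$fragment_id[fi],
    genome_id = frags$genome_id[fi],
    rname = frags$rname[fi],
    pos1 = start,
    pos2 = start + insert - rl,
    insert = insert
  )
  pairs[]
}

# per-group running index for a sorted integer vector of group ids
sequence_within <- function(group) {
  seq_along(group) - match(group, group) + 1L
}

# inject substitution errors; returns modified sequences and quality strings
# (Q35 = "D" for correct bases, Q20 = "5" at injected errors)
inject_errors <- function(seqs, rate) {
  L <- nchar(seqs)
  quals <- strrep("D", L)
  if (rate > 0 && length(seqs)) {
    stopifnot(length(unique(L)) == 1L)
    rl <- L[1L]
    hits <- which(runif(length(seqs) * rl) < rate)
    if (length(hits)) {
      ri <- (hits - 1L) %/% rl + 1L
      pp <- (hits - 1L) %% rl + 1L
      alts <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                   G = c("A", "C", "T"), T = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))
      for (j in seq_along(hits)) {
        cur <- substr(seqs[ri[j]], pp[j], pp[j])
        sub <- sample(alts[[cur]], 1L)
        substr(seqs[ri[j]], pp[j], pp[j]) <- sub
        substr(quals[ri[j]], pp[j], pp[j]) <- "5"
      }
    }
  }
  list(seq = seqs, qual = quals)
}

#' Generate reads and truth alignments from placed pairs
#'
#' Materializes read sequences for simulated pair placements, injecting
#' i.i.d. substitution errors at `error_rate` (quality Q35 for correct
#' bases, Q20 at injected errors), and returns both the unified FASTQ
#' records and the matching truth alignment table. R2 is sequenced from the
#' reverse strand, so its FASTQ sequence is the reverse complement of the
#' reference substring while the truth SAM stores the forward-strand
#' sequence with the reverse flag set. FASTQ and SAM describe the identical
#' read set.
#'
#' @param pairs pair table from [simulate_read_pairs()].
#' @param sequences named character vector (or `DNAStringSet`) of reference
#'   sequences, names matching `rname`.
#' @param config a [sim_config()].
#' @return list with `records` (unified FASTQ `data.table`, both mates) and
#'   `truth` (alignment `data.table` ready for [write_sam()]).
#' @export
generate_reads <- function(pairs, sequences, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- as.character(sequences)
  }
  rl <- config$read_length
  missing_ref <- setdiff(unique(pairs$rname), names(sequences))
  if (length(missing_ref)) {
    stop("missing reference sequence(s): ", paste(missing_ref, collapse = ", "))
  }
  ref <- sequences[pairs$rname]
  fwd1 <- substr(ref, pairs$pos1, pairs$pos1 + rl - 1L)
  fwd2 <- substr(ref, pairs$pos2, pairs$pos2 + rl - 1L)
  e1 <- inject_errors(fwd1, config$error_rate)
  # errors are injected in read space for R2: mutate the read as sequenced
  r2_read <- revcomp(fwd2)
  e2 <- inject_errors(r2_read, config$error_rate)

  bc_obs <- pairs$barcode
  if (config$barcode_error_rate > 0) {
    eb <- inject_errors(bc_obs, config$barcode_error_rate)
    bc_obs <- eb$seq
  }

  records <- rbindlist(list(
    data.table(read_id = pairs$read_id, mate = 1L,
               sequence = e1$seq, qualities = e1$qual, barcode = bc_obs),
    data.table(read_id = pairs$read_id, mate = 2L,
               sequence = e2$seq, qualities = e2$qual, barcode = bc_obs)
  ))
  records[, platform := config$platform]

  truth <- rbindlist(list(
    data.table(read_id = pairs$read_id, flag = 99L, rname = pairs$rname,
               pos = pairs$pos1, mapq = 60L, cigar = paste0(rl, "M"),
               mate_rname = pairs$rname, mate_pos = pairs$pos2,
               isize = pairs$insert, barcode = pairs$barcode,
               seq = e1$seq, qual = e1$qual),
    data.table(read_id = pairs$read_id, flag = 147L, rname = pairs$rname,
               pos = pairs$pos2, mapq = 60L, cigar = paste0(rl, "M"),
               mate_rname = pairs$rname, mate_pos = pairs$pos1,
               isize = -pairs$insert, barcode = pairs$barcode,
               seq = revcomp(e2$seq), qual = reverse_string(e2$qual))
  ))
  list(records = records[], truth = truth[])
}

reverse_string <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Generate a random reference genome
#'
#' Uniform random nucleotide sequences, for tests and self-contained
#' simulations.
#'
#' @param lengths named numeric vector of replicon lengths.
#' @param seed optional seed.
#' @return named character vector of sequences.
#' @export
random_genome <- function(lengths, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- vapply(lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
  names(out) <- names(lengths)
  out
}

#' Simulate a complete linked-read library
#'
#' End-to-end convenience wrapper: draws abundances (for multi-genome
#' references), samples fragments and read pairs, materializes reads, and
#' optionally writes the unified FASTQ pair, truth SAM, truth-fragment TSV
#' and a JSON manifest of realized parameters.
#'
#' @param refs reference description (see [sample_fragments()]).
#' @param config a [sim_config()].
#' @param sequences reference sequences; generated at random when `NULL` and
#'   reads are requested.
#' @param abundances optional abundances; when `NULL` and there are several
#'   genomes, drawn with [sample_abundances()] (lognormal sigma 1).
#' @param out_prefix when non-`NULL`, output files
#'   `<prefix>_R1.fq`, `<prefix>_R2.fq`, `<prefix>_truth.sam`,
#'   `<prefix>_fragments.tsv` and `<prefix>_manifest.json` are written.
#' @param reads logical; materialize read sequences (requires `sequences` or
#'   random generation). With `reads = FALSE` only coordinates are produced,
#'   which is considerably cheaper on large references.
#' @return list with `config`, `abundances`, `fragments`, `pairs`, and (with
#'   `reads = TRUE`) `records`, `truth`, plus `files` when written.
#' @export
simulate_library <- function(refs, config, sequences = NULL,
                             abundances = NULL, out_prefix = NULL,
                             reads = !is.null(sequences) || !is.null(out_prefix)) {
  refs <- as_ref_table(refs)
  genomes <- unique(refs$genome_id)
  if (is.null(abundances)) {
    abundances <- if (length(genomes) > 1L) {
      sample_abundances(genomes, 0, 1, seed = config$seed)
    } else {
      stats::setNames(1, genomes)
    }
  }
  frags <- sample_fragments(refs, config, abundances)
  pairs <- simulate_read_pairs(frags, config)
  out <- list(config = config, abundances = abundances,
              fragments = frags, pairs = pairs)
  if (reads) {
    if (is.null(sequences)) {
      sequences <- random_genome(stats::setNames(refs$length, refs$rname),
                                 seed = config$seed + 3L)
    }
    gen <- generate_reads(pairs, sequences, config)
    out$records <- gen$records
    out$truth <- gen$truth
  }
  if (!is.null(out_prefix)) {
    ref_lengths <- stats::setNames(refs$length, refs$rname)
    files <- list(
      r1 = paste0(out_prefix, "_R1.fq"),
      r2 = paste0(out_prefix, "_R2.fq"),
      sam = paste0(out_prefix, "_truth.sam"),
      fragments = paste0(out_prefix, "_fragments.tsv"),
      manifest = paste0(out_prefix, "_manifest.json")
    )
    write_unified_fastq(out$records[mate == 1L], files$r1)
    write_unified_fastq(out$records[mate == 2L], files$r2)
    write_sam(out$truth, ref_lengths, files$sam)
    fwrite(frags, files$fragments, sep = "\t")
    manifest <- list(
      config = unclass(config)[c("c_f", "c_r", "n_fp", "mu_fl", "read_length",
                                 "insert_mean", "insert_sd", "error_rate",
                                 "barcode_error_rate", "platform", "seed")],
      realized = list(
        n_fragments = nrow(frags),
        n_barcodes = uniqueN(frags$barcode),
        n_read_pairs = nrow(pairs),
        mean_fragment_length = mean(frags$length)
      )
    )
    write_json(manifest, files$manifest, auto_unbox = TRUE, digits = NA)
    out$files <- files
  }
  out
}
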