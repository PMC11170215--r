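#' Filter metagenomic SNVs by caller-appropriate thresholds
#'
#' For FreeBayes and SAMtools/BCFtools calls, a record is kept iff its total
#' depth is at least `min_depth` (default 6), at least `min_alt` reads
#' (default 2) support the alternative allele, and the variant quality is at
#' least `min_qual` (default 15) -- i.e. records *below* any threshold are
#' removed, boundary values pass. inStrain does not report variant quality
#' scores, so its records bypass quality control entirely.
#'
#' @param records SNV `data.table` with columns `total_depth`, `alt_support`,
#'   `quality` (see [read_snv_vcf()]).
#' @param caller one of `"freebayes"`, `"samtools"`, `"instrain"`.
#' @param min_depth,min_alt,min_qual thresholds (records strictly below are
#'   removed).
#' @return the filtered `data.table`.
#' @export
filter_snvs <- function(records, caller = c("freebayes", "samtools", "instrain"),
                        min_depth = 6, min_alt = 2, min_qual = 15) {
  caller <- match.arg(caller)
  records <- as.data.table(records)
  if (caller == "instrain") return(records[])
  need <- c("total_depth", "alt_support", "quality")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("record error: missing field(s) ", paste(miss, collapse = ", "),
         " required to filter ", caller, " calls")
  }
  if (anyNA(records[, .SD, .SDcols = need])) {
    stop("record error: NA depth/support/quality in ", caller, " records")
  }
  records[total_depth >= min_depth & alt_support >= min_alt &
            quality >= min_qual]
}

#' Minor-allele-frequency matrix across samples
#'
#' Builds the SNV-by-sample MAF matrix used for strain analysis. Sites are
#' biallelic SNVs keyed by (genome, position, ref, alt). The minor allele of
#' each site is fixed by the designated reference sample: the allele whose
#' frequency there is at most 0.5 (a 50/50 tie resolves to the alternative
#' allele). Cells hold `minor_count / total_count` in each sample -- by
#' construction at most 0.5 in the reference column, but free to exceed 0.5
#' elsewhere, which is exactly the strain-replacement signal. A site enters
#' the matrix only if at least one sample supports its minor allele with at
#' least `min_support` reads; sites absent from the reference sample are
#' dropped (their number is reported in the `dropped_no_reference`
#' attribute). Sites absent from a non-reference sample are missing (`NA`).
#'
#' @param records combined filtered SNV table over samples; required columns
#'   `sample_id`, `genome_id`, `pos`, `ref`, `alt`, `total_depth`,
#'   `alt_support`.
#' @param reference_sample sample id anchoring the minor-allele definition.
#' @param min_support minimum minor-allele read support for a site to enter
#'   the combined set (default 3, i.e. "exceeding 2").
#' @return object of class `maf_matrix`: list with `maf` (numeric matrix,
#'   rows = site keys, columns = samples), `sites` (site `data.table`), and
#'   `reference_sample`.
#' @export
build_maf_matrix <- function(records, reference_sample, min_support = 3) {
  records <- as.data.table(records)
  need <- c("sample_id", "genome_id", "pos", "ref", "alt",
            "total_depth", "alt_support")
  stopifnot(all(need %in% names(records)))
  if (!reference_sample %in% records$sample_id) {
    stop("reference sample '", reference_sample, "' has no records")
  }
  records <- records[nchar(ref) == 1L & nchar(alt) == 1L]  # biallelic SNVs only
  all_samples <- unique(records$sample_id)
  records[, site := paste(genome_id, pos, ref, alt, sep = ":")]

  refrec <- records[sample_id == reference_sample]
  n_sites_all <- uniqueN(records$site)
  dropped <- n_sites_all - uniqueN(records[site %in% refrec$site, site])
  records <- records[site %in% refrec$site]

  # minor allele fixed by the reference sample (tie at 0.5 -> alt)
  minor <- refrec[, .(minor_is_alt = (alt_support / total_depth) <= 0.5),
                  by = site]
  records <- merge(records, minor, by = "site")
  records[, minor_count := fifelse(minor_is_alt, alt_support,
                                   total_depth - alt_support)]
  records[, maf := minor_count / total_depth]

  keep_sites <- records[minor_count >= min_support, unique(site)]
  records <- records[site %in% keep_sites]
  if (nrow(records) == 0L) stop("no site passes the minor-allele support filter")

  wide <- dcast(records, site ~ sample_id, value.var = "maf",
                fun.aggregate = function(x) x[1L])
  m <- as.matrix(wide[, !"site"])
  rownames(m) <- wide$site
  absent <- setdiff(all_samples, colnames(m))
  if (length(absent)) {
    m <- cbind(m, matrix(NA_real_, nrow(m), length(absent),
                         dimnames = list(NULL, absent)))
  }
  m <- m[, all_samples, drop = FALSE]
  sites <- unique(records[, .(site, genome_id, pos, ref, alt, minor_is_alt)])
  setkey(sites, NULL)
  out <- structure(list(maf = m,
                        sites = sites[match(rownames(m), site)],
                        reference_sample = reference_sample),
                   class = "maf_matrix")
  attr(out, "dropped_no_reference") <- dropped
  out
}

#' @export
print.maf_matrix <- function(x, ...) {
  cat("maf_matrix:", nrow(x$maf), "SNV sites x", ncol(x$maf),
      "samples (reference:", x$reference_sample, ")\n")
  invisible(x)
}

# Calinski-Harabasz index of a kmeans fit
calinski_harabasz <- function(km, n) {
  k <- length(km$size)
  if (k <= 1L) return(NA_real_)
  w <- km$tot.withinss
  b <- km$betweenss
  if (w <= 0) return(Inf)
  (b / (k - 1)) / (w / (n - k))
}

#' Cluster SNVs by minor-allele frequency
#'
#' Runs k-means (Lloyd's algorithm, 10 restarts, up to 300 iterations) on
#' the complete-case rows of a MAF matrix restricted to the given samples,
#' for every k in `k_range` with `k < n` rows, and selects the k maximizing
#' the Calinski--Harabasz index. Degenerate inputs (all rows identical)
#' yield a single cluster with `chosen_k = 1`.
#'
#' @param maf numeric matrix of MAF values (rows = SNVs); typically
#'   `x$maf[, c(ref, target)]` of a [build_maf_matrix()] object. Rows with
#'   any missing value are excluded (no imputation).
#' @param k_range candidate cluster numbers (default 2:10).
#' @param seed RNG seed fixed before clustering.
#' @return list with `labels` (named by row), `chosen_k`, `ch` (named vector
#'   of Calinski--Harabasz scores), `centers`, `rows_used`.
#' @export
cluster_maf <- function(maf, k_range = 2:10, seed = 1L) {
  maf <- as.matrix(maf)
  complete <- stats::complete.cases(maf)
  m <- maf[complete, , drop = FALSE]
  if (nrow(m) < 3L) {
    stop("cluster error: fewer than 3 SNVs with complete values")
  }
  n_distinct <- nrow(unique(m))
  ks <- k_range[k_range < nrow(m) & k_range <= n_distinct]
  if (n_distinct == 1L || length(ks) == 0L) {
    labels <- rep(1L, nrow(m))
    names(labels) <- rownames(m)
    return(list(labels = labels, chosen_k = 1L,
                ch = stats::setNames(numeric(0), character(0)),
                centers = matrix(colMeans(m), nrow = 1,
                                 dimnames = list(NULL, colnames(m))),
                rows_used = rownames(m)))
  }
  set.seed(seed)
  fits <- lapply(ks, function(k) {
    # empty-cluster warnings are routine when probing k values beyond the
    # structure actually present; the CH index weeds those fits out
    suppressWarnings(
      kmeans(m, centers = k, nstart = 10, iter.max = 300,
             algorithm = "Lloyd")
    )
  })
  ch <- vapply(fits, calinski_harabasz, numeric(1), n = nrow(m))
  names(ch) <- ks
  best <- which.max(ch)
  labels <- fits[[best]]$cluster
  names(labels) <- rownames(m)
  list(labels = labels, chosen_k = ks[best], ch = ch,
       centers = fits[[best]]$centers, rows_used = rownames(m))
}

#' Detect strain-frequency-change events
#'
#' Summarizes each SNV cluster of a sample pair: mean minor-allele frequency
#' in the reference and target samples, and whether the cluster *crossed*
#' (its minor alleles in the reference became major in the target:
#' `mean_ref < threshold` and `mean_target > threshold`, both strict).
#' Events are sorted by decreasing `|delta_maf|`.
#'
#' @param labels cluster labels from [cluster_maf()].
#' @param maf the matrix the clustering ran on (reference column first,
#'   target second).
#' @param sample_pair character vector `c(reference, target)`; defaults to
#'   the matrix column names.
#' @param cross_threshold MAF threshold for a minor/major flip (default 0.5).
#' @param genome_id optional genome annotation carried onto the events.
#' @return `data.table(genome_id, cluster_id, snv_count, maf_ref, maf_target,
#'   delta_maf, crossed)`.
#' @export
detect_strain_shift <- function(labels, maf, sample_pair = colnames(maf),
                                cross_threshold = 0.5, genome_id = NA_character_) {
  maf <- as.matrix(maf)[names(labels), , drop = FALSE]
  ev <- data.table(cluster_id = labels,
                   maf_ref = maf[, sample_pair[1L]],
                   maf_target = maf[, sample_pair[2L]])
  ev <- ev[, .(snv_count = .N,
               maf_ref = mean(maf_ref),
               maf_target = mean(maf_target)),
           by = cluster_id]
  ev[, genome_id := genome_id]
  ev[, delta_maf := maf_target - maf_ref]
  ev[, crossed := maf_ref < cross_threshold & maf_target > cross_threshold]
  ev <- ev[order(-abs(delta_maf))]
  setcolorder(ev, c("genome_id", "cluster_id", "snv_count",
                    "maf_ref", "maf_target", "delta_maf", "crossed"))
  ev[]
}

#' Strain-shift analysis for one sample pair
#'
#' Convenience wrapper running [cluster_maf()] and [detect_strain_shift()]
#' per genome for a reference/target sample pair, skipping (with a message)
#' genomes with fewer than 3 complete SNV rows.
#'
#' @param maf_obj a [build_maf_matrix()] object.
#' @param target_sample target sample id (the reference is the matrix's
#'   anchoring sample).
#' @param k_range,seed passed to [cluster_maf()].
#' @param cross_threshold passed to [detect_strain_shift()].
#' @return `data.table` of events over all analyzable genomes.
#' @export
strain_shift_events <- function(maf_obj, target_sample, k_range = 2:10,
                                seed = 1L, cross_threshold = 0.5) {
  stopifnot(inherits(maf_obj, "maf_matrix"),
            target_sample %in% colnames(maf_obj$maf))
  pair <- c(maf_obj$reference_sample, target_sample)
  out <- list()
  for (g in unique(maf_obj$sites$genome_id)) {
    rows <- maf_obj$sites[genome_id == g, site]
    m <- maf_obj$maf[rows, pair, drop = FALSE]
    cl <- tryCatch(cluster_maf(m, k_range = k_range, seed = seed),
                   error = function(e) NULL)
    if (is.null(cl)) {
      message("skipping genome ", g, ": fewer than 3 complete SNV rows")
      next
    }
    out[[g]] <- detect_strain_shift(cl$labels, m, sample_pair = pair,
                                    cross_threshold = cross_threshold,
                                    genome_id = g)
  }
  if (length(out) == 0L) {
    return(data.table(genome_id = character(), cluster_id = integer(),
                      snv_count = integer(), maf_ref = numeric(),
                      maf_target = numeric(), delta_maf = numeric(),
                      crossed = logical()))
  }
  rbindlist(out)
}
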