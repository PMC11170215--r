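#' Read SNV records from a VCF file
#'
#' Parses a single-sample VCF 4.x into the flat SNV record table the strain
#' module consumes. Multi-allelic rows are split into one record per
#' alternative allele and non-SNV alleles are dropped. Total depth is taken
#' from the genotype `DP` field (falling back to `INFO/DP`); alternative
#' allele support from genotype `AD` (allele depths), falling back to
#' `AO`/`INFO/AO` (FreeBayes) or `INFO/DP4` (BCFtools).
#'
#' @param path VCF file (plain or bgzipped).
#' @param sample_id sample label to stamp on the records; defaults to the
#'   VCF sample name (or the file name for site-only VCFs).
#' @return `data.table(sample_id, genome_id, pos, ref, alt, total_depth,
#'   alt_support, quality)` where `genome_id` is the VCF CHROM.
#' @export
read_snv_vcf <- function(path, sample_id = NULL) {
  vcf <- VariantAnnotation::readVcf(path)
  n <- length(vcf)
  if (is.null(sample_id)) {
    sn <- colnames(vcf)
    sample_id <- if (length(sn) >= 1L) sn[1L] else basename(path)
  }
  if (n == 0L) {
    return(data.table(sample_id = character(), genome_id = character(),
                      pos = integer(), ref = character(), alt = character(),
                      total_depth = numeric(), alt_support = numeric(),
                      quality = numeric()))
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt_list <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt_list)
  row_idx <- rep(seq_len(n), n_alt)
  alt_idx <- unlist(lapply(n_alt, seq_len), use.names = FALSE)

  g <- VariantAnnotation::geno(vcf)
  info <- VariantAnnotation::info(vcf)
  # total depth per VCF row
  dp <- rep(NA_real_, n)
  if ("DP" %in% names(g) && ncol(vcf) >= 1L) {
    dp <- as.numeric(g$DP[, 1L])
  }
  if (all(is.na(dp)) && "DP" %in% names(info)) {
    dp <- as.numeric(info$DP)
  }
  # alt support per (row, alt allele)
  ad_of <- function(i, j) NA_real_
  if ("AD" %in% names(g) && ncol(vcf) >= 1L) {
    ad <- g$AD[, 1L]
    ad_of <- function(i, j) {
      v <- ad[[i]]
      if (length(v) >= j + 1L) as.numeric(v[j + 1L]) else NA_real_
    }
  } else if ("AO" %in% names(g) && ncol(vcf) >= 1L) {
    ao <- g$AO[, 1L]
    ad_of <- function(i, j) {
      v <- ao[[i]]
      if (length(v) >= j) as.numeric(v[j]) else NA_real_
    }
  } else if ("AO" %in% names(info)) {
    ao <- info$AO
    ad_of <- function(i, j) {
      v <- ao[[i]]
      if (length(v) >= j) as.numeric(v[j]) else NA_real_
    }
  } else if ("DP4" %in% names(info)) {
    dp4 <- info$DP4
    ad_of <- function(i, j) {
      v <- dp4[[i]]
      if (length(v) == 4L) sum(as.numeric(v[3:4])) else NA_real_
    }
  }

  dt <- data.table(
    sample_id = sample_id,
    genome_id = as.character(GenomeInfoDb::seqnames(rr))[row_idx],
    pos = BiocGenerics::start(rr)[row_idx],
    ref = as.character(VariantAnnotation::ref(vcf))[row_idx],
    alt = as.character(unlist(alt_list, use.names = FALSE)),
    total_depth = dp[row_idx],
    alt_support = mapply(ad_of, row_idx, alt_idx),
    quality = as.numeric(rr$QUAL)[row_idx]
  )
  dt[nchar(ref) == 1L & nchar(alt) == 1L & alt %chin% c("A", "C", "G", "T")][]
}
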