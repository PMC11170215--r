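#' Classify a MAG by completeness, contamination and RNA genes
#'
#' Standard minimum-information tiers, checked in order (the first matching
#' rule wins, making the tiers disjoint and exhaustive):
#'
#' 1. `near_complete` -- completeness > 90, contamination < 5, all of the
#'    5S/16S/23S ribosomal RNAs detected, and at least 18 transfer RNAs;
#' 2. `high` -- completeness > 90 and contamination < 5;
#' 3. `medium` -- completeness >= 50 and contamination < 10;
#' 4. `low` -- everything else.
#'
#' All arguments are vectorized.
#'
#' @param completeness percent in `[0, 100]`.
#' @param contamination percent, `>= 0`.
#' @param has_5s,has_16s,has_23s logical; the respective rRNA was detected.
#' @param trna_count number of distinct transfer RNAs detected.
#' @return character vector of tiers.
#' @export
classify_mag <- function(completeness, contamination,
                         has_5s = FALSE, has_16s = FALSE, has_23s = FALSE,
                         trna_count = 0) {
  if (any(completeness < 0 | completeness > 100)) {
    stop("input error: completeness must be in [0, 100]")
  }
  if (any(contamination < 0)) {
    stop("input error: contamination must be >= 0")
  }
  if (any(trna_count < 0)) {
    stop("input error: trna_count must be >= 0")
  }
  hq <- completeness > 90 & contamination < 5
  nc <- hq & has_5s & has_16s & has_23s & trna_count >= 18
  med <- completeness >= 50 & contamination < 10
  fifelse(nc, "near_complete",
          fifelse(hq, "high",
                  fifelse(med, "medium", "low")))
}

#' Machine-readable run summary
#'
#' Aggregates the outputs of the individual modules into one JSON-ready
#' summary object with deterministic section order
#' (`preprocess`, `library`, `quant`, `snv`, `strain`); absent sections are
#' omitted. At least one section must be present.
#'
#' @param preprocess barcode-correction stats (the `stats` element of
#'   [correct_records()]).
#' @param library a [compute_library_stats()] object.
#' @param quant abundance table from [quantify_metagenome()].
#' @param snv list with `pre` and `post` filter record counts.
#' @param strain events table from [strain_shift_events()].
#' @param top_n number of top-abundance genomes reported in the quant
#'   section.
#' @param path optional path; when given the summary is written as JSON.
#' @return the summary as a named list (invisibly when written to `path`).
#' @export
summarize_run <- function(preprocess = NULL, library = NULL, quant = NULL,
                          snv = NULL, strain = NULL, top_n = 10L,
                          path = NULL) {
  sections <- list()
  if (!is.null(preprocess)) sections$preprocess <- preprocess
  if (!is.null(library)) sections$library <- unclass(library)
  if (!is.null(quant)) {
    quant <- as.data.table(quant)
    setorder(quant, -relative_abundance)
    sections$quant <- head(quant, top_n)
  }
  if (!is.null(snv)) {
    stopifnot(is.list(snv), all(c("pre", "post") %in% names(snv)))
    if (snv$post > snv$pre) {
      stop("inconsistent SNV section: post-filter count exceeds pre-filter count")
    }
    sections$snv <- snv[c("pre", "post")]
  }
  if (!is.null(strain)) sections$strain <- as.data.table(strain)
  if (length(sections) == 0L) {
    stop("error: no module artifacts supplied ",
         "(need at least one of preprocess/library/quant/snv/strain)")
  }
  if (!is.null(path)) {
    write_json(sections, path, auto_unbox = TRUE, digits = NA, na = "null")
    return(invisible(sections))
  }
  sections
}
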