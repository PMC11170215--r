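# linkreads

Platform-agnostic processing of **linked-read sequencing data** in R.

Linked-read technologies (10x Genomics Chromium, stLFR, TELL-seq) partition
long, high-molecular-weight DNA fragments into droplets or onto beads, attach
a partition barcode, and sequence short reads from each fragment. The barcode
ties short reads back to their fragment of origin, providing long-range
information at short-read cost — valuable for metagenome assembly, strain
tracking, and structural variation. Each platform, however, ships its own raw
read layout, barcode chemistry and (sometimes) whitelist, and most pipelines
are locked to one platform and to the human genome.

`linkreads` is for bioinformaticians working with linked reads from any of
the three major platforms, on microbial communities or single genomes. It
provides the platform-independent computational core:

* **Unified representation** — raw platform reads are converted into a
  barcoded FASTQ in which the partition barcode travels as a `BX:Z:` token on
  the header (the SAM `BX` tag convention), 16 bp for 10x, 30 bp for stLFR,
  18 bp for TELL-seq.
* **Barcode error correction** — against a whitelist by Hamming distance
  (exact / single-mismatch / ambiguous / uncorrectable), or whitelist-free by
  supporting-read counts (TELL-seq style).
* **Linked-read simulation** — libraries with known ground truth under the
  standard parameterization C_F (fragment coverage), C_R (read coverage per
  fragment), N_F/P (fragments per partition) and μ_FL (mean fragment
  length), emitting unified FASTQ, truth SAM and truth fragment tables.
* **Fragment reconstruction** — co-barcoded read pairs are used as seeds and
  greedily extended (equivalently: single-linkage clustered) up to a 200-kb
  gap, after discarding pairs with outer distance > μ_PE + 3σ_PE.
* **Library statistics** — C_R, C_F, N_F/P, μ_FL and the length-weighted
  Wμ_FL = ΣL²/ΣL over the reconstructed fragments.
* **Metagenomic quantification** — a tiered scheme: genomes pass a first
  filter (coverage rate > 40% and covered bases > 500 kb), then reads are
  counted in 10-kb windows with multimapped reads split across their N hit
  genomes with weights ω_j = U_j/ΣU (unique-read counts); per-genome depth
  is a percentile-trimmed window mean and relative abundance is
  depth_i / Σ depth.
* **Strain dynamics** — caller-aware metagenomic SNV filtering (depth ≥ 6,
  alt support ≥ 2, quality ≥ 15; inStrain exempt), minor-allele-frequency
  matrices anchored on a reference sample, k-means clustering with
  Calinski–Harabasz model selection, and detection of clusters whose minor
  alleles become major between time points.
* **MAG tiers** — near-complete / high / medium / low classification from
  completeness, contamination and rRNA/tRNA detection.

## Worked example

Simulate an stLFR-style library (ideal case: one fragment per barcode) with
sequencing errors injected into the observed barcodes, correct the barcodes,
then reconstruct the fragments from the truth alignments:

```r
library(linkreads)

## 1. simulate: C_F = 20, C_R = 0.2, N_F/P = 1, mu_FL = 20 kb on a 1-Mb genome
cfg <- sim_config(c_f = 20, c_r = 0.2, n_fp = 1, mu_fl = 20,
                  platform = "stlfr", barcode_error_rate = 0.005, seed = 7)
sim <- simulate_library(c(chr1 = 1e6), cfg,
                        out_prefix = file.path(tempdir(), "demo"))

## 2. correct the observed barcodes against the simulation's barcode pool
wl  <- as_whitelist(unique(sim$fragments$barcode))
out <- correct_records(sim$records, wl)
str(out$stats)
#> List of 5
#>  $ exact         : int 24252
#>  $ corrected     : int 3590
#>  $ ambiguous     : int 0
#>  $ uncorrectable : int 254
#>  $ whitelist_rate: num 0.991

## 3. reconstruct long fragments from the truth alignments
aln   <- load_barcoded_alignments(sim$files$sam)
pairs <- build_pairs(aln)
model <- estimate_insert_model(pairs)
model
#> insert_model: mu_PE = 351.0, sigma_PE = 32.1 (n = 13978 pairs)
frags <- reconstruct_fragments(filter_pairs(pairs, model))
compute_library_stats(frags, genome_length = 1e6)
#> library_stats over 1000 fragments / 1000 barcodes:
#>   C_R    = 0.225
#>   C_F    = 18.66
#>   N_F/P  = 1.00
#>   mu_FL  = 18.66 kb
#>   Wmu_FL = 39.79 kb
```

Reading the output: with a per-base barcode error rate of 0.005 on 30-bp
barcodes, ~86% of reads carry an error-free barcode and single-mismatch
correction lifts the on-whitelist rate to 99.1%. Reconstruction recovers
exactly one fragment per barcode (N_F/P = 1.00, the stLFR ideal the library
was simulated with). The recovered μ_FL (18.7 kb) sits slightly below the
configured 20 kb because a fragment's reconstructed extent is the span of
its sampled reads, not the full molecule; C_R (0.225) is correspondingly a
little above the configured 0.2. Wμ_FL > μ_FL always holds — long fragments
carry more of the DNA mass than their count suggests.

A command-line surface over the same functions ships in
`inst/scripts/linkreads-cli.R` (subcommands `fqconvert`, `mkfq`,
`fragments`, `quant`, `snvfilter`, `classify`).

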