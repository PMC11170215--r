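---
title: "Methods: linked-read models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linked-read models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of the science it implements: the
models and their assumptions, the tunable parameters with their defaults and
units, what the simulator does and does not emulate, the numerical choices,
and the places where the design was genuinely open and a decision had to be
made. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The unified barcoded representation

A linked read is a short read plus the barcode of the partition (droplet or
bead) its source DNA fragment was captured in. The three supported platforms
store that barcode differently in the raw reads:

| platform | barcode | location in raw reads | whitelist |
|----------|---------|------------------------|-----------|
| `tenx`   | 16 bp   | inline prefix of R1 (trimmed on conversion) | yes |
| `stlfr`  | 30 bp   | three 10-bp segments at the R2 tail (trimmed) | yes |
| `tellseq`| 18 bp   | separate index read I1 (payload untouched) | no |

Conversion concatenates the layout's segments in order and attaches the
result as a single whitespace-separated `BX:Z:<barcode>` token in the FASTQ
comment field. Choosing the SAM `BX` tag syntax means a barcode-aware
aligner can propagate the token into alignments unmodified, and downstream
modules read one convention everywhere. Reads without a resolvable barcode
carry the literal sentinel `"NA"`; they stay in the stream but are excluded
from every barcode-grouped computation.

Layouts are data, not code: presets can be overridden with any
`(source, offset, length, trim)` table, with negative offsets counted from
the read end. This covers the open question of whether a given stLFR
chemistry interleaves linkers between its three barcode segments — users
with linkered reads configure three non-adjacent offsets instead of editing
the package.

## Barcode error correction

Barcodes are fixed-length codes, so errors are modelled as substitutions
only and "fewer than 2 mismatches" is read as Hamming distance ≤ 1; `N`
counts as a mismatch at its position. With a whitelist:

* exact member → unchanged (`exact`);
* distance exactly 1 from exactly one entry → that entry (`corrected`);
* distance 1 from two or more entries → nulled (`ambiguous`);
* distance ≥ 2 from everything → nulled (`uncorrectable`).

Ambiguous hits are deliberately *not* resolved by entry abundance. Barcode
specificity — distinct partitions staying distinct — is the property the
whole technology exists to provide, and abundance-based tie-breaking
systematically merges rare barcodes into common ones. Nulling loses a small
amount of data; merging corrupts fragment reconstruction silently. (If the
trade-off is wanted anyway, correction is a pure function over a count
table, so a caller can implement any tie-break on top.)

Without a whitelist (TELL-seq), the observed barcodes are their own
reference: a barcode supported by a single read that lies at distance 1 from
exactly one barcode with ≥ 2 supporting reads is treated as a sequencing
error of that barcode; all other barcodes, and all multi-read barcodes, map
to themselves. This is conservative in the same way: no merging between two
real partitions that happen to be neighbours, because both will typically
have multiple reads.

Both modes are idempotent (a corrected stream passes through unchanged), and
the count-based mode conserves the total read count — properties the test
suite asserts over randomized inputs.

## The simulator: the stated world

`sim_config()` defaults are the published 10x simulation preset:

| parameter | meaning | default | units |
|-----------|---------|---------|-------|
| `c_f` | physical coverage of the genome by fragments | 500 | fold |
| `c_r` | short-read coverage within a fragment | 0.2 | fold |
| `n_fp` | fragments per partition | 16 | count |
| `mu_fl` | mean fragment length | 20 | kb |
| `read_length` | read length | 150 | bases |
| `insert_mean`, `insert_sd` | paired-end insert model | 350, 35 | bases |
| `error_rate` | payload substitution rate | 0.001 | per base |
| `barcode_error_rate` | barcode substitution rate in FASTQ output | 0 | per base |

The stLFR preset differs only in `n_fp = 1`. The insert defaults (350 ± 35)
and payload error rate (0.001) are typical Illumina paired-end values; they
are stated once here and not tuned thereafter.

Where the literature does not fix a law, one had to be chosen:

* **Fragment lengths** are exponential with mean `mu_fl` (the standard
  molecule-length model for linked-read libraries, where fragmentation is
  approximately a Poisson process along the DNA), truncated to
  [1 kb, replicon length]. A `fixed` alternative exists for debugging.
* **Fragments per partition** are zero-truncated Poisson(`n_fp`). The case
  `n_fp = 1` is made deterministic — exactly one fragment per barcode — to
  model the stLFR/TELL-seq ideal of one fragment per bead rather than a
  ZTP(1), whose mean is 1.58.
* **Pairs per fragment** follow the configured coverage identity
  `round(c_r * L / (2 * read_length))`; inserts are Normal, rounded and
  truncated to [2·`read_length`, L]; the pair's leftmost base is uniform in
  the fragment.
* **Abundances** for multi-genome communities are i.i.d. lognormal,
  normalized to sum to 1; genome *g* receives physical coverage
  `c_f * n_genomes * a_g`, so equal abundances give every genome `c_f`.
* **Qualities** are constant Q35 with Q20 at injected error positions — a
  deliberately simple two-level model. Error-model fidelity (quality-runs,
  motif bias, indels) is not a goal; no module here consumes quality values
  beyond carrying them.

What the simulator does **not** emulate: PCR duplicates, indel errors,
platform linker artifacts, chimeric fragments, GC bias, and alignment
ambiguity (truth alignments are exact). A green parameter-recovery test
therefore establishes that the reconstruction algebra is right, not that the
pipeline is robust to real aligner noise — that robustness enters only
through the insert-model trim and the pair-distance filter.

Determinism: every sampling entry point reseeds from `config$seed` (with
fixed offsets per stage), so a fixed seed makes FASTQ, SAM and fragment
tables byte-identical across runs, which the tests assert.

## Fragment reconstruction

Unique-mapped proper pairs give the insert-size model: mean and *population*
standard deviation (divide by *n* — the data is the complete set of pairs
being modelled, not a sample from a larger one) after discarding sizes above
the 99.5th-percentile order statistic. The trim uses the type-1 (inverted
ECDF) quantile so that small samples are handled exactly: on two pairs
{300, 400} nothing is discarded and the model is (350, 50), whereas an
interpolated quantile would absurdly discard the larger of two observations.
The pair distance `Dis(R1, R2)` is the outer distance — leftmost start to
rightmost end, the magnitude of the SAM template length — matching how the
insert model itself is fit; pairs are removed when it *strictly* exceeds
μ_PE + 3σ_PE or when mates map to different references.

Surviving pairs seed the fragments: within one (barcode, reference) group
sorted by coordinate, a seed joins the current fragment when the gap from
the fragment's rightmost aligned base is ≤ 200 kb (default), else it opens a
new fragment. A running `cummax` of seed ends makes the greedy sweep exactly
equivalent to single-linkage clustering of seed intervals at that cutoff,
which the tests verify against a brute-force union-find oracle. Fragments
never span references, and reconstruction is invariant to input order.

### Library statistics and the C_R estimator

Over the reconstructed fragments: `n_fp` = fragments per barcode, `mu_fl` =
mean length, `wmu_fl` = ΣL²/ΣL (≥ `mu_fl` by Cauchy–Schwarz, with equality
iff all lengths are equal), `c_f` = Σ length / genome length (for
metagenomes, genome length defaults to the summed length of references that
carry fragments).

C_R — read coverage within fragments — is computed as the **pooled ratio**
Σ aligned read bases / Σ fragment length, i.e. the length-weighted mean
coverage. The per-fragment mean of `aligned_read_bases/length` is also
available (`cr_mode = "per_fragment_mean"`) but is not the default for a
structural reason: a fragment supported by a single pair reconstructs with
length ≈ the insert size (~350 bp), so its ratio is ≈ 300/350 ≈ 0.86
*regardless of the true coverage*, and at C_R = 0.2 with exponential
fragment lengths such singletons are ~6% of fragments — enough to drag the
mean of ratios far off the generating value while the pooled ratio stays
within a few percent (the acceptance suite computes both regimes). The same
singleton issue motivates the `min_pairs_per_fragment` switch: singleton
seeds are legitimate fragments, but excluding them deflates N_F/P, so the
default keeps them and the flag is exposed.

### Scale matters: the co-barcode collision regime

Reconstruction can only tell two co-barcoded fragments apart if they lie
farther apart than the extension distance. With `n_fp` fragments per
barcode placed uniformly on total reference length *G* and gap cutoff *d*,
the probability that a given co-barcode spacing exceeds *d* is roughly
`(1 - d/G)^n_fp`, so the expected reconstructed fragments per barcode is
about `1 + (n_fp - 1) * (1 - d/G)^n_fp`. For the 10x preset
(`n_fp = 16`, `d = 200 kb`) on a 1-Mb reference this is ~1.4 — essentially
everything merges and N_F/P, μ_FL are unrecoverable *by any correct
implementation*; on a 160-Mb community (40 replicons × 4 Mb, the scale of a
40-genome bacterial metagenome) it is ~15.6 and recovery closes to within a
few percent. The acceptance experiments therefore run the 10x preset on the
40-replicon community and the stLFR preset (`n_fp = 1`, immune to the
effect) on a 1-Mb genome. The rule of thumb for simulation design:
`G >> n_fp * max_gap`.

## Tiered metagenomic quantification

First pass: per-genome coverage (union of read intervals via interval
reduction) over *all* primary alignments, multimapped included — filtering
precedes deconvolution. A genome survives iff coverage rate > 0.40 **and**
covered bases > 500 kb, both strict, matching the printed thresholds.

Second pass, restricted to surviving genomes: each genome is cut into 10-kb
windows (the final window keeps its true, shorter length in all rate
denominators — padding would deflate the tail rate). A read's window is the
one containing its leftmost aligned base. Reads hitting one genome are
unique (`U`); a read hitting *N* ≥ 2 genomes contributes weight
`ω_j = U_j / Σ_k U_k` to one window per hit genome, with the uniform
fallback 1/N when all `U_k` are zero. Three decisions here were genuinely
open:

* The published weight formula mixes a raw count (*U*) with per-length
  rates (*RC(U)*) in its denominator. ω must be dimensionless and sum to 1
  over the hit set, which only holds if numerator and denominator use the
  same quantity; unique-read **counts** are used uniformly. (A rate-based
  denominator would additionally weight genomes by their lengths inside ω,
  double-counting length, which already divides the window rates.)
* *U* is taken at **genome** level, not window level: the window-level
  unique count is frequently zero at moderate depth, which would make ω
  degenerate for most multireads.
* When the second pass restricts a multiread's hit set to the candidate
  genomes, ω is renormalized over the reduced set — read mass is conserved
  by construction, and the tests assert Σ(U + ω-mass) equals the read count
  exactly, against an exhaustive per-read tally oracle.

"Windows with an extreme number of reads" (repeats, conserved operons,
edge artifacts) are removed before averaging: the default drops windows
whose total rate falls outside the [5th, 95th] percentile of the genome's
*nonzero*-window rates (zeros would otherwise drag the lower percentile to
zero on sparsely covered genomes and nothing would ever be trimmed at the
top); a mean ± 3 SD rule is available. If trimming empties a genome, the
untrimmed mean is the fallback. Depth is the mean rate of surviving
windows; relative abundance is `depth_i / Σ depth`. Monotonicity (more
unique reads never lower your abundance) and rank preservation on
error-free simulated communities are asserted in the tests.

One representational note: quantification treats each reference sequence as
a genome (UHGG-style representative genomes are single sequences). A
`genome_of` map exists for grouped coverage, but windowed counting assumes
per-reference coordinates.

## Strain-frequency dynamics

SNV records from FreeBayes or SAMtools/BCFtools are kept iff total depth
≥ 6, alternative-allele support ≥ 2 and quality ≥ 15 — the removal
conditions are the printed strict "less than" rules, so boundary values
pass. inStrain reports no quality score and its records bypass filtering
entirely. Multi-allelic VCF rows are split and non-SNV alleles dropped.

For a longitudinal sample set, one sample anchors the minor-allele
definition: at each site the minor allele is the one whose frequency in the
reference sample is ≤ 0.5, with the 50/50 tie resolved to the alternative
allele (deterministic, and the alternative is the allele whose presence the
caller actually asserted). Cells are minor-count/total-count, so the
reference column is ≤ 0.5 by construction while other samples may exceed
0.5 — that excursion *is* the strain-replacement signal. A site enters the
matrix only if some sample supports its minor allele with ≥ 3 reads
("exceeding 2"); this is a separate, stricter screen than the caller-level
alt-support filter. Sites absent from the reference sample are dropped and
counted.

Clustering runs per sample pair (reference, target) on the two MAF columns:
rows with missing values are excluded (no imputation — imputing a MAF would
invent the very signal being tested), k-means with Lloyd iterations, 10
restarts, 300-iteration cap, fixed seed, for k in 2..10 (capped below the
number of distinct rows), choosing k by the Calinski–Harabasz index
(between-group over within-group variance, df-corrected). Identical rows —
zero variance — short-circuit to a single cluster. Each cluster yields an
event with its mean reference and target MAF; the cluster *crossed* when
the reference mean is < 0.5 and the target mean > 0.5, both strict. Pairwise
mode was chosen over clustering the full multi-sample matrix because
complete-case rows across many samples vanish quickly in real longitudinal
data; a caller wanting full-matrix clustering can pass any column subset to
`cluster_maf()` directly. The species gate ("high-abundance") is left to the
caller via the quantification output; 1% relative abundance is a reasonable
working threshold.

## MAG quality tiers

Tiers are checked in precedence order — near-complete (completeness > 90,
contamination < 5, all of 5S/16S/23S detected, ≥ 18 tRNAs), then high
(> 90, < 5), then medium (≥ 50, < 10), then low — making them disjoint and
exhaustive; ≥/> follow the printed symbols exactly, and "detected" means at
least one copy. Classification is total and monotone in completeness,
anti-monotone in contamination (property-tested).

## Degenerate inputs and numerical conventions

* Insert model on constant sizes → SD 0; σ_PE = 0 makes the pair filter keep
  only spans ≤ μ_PE.
* `max_gap = Inf` → at most one fragment per (barcode, reference);
  `max_gap = 0` → every non-touching seed is its own fragment.
* All-zero unique counts → uniform ω; all-windows-trimmed → untrimmed mean;
  all-depths-zero → explicit quantification error.
* Percentile trims use type-7 quantiles (R default) on nonzero windows; the
  insert trim uses type-1 (order statistic) as argued above.
* Coordinates are 1-based inclusive (SAM convention) everywhere internally.
* Sums of ω per read are exact to floating point (a shared denominator), and
  abundance normalization is asserted to 1e-9.

## Known limitations

* Truth alignments, not a real aligner, close the simulation loop; aligner
  soft-clips, mismapping and duplicate reads are out of scope (duplicate
  marking is an upstream concern).
* The window scheme assumes single-sequence genomes for windowed counting.
* Whitelist correction considers substitutions only; an indel in a barcode
  is uncorrectable by design.
* The count-based (whitelist-free) mode needs the barcode count table in
  memory; it is built for barcode cardinalities typical of TELL-seq
  libraries (millions), not billions.
* k-means with CH favours compact, isotropic clusters in MAF space; gradual
  frequency drift without cluster structure will not produce a crossing
  event even when individual SNVs cross.
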