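snv_rec <- function(depth, alt, qual, sample = "S1", genome = "sp1",
                    pos = 100L, ref = "A", altb = "G") {
  data.table::data.table(sample_id = sample, genome_id = genome, pos = pos,
                         ref = ref, alt = altb, total_depth = depth,
                         alt_support = alt, quality = qual)
}

test_that("SNV filtering enforces the caller thresholds at the printed boundaries", {
  # boundary values pass: removal conditions are depth < 6, alt < 2, qual < 15
  expect_equal(nrow(filter_snvs(snv_rec(6, 2, 15), "freebayes")), 1L)
  expect_equal(nrow(filter_snvs(snv_rec(5, 10, 99), "samtools")), 0L)
  expect_equal(nrow(filter_snvs(snv_rec(99, 1, 99), "freebayes")), 0L)
  expect_equal(nrow(filter_snvs(snv_rec(99, 10, 14.9), "samtools")), 0L)
  # inStrain records bypass quality control entirely
  expect_equal(nrow(filter_snvs(snv_rec(3, 1, 0), "instrain")), 1L)

  bad <- snv_rec(6, 2, 15)[, !"quality"]
  expect_error(filter_snvs(bad, "freebayes"), "missing field")
})

test_that("filtering is monotone in every threshold", {
  set.seed(19)
  recs <- data.table::data.table(
    sample_id = "S1", genome_id = "sp1", pos = 1:400,
    ref = "A", alt = "G",
    total_depth = sample(0:30, 400, replace = TRUE),
    alt_support = sample(0:10, 400, replace = TRUE),
    quality = stats::runif(400, 0, 60))
  recs <- recs[alt_support <= total_depth]
  base_n <- nrow(filter_snvs(recs, "freebayes"))
  for (arg in c("min_depth", "min_alt", "min_qual")) {
    args <- list(records = recs, caller = "freebayes")
    args[[arg]] <- switch(arg, min_depth = 10, min_alt = 4, min_qual = 30)
    expect_lte(nrow(do.call(filter_snvs, args)), base_n)
  }
})

test_that("MAF matrix fixes the minor allele by the reference sample", {
  recs <- data.table::rbindlist(list(
    snv_rec(10, 2, 50, "S1"),                       # ref sample: alt minor, MAF 0.2
    snv_rec(12, 10, 50, "S5"),                      # same site elsewhere: 10/12
    snv_rec(10, 5, 50, "S1", pos = 200L),           # tie 5:5 -> minor = alt
    snv_rec(10, 8, 50, "S1", pos = 300L),           # alt freq 0.8 -> minor = REF
    snv_rec(10, 4, 50, "S5", pos = 300L)
  ))
  m <- build_maf_matrix(recs, reference_sample = "S1", min_support = 2)
  maf <- m$maf
  expect_equal(maf["sp1:100:A:G", "S1"], 0.2)
  expect_equal(maf["sp1:100:A:G", "S5"], 10 / 12)   # minor fixed by reference
  expect_equal(maf["sp1:200:A:G", "S1"], 0.5)
  expect_true(m$sites[m$sites$pos == 200, ]$minor_is_alt)
  # site 300: minor allele is the reference base; S1 cell = 2/10, S5 = 6/10
  expect_equal(maf["sp1:300:A:G", "S1"], 0.2)
  expect_equal(maf["sp1:300:A:G", "S5"], 0.6)
  # reference column always <= 0.5
  expect_true(all(maf[, "S1"] <= 0.5))
})

test_that("MAF matrix support threshold and reference-absence accounting", {
  recs <- data.table::rbindlist(list(
    snv_rec(100, 2, 50, "S1"),               # minor support 2 everywhere
    snv_rec(100, 2, 50, "S5"),
    snv_rec(100, 10, 50, "S1", pos = 200L),  # well-supported site
    snv_rec(100, 40, 50, "S5", pos = 999L)   # absent from the reference sample
  ))
  m <- build_maf_matrix(recs, reference_sample = "S1", min_support = 3)
  expect_equal(rownames(m$maf), "sp1:200:A:G")  # weak site + orphan dropped
  expect_equal(attr(m, "dropped_no_reference"), 1L)
  # missing cells are NA for samples lacking the site
  expect_true(is.na(m$maf["sp1:200:A:G", "S5"]))

  # "exceeding 2" = support >= 3 admits the weak site at min_support 2
  m2 <- build_maf_matrix(recs, reference_sample = "S1", min_support = 2)
  expect_equal(nrow(m2$maf), 2L)
  expect_error(build_maf_matrix(recs, reference_sample = "nope"),
               "no records")
})

test_that("reference-column MAF <= 0.5 holds on random record sets", {
  set.seed(23)
  for (i in 1:10) {
    n <- 60
    recs <- data.table::data.table(
      sample_id = sample(c("S1", "S2", "S3"), n, replace = TRUE),
      genome_id = "sp", pos = sample(1:30, n, replace = TRUE),
      ref = "A", alt = "G",
      total_depth = sample(10:60, n, replace = TRUE))
    recs[, alt_support := vapply(total_depth, function(d) sample(0:d, 1), numeric(1))]
    recs[, quality := 50]
    recs <- unique(recs, by = c("sample_id", "genome_id", "pos"))
    m <- tryCatch(build_maf_matrix(recs, "S1", min_support = 1),
                  error = function(e) NULL)
    if (is.null(m)) next
    expect_true(all(m$maf[, "S1"] <= 0.5, na.rm = TRUE))
  }
})

test_that("k-means + Calinski-Harabasz recovers two planted blobs", {
  set.seed(41)
  blob <- function(cx, cy, n, s = 0.02) {
    cbind(pmin(pmax(stats::rnorm(n, cx, s), 0), 1),
          pmin(pmax(stats::rnorm(n, cy, s), 0), 1))
  }
  m <- rbind(blob(0.10, 0.10, 50), blob(0.45, 0.90, 50))
  colnames(m) <- c("S1", "S5")
  rownames(m) <- sprintf("site%03d", 1:100)
  cl <- cluster_maf(m, k_range = 2:10, seed = 7)
  expect_equal(cl$chosen_k, 2L)
  # labels match blob membership up to permutation
  tab <- table(cl$labels, rep(c("a", "b"), each = 50))
  expect_equal(sort(diag(tab[order(tab[, 1], decreasing = TRUE), ])),
               sort(c(50L, 50L)), ignore_attr = TRUE)

  # shuffling rows leaves the chosen k and the partition unchanged
  perm <- sample(100)
  cl2 <- cluster_maf(m[perm, ], k_range = 2:10, seed = 7)
  expect_equal(cl2$chosen_k, 2L)
  expect_equal(unname(cl2$labels[rownames(m)] == cl2$labels[rownames(m)[1]]),
               unname(cl$labels == cl$labels[1]))
})

test_that("degenerate clustering inputs fall back to a single cluster", {
  m <- matrix(0.3, nrow = 8, ncol = 2,
              dimnames = list(sprintf("s%d", 1:8), c("S1", "S2")))
  cl <- cluster_maf(m)
  expect_equal(cl$chosen_k, 1L)
  expect_true(all(cl$labels == 1L))
  expect_error(cluster_maf(m[1:2, ]), "fewer than 3")
  # rows with missing values are excluded before the count check
  m[1:6, 1] <- NA
  expect_error(cluster_maf(m), "fewer than 3")
})

test_that("strain-shift events follow the crossing rule and ordering", {
  labels <- stats::setNames(rep(1:3, each = 4), sprintf("r%02d", 1:12))
  maf <- cbind(S1 = c(rep(0.10, 4), rep(0.10, 4), rep(0.50, 4)),
               S5 = c(rep(0.80, 4), rep(0.30, 4), rep(0.50, 4)))
  rownames(maf) <- names(labels)
  ev <- detect_strain_shift(labels, maf, sample_pair = c("S1", "S5"))
  expect_equal(ev$crossed, c(TRUE, FALSE, FALSE))    # sorted by |delta|
  expect_equal(ev$cluster_id, c(1L, 2L, 3L))
  expect_equal(ev$delta_maf, c(0.7, 0.2, 0.0))
  expect_equal(ev$snv_count, rep(4L, 3))
  # boundary: means exactly at the threshold do not cross (strict)
  expect_false(ev[ev$cluster_id == 3L, ]$crossed)
})

test_that("planted strain shifts are recovered in >= 95% of seeded replicates", {
  hits <- 0L
  n_rep <- 40L
  for (s in seq_len(n_rep)) {
    set.seed(1000 + s)
    n <- 25
    shift_rows <- cbind(S1 = pmin(pmax(stats::rnorm(n, 0.10, 0.05), 0), 0.5),
                        S5 = pmin(pmax(stats::rnorm(n, 0.90, 0.05), 0), 1))
    stable_rows <- cbind(S1 = pmin(pmax(stats::rnorm(n, 0.30, 0.05), 0), 0.5),
                         S5 = pmin(pmax(stats::rnorm(n, 0.30, 0.05), 0), 1))
    m <- rbind(shift_rows, stable_rows)
    rownames(m) <- sprintf("site%03d", seq_len(2 * n))
    cl <- cluster_maf(m, seed = s)
    ev <- detect_strain_shift(cl$labels, m, sample_pair = c("S1", "S5"))
    planted <- rownames(m)[seq_len(n)]
    # the cluster holding most planted rows must have crossed
    top <- names(sort(table(cl$labels[planted]), decreasing = TRUE))[1]
    if (isTRUE(ev[ev$cluster_id == as.integer(top), ]$crossed)) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("per-genome orchestration skips sparse genomes and is deterministic", {
  set.seed(61)
  mk <- function(genome, pos, d_ref, a_ref, d_t, a_t) {
    data.table::rbindlist(list(
      snv_rec(d_ref, a_ref, 50, "S1", genome, pos),
      snv_rec(d_t, a_t, 50, "S5", genome, pos)))
  }
  recs <- data.table::rbindlist(c(
    lapply(1:12, function(i) mk("spA", i * 10L, 40, 4, 40, 36)),   # crossing
    lapply(1:12, function(i) mk("spA", 1000L + i * 10L, 40, 12, 40, 12)),
    lapply(1:2, function(i) mk("spB", i * 10L, 40, 10, 40, 10))    # too sparse
  ))
  m <- build_maf_matrix(recs, "S1")
  expect_message(ev <- strain_shift_events(m, "S5", seed = 3), "skipping genome spB")
  expect_true(all(ev$genome_id == "spA"))
  expect_true(any(ev$crossed))
  ev2 <- suppressMessages(strain_shift_events(m, "S5", seed = 3))
  expect_equal(ev, ev2)     # end-to-end determinism under a fixed seed
})

test_that("VCF records parse into the flat SNV schema", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "s1.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=sp1,length=100000>",
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="depth">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="gt">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="allele depths">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMP1",
    "sp1\t100\t.\tA\tG\t50\t.\tDP=20\tGT:DP:AD\t0/1:20:12,8",
    "sp1\t200\t.\tC\tT,G\t30\t.\tDP=30\tGT:DP:AD\t1/2:30:10,15,5",
    "sp1\t300\t.\tC\tCTT\t99\t.\tDP=25\tGT:DP:AD\t0/1:25:20,5"
  ), vcf)
  recs <- read_snv_vcf(vcf)
  expect_equal(recs$sample_id, rep("SAMP1", 3))      # indel row dropped
  expect_equal(recs$pos, c(100L, 200L, 200L))        # multi-allelic split
  expect_equal(recs$alt, c("G", "T", "G"))
  expect_equal(recs$total_depth, c(20, 30, 30))
  expect_equal(recs$alt_support, c(8, 15, 5))
  expect_equal(recs$quality, c(50, 30, 30))
  # parsed records feed the caller filter directly
  expect_equal(nrow(filter_snvs(recs, "samtools")), 3L)
})
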