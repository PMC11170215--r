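test_that("platform presets carry the published barcode lengths", {
  expect_equal(platform_spec("tenx")$barcode_length, 16L)
  expect_equal(platform_spec("tellseq")$barcode_length, 18L)
  expect_equal(platform_spec("stlfr")$barcode_length, 30L)
  # preset invariant: segment lengths sum to the barcode length
  for (p in c("tenx", "stlfr", "tellseq")) {
    spec <- platform_spec(p)
    expect_equal(sum(spec$layout$length), spec$barcode_length)
  }
  expect_error(platform_spec("tenx", barcode_length = 14), "layout error")
})

test_that("tenx conversion splits the inline 16 bp prefix from the payload", {
  set.seed(7)
  dir <- withr::local_tempdir()
  bc <- "ACGTACGTACGTACGT"
  payload <- rand_dna(1, 134)
  r1 <- write_raw_fastq("p1", paste0(bc, payload), file.path(dir, "r1.fq"))
  r2 <- write_raw_fastq("p1", rand_dna(1, 150), file.path(dir, "r2.fq"))
  rec <- convert_to_unified(r1, r2, platform_spec("tenx"))

  expect_equal(nrow(rec), 2L)
  expect_equal(unique(rec$barcode), bc)
  expect_equal(nchar(rec$barcode), c(16L, 16L))
  expect_equal(rec[rec$mate == 1L, ]$sequence, payload)
  expect_equal(nchar(rec[rec$mate == 1L, ]$sequence), 134L)
  expect_equal(nchar(rec[rec$mate == 1L, ]$qualities), 134L)
  # R2 untouched by the tenx layout
  expect_equal(nchar(rec[rec$mate == 2L, ]$sequence), 150L)
})

test_that("stlfr conversion concatenates the three R2 tail segments", {
  dir <- withr::local_tempdir()
  payload <- rand_dna(1, 100)
  tail30 <- paste0(strrep("A", 10), strrep("C", 10), strrep("G", 10))
  r1 <- write_raw_fastq("s1", rand_dna(1, 100), file.path(dir, "r1.fq"))
  r2 <- write_raw_fastq("s1", paste0(payload, tail30), file.path(dir, "r2.fq"))
  rec <- convert_to_unified(r1, r2, platform_spec("stlfr"))

  # concatenation oracle over the declared segments
  expect_equal(unique(rec$barcode),
               paste0(strrep("A", 10), strrep("C", 10), strrep("G", 10)))
  expect_equal(nchar(unique(rec$barcode)), 30L)
  expect_equal(rec[rec$mate == 2L, ]$sequence, payload)  # tail trimmed
})

test_that("tellseq conversion reads the barcode from I1 without trimming", {
  dir <- withr::local_tempdir()
  bc <- rand_dna(1, 18)
  r1 <- write_raw_fastq("t1", rand_dna(1, 150), file.path(dir, "r1.fq"))
  r2 <- write_raw_fastq("t1", rand_dna(1, 150), file.path(dir, "r2.fq"))
  i1 <- write_raw_fastq("t1", bc, file.path(dir, "i1.fq"))
  rec <- convert_to_unified(r1, r2, platform_spec("tellseq"), i1 = i1)
  expect_equal(unique(rec$barcode), bc)
  expect_equal(nchar(rec$sequence), c(150L, 150L))
  expect_error(convert_to_unified(r1, r2, platform_spec("tellseq")),
               "layout error")
})

test_that("zero-length layout yields the null barcode and identity payload", {
  dir <- withr::local_tempdir()
  s1 <- rand_dna(1, 120)
  r1 <- write_raw_fastq("n1", s1, file.path(dir, "r1.fq"))
  r2 <- write_raw_fastq("n1", rand_dna(1, 120), file.path(dir, "r2.fq"))
  spec <- platform_spec("tenx",
                        layout = data.frame(source = "R1", offset = 1,
                                            length = 0, trim = FALSE),
                        barcode_length = 0)
  rec <- convert_to_unified(r1, r2, spec)
  expect_true(all(is_null_barcode(rec$barcode)))
  expect_equal(rec[rec$mate == 1L, ]$sequence, s1)
})

test_that("conversion conserves read pairs and barcode lengths per platform", {
  set.seed(11)
  dir <- withr::local_tempdir()
  n <- 25L
  worlds <- list(
    tenx = list(r1 = rand_dna(n, 150), r2 = rand_dna(n, 150), i1 = NULL),
    stlfr = list(r1 = rand_dna(n, 100), r2 = rand_dna(n, 130), i1 = NULL),
    tellseq = list(r1 = rand_dna(n, 150), r2 = rand_dna(n, 150),
                   i1 = rand_dna(n, 18))
  )
  for (p in names(worlds)) {
    w <- worlds[[p]]
    ids <- sprintf("%s_%03d", p, seq_len(n))
    r1 <- write_raw_fastq(ids, w$r1, file.path(dir, paste0(p, "_1.fq")))
    r2 <- write_raw_fastq(ids, w$r2, file.path(dir, paste0(p, "_2.fq")))
    i1 <- if (!is.null(w$i1)) {
      write_raw_fastq(ids, w$i1, file.path(dir, paste0(p, "_I1.fq")))
    }
    spec <- platform_spec(p)
    rec <- convert_to_unified(r1, r2, spec, i1 = i1)
    expect_equal(nrow(rec), 2L * n)                        # pairs conserved
    expect_true(all(nchar(rec$barcode) == spec$barcode_length))
    # both mates of a pair carry identical barcodes
    bc_by_pair <- tapply(rec$barcode, rec$read_id, function(x) length(unique(x)))
    expect_true(all(bc_by_pair == 1L))
  }
})

test_that("truncated or malformed FASTQ input is rejected with context", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.fq")
  writeLines(c("@r1", "ACGT", "+"), bad)            # 3 lines: truncated
  expect_error(parse_err <- convert_to_unified(bad, bad, platform_spec("tenx")),
               "truncated FASTQ.*record 1")
  short <- write_raw_fastq("r1", "ACGTACGT", file.path(dir, "short.fq"))
  ok <- write_raw_fastq("r1", rand_dna(1, 150), file.path(dir, "ok.fq"))
  expect_error(convert_to_unified(short, ok, platform_spec("tenx")),
               "layout error.*out of range")
})

test_that("unified FASTQ round-trips field-for-field", {
  set.seed(3)
  dir <- withr::local_tempdir()
  rec <- data.table::data.table(
    read_id = rep(sprintf("rt%02d", 1:10), each = 2),
    mate = rep(1:2, 10),
    sequence = rand_dna(20, 80),
    qualities = strrep("E", rep(80, 20)),
    barcode = rep(c(rand_dna(9, 16), NULL_BARCODE), each = 2),
    platform = "tenx"
  )
  path <- file.path(dir, "unified.fq.gz")
  write_unified_fastq(rec, path)
  back <- read_unified_fastq(path, platform = "tenx")
  expect_equal(as.data.frame(back), as.data.frame(rec))

  # string-parse oracle: the BX token is literally on the header line
  plain <- file.path(dir, "unified.fq")
  write_unified_fastq(rec[1:2], plain)
  expect_match(readLines(plain)[1],
               paste0("^@rt01/1 BX:Z:", rec$barcode[1], "$"))
  # headers lacking a token parse to the sentinel
  writeLines(c("@naked", "ACGT", "+", "IIII"), plain)
  expect_equal(read_unified_fastq(plain)$barcode, NULL_BARCODE)
  # malformed BX token errors with a line number
  writeLines(c("@bad BX:Z:", "ACGT", "+", "IIII"), plain)
  expect_error(read_unified_fastq(plain), "malformed BX token at line 1")
})

test_that("SAM loading excludes unmapped reads and flags multi-genome hits", {
  dir <- withr::local_tempdir()
  sam <- write_tiny_sam(list(
    list(qname = "u1", flag = 99, rname = "gA", pos = 100, tlen = 350,
         rnext = "=", pnext = 350, tags = "BX:Z:AAAACCCCGGGGTTTT"),
    list(qname = "u1", flag = 147, rname = "gA", pos = 350, tlen = -350,
         rnext = "=", pnext = 100, tags = "BX:Z:AAAACCCCGGGGTTTT"),
    list(qname = "m1", flag = 0, rname = "gA", pos = 500,
         tags = "BX:Z:AAAACCCCGGGGTTTT"),
    list(qname = "m1", flag = 2048, rname = "gB", pos = 700, cigar = "50M50S",
         tags = "BX:Z:AAAACCCCGGGGTTTT"),
    list(qname = "gone", flag = 4, rname = "*", pos = 0, cigar = "*",
         tags = "BX:Z:AAAACCCCGGGGTTTT"),
    list(qname = "nobx", flag = 0, rname = "gA", pos = 900)
  ), c(gA = 10000, gB = 10000), file.path(dir, "toy.sam"))

  expect_warning(aln <- load_barcoded_alignments(sam), "without a BX tag")
  expect_false("gone" %in% aln$read_id)          # unmapped never yielded
  expect_false("nobx" %in% aln$read_id)          # skipped, counted
  expect_equal(attr(aln, "skipped_no_bx"), 1L)

  u1 <- aln[aln$read_id == "u1", ]
  expect_true(all(u1$is_unique))                 # mapped once each mate
  m1 <- aln[aln$read_id == "m1", ]
  expect_true(all(!m1$is_unique))                # primary gA + supplementary gB
  expect_setequal(m1$rname, c("gA", "gB"))
  expect_equal(m1[m1$rname == "gB", ]$aligned_bases, 50)  # soft-clip excluded
})

test_that("write_sam never emits scientific notation for large coordinates", {
  dir <- withr::local_tempdir()
  aln <- data.table::data.table(
    read_id = "big", flag = 99L, rname = "gA", pos = 1e5, mapq = 60L,
    cigar = "150M", mate_rname = "gA", mate_pos = 2e5, isize = 100151,
    barcode = "AAAACCCCGGGGTTTT")
  p <- file.path(dir, "big.sam")
  write_sam(aln, c(gA = 5e5), p)
  expect_false(any(grepl("e\\+", readLines(p))))
  back <- load_barcoded_alignments(p)
  expect_equal(back$pos, 100000L)
  expect_equal(back$mate_pos, 200000L)
})
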