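test_that("VCF records map to variant calls with INFO RO/AO", {
  vcf <- write_test_vcf(withr::local_tempfile(fileext = ".vcf"), c(
    "chr1\t100\t.\tC\tA\t50\t.\tRO=0;AO=15",
    "chr2\t300\t.\tT\tG\t60\t.\tRO=12;AO=11"
  ))
  calls <- read_variant_calls(vcf)
  expect_equal(calls$chrom, c("chr1", "chr2"))
  expect_equal(calls$pos, c(100L, 300L))
  expect_equal(calls$ro, c(0L, 12L))
  expect_equal(calls$ao, c(15L, 11L))
  expect_equal(unname(attr(calls, "skipped")), c(0L, 0L, 0L))
})

test_that("multi-allelic records are decomposed with per-allele AO and shared RO", {
  vcf <- write_test_vcf(withr::local_tempfile(fileext = ".vcf"),
                        "chr1\t200\t.\tG\tA,T\t50\t.\tRO=9;AO=4,6")
  calls <- read_variant_calls(vcf)
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$alt, c("A", "T"))
  expect_equal(calls$ro, c(9L, 9L))
  expect_equal(calls$ao, c(4L, 6L))
  # AO conservation under decomposition
  expect_equal(sum(calls$ao), 4L + 6L)
})

test_that("empty VCF body, QUAL filtering, symbolic alts and FORMAT fallback", {
  empty <- write_test_vcf(withr::local_tempfile(fileext = ".vcf"), character())
  calls <- read_variant_calls(empty)
  expect_equal(nrow(calls), 0L)
  expect_equal(sum(attr(calls, "skipped")), 0L)

  mixed <- write_test_vcf(withr::local_tempfile(fileext = ".vcf"), c(
    "chr1\t100\t.\tC\tA\t5\t.\tRO=0;AO=15",
    "chr1\t150\t.\tC\t<DEL>\t99\t.\tRO=3;AO=8",
    "chr1\t180\t.\tC\tA\t99\t.\tDP=20",
    "chr1\t200\t.\tC\tA\t99\t.\tRO=1;AO=9"
  ))
  calls <- read_variant_calls(mixed, min_qual = 10)
  expect_equal(calls$pos, 200L)
  skipped <- attr(calls, "skipped")
  expect_equal(unname(skipped[c("low_qual", "symbolic_alt", "no_counts")]),
               c(1L, 1L, 1L))

  fmt <- write_test_vcf(withr::local_tempfile(fileext = ".vcf"),
                        "chr1\t100\t.\tC\tA\t50\t.\tDP=20\tGT:RO:AO\t0/1:7:13",
                        info = FALSE)
  calls <- read_variant_calls(fmt)
  expect_equal(calls$ro, 7L)
  expect_equal(calls$ao, 13L)
})

test_that("a VCF with no RO/AO anywhere fails with a remediation hint", {
  vcf <- write_test_vcf(withr::local_tempfile(fileext = ".vcf"), c(
    "chr1\t100\t.\tC\tA\t50\t.\tDP=20",
    "chr1\t200\t.\tC\tA\t50\t.\tDP=30"
  ))
  expect_error(read_variant_calls(vcf), "RO/AO")
})

test_that("genome index reader preserves order and rejects duplicates", {
  fai <- withr::local_tempfile(fileext = ".fai")
  writeLines(c("chr1\t59578282\t6\t60\t61", "chr2\t1000000\t60571428\t60\t61"), fai)
  gi <- read_genome_index(fai)
  expect_equal(gi$chrom, c("chr1", "chr2"))
  expect_equal(gi$length, c(59578282, 1000000))

  dup <- withr::local_tempfile(fileext = ".fai")
  writeLines(c("chr1\t100\t0\t60\t61", "chr1\t200\t0\t60\t61"), dup)
  expect_error(read_genome_index(dup), "duplicate")

  bad <- withr::local_tempfile(fileext = ".fai")
  writeLines("chr1", bad)
  expect_error(read_genome_index(bad), "line 1")
})

test_that("refFlat models convert 0-based half-open to 1-based inclusive", {
  rf <- withr::local_tempfile(fileext = ".txt")
  writeLines(paste(
    "gA", "txA", "chr1", "+", 0, 30, 10, 21, 2, "0,20,", "15,30,",
    sep = "\t"
  ), rf)
  m <- read_gene_models(rf, "refflat")
  expect_equal(m$tx_start, 1)
  expect_equal(m$tx_end, 30)
  expect_equal(m$cds_start, 11)
  expect_equal(m$cds_end, 21)
  expect_equal(m$exon_starts[[1]], c(1, 21))
  expect_equal(m$exon_ends[[1]], c(15, 30))
})

test_that("non-coding and invalid refFlat rows are handled", {
  rf <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    paste("gNC", "txNC", "chr1", "+", 0, 30, 30, 30, 1, "0,", "30,", sep = "\t"),
    paste("gBad", "txBad", "chr1", "+", 0, 30, 10, 22, 2, "0,", "15,30,", sep = "\t")
  ), rf)
  expect_warning(m <- read_gene_models(rf, "refflat"), "exon count")
  expect_equal(m$transcript, "txNC")
  expect_true(is.na(m$cds_start))
})

test_that("GFF3 gene models are read with exon structure", {
  skip_if_not_installed("rtracklayer")
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1\t60\t.\t+\t.\tID=geneA",
    "chr1\tsrc\tmRNA\t1\t60\t.\t+\t.\tID=txA;Parent=geneA",
    "chr1\tsrc\texon\t1\t20\t.\t+\t.\tParent=txA",
    "chr1\tsrc\texon\t41\t60\t.\t+\t.\tParent=txA",
    "chr1\tsrc\tCDS\t10\t50\t.\t+\t0\tParent=txA"
  ), gff)
  m <- read_gene_models(gff, "gff3")
  expect_equal(nrow(m), 1L)
  expect_equal(length(m$exon_starts[[1]]), 2L)
  expect_equal(m$cds_start, 10)
  expect_equal(m$cds_end, 50)
})

test_that("SIFT table lookups work and out-of-range scores are rejected", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "chrom\tpos\tref\talt\tsift",
    "chr1\t100\tC\tA\t0.02",
    "chr1\t200\tG\tT\t1.5"
  ), tsv)
  expect_warning(s <- read_sift_table(tsv), "rejected")
  expect_equal(nrow(s), 1L)
  expect_equal(s$sift[s$chrom == "chr1" & s$pos == 100], 0.02)
  expect_equal(nrow(dplyr::filter(s, pos == 200)), 0L)
})

test_that("bedGraph and BED writers use 0-based half-open coordinates", {
  tr <- track_tbl(1.25)[1, ]
  tr$win_start <- 10001
  tr$win_end <- 20000
  path <- withr::local_tempfile(fileext = ".bedgraph")
  write_track_bedgraph(tr, path)
  expect_equal(readLines(path), "chr1\t10000\t20000\t1.250000")

  iv <- tibble(chrom = "chr1", left = 2460001, right = 13870000)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_interval_bed(iv, bed, "iv")
  expect_equal(readLines(bed), "chr1\t2460000\t13870000\tiv")
})

test_that("candidates TSV round-trips exactly, including the empty table", {
  cand <- tibble(
    chrom = c("chr1", "chr1"), pos = c(100, 200), ref = c("C", "G"),
    alt = c("A", "T"), ro_mut = c(0L, 1L), ao_mut = c(15L, 9L),
    ro_wt = c(10L, NA), ao_wt = c(8L, NA),
    gene = c("gA", NA), transcript = c("txA", NA),
    region = c("exonic", NA), effect = c("stopgain", NA),
    cdna_change = c("c.C9A", NA), protein_change = c("p.C3X", NA),
    sift = c(0.02, NA)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_candidates_tsv(cand, path)
  back <- read_candidates_tsv(path)
  expect_equal(as.data.frame(back), as.data.frame(cand))

  write_candidates_tsv(cand[0, ], path)
  expect_equal(length(readLines(path)), 1L) # header only
  expect_equal(nrow(read_candidates_tsv(path)), 0L)
})

test_that("coordinate conversion refFlat -> internal -> BED is involutive", {
  rf <- withr::local_tempfile(fileext = ".txt")
  writeLines(paste(
    "gA", "txA", "chr1", "+", 2460000, 13870000, 13870000, 13870000, 1,
    "2460000,", "13870000,", sep = "\t"
  ), rf)
  m <- read_gene_models(rf, "refflat")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_interval_bed(tibble(chrom = m$chrom, left = m$tx_start,
                            right = m$tx_end), bed)
  fields <- strsplit(readLines(bed), "\t")[[1]]
  expect_equal(as.numeric(fields[2:3]), c(2460000, 13870000))
})
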