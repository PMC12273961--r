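test_that("heterozygous-point rule needs both alleles at balanced ratio", {
  calls <- calls_tbl("c", 1:5, ro = c(10, 0, 10, 2, 1), ao = c(8, 20, 1, 8, 1))
  expect_equal(is_heterozygous_point(calls),
               c(TRUE, FALSE, FALSE, TRUE, FALSE))
  # ratio bounds inclusive: ro/ao = 0.25 and 4 both pass
  edge <- calls_tbl("c", 1:2, ro = c(2, 8), ao = c(8, 2))
  expect_true(all(is_heterozygous_point(edge)))
})

test_that("window heterozygosity counts per tiling window with correct geometry", {
  g <- genome_index(c(chr1 = 30000))
  cfg <- index_config(min_chrom_len = 1)
  calls <- calls_tbl("chr1", c(5001, 5002, 19999))
  h <- window_heterozygosity(calls, g, cfg)
  expect_equal(h$het, c(2L, 1L, 0L))
  expect_equal(h$center, c(5000, 15000, 25000))
  expect_equal(nrow(h), floor((30000 - 10000) / 10000) + 1)

  # empty input: all-zero track with correct window count
  h0 <- window_heterozygosity(calls_tbl("chr1", numeric()), g, cfg)
  expect_equal(h0$het, c(0L, 0L, 0L))

  # boundary: pos exactly at window_width counted in window 1 only
  h1 <- window_heterozygosity(calls_tbl("chr1", 10000), g, cfg)
  expect_equal(h1$het, c(1L, 0L, 0L))

  # calls on unknown chromosomes are skipped with a warning
  expect_warning(
    h2 <- window_heterozygosity(calls_tbl("chrX", 5000), g, cfg),
    "absent"
  )
  expect_equal(sum(h2$het), 0L)
})

test_that("overlapping windows (step < width) count calls in every spanning window", {
  g <- genome_index(c(chr1 = 30000))
  cfg <- index_config(window_width = 10000, window_step = 5000,
                      min_chrom_len = 1)
  h <- window_heterozygosity(calls_tbl("chr1", 12000), g, cfg)
  # windows [1,10000],[5001,15000],[10001,20000],[15001,25000],[20001,30000]
  expect_equal(h$het, c(0L, 1L, 1L, 0L, 0L))
})

test_that("SNP index follows (Hwt - Hmut)/(2 + Hmut)", {
  g <- genome_index(c(chr1 = 30000))
  cfg <- index_config(min_chrom_len = 1)
  base <- window_heterozygosity(calls_tbl("chr1", numeric()), g, cfg)
  hw <- base; hw$het <- c(10L, 7L, 0L)
  hm <- base; hm$het <- c(0L, 7L, 10L)
  idx <- snp_index(hw, hm)
  expect_equal(idx$snp_index, c(5, 0, -10 / 12))

  # identical tracks give zero everywhere
  expect_true(all(snp_index(hw, hw)$snp_index == 0))

  # mismatched centers are fatal
  hm2 <- hm[-1, ]
  expect_error(snp_index(hw, hm2), "mismatch")
})

test_that("SNP index is bounded in (-1, Hwt/2] and monotone in Hwt", {
  set.seed(11)
  g <- genome_index(c(chr1 = 2e6))
  cfg <- index_config(min_chrom_len = 1)
  base <- window_heterozygosity(calls_tbl("chr1", numeric()), g, cfg)
  for (i in 1:50) {
    hw <- base; hw$het <- rpois(nrow(base), 5)
    hm <- base; hm$het <- rpois(nrow(base), 5)
    v <- snp_index(hw, hm)$snp_index
    expect_true(all(v > -1))
    expect_true(all(v <= hw$het / 2))
    expect_true(all(v[hw$het == hm$het] == 0))
    # adding wild-type heterozygous points never decreases the index
    hw2 <- hw; hw2$het <- hw$het + rpois(nrow(base), 2)
    expect_true(all(snp_index(hw2, hm)$snp_index >= v))
  }
})

test_that("moving average matches hand-worked examples and truncates at ends", {
  tr <- track_tbl(c(0, 0, 3, 0, 0))
  out <- moving_average(tr, index_config(ma_width = 30000))
  expect_equal(out$ma, c(0, 1, 1, 1, 0))

  # constant track is invariant
  cst <- track_tbl(rep(2.5, 7))
  expect_true(all(moving_average(cst, index_config())$ma == 2.5))

  # single-window chromosome: MA equals raw
  one <- track_tbl(0.7)
  expect_equal(moving_average(one, index_config())$ma, 0.7)
})

test_that("moving average equals the brute-force mean oracle on random tracks", {
  set.seed(7)
  for (i in 1:100) {
    n <- sample(1:200, 1)
    step <- sample(c(5000, 10000), 1)
    tr <- track_tbl(rnorm(n), step = step, width = step)
    ma_width <- sample(1:6, 1) * step
    out <- moving_average(tr, index_config(window_width = step,
                                           window_step = step,
                                           ma_width = ma_width))
    expect_equal(out$ma, ma_oracle(tr, ma_width))
  }
})

test_that("interval selection walks to the first non-positive center", {
  tr <- track_tbl(c(-1, 0.5, 2, 0.7, -0.2))
  tr$ma <- tr$snp_index
  g <- genome_index(c(chr1 = 50000))
  iv <- select_interval(tr, g)
  expect_equal(iv$chrom, "chr1")
  expect_equal(iv$argmax, 25000)
  expect_equal(iv$left, 10000)
  expect_equal(iv$right, 40000)
  expect_equal(iv$peak, 2)
  # argmax inside the interval; MA > 0 at interior centers
  expect_true(iv$left <= iv$argmax && iv$argmax <= iv$right)
  interior <- tr$center > iv$left & tr$center < iv$right
  expect_true(all(tr$ma[interior] > 0))

  # a second chromosome below the peak leaves the interval unchanged
  tr2 <- track_tbl(rep(0.1, 5), chrom = "chr2")
  tr2$ma <- tr2$snp_index
  both <- dplyr::bind_rows(tr, tr2)
  iv2 <- select_interval(both, genome_index(c(chr1 = 50000, chr2 = 50000)))
  expect_equal(as.data.frame(iv2), as.data.frame(iv))

  # all-positive chromosome: interval spans [1, chrom_len]
  pos <- track_tbl(c(0.5, 1, 0.5))
  pos$ma <- pos$snp_index
  iv3 <- select_interval(pos, genome_index(c(chr1 = 30000)))
  expect_equal(c(iv3$left, iv3$right), c(1, 30000))

  # nowhere positive is fatal with guidance
  neg <- track_tbl(c(-1, 0, -2))
  neg$ma <- neg$snp_index
  expect_error(select_interval(neg, genome_index(c(chr1 = 30000))),
               "no positive")
})

test_that("global-argmax ties break by chromosome name then coordinate", {
  a <- track_tbl(c(1, 2, 2), chrom = "chrB")
  b <- track_tbl(c(2, 1, 1), chrom = "chrA")
  a$ma <- a$snp_index
  b$ma <- b$snp_index
  iv <- select_interval(dplyr::bind_rows(a, b),
                        genome_index(c(chrB = 30000, chrA = 30000)))
  expect_equal(iv$chrom, "chrA")
  expect_equal(iv$argmax, 5000)
})

test_that("mean local index averages raw values near a position", {
  tr <- track_tbl(c(1, 2, 3))
  expect_equal(mean_local_index(tr, "chr1", 15000, radius = 740000), 2)
  # truncation at the chromosome start
  expect_equal(mean_local_index(tr, "chr1", 5000, radius = 10000), 1.5)
  # constant track returns the constant
  cst <- track_tbl(rep(0.4, 5))
  expect_equal(mean_local_index(cst, "chr1", 25000), 0.4)
  expect_error(mean_local_index(tr, "chr2", 15000), "no window centers")
})
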