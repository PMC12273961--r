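test_that("recombination frequency counts heterozygous mutants", {
  tbl <- tibble(
    animal = c(paste0("r", 1:12), paste0("h", 1:23)),
    chrom = "chr1", pos = 2.5e6,
    genotype = rep(c("het", "hom_mut"), c(12, 23)), inferred = FALSE
  )
  est <- recombination_frequency(tbl)
  expect_equal(est$recombinants, 12L)
  expect_equal(est$genotyped, 35L)
  expect_equal(est$rf, 12 / 35, tolerance = 1e-12)

  # fully linked marker
  all_hom <- tibble(animal = paste0("a", 1:35), chrom = "chr1", pos = 1e6,
                    genotype = "hom_mut", inferred = FALSE)
  expect_equal(recombination_frequency(all_hom)$rf, 0)

  # unknowns are excluded from the denominator
  mixed <- geno_tbl(1e6, a1 = "het", a2 = "unknown", a3 = "hom_mut")
  est2 <- recombination_frequency(mixed)
  expect_equal(est2$genotyped, 2L)
  expect_equal(est2$rf, 0.5)

  all_unk <- geno_tbl(1e6, a1 = "unknown", a2 = "unknown")
  expect_error(recombination_frequency(all_unk), "no genotyped")
})

test_that("distance estimate converts Rf to Mb at 0.74 Mb/cM", {
  est <- tibble(rf = c(12 / 35, 1 / 35, 0))
  d <- distance_estimate(est)
  expect_equal(d$distance_mb, c(12 / 35 * 74, 1 / 35 * 74, 0),
               tolerance = 1e-12)
  expect_equal(d$distance_mb_rounded, c(25, 2, 0))
})

test_that("missing genotypes are inferred only between concordant flanks", {
  pos <- c(1e6, 2e6, 3e6)
  tbl <- dplyr::bind_rows(
    tibble(animal = "a", chrom = "c", pos = pos,
           genotype = c("hom_mut", "unknown", "hom_mut"), inferred = FALSE),
    tibble(animal = "b", chrom = "c", pos = pos,
           genotype = c("hom_mut", "unknown", "het"), inferred = FALSE),
    tibble(animal = "d", chrom = "c", pos = pos,
           genotype = c("unknown", "hom_mut", "hom_mut"), inferred = FALSE)
  )
  out <- infer_missing_genotypes(tbl)
  a <- dplyr::filter(out, animal == "a")
  expect_equal(a$genotype[a$pos == 2e6], "hom_mut")
  expect_true(a$inferred[a$pos == 2e6])
  b <- dplyr::filter(out, animal == "b")
  expect_equal(b$genotype[b$pos == 2e6], "unknown")
  d <- dplyr::filter(out, animal == "d")
  expect_equal(d$genotype[d$pos == 1e6], "unknown")
  # known genotypes are never altered
  expect_equal(dplyr::filter(out, genotype != "unknown" & !inferred),
               dplyr::filter(tbl, genotype != "unknown"))
})

# the published two-marker worked example: interval 2.46-13.87 Mb,
# markers A at 2.50 Mb and B at 10.71 Mb; 11 animals recombinant at A only,
# one recombinant at both, 23 non-recombinant
two_marker_table <- function() {
  pos <- c(2.50e6, 10.71e6)
  dplyr::bind_rows(
    purrr::map_dfr(1:11, ~ tibble(animal = paste0("rA", .x), chrom = "chr1",
                                  pos = pos, genotype = c("het", "hom_mut"),
                                  inferred = FALSE)),
    tibble(animal = "animal5", chrom = "chr1", pos = pos,
           genotype = c("het", "het"), inferred = FALSE),
    purrr::map_dfr(1:23, ~ tibble(animal = paste0("h", .x), chrom = "chr1",
                                  pos = pos, genotype = c("hom_mut", "hom_mut"),
                                  inferred = FALSE))
  )
}

test_that("two-marker refinement reproduces the 3.16 Mb interval", {
  interval <- tibble(chrom = "chr1", left = 2.46e6, right = 13.87e6)
  r <- refine_interval(interval, two_marker_table())
  expect_equal(r$interval$left, 10.71e6)
  expect_equal(r$interval$right, 13.87e6)
  expect_equal((r$interval$right - r$interval$left) / 1e6, 3.16,
               tolerance = 1e-9)
  expect_length(r$conflicting, 0)
  # the all-het animal was resolved to the left side
  a5 <- dplyr::filter(r$exclusions, animal == "animal5")
  expect_equal(a5$side, "left")
  expect_equal(a5$excl_end, 10.71e6)
})

test_that("five-marker refinement retains the span between innermost recombinant markers", {
  pos <- c(19.034592e6, 26.124850e6, 28.090051e6, 29.087847e6, 31.609203e6)
  tbl <- dplyr::bind_rows(
    tibble(animal = "left1", chrom = "chr7", pos = pos,
           genotype = c("het", rep("hom_mut", 4)), inferred = FALSE),
    tibble(animal = "right1", chrom = "chr7", pos = pos,
           genotype = c("hom_mut", rep("het", 4)), inferred = FALSE),
    tibble(animal = "right2", chrom = "chr7", pos = pos,
           genotype = c("hom_mut", "hom_mut", "hom_mut", "het", "het"),
           inferred = FALSE),
    tibble(animal = "h1", chrom = "chr7", pos = pos,
           genotype = rep("hom_mut", 5), inferred = FALSE)
  )
  interval <- tibble(chrom = "chr7", left = 12.53e6, right = 42.96e6)
  r <- refine_interval(interval, tbl)
  expect_equal(r$interval$left, 19.034592e6)
  expect_equal(r$interval$right, 26.124850e6)
  expect_equal((r$interval$right - r$interval$left) / 1e6, 7.09,
               tolerance = 0.01)
})

test_that("refinement is conservative, idempotent, and flags conflicts", {
  interval <- tibble(chrom = "chr1", left = 2.46e6, right = 13.87e6)
  tbl <- two_marker_table()
  r1 <- refine_interval(interval, tbl)
  # output within input
  expect_gte(r1$interval$left, interval$left)
  expect_lte(r1$interval$right, interval$right)
  # idempotent
  r2 <- refine_interval(r1$interval, tbl)
  expect_equal(r2$interval$left, r1$interval$left)
  expect_equal(r2$interval$right, r1$interval$right)

  # all-hom table changes nothing
  hom_only <- dplyr::filter(tbl, genotype == "hom_mut")
  r3 <- refine_interval(interval, hom_only)
  expect_equal(c(r3$interval$left, r3$interval$right),
               c(interval$left, interval$right))

  # interior het between hom markers implies a double crossover -> conflict
  pos <- c(3e6, 7e6, 11e6)
  bad <- tibble(animal = "dx", chrom = "chr1", pos = pos,
                genotype = c("hom_mut", "het", "hom_mut"), inferred = FALSE)
  ok <- tibble(animal = "ok", chrom = "chr1", pos = pos,
               genotype = rep("hom_mut", 3), inferred = FALSE)
  r4 <- refine_interval(interval, dplyr::bind_rows(ok, bad))
  expect_equal(r4$conflicting, "dx")
  expect_equal(c(r4$interval$left, r4$interval$right),
               c(interval$left, interval$right))

  # refinement that would empty the interval errors with the animals named
  wipe <- dplyr::bind_rows(
    tibble(animal = "L", chrom = "chr1", pos = pos,
           genotype = c("het", "het", "hom_mut"), inferred = FALSE),
    tibble(animal = "R", chrom = "chr1", pos = pos,
           genotype = c("hom_mut", "het", "het"), inferred = FALSE)
  )
  expect_error(refine_interval(interval, wipe), "entire interval")
})

test_that("locus position estimation picks the in-interval candidate", {
  est <- tibble(pos = c(10e6, 30e6), distance_mb = c(5, 15))
  interval <- tibble(chrom = "c", left = 12e6, right = 18e6)
  out <- locus_position_estimate(est, interval)
  expect_equal(out$per_marker$candidate_mb, c(15, 15))
  expect_equal(out$mean_mb, 15)
  expect_equal(out$sd_mb, 0)

  # single marker: sd reported 0 with a flag
  one <- locus_position_estimate(est[1, ], interval)
  expect_true(one$single_marker)
  expect_equal(one$sd_mb, 0)

  # both candidates outside: nearest to the interval, flagged
  est2 <- tibble(pos = c(10e6), distance_mb = c(1))
  out2 <- locus_position_estimate(est2, interval)
  expect_true(out2$per_marker$flagged)
  expect_equal(out2$per_marker$candidate_mb, 11)
})

test_that("pairing probability and genomes screened follow 1-(1-f^2)^n", {
  expect_equal(pairing_probability(6), 1 - 0.75^6)
  expect_equal(round(pairing_probability(6), 2), 0.82)
  expect_equal(pairing_probability(0), 0)
  expect_equal(pairing_probability(1, carrier_fraction = 1), 1)
  expect_equal(genomes_screened(c(6)), 1 - 0.75^6)
  expect_equal(genomes_screened(numeric()), 0)
  expect_equal(genomes_screened(c(6, 6)), 2 * (1 - 0.75^6))
  cov <- genomes_screened(rep(6, 10), per_locus_hit_rate = 0.0013)
  expect_equal(cov$coverage, cov$genomes * 0.0013)
})

test_that("genotype tables round-trip through the wide TSV format", {
  tbl <- geno_tbl(c(1e6, 2e6), a1 = c("hom_mut", "het"),
                  a2 = c("unknown", "hom_mut"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_table(tbl, path)
  back <- read_genotype_table(path)
  expect_equal(
    dplyr::arrange(back, animal, pos)[, c("animal", "chrom", "pos", "genotype")],
    dplyr::arrange(tbl, animal, pos)[, c("animal", "chrom", "pos", "genotype")]
  )
})
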