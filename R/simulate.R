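#' Configuration for the synthetic incross simulator
#'
#' Defines the study conditions of a simulated recessive forward-genetic
#' cross: heterozygous carrier parents are incrossed, offspring are sorted
#' by phenotype (homozygous mutant vs. sibling), and the two pools are
#' "sequenced" by Poisson-depth / binomial-allele read sampling. Defaults
#' mirror a desk-scale zebrafish design: a two-chromosome 2 x 25 Mb
#' genome, 300 heterozygous founder SNPs/Mb and 50 indels/Mb per parent,
#' 3 clutches (independent parent pairs) contributing 30 animals per
#' phenotype pool, and 30X mean coverage.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths
#'   (default `c(chr1 = 25e6, chr2 = 25e6)`).
#' @param snp_per_mb Expected heterozygous SNPs per Mb per parent
#'   (default 300).
#' @param indel_per_mb Expected heterozygous indels per Mb per parent
#'   (default 50).
#' @param causative List `(chrom, pos)` of the planted causative
#'   substitution (default chr1:12,000,000).
#' @param n_clutches Number of independent parent pairs (default 3).
#' @param pool_size Animals per phenotype pool, summed over clutches
#'   (default 30).
#' @param coverage Mean sequencing depth per pool (default 30).
#' @param mb_per_cM Physical-to-genetic scale used by the Haldane
#'   crossover model (default 0.74 Mb/cM).
#' @param indel_len_max Maximum simulated indel length difference in bp
#'   (default 10; lengths are uniform on 1..max).
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(chrom_lengths = c(chr1 = 25e6, chr2 = 25e6),
                       snp_per_mb = 300, indel_per_mb = 50,
                       causative = list(chrom = "chr1", pos = 12e6),
                       n_clutches = 3, pool_size = 30, coverage = 30,
                       mb_per_cM = 0.74, indel_len_max = 10) {
  stopifnot(
    !is.null(names(chrom_lengths)), all(chrom_lengths > 0),
    snp_per_mb >= 0, indel_per_mb >= 0,
    causative$chrom %in% names(chrom_lengths),
    causative$pos >= 1, causative$pos <= chrom_lengths[[causative$chrom]],
    n_clutches >= 1, pool_size >= 1, coverage > 0, mb_per_cM > 0
  )
  structure(
    list(chrom_lengths = chrom_lengths, snp_per_mb = snp_per_mb,
         indel_per_mb = indel_per_mb, causative = causative,
         n_clutches = n_clutches, pool_size = pool_size,
         coverage = coverage, mb_per_cM = mb_per_cM,
         indel_len_max = indel_len_max),
    class = "sim_config"
  )
}

.BASES <- c("A", "C", "G", "T")

.random_alleles <- function(n, type, indel_len_max) {
  ref <- sample(.BASES, n, replace = TRUE)
  if (type == "snp") {
    alt <- purrr::map_chr(ref, ~ sample(setdiff(.BASES, .x), 1))
    return(list(ref = ref, alt = alt))
  }
  k <- sample.int(indel_len_max, n, replace = TRUE)
  extra <- purrr::map_chr(k, ~ paste(sample(.BASES, .x, replace = TRUE),
                                     collapse = ""))
  del <- runif(n) < 0.5
  list(
    ref = ifelse(del, paste0(ref, extra), ref),
    alt = ifelse(del, ref, paste0(ref, extra))
  )
}

# Haldane recombination probability between loci d Mb apart
.haldane_r <- function(d_mb, mb_per_cM) {
  0.5 * (1 - exp(-2 * d_mb / (100 * mb_per_cM)))
}

# Simulate one clutch's gamete haplotype states on one chromosome.
# States: 0 = mutant-founder haplotype (shared, identical by descent in
# both parents), 1 = that parent's wild-type haplotype. `anchor` is the
# site index whose states are fixed by `init` (the causative locus on its
# chromosome); elsewhere states evolve by Haldane switching in both
# directions from the anchor.
.gamete_states <- function(n_gametes, pos, anchor, init, mb_per_cM) {
  S <- length(pos)
  if (S == 1) return(matrix(init, n_gametes, 1))
  r <- .haldane_r(diff(pos) / 1e6, mb_per_cM)
  sw <- matrix(runif(n_gametes * (S - 1)), n_gametes) <
    matrix(r, n_gametes, S - 1, byrow = TRUE)
  cum <- cbind(0L, t(apply(sw, 1, cumsum)))
  (init + cum - cum[, anchor]) %% 2
}

#' Simulate a phenotype-sorted incross
#'
#' Generates founder polymorphism, forms gametes with Haldane-model
#' crossovers (no interference), assigns phenotype by causative genotype,
#' and returns true pool allele fractions for both phenotype pools along
#' with per-animal marker genotypes for the pooled mutant animals.
#'
#' Each clutch is an independent parent pair sharing one mutagenized
#' founder haplotype (identical by descent through the carrier lineage)
#' so the mutant pool is fully homozygous at the causative locus and its
#' linked neighbourhood. Candidate polymorphic sites are laid down at
#' twice the nominal density and each founder haplotype draws the
#' alternate allele with probability 1/2, making each parent heterozygous
#' at the nominal density in expectation.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; fixed seed gives identical output.
#' @return A list of class `"segmap_sim"`: `sites` (tibble `chrom`, `pos`,
#'   `ref`, `alt`, `type`, `frac_mut`, `frac_wt`), `truth` (one-row tibble
#'   for the causative variant), `genotypes` (long genotype tibble of
#'   pooled mutant animals at informative indel markers on the causative
#'   chromosome), and `cfg`.
#' @export
simulate_cross <- function(cfg = sim_config(), seed = 1) {
  set.seed(seed)
  chroms <- names(cfg$chrom_lengths)

  # candidate polymorphic sites (2x density; see Details)
  sites <- purrr::map_dfr(chroms, function(ch) {
    len <- cfg$chrom_lengths[[ch]]
    n_snp <- rpois(1, 2 * cfg$snp_per_mb * len / 1e6)
    n_ind <- rpois(1, 2 * cfg$indel_per_mb * len / 1e6)
    pos <- sample.int(len, n_snp + n_ind)
    type <- rep(c("snp", "indel"), c(n_snp, n_ind))
    snp_al <- .random_alleles(n_snp, "snp", cfg$indel_len_max)
    ind_al <- .random_alleles(n_ind, "indel", cfg$indel_len_max)
    tibble(chrom = ch, pos = pos, ref = c(snp_al$ref, ind_al$ref),
           alt = c(snp_al$alt, ind_al$alt), type = type)
  })
  # plant the causative substitution, displacing any colliding site
  sites <- sites[!(sites$chrom == cfg$causative$chrom &
                     sites$pos == cfg$causative$pos), ]
  caus_al <- .random_alleles(1, "snp", cfg$indel_len_max)
  sites <- bind_rows(sites, tibble(
    chrom = cfg$causative$chrom, pos = cfg$causative$pos,
    ref = caus_al$ref, alt = caus_al$alt, type = "causative"
  ))
  sites <- arrange(sites, match(chrom, chroms), pos)

  n_per_clutch <- diff(round(seq(0, cfg$pool_size, length.out = cfg$n_clutches + 1)))
  alt_mut <- alt_wt <- numeric(nrow(sites))
  geno_rows <- list()
  n_chrom_mut <- n_chrom_wt <- 0

  for (cl in seq_len(cfg$n_clutches)) {
    n_animals <- n_per_clutch[cl]
    if (n_animals == 0) next
    # founder haplotype alleles: M (shared mutagenized), W1, W2
    A <- matrix(runif(nrow(sites) * 3) < 0.5, nrow(sites), 3)
    ci <- which(sites$type == "causative")
    A[ci, ] <- c(TRUE, FALSE, FALSE)

    for (ch in chroms) {
      idx <- which(sites$chrom == ch)
      pos <- sites$pos[idx]
      on_caus <- ch == cfg$causative$chrom
      anchor <- if (on_caus) which(idx == ci) else 1L
      G_mut <- 2L * n_animals
      G_wt <- 2L * n_animals
      init_mut <- if (on_caus) rep(0L, G_mut) else
        sample(0:1, G_mut, replace = TRUE)
      init_wt <- if (on_caus) {
        # sibling pool: genotypes at the locus uniform on {MW, WM, WW}
        picks <- sample(1:3, n_animals, replace = TRUE)
        as.integer(rbind(c(0L, 1L, 1L)[picks], c(1L, 0L, 1L)[picks]))
      } else {
        sample(0:1, G_wt, replace = TRUE)
      }
      st_mut <- .gamete_states(G_mut, pos, anchor, init_mut, cfg$mb_per_cM)
      st_wt <- .gamete_states(G_wt, pos, anchor, init_wt, cfg$mb_per_cM)

      # allele per gamete: M allele where state 0, parent's W allele where 1
      allele_of <- function(st) {
        G <- nrow(st)
        parent <- rep(1:2, G / 2) # rows alternate parent1/parent2 per animal
        M <- matrix(A[idx, 1], G, length(idx), byrow = TRUE)
        W <- rbind(A[idx, 2], A[idx, 3])[parent, , drop = FALSE]
        ifelse(st == 0, M, W)
      }
      al_mut <- allele_of(st_mut)
      al_wt <- allele_of(st_wt)
      alt_mut[idx] <- alt_mut[idx] + colSums(al_mut)
      alt_wt[idx] <- alt_wt[idx] + colSums(al_wt)

      if (on_caus) {
        # per-animal genotypes of pooled mutants at informative indels:
        # markers heterozygous in both parents (M differs from W1 and W2)
        informative <- sites$type[idx] == "indel" &
          (A[idx, 1] != A[idx, 2]) & (A[idx, 1] != A[idx, 3])
        mi <- which(informative)
        if (length(mi) > 0) {
          m_count <- (st_mut[seq(1, G_mut, 2), mi, drop = FALSE] == 0) +
            (st_mut[seq(2, G_mut, 2), mi, drop = FALSE] == 0)
          geno_rows[[length(geno_rows) + 1]] <- tibble(
            animal = rep(paste0("clutch", cl, "_m", seq_len(n_animals)),
                         times = length(mi)),
            chrom = ch,
            pos = rep(pos[mi], each = n_animals),
            genotype = c("unknown", "het", "hom_mut")[as.vector(m_count) + 1]
          )
        }
      }
    }
    n_chrom_mut <- n_chrom_mut + 2 * n_animals
    n_chrom_wt <- n_chrom_wt + 2 * n_animals
  }

  sites$frac_mut <- alt_mut / n_chrom_mut
  sites$frac_wt <- alt_wt / n_chrom_wt
  genotypes <- if (length(geno_rows)) {
    genotype_table(
      animal = bind_rows(geno_rows)$animal,
      chrom = bind_rows(geno_rows)$chrom,
      pos = bind_rows(geno_rows)$pos,
      genotype = bind_rows(geno_rows)$genotype
    )
  } else {
    genotype_table(character(), character(), numeric(), character())
  }
  structure(
    list(
      sites = sites,
      truth = sites[sites$type == "causative",
                    c("chrom", "pos", "ref", "alt", "frac_mut", "frac_wt")],
      genotypes = genotypes,
      cfg = cfg
    ),
    class = "segmap_sim"
  )
}

#' Sample pooled sequencing reads from true allele fractions
#'
#' Per site and pool: depth ~ Poisson(coverage), alternate reads
#' ~ Binomial(depth, pool fraction), reference reads = depth - alt.
#' Sites with zero alternate reads are omitted from that pool's calls,
#' mimicking a variant caller that only reports observed variants (this is
#' what makes the "not observed in the wild-type pool" filter branch
#' reachable).
#'
#' @param sim A `segmap_sim` from [simulate_cross()].
#' @param coverage Mean depth; defaults to the simulation's configured
#'   coverage. Resampling the same simulation at several coverages reuses
#'   the same true fractions.
#' @param seed Integer seed for the read sampling.
#' @return A list with variant-call tibbles `mut_calls` and `wt_calls`
#'   (columns `chrom`, `pos`, `ref`, `alt`, `ro`, `ao`, `qual`).
#' @export
simulate_reads <- function(sim, coverage = NULL, seed = 1) {
  coverage <- coverage %||% sim$cfg$coverage
  set.seed(seed)
  draw_pool <- function(frac) {
    n <- length(frac)
    depth <- rpois(n, coverage)
    ao <- rbinom(n, depth, frac)
    keep <- ao > 0
    tibble(
      chrom = sim$sites$chrom[keep], pos = sim$sites$pos[keep],
      ref = sim$sites$ref[keep], alt = sim$sites$alt[keep],
      ro = (depth - ao)[keep], ao = ao[keep], qual = 50
    )
  }
  list(mut_calls = draw_pool(sim$sites$frac_mut),
       wt_calls = draw_pool(sim$sites$frac_wt))
}

#' Write a simulation to disk
#'
#' Emits freebayes-style VCFs for both pools (v4.2, `RO`/`AO` in INFO), a
#' machine-readable truth table, a `.fai` genome index, the mutant-animal
#' marker genotype table, and optionally a random reference FASTA matching
#' the configured chromosome lengths (off by default; only needed when
#' annotation fixtures are planted on the simulated genome).
#'
#' @param sim A `segmap_sim` from [simulate_cross()].
#' @param reads Read-count list from [simulate_reads()].
#' @param out_dir Output directory (created if needed).
#' @param write_reference Also generate and write `genome.fa` (default
#'   FALSE; slow for large genomes).
#' @param seed Seed for reference sequence generation.
#' @return Named list of written paths, invisibly.
#' @export
write_simulation <- function(sim, reads, out_dir, write_reference = FALSE,
                             seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(paste0("cannot create directory ", out_dir))
  paths <- list(
    mut_vcf = file.path(out_dir, "mut.vcf"),
    wt_vcf = file.path(out_dir, "wt.vcf"),
    truth = file.path(out_dir, "truth.tsv"),
    fai = file.path(out_dir, "genome.fa.fai"),
    genotypes = file.path(out_dir, "genotypes.tsv")
  )
  .write_vcf(reads$mut_calls, sim$cfg$chrom_lengths, paths$mut_vcf)
  .write_vcf(reads$wt_calls, sim$cfg$chrom_lengths, paths$wt_vcf)
  readr::write_tsv(sim$truth, paths$truth)
  .write_fai(sim$cfg$chrom_lengths, paths$fai)
  if (nrow(sim$genotypes) > 0) {
    write_genotype_table(sim$genotypes, paths$genotypes)
  }
  if (write_reference) {
    set.seed(seed)
    paths$fasta <- file.path(out_dir, "genome.fa")
    con <- file(paths$fasta, "w")
    on.exit(close(con))
    for (ch in names(sim$cfg$chrom_lengths)) {
      writeLines(paste0(">", ch), con)
      len <- sim$cfg$chrom_lengths[[ch]]
      seq <- paste(sample(.BASES, len, replace = TRUE), collapse = "")
      writeLines(substring(seq, seq(1, len, 60), pmin(seq(1, len, 60) + 59, len)),
                 con)
    }
  }
  invisible(paths)
}

.write_vcf <- function(calls, chrom_lengths, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=segmapr-simulator",
    paste0("##contig=<ID=", names(chrom_lengths), ",length=",
           format(chrom_lengths, scientific = FALSE, trim = TRUE), ">"),
    "##INFO=<ID=RO,Number=1,Type=Integer,Description=\"Reference allele observation count\">",
    "##INFO=<ID=AO,Number=A,Type=Integer,Description=\"Alternate allele observation count\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t%g\t.\tRO=%d;AO=%d",
                  calls$chrom, as.integer(calls$pos), calls$ref, calls$alt,
                  calls$qual, calls$ro, calls$ao)
  writeLines(c(header, body), path)
  invisible(path)
}

.write_fai <- function(chrom_lengths, path) {
  len <- as.numeric(chrom_lengths)
  linebases <- 60
  nlines <- ceiling(len / linebases)
  offsets <- cumsum(c(0, head(nchar(names(chrom_lengths)) + 2 + len + nlines, -1)))
  lines <- sprintf("%s\t%s\t%s\t%d\t%d",
                   names(chrom_lengths),
                   format(len, scientific = FALSE, trim = TRUE),
                   format(offsets + nchar(names(chrom_lengths)) + 2,
                          scientific = FALSE, trim = TRUE),
                   linebases, linebases + 1)
  writeLines(lines, path)
  invisible(path)
}
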