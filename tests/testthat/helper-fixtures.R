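# Fixture builders and independent oracles shared across test files.
# Everything is generated in code; no binary fixtures.

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# minimal call tibble
calls_tbl <- function(chrom, pos, ref = "A", alt = "C", ro = 10, ao = 10,
                      qual = 50) {
  tibble(chrom = chrom, pos = pos, ref = ref, alt = alt,
         ro = as.integer(ro), ao = as.integer(ao), qual = qual)
}

# write a small VCF by hand (INFO RO/AO unless info = FALSE, in which case
# counts go in FORMAT of a single sample)
write_test_vcf <- function(path, rows, info = TRUE) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=RO,Number=1,Type=Integer,Description=\"ref obs\">",
    "##INFO=<ID=AO,Number=A,Type=Integer,Description=\"alt obs\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"genotype\">",
    "##FORMAT=<ID=RO,Number=1,Type=Integer,Description=\"ref obs\">",
    "##FORMAT=<ID=AO,Number=A,Type=Integer,Description=\"alt obs\">",
    if (info) "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO" else
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1"
  )
  writeLines(c(header, rows), path)
  path
}

# regular-grid SNP-index track
track_tbl <- function(values, chrom = "chr1", step = 10000, width = 10000) {
  k <- seq_along(values)
  tibble(
    chrom = chrom,
    win_start = (k - 1) * step + 1,
    win_end = (k - 1) * step + width,
    center = (k - 1) * step + width / 2,
    snp_index = values
  )
}

# brute-force moving-average oracle: literal mean over |C' - C| <= half
ma_oracle <- function(track, ma_width) {
  half <- ma_width / 2
  vapply(seq_len(nrow(track)), function(i) {
    sel <- track$chrom == track$chrom[i] &
      abs(track$center - track$center[i]) <= half + 1e-9
    mean(track$snp_index[sel])
  }, numeric(1))
}

# genotype-table builder: one row per animal, genotypes in marker order
geno_tbl <- function(marker_pos, ..., chrom = "chr1") {
  animals <- list(...)
  bind_rows(purrr::imap(animals, function(g, nm) {
    tibble(animal = nm, chrom = chrom, pos = marker_pos, genotype = g,
           inferred = FALSE)
  }))
}

# --- random coding-gene fixture for annotation oracle tests ---------------

# Builds a random multi-exon coding model on a random genome. The whole
# transcript is coding (CDS = transcript span) with total exon length a
# multiple of 3 and an ATG start on the coding strand.
random_coding_model <- function(chrom = "chrR", n_exons = sample(1:4, 1),
                                strand = sample(c("+", "-"), 1)) {
  exon_lens <- sample(3:30, n_exons, replace = TRUE)
  rem <- sum(exon_lens) %% 3
  exon_lens[1] <- exon_lens[1] + (3 - rem) %% 3
  intron_lens <- if (n_exons > 1) sample(7:40, n_exons - 1, replace = TRUE) else integer()
  pad <- 10
  starts <- integer(n_exons)
  ends <- integer(n_exons)
  cur <- pad + 1
  for (i in seq_len(n_exons)) {
    starts[i] <- cur
    ends[i] <- cur + exon_lens[i] - 1
    cur <- ends[i] + 1 + if (i < n_exons) intron_lens[i] else 0
  }
  glen <- ends[n_exons] + pad
  seq <- sample(c("A", "C", "G", "T"), glen, replace = TRUE)
  # plant ATG at the coding-strand start of the CDS
  if (strand == "+") {
    first3 <- exon_base_positions(starts, ends)[1:3]
    seq[first3] <- c("A", "T", "G")
  } else {
    last3 <- rev(exon_base_positions(starts, ends))[1:3]
    seq[last3] <- c("T", "A", "C") # revcomp(ATG) laid 3'->5'
  }
  genome <- setNames(paste(seq, collapse = ""), chrom)
  model <- gene_models("gene_r", "tx_r", chrom, strand,
                       starts, ends, starts[1], ends[n_exons])
  list(model = model, genome = genome, chrom = chrom, strand = strand,
       starts = starts, ends = ends)
}

# genomic positions of exonic bases in genomic order
exon_base_positions <- function(starts, ends) {
  unlist(purrr::map2(starts, ends, seq))
}

# Independent consequence oracle for a 1-bp substitution in the CDS:
# walks the exons to find the CDS offset, rebuilds the full alternate CDS,
# translates ref and alt CDS with Biostrings::translate, and derives the
# class from the amino-acid comparison.
oracle_substitution <- function(fix, pos, alt_base) {
  bases <- exon_base_positions(fix$starts, fix$ends)
  stopifnot(pos %in% bases)
  seq_chars <- strsplit(fix$genome[[fix$chrom]], "")[[1]]
  ref_cds_plus <- paste(seq_chars[bases], collapse = "")
  alt_chars <- seq_chars
  alt_chars[pos] <- alt_base
  alt_cds_plus <- paste(alt_chars[bases], collapse = "")
  if (fix$strand == "-") {
    ref_cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ref_cds_plus)))
    alt_cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(alt_cds_plus)))
    cds_pos <- length(bases) - match(pos, bases) + 1
  } else {
    ref_cds <- ref_cds_plus
    alt_cds <- alt_cds_plus
    cds_pos <- match(pos, bases)
  }
  ref_aa <- as.character(Biostrings::translate(Biostrings::DNAString(ref_cds),
                                               if.fuzzy.codon = "X"))
  alt_aa <- as.character(Biostrings::translate(Biostrings::DNAString(alt_cds),
                                               if.fuzzy.codon = "X"))
  ci <- ceiling(cds_pos / 3)
  r <- substr(ref_aa, ci, ci)
  a <- substr(alt_aa, ci, ci)
  class <- if (ci == 1 && substr(ref_cds, 1, 3) == "ATG" &&
               substr(alt_cds, 1, 3) != "ATG") {
    "startloss"
  } else if (r == "*" && a != "*") {
    "stoploss"
  } else if (a == "*" && r != "*") {
    "stopgain"
  } else if (r == a) {
    "synonymous"
  } else {
    "nonsynonymous"
  }
  list(class = class, cds_pos = cds_pos, codon_idx = ci,
       ref_aa = r, alt_aa = a)
}

# small default simulation for pipeline tests (fast: one 8 Mb chromosome
# pair, smaller pools)
small_sim_config <- function(...) {
  sim_config(chrom_lengths = c(chr1 = 8e6, chr2 = 8e6),
             causative = list(chrom = "chr1", pos = 4e6),
             pool_size = 12, n_clutches = 3, ...)
}
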