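#' Read and write marker genotype tables
#'
#' The exchange format is a wide TSV: first column `animal`, one column per
#' marker named `chrom:pos`, cells `M` (homozygous mutant-linked allele),
#' `H` (heterozygous, i.e. recombinant) or `?` (unknown). Internally
#' genotypes are handled long-form, one row per (animal, marker), ordered
#' by marker position.
#'
#' @param path Path to the TSV.
#' @return A long tibble: `animal`, `chrom`, `pos`, `genotype`
#'   (`hom_mut`/`het`/`unknown`), `inferred` (logical).
#' @export
read_genotype_table <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  names(wide)[1] <- "animal"
  long <- tidyr::pivot_longer(wide, -animal,
                              names_to = "marker", values_to = "code")
  parts <- stringr::str_match(long$marker, "^(.+):(\\d+)$")
  if (anyNA(parts[, 1])) {
    abort("marker columns must be named 'chrom:pos'")
  }
  genotype_table(
    animal = long$animal,
    chrom = parts[, 2],
    pos = as.numeric(parts[, 3]),
    genotype = dplyr::recode(long$code,
                             "M" = "hom_mut", "H" = "het", "?" = "unknown",
                             .default = "unknown", .missing = "unknown")
  )
}

#' @rdname read_genotype_table
#' @param table Long genotype tibble.
#' @export
write_genotype_table <- function(table, path) {
  code <- c(hom_mut = "M", het = "H", unknown = "?")
  wide <- table %>%
    mutate(marker = paste0(chrom, ":",
                           format(.data$pos, scientific = FALSE, trim = TRUE)),
           code = code[genotype]) %>%
    select(animal, marker, code) %>%
    tidyr::pivot_wider(names_from = "marker", values_from = "code")
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Construct a marker genotype table in code
#'
#' @param animal,chrom,pos,genotype Vectors (recycled as usual) defining one
#'   row per (animal, marker); `genotype` in `hom_mut`/`het`/`unknown`.
#' @param inferred Logical flag per row (default FALSE).
#' @return A validated long genotype tibble, markers on one chromosome.
#' @export
genotype_table <- function(animal, chrom, pos, genotype, inferred = FALSE) {
  tbl <- tibble(animal = as.character(animal), chrom = chrom,
                pos = as.numeric(pos), genotype = genotype,
                inferred = inferred)
  if (!all(tbl$genotype %in% c("hom_mut", "het", "unknown"))) {
    abort("genotypes must be 'hom_mut', 'het' or 'unknown'")
  }
  if (length(unique(tbl$chrom)) > 1) {
    abort("all markers in a genotype table must lie on one chromosome")
  }
  arrange(tbl, animal, pos)
}

#' Species genetic-to-physical scale
#'
#' @param mb_per_cM Physical distance per centimorgan (default 0.74 Mb,
#'   the zebrafish genome-wide average).
#' @return A list of class `"species_params"`.
#' @export
species_params <- function(mb_per_cM = 0.74) {
  stopifnot(mb_per_cM > 0)
  structure(list(mb_per_cM = mb_per_cM), class = "species_params")
}

#' Recombination frequency per marker
#'
#' In phenotypically mutant (homozygous) progeny, a heterozygous genotype
#' at a marker means a recombination event separated the marker from the
#' causative locus. Rf = heterozygous animals / genotyped animals.
#'
#' @param table Long genotype tibble (see [genotype_table()]).
#' @return A tibble with one row per marker: `chrom`, `pos`,
#'   `recombinants`, `genotyped`, `rf`.
#' @examples
#' # 12 of 35 mutants heterozygous at a marker -> Rf = 0.3429
#' tbl <- genotype_table(
#'   animal = rep(1:35, 1), chrom = "chr1", pos = 2500000,
#'   genotype = rep(c("het", "hom_mut"), c(12, 23))
#' )
#' recombination_frequency(tbl)
#' @export
recombination_frequency <- function(table) {
  out <- table %>%
    group_by(chrom, pos) %>%
    summarise(
      recombinants = sum(genotype == "het"),
      genotyped = sum(genotype != "unknown"),
      .groups = "drop"
    ) %>%
    arrange(pos)
  if (any(out$genotyped == 0)) {
    abort(paste0("marker at position ",
                 out$pos[out$genotyped == 0][1],
                 " has no genotyped animal"))
  }
  out$rf <- out$recombinants / out$genotyped
  out
}

#' Physical distance from recombination frequency
#'
#' Converts Rf to an estimated physical distance: Rf (fraction) x 100 gives
#' centimorgans, times `mb_per_cM` gives megabases. No map-function
#' correction is applied (raw Rf, appropriate at the short distances of
#' within-interval mapping).
#'
#' @param est Tibble from [recombination_frequency()] (column `rf`).
#' @param sp A [species_params()].
#' @return `est` with added `distance_mb` (full precision) and
#'   `distance_mb_rounded` (nearest integer Mb).
#' @examples
#' est <- tibble::tibble(rf = c(12 / 35, 1 / 35))
#' distance_estimate(est)$distance_mb_rounded # 25 2
#' @export
distance_estimate <- function(est, sp = species_params()) {
  est$distance_mb <- est$rf * 100 * sp$mb_per_cM
  est$distance_mb_rounded <- round(est$distance_mb)
  est
}

#' Infer missing marker genotypes from flanking markers
#'
#' An unknown genotype whose nearest known genotypes on both sides (in
#' marker order) agree is set to that shared genotype and flagged
#' `inferred` — the double crossover needed to violate this within a short
#' interval is vanishingly rare. Unknowns at the ends of the marker order,
#' or between discordant neighbours, remain unknown. Known genotypes are
#' never altered.
#'
#' @param table Long genotype tibble.
#' @return The table with inferred genotypes filled and flagged.
#' @export
infer_missing_genotypes <- function(table) {
  table %>%
    group_by(animal) %>%
    group_modify(function(d, key) {
      d <- arrange(d, pos)
      g <- d$genotype
      unk <- which(g == "unknown")
      for (i in unk) {
        left_known <- g[seq_len(i - 1)]
        left_known <- left_known[left_known != "unknown"]
        right_known <- if (i < length(g)) g[(i + 1):length(g)] else character()
        right_known <- right_known[right_known != "unknown"]
        if (length(left_known) > 0 && length(right_known) > 0 &&
            tail(left_known, 1) == right_known[1]) {
          d$genotype[i] <- right_known[1]
          d$inferred[i] <- TRUE
        }
      }
      d
    }) %>%
    ungroup()
}

# Per-animal crossover evidence: maximal run of het markers anchored at
# each end of the marker order. Unknowns neither extend nor break a run.
.animal_runs <- function(g) {
  known <- which(g != "unknown")
  het <- g == "het"
  hom <- g == "hom_mut"
  left_run <- integer()
  for (i in seq_along(g)) {
    if (hom[i]) break
    if (het[i]) left_run <- c(left_run, i)
  }
  right_run <- integer()
  for (i in rev(seq_along(g))) {
    if (hom[i]) break
    if (het[i]) right_run <- c(i, right_run)
  }
  hom_idx <- which(hom)
  interior_het <- any(het & seq_along(g) > min(c(hom_idx, Inf)) &
                        seq_along(g) < max(c(hom_idx, -Inf)))
  all_het <- length(known) > 0 && all(het[known])
  list(left_run = left_run, right_run = right_run,
       interior_het = interior_het, all_het = all_het,
       any_known = length(known) > 0)
}

#' Refine a mapped interval from recombinant genotypes
#'
#' Each recombinant animal excludes part of the interval: a run of
#' heterozygous markers anchored at the left end of the marker order
#' places the causative locus to the right of the innermost such marker
#' (exclude `[interval_left, marker_pos]`), and symmetrically for runs
#' anchored at the right end. Animals with a heterozygous marker strictly
#' between homozygous markers would require a double crossover and are
#' flagged `conflicting` and excluded from refinement. Animals
#' heterozygous at every genotyped marker are side-ambiguous (a single
#' crossover outside the marker span on either side explains them); they
#' are assigned to whichever side is consistent with the interval refined
#' from the unambiguous animals, or flagged conflicting when neither or
#' both sides are consistent.
#'
#' @param interval Mapped interval (`chrom`, `left`, `right`).
#' @param table Long genotype tibble with markers inside the interval.
#' @return A list: `interval` (refined one-row tibble), `exclusions`
#'   (per-animal tibble with `side` and excluded span), `conflicting`
#'   (character vector of animal ids). Errors if refinement empties the
#'   interval.
#' @export
refine_interval <- function(interval, table) {
  markers <- sort(unique(table$pos))
  if (length(markers) == 0) abort("genotype table has no markers")
  animals <- unique(table$animal)

  left_cut <- interval$left
  right_cut <- interval$right
  exclusions <- list()
  conflicting <- character()
  ambiguous <- character()

  per_animal <- table %>%
    arrange(animal, pos) %>%
    group_by(animal) %>%
    summarise(g = list(genotype[match(markers, pos)]), .groups = "drop")

  for (i in seq_len(nrow(per_animal))) {
    a <- per_animal$animal[i]
    g <- per_animal$g[[i]]
    g[is.na(g)] <- "unknown"
    runs <- .animal_runs(g)
    if (!runs$any_known) next
    if (runs$interior_het) {
      conflicting <- c(conflicting, a)
      next
    }
    if (runs$all_het) {
      ambiguous <- c(ambiguous, a)
      next
    }
    if (length(runs$left_run) > 0) {
      cut <- markers[max(runs$left_run)]
      left_cut <- max(left_cut, cut)
      exclusions[[length(exclusions) + 1]] <-
        tibble(animal = a, side = "left",
               excl_start = interval$left, excl_end = cut)
    }
    if (length(runs$right_run) > 0) {
      cut <- markers[min(runs$right_run)]
      right_cut <- min(right_cut, cut)
      exclusions[[length(exclusions) + 1]] <-
        tibble(animal = a, side = "right",
               excl_start = cut, excl_end = interval$right)
    }
  }

  # side-ambiguous animals: single crossover outside the marker span;
  # pick the side consistent with the interval refined so far
  for (a in ambiguous) {
    span_lo <- markers[1]
    span_hi <- markers[length(markers)]
    left_ok <- span_hi < right_cut    # locus right of all markers
    right_ok <- span_lo > left_cut    # locus left of all markers
    if (left_ok && !right_ok) {
      left_cut <- max(left_cut, span_hi)
      exclusions[[length(exclusions) + 1]] <-
        tibble(animal = a, side = "left",
               excl_start = interval$left, excl_end = span_hi)
    } else if (right_ok && !left_ok) {
      right_cut <- min(right_cut, span_lo)
      exclusions[[length(exclusions) + 1]] <-
        tibble(animal = a, side = "right",
               excl_start = span_lo, excl_end = interval$right)
    } else {
      conflicting <- c(conflicting, a)
    }
  }

  if (left_cut >= right_cut) {
    abort(paste0(
      "marker genotypes exclude the entire interval; incompatible animals: ",
      paste(unique(purrr::map_chr(exclusions, ~ .x$animal)), collapse = ", ")
    ))
  }
  refined <- tibble(chrom = interval$chrom, left = left_cut,
                    right = right_cut,
                    argmax = if ("argmax" %in% names(interval) &&
                                 !is.na(interval$argmax) &&
                                 interval$argmax >= left_cut &&
                                 interval$argmax <= right_cut)
                      interval$argmax else NA_real_,
                    peak = NA_real_)
  class(refined) <- c("mapped_interval", class(refined))
  list(
    interval = refined,
    exclusions = if (length(exclusions)) bind_rows(exclusions) else
      tibble(animal = character(), side = character(),
             excl_start = double(), excl_end = double()),
    conflicting = unique(conflicting)
  )
}

#' Estimate the causative locus position from marker distances
#'
#' Each marker predicts the locus at `pos +/- distance`; the sign landing
#' inside the refined interval is taken (or, if neither lands inside, the
#' candidate nearest the interval, flagged). Returns the mean and sample
#' standard deviation over markers (SD is 0 with a flag for a single
#' marker).
#'
#' @param est Tibble with `pos` and `distance_mb` per marker (positions in
#'   bp, distances in Mb; see [distance_estimate()]).
#' @param interval Refined interval (`left`, `right`, bp).
#' @return A list: `mean_mb`, `sd_mb`, `per_marker` tibble
#'   (`pos`, `candidate_mb`, `flagged`), `single_marker` flag.
#' @export
locus_position_estimate <- function(est, interval) {
  stopifnot(nrow(est) >= 1)
  lo <- interval$left / 1e6
  hi <- interval$right / 1e6
  mid <- (lo + hi) / 2
  per <- purrr::map_dfr(seq_len(nrow(est)), function(i) {
    pos_mb <- est$pos[i] / 1e6
    cands <- c(pos_mb + est$distance_mb[i], pos_mb - est$distance_mb[i])
    inside <- cands >= lo & cands <= hi
    if (sum(inside) == 1) {
      tibble(pos = est$pos[i], candidate_mb = cands[inside], flagged = FALSE)
    } else if (sum(inside) == 2) {
      tibble(pos = est$pos[i],
             candidate_mb = cands[which.min(abs(cands - mid))],
             flagged = TRUE)
    } else {
      dist_out <- pmax(lo - cands, cands - hi, 0)
      tibble(pos = est$pos[i],
             candidate_mb = cands[which.min(dist_out)], flagged = TRUE)
    }
  })
  single <- nrow(per) == 1
  list(
    mean_mb = mean(per$candidate_mb),
    sd_mb = if (single) 0 else sd(per$candidate_mb),
    per_marker = per,
    single_marker = single
  )
}

#' Probability of pairing two carriers in blind incrosses
#'
#' In an F2 family segregating a recessive allele, a random pair of fish
#' are both carriers with probability `carrier_fraction^2` (1/4 at the
#' default 0.5). Over `n` independent blind pairings the probability of at
#' least one carrier x carrier cross is `1 - (1 - carrier_fraction^2)^n` —
#' e.g. 1 - 0.75^6 ~= 0.82 for six pairs.
#'
#' @param n_crosses Number of blind pairings (vectorised).
#' @param carrier_fraction Fraction of the family carrying the allele
#'   (default 0.5).
#' @return Probability in \[0,1\].
#' @export
pairing_probability <- function(n_crosses, carrier_fraction = 0.5) {
  stopifnot(all(n_crosses >= 0), carrier_fraction >= 0, carrier_fraction <= 1)
  1 - (1 - carrier_fraction^2)^n_crosses
}

#' Expected genomes screened across families
#'
#' Sums the pairing probability over families: each family contributes the
#' probability that at least one of its blind incrosses paired two
#' carriers, i.e. the expected number of mutagenized genomes effectively
#' screened.
#'
#' @param pairs_per_family Integer vector: blind pairings per family.
#' @param carrier_fraction Carrier fraction (default 0.5).
#' @param per_locus_hit_rate Optional single-locus hit rate; when supplied
#'   the result also reports `coverage = genomes * per_locus_hit_rate`.
#' @return The summed genome count, or a list with `genomes` and
#'   `coverage` when `per_locus_hit_rate` is given.
#' @export
genomes_screened <- function(pairs_per_family, carrier_fraction = 0.5,
                             per_locus_hit_rate = NULL) {
  g <- sum(pairing_probability(pairs_per_family, carrier_fraction))
  if (is.null(per_locus_hit_rate)) return(g)
  list(genomes = g, coverage = g * per_locus_hit_rate)
}
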