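#' Segregation thresholds for candidate selection
#'
#' A causative recessive variant must be near-fixed in the mutant pool
#' (`ro < mut_max_ro` and `ao >= mut_min_ao`) and, in the wild-type sibling
#' pool, either heterozygous (RO/AO strictly inside
#' (`wt_ratio_lo`, `wt_ratio_hi`); a pooled wild-type sample of 1/3 +/+ and
#' 2/3 +/- siblings has expected RO/AO near 2) or not observed at all.
#'
#' @param mut_max_ro Exclusive cap on mutant-pool reference reads (default 2).
#' @param mut_min_ao Minimum mutant-pool alternate reads (default 2).
#' @param wt_ratio_lo,wt_ratio_hi Exclusive RO/AO bounds for the wild-type
#'   pool heterozygosity check (defaults 1 and 4).
#' @return A list of class `"segregation_thresholds"`.
#' @export
segregation_thresholds <- function(mut_max_ro = 2, mut_min_ao = 2,
                                   wt_ratio_lo = 1, wt_ratio_hi = 4) {
  stopifnot(mut_min_ao >= 1, wt_ratio_lo > 0, wt_ratio_lo < wt_ratio_hi)
  structure(
    list(mut_max_ro = mut_max_ro, mut_min_ao = mut_min_ao,
         wt_ratio_lo = wt_ratio_lo, wt_ratio_hi = wt_ratio_hi),
    class = "segregation_thresholds"
  )
}

#' Does a variant segregate with the mutant phenotype?
#'
#' Vectorised over rows: each variant carries its mutant-pool counts
#' (`ro_mut`, `ao_mut`) and, where the site was observed in the wild-type
#' pool, the matched counts (`ro_wt`, `ao_wt`; `NA` = not observed).
#' "Not observed" satisfies the wild-type condition: the causative allele
#' may be absent from the sibling pool's caller output entirely.
#'
#' @param variants Tibble with columns `ro_mut`, `ao_mut` and optionally
#'   `ro_wt`, `ao_wt` (NA where unobserved).
#' @param thr A [segregation_thresholds()].
#' @return Logical vector.
#' @examples
#' v <- tibble::tibble(ro_mut = c(0, 3, 1), ao_mut = c(12, 10, 2),
#'                     ro_wt = c(18, 10, NA), ao_wt = c(9, 10, NA))
#' segregates_with_phenotype(v) # TRUE FALSE TRUE
#' @export
segregates_with_phenotype <- function(variants, thr = segregation_thresholds()) {
  mut_ok <- variants$ro_mut < thr$mut_max_ro & variants$ao_mut >= thr$mut_min_ao
  if (!all(c("ro_wt", "ao_wt") %in% names(variants))) {
    return(mut_ok)
  }
  wt_absent <- is.na(variants$ro_wt) & is.na(variants$ao_wt)
  ratio <- ifelse(!wt_absent & variants$ao_wt > 0,
                  variants$ro_wt / variants$ao_wt, NA_real_)
  wt_ok <- wt_absent |
    (!is.na(ratio) & ratio > thr$wt_ratio_lo & ratio < thr$wt_ratio_hi)
  mut_ok & wt_ok
}

#' Is a variant a plausible point-mutagen product?
#'
#' Chemical mutagens such as ENU induce predominantly single (occasionally
#' double) base-pair substitutions, so candidate causative variants are
#' restricted to length-preserving changes of at most 2 bp.
#'
#' @param variants Tibble with `ref` and `alt` columns.
#' @return Logical vector: `nchar(ref) == nchar(alt)` and `nchar(ref) <= 2`.
#' @export
is_enu_like <- function(variants) {
  nchar(variants$ref) == nchar(variants$alt) & nchar(variants$ref) <= 2
}

# effect classes reported in the filtered candidate list
.reported_effects <- c("nonsynonymous", "stopgain", "stoploss",
                       "startloss", "splicing")

# join wild-type counts onto mutant calls by exact (chrom,pos,ref,alt) match
.pair_pools <- function(mut_calls, wt_calls) {
  mut <- mut_calls %>%
    select(chrom, pos, ref, alt, ro_mut = ro, ao_mut = ao)
  if (is.null(wt_calls) || nrow(wt_calls) == 0) {
    mut$ro_wt <- NA_integer_
    mut$ao_wt <- NA_integer_
    return(mut)
  }
  wt <- wt_calls %>%
    select(chrom, pos, ref, alt, ro_wt = ro, ao_wt = ao) %>%
    distinct(chrom, pos, ref, alt, .keep_all = TRUE)
  left_join(mut, wt, by = c("chrom", "pos", "ref", "alt"))
}

# collapse per-transcript annotations to one row per variant carrying the
# most severe class; all transcript annotations retained in 'all_annotations'
.collapse_annotations <- function(annotations) {
  if (is.null(annotations) || nrow(annotations) == 0) return(NULL)
  annotations %>%
    mutate(
      class = ifelse(.data$region == "splicing", "splicing",
                     ifelse(is.na(.data$effect), .data$region, .data$effect)),
      sev = severity_rank(.data$class)
    ) %>%
    group_by(chrom, pos, ref, alt) %>%
    arrange(desc(.data$sev), .by_group = TRUE) %>%
    summarise(
      all_annotations = paste(
        stats::na.omit(unique(paste0(transcript, ":", .data$class))),
        collapse = ";"
      ),
      gene = first(gene), transcript = first(transcript),
      region = first(region), effect = first(.data$class),
      cdna_change = first(.data$cdna_change),
      protein_change = first(.data$protein_change),
      .groups = "drop"
    ) %>%
    relocate(all_annotations, .after = last_col())
}

#' Filter candidate causative variants inside the mapped interval
#'
#' Produces the unfiltered list (every mutant-pool variant inside the
#' interval, with matched wild-type counts) and the filtered list: variants
#' that additionally pass the segregation test, look mutagen-induced
#' ([is_enu_like()]), and — when annotations are supplied — have a reported
#' consequence class (nonsynonymous, stopgain, stoploss, startloss or
#' splicing). SIFT scores are attached where available. When `annotations`
#' is `NULL` (no gene models), the consequence condition is skipped and the
#' effect columns are left empty.
#'
#' @param mut_calls,wt_calls Variant-call tibbles for the two pools.
#' @param interval Mapped interval from [select_interval()] (or any tibble
#'   with `chrom`, `left`, `right`).
#' @param annotations Optional per-transcript annotation tibble from
#'   [annotate_variants()].
#' @param sift Optional SIFT tibble from [read_sift_table()].
#' @param thr A [segregation_thresholds()].
#' @return A list with tibbles `unfiltered` and `filtered`, both sorted by
#'   position, in the candidates-TSV column layout.
#' @export
filter_candidates <- function(mut_calls, wt_calls, interval,
                              annotations = NULL, sift = NULL,
                              thr = segregation_thresholds()) {
  inside <- mut_calls$chrom == interval$chrom &
    mut_calls$pos >= interval$left & mut_calls$pos <= interval$right
  if (!any(inside)) {
    warn(paste0("no mutant-pool variants inside the interval ",
                interval$chrom, ":", interval$left, "-", interval$right))
  }
  unfiltered <- .pair_pools(mut_calls[inside, ], wt_calls)

  ann <- .collapse_annotations(annotations)
  if (!is.null(ann)) {
    unfiltered <- left_join(unfiltered, ann,
                            by = c("chrom", "pos", "ref", "alt"))
  } else {
    unfiltered$gene <- NA_character_
    unfiltered$transcript <- NA_character_
    unfiltered$region <- NA_character_
    unfiltered$effect <- NA_character_
    unfiltered$cdna_change <- NA_character_
    unfiltered$protein_change <- NA_character_
  }
  if (!is.null(sift)) {
    unfiltered <- left_join(unfiltered, sift,
                            by = c("chrom", "pos", "ref", "alt"))
  } else {
    unfiltered$sift <- NA_real_
  }
  unfiltered <- arrange(unfiltered, pos)

  pass <- segregates_with_phenotype(unfiltered, thr) &
    is_enu_like(unfiltered)
  if (!is.null(ann)) {
    pass <- pass & !is.na(unfiltered$effect) &
      unfiltered$effect %in% .reported_effects
  }
  list(unfiltered = unfiltered, filtered = unfiltered[pass, ])
}

#' Count distinct candidate genes
#'
#' Number of distinct gene symbols among filtered candidates whose class is
#' missense (nonsynonymous), nonsense (stopgain) or splicing — the gene-level
#' summary used to size the remaining search space.
#'
#' @param filtered Filtered candidate tibble from [filter_candidates()].
#' @return Integer count.
#' @export
count_candidate_genes <- function(filtered) {
  d <- filtered[!is.na(filtered$effect) &
                  filtered$effect %in% c("nonsynonymous", "stopgain", "splicing") &
                  !is.na(filtered$gene), ]
  length(unique(d$gene))
}

#' Tally filtered candidates by consequence class
#'
#' @param filtered Filtered candidate tibble from [filter_candidates()].
#' @return A one-row tibble with counts `nonsense` (stopgain),
#'   `nonsynonymous`, `startloss`, `stoploss`, `splicing` and
#'   `candidate_snps` (total filtered candidates).
#' @export
class_tally <- function(filtered) {
  eff <- filtered$effect
  tibble(
    nonsense = sum(eff == "stopgain", na.rm = TRUE),
    nonsynonymous = sum(eff == "nonsynonymous", na.rm = TRUE),
    startloss = sum(eff == "startloss", na.rm = TRUE),
    stoploss = sum(eff == "stoploss", na.rm = TRUE),
    splicing = sum(eff == "splicing", na.rm = TRUE),
    candidate_snps = nrow(filtered)
  )
}
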