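#' Extract mutant-homozygous points
#'
#' The classical bulked-segregant comparator: sites whose mutant-pool
#' alternate allele fraction `ao/(ro+ao)` exceeds `hom_threshold`,
#' optionally restricted to sites heterozygous in the wild-type sibling
#' pool (which removes strain-background homozygosity). Sites with zero
#' total depth are skipped.
#'
#' @param mut_calls Mutant-pool variant-call tibble.
#' @param wt_calls Optional wild-type-pool tibble; required when
#'   `require_wt_het = TRUE`.
#' @param hom_threshold Alternate-fraction threshold, exclusive
#'   (default 0.9).
#' @param require_wt_het Keep only sites whose matched wild-type call is a
#'   heterozygous point (default TRUE; set FALSE for the mutant-only
#'   variant of the method).
#' @param cfg An [index_config()] supplying the heterozygous-point rule.
#' @return A tibble: `chrom`, `pos`, `ref`, `alt`, `alt_fraction`.
#' @export
extract_homozygous_points <- function(mut_calls, wt_calls = NULL,
                                      hom_threshold = 0.9,
                                      require_wt_het = TRUE,
                                      cfg = index_config()) {
  depth <- mut_calls$ro + mut_calls$ao
  frac <- ifelse(depth > 0, mut_calls$ao / depth, NA_real_)
  keep <- !is.na(frac) & frac > hom_threshold
  pts <- mut_calls[keep, c("chrom", "pos", "ref", "alt")]
  pts$alt_fraction <- frac[keep]
  if (require_wt_het) {
    if (is.null(wt_calls)) {
      abort("require_wt_het = TRUE needs wild-type calls; pass wt_calls or set require_wt_het = FALSE")
    }
    wt <- wt_calls[is_heterozygous_point(wt_calls, cfg),
                   c("chrom", "pos", "ref", "alt")]
    pts <- semi_join(pts, wt, by = c("chrom", "pos", "ref", "alt"))
  }
  pts
}

#' Genome-wide density of homozygous points
#'
#' Bins the homozygous points into fixed-width tiles per chromosome for
#' density plotting/comparison. Bins are half-open `[start, end)` in
#' 1-based terms, so a point exactly on a boundary belongs to the
#' right-hand bin.
#'
#' @param points Tibble from [extract_homozygous_points()].
#' @param genome Genome index tibble (`chrom`, `length`).
#' @param binwidth Bin width in bp (default 1e6).
#' @return A tibble: `chrom`, `win_start`, `win_end` (1-based inclusive),
#'   `count`; counts sum to `nrow(points)` for points on indexed
#'   chromosomes.
#' @export
point_density <- function(points, genome, binwidth = 1e6) {
  purrr::map_dfr(seq_len(nrow(genome)), function(i) {
    chrom_i <- genome$chrom[i]
    len <- genome$length[i]
    n_bins <- ceiling(len / binwidth)
    pos <- points$pos[points$chrom == chrom_i]
    bin <- pmin(floor((pos - 1) / binwidth) + 1, n_bins)
    tibble(
      chrom = chrom_i,
      win_start = (seq_len(n_bins) - 1) * binwidth + 1,
      win_end = pmin(seq_len(n_bins) * binwidth, len),
      count = tabulate(bin, nbins = n_bins)
    )
  })
}
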