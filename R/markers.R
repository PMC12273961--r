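#' Extract segregating indel markers from the mapped interval
#'
#' Insertion/deletion variants inside the homozygous interval that
#' segregate with the mutant phenotype are usable as PCR genotyping
#' markers: the ref/alt length difference is the expected product size
#' shift on a gel. Markers pass the same segregation predicate as
#' candidate SNPs ([segregates_with_phenotype()]). The default minimum
#' length difference of 4 bp keeps markers gel-resolvable; set
#' `min_len_diff = 1` to keep every indel.
#'
#' @param mut_calls,wt_calls Variant-call tibbles for the two pools.
#' @param interval Mapped interval (`chrom`, `left`, `right`).
#' @param thr A [segregation_thresholds()].
#' @param min_len_diff Minimum |nchar(ref) - nchar(alt)| in bp (default 4).
#' @param context Flanking distance reported for external primer design
#'   (default 500 bp); emitted as `context_start`/`context_end`.
#' @return A tibble sorted by position: `chrom`, `pos`, `ref`, `alt`,
#'   `indel_len_diff`, `ro_mut`, `ao_mut`, `ro_wt`, `ao_wt`,
#'   `context_start`, `context_end`.
#' @export
extract_indel_markers <- function(mut_calls, wt_calls, interval,
                                  thr = segregation_thresholds(),
                                  min_len_diff = 4, context = 500) {
  inside <- mut_calls$chrom == interval$chrom &
    mut_calls$pos >= interval$left & mut_calls$pos <= interval$right
  paired <- .pair_pools(mut_calls[inside, ], wt_calls)
  len_diff <- abs(nchar(paired$ref) - nchar(paired$alt))
  keep <- len_diff >= pmax(1, min_len_diff) & len_diff >= 1 &
    segregates_with_phenotype(paired, thr)
  out <- paired[keep, ]
  out$indel_len_diff <- len_diff[keep]
  out$context_start <- pmax(1, out$pos - context)
  out$context_end <- out$pos + context
  arrange(out, pos)
}
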