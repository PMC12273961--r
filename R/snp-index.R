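#' Configuration for SNP-index homozygosity mapping
#'
#' Bundles the tunable parameters of the windowed heterozygosity statistic.
#' Defaults follow the published method for zebrafish: 10 kb tiling windows,
#' a 750 kb moving-average width (1 cM at 0.74 Mb/cM), and chromosomes
#' shorter than 1 Mb excluded to avoid scaffold noise.
#'
#' @param window_width Window width in bp (default 10000).
#' @param window_step Step between window starts in bp; must be <= width.
#'   Default equals the width (tiling windows).
#' @param ma_width Moving-average filter width in bp (default 750000).
#' @param het_min_each Minimum reads per allele for a site to count as a
#'   heterozygous point (default 2).
#' @param het_ratio_bounds Allowed RO/AO ratio interval for a heterozygous
#'   point, inclusive (default `c(0.25, 4)`).
#' @param min_chrom_len Chromosomes shorter than this are excluded from
#'   mapping (default 1e6 bp).
#' @return A list of class `"index_config"`.
#' @export
index_config <- function(window_width = 10000, window_step = window_width,
                         ma_width = 750000, het_min_each = 2,
                         het_ratio_bounds = c(0.25, 4),
                         min_chrom_len = 1e6) {
  stopifnot(
    window_width > 0, window_step > 0, window_step <= window_width,
    ma_width >= window_width, het_min_each >= 1,
    length(het_ratio_bounds) == 2,
    het_ratio_bounds[1] > 0, het_ratio_bounds[1] < het_ratio_bounds[2]
  )
  structure(
    list(window_width = window_width, window_step = window_step,
         ma_width = ma_width, het_min_each = het_min_each,
         het_ratio_bounds = het_ratio_bounds, min_chrom_len = min_chrom_len),
    class = "index_config"
  )
}

#' Is a variant site a heterozygous point?
#'
#' A pooled-sample site counts as heterozygous when both alleles are
#' supported by at least `het_min_each` reads and the RO/AO ratio lies
#' inside `het_ratio_bounds` (inclusive). Sites with one allele absent are
#' never heterozygous; no division is attempted when `ao = 0`.
#'
#' @param calls Variant-call tibble with columns `ro`, `ao` (vectorised).
#' @param cfg An [index_config()].
#' @return Logical vector, one element per row of `calls`.
#' @examples
#' calls <- tibble::tibble(ro = c(10, 0, 10), ao = c(8, 20, 1))
#' is_heterozygous_point(calls) # TRUE FALSE FALSE
#' @export
is_heterozygous_point <- function(calls, cfg = index_config()) {
  ro <- calls$ro
  ao <- calls$ao
  ok <- pmin(ro, ao) >= cfg$het_min_each
  ratio <- ifelse(ao > 0, ro / ao, Inf)
  ok & ratio >= cfg$het_ratio_bounds[1] & ratio <= cfg$het_ratio_bounds[2]
}

# window geometry shared by the track builders: window k (1-based) spans
# [(k-1)*step + 1, (k-1)*step + width], center (k-1)*step + width/2
.n_windows <- function(chrom_len, cfg) {
  max(0L, as.integer(floor((chrom_len - cfg$window_width) / cfg$window_step)) + 1L)
}

.window_frame <- function(chrom, chrom_len, cfg) {
  n <- .n_windows(chrom_len, cfg)
  k <- seq_len(n)
  tibble(
    chrom = chrom,
    win_start = (k - 1) * cfg$window_step + 1,
    win_end = (k - 1) * cfg$window_step + cfg$window_width,
    center = (k - 1) * cfg$window_step + cfg$window_width / 2
  )
}

#' Windowed heterozygosity track
#'
#' Counts heterozygous points per sliding window on each chromosome. With
#' the default tiling step every call lands in exactly one window; with
#' `window_step < window_width` overlapping windows each count the calls
#' they span. Calls on chromosomes absent from `genome` (or shorter than
#' `min_chrom_len`) are skipped with a warning.
#'
#' @param calls Variant-call tibble (from [read_variant_calls()]).
#' @param genome Genome index tibble (`chrom`, `length`), e.g. from
#'   [read_genome_index()].
#' @param cfg An [index_config()].
#' @return A tibble with columns `chrom`, `win_start`, `win_end`, `center`,
#'   `het` covering every window of every retained chromosome.
#' @export
window_heterozygosity <- function(calls, genome, cfg = index_config()) {
  genome <- genome[genome$length >= cfg$min_chrom_len, ]
  if (nrow(genome) == 0) {
    abort("no chromosome passes min_chrom_len; nothing to window")
  }
  het_calls <- calls[is_heterozygous_point(calls, cfg), c("chrom", "pos")]
  off_genome <- setdiff(unique(calls$chrom), genome$chrom)
  if (length(off_genome) > 0) {
    warn(paste0("calls on ", length(off_genome),
                " sequence(s) absent from the genome index (or below ",
                "min_chrom_len) were skipped: ",
                paste(head(off_genome, 5), collapse = ", ")))
  }
  purrr::map_dfr(seq_len(nrow(genome)), function(i) {
    chrom_i <- genome$chrom[i]
    wf <- .window_frame(chrom_i, genome$length[i], cfg)
    n <- nrow(wf)
    if (n == 0) return(wf[0, ])
    pos <- het_calls$pos[het_calls$chrom == chrom_i]
    pos <- pos[pos >= 1 & pos <= genome$length[i]]
    counts <- integer(n)
    if (length(pos) > 0) {
      # window k contains pos iff ceil((pos-w)/s) < k <= floor((pos-1)/s) + 1
      k_hi <- pmin(floor((pos - 1) / cfg$window_step) + 1, n)
      k_lo <- pmax(ceiling((pos - cfg$window_width) / cfg$window_step) + 1, 1)
      valid <- k_lo <= k_hi
      if (any(valid)) {
        ks <- unlist(purrr::map2(k_lo[valid], k_hi[valid], seq))
        counts <- tabulate(ks, nbins = n)
      }
    }
    wf$het <- counts
    wf
  })
}

#' The heterozygosity-difference SNP index
#'
#' For each window center C the statistic is
#' `(Het_wt(C) - Het_mut(C)) / (2 + Het_mut(C))`: large and positive where
#' the mutant pool has lost heterozygosity relative to its wild-type
#' siblings (the homozygous region around a recessive causative locus),
#' near zero elsewhere. The denominator offset keeps the value finite in
#' empty windows and bounds the index in `(-1, Het_wt/2]`.
#'
#' @param het_wt,het_mut Heterozygosity tracks from
#'   [window_heterozygosity()] computed on the same genome and config.
#' @return A tibble with the window columns plus `het_wt`, `het_mut` and
#'   `snp_index` (raw, unsmoothed).
#' @export
snp_index <- function(het_wt, het_mut) {
  if (nrow(het_wt) != nrow(het_mut) ||
      !all(het_wt$chrom == het_mut$chrom) ||
      !all(het_wt$center == het_mut$center)) {
    abort("het_wt and het_mut tracks have mismatched chromosomes/centers; recompute both with the same genome index and config")
  }
  out <- het_wt[, c("chrom", "win_start", "win_end", "center")]
  out$het_wt <- het_wt$het
  out$het_mut <- het_mut$het
  out$snp_index <- (out$het_wt - out$het_mut) / (2 + out$het_mut)
  out
}

#' Moving-average smoothing of the SNP index
#'
#' Smooths the raw index with a centered moving average of width `ma_width`
#' bp: `MA(C)` is the mean of the raw index over all window centers C' with
#' `|C' - C| <= ma_width/2`. The mean is truncated at chromosome ends (no
#' zero padding), so ends are not dragged toward zero artificially.
#'
#' @param track Raw SNP-index track from [snp_index()].
#' @param cfg An [index_config()] supplying `ma_width`.
#' @return `track` with an added `ma` column.
#' @export
moving_average <- function(track, cfg = index_config()) {
  half <- cfg$ma_width / 2
  eps <- 1e-6
  track %>%
    group_by(chrom) %>%
    group_modify(function(d, key) {
      d <- d[order(d$center), ]
      cs <- c(0, cumsum(d$snp_index))
      j1 <- findInterval(d$center - half - eps, d$center) + 1
      j2 <- findInterval(d$center + half + eps, d$center)
      d$ma <- (cs[j2 + 1] - cs[j1]) / (j2 - j1 + 1)
      d
    }) %>%
    ungroup()
}

#' Select the zero-bounded homozygous interval
#'
#' Scans all chromosomes for the highest smoothed SNP-index value and walks
#' outward from the peak until the smoothed index first drops to zero or
#' below on each side. Each bound is placed midway between that first
#' non-positive center and its interval-side neighbor; if no zero crossing
#' exists the bound is the chromosome end. Ties at the global maximum are
#' broken by chromosome name, then coordinate.
#'
#' @param track Smoothed track from [moving_average()] covering all
#'   chromosomes (must have an `ma` column).
#' @param genome Genome index tibble giving chromosome lengths.
#' @return A one-row tibble of class `"mapped_interval"` with columns
#'   `chrom`, `left`, `right`, `argmax`, `peak`.
#' @export
select_interval <- function(track, genome) {
  if (!"ma" %in% names(track)) {
    abort("track has no 'ma' column; run moving_average() first")
  }
  if (nrow(track) == 0) abort("empty track")
  if (all(track$ma <= 0)) {
    abort(paste0(
      "no positive smoothed SNP-index signal anywhere in the genome; ",
      "check that the mutant and wild-type pools are correctly assigned ",
      "and that the VCFs carry comparable depth"
    ))
  }
  peak_val <- max(track$ma)
  cand <- track[track$ma == peak_val, ]
  cand <- cand[order(cand$chrom, cand$center), ]
  chrom_sel <- cand$chrom[1]
  argmax_c <- cand$center[1]

  d <- track[track$chrom == chrom_sel, ]
  d <- d[order(d$center), ]
  i <- which(d$center == argmax_c)[1]
  chrom_len <- genome$length[match(chrom_sel, genome$chrom)]

  left <- 1
  if (i > 1) {
    nonpos <- which(d$ma[seq_len(i - 1)] <= 0)
    if (length(nonpos) > 0) {
      j <- max(nonpos)
      left <- (d$center[j] + d$center[j + 1]) / 2
    }
  }
  right <- chrom_len
  n <- nrow(d)
  if (i < n) {
    nonpos <- which(d$ma[(i + 1):n] <= 0)
    if (length(nonpos) > 0) {
      j <- i + min(nonpos)
      right <- (d$center[j - 1] + d$center[j]) / 2
    }
  }
  out <- tibble(chrom = chrom_sel, left = left, right = right,
                argmax = argmax_c, peak = peak_val)
  class(out) <- c("mapped_interval", class(out))
  out
}

#' Mean raw SNP index around a position
#'
#' The mean of the raw (unsmoothed) SNP index over all window centers
#' within `radius` bp of `position` — by default +/- 740 kb, i.e. the
#' 2 cM neighbourhood at 0.74 Mb/cM used to report local signal strength.
#' Truncated at chromosome ends.
#'
#' @param track Raw SNP-index track from [snp_index()].
#' @param chrom,position Locus of interest.
#' @param radius Half-width in bp (default 740000).
#' @return The mean raw index (scalar).
#' @export
mean_local_index <- function(track, chrom, position, radius = 740000) {
  d <- track[track$chrom == chrom &
               abs(track$center - position) <= radius, ]
  if (nrow(d) == 0) {
    abort("no window centers within radius of the given position")
  }
  mean(d$snp_index)
}
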