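#' Tidy a mapped interval
#'
#' One row per interval with bounds in bp and Mb, broom-style.
#'
#' @param x A `mapped_interval`.
#' @param ... Unused.
#' @return A tibble: `chrom`, `left`, `right`, `argmax`, `peak`,
#'   `size_mb`.
#' @export
tidy.mapped_interval <- function(x, ...) {
  tibble(
    chrom = x$chrom, left = x$left, right = x$right,
    argmax = x$argmax, peak = x$peak,
    size_mb = (x$right - x$left) / 1e6
  )
}

#' @rdname tidy.mapped_interval
#' @export
glance.mapped_interval <- function(x, ...) {
  tibble(size_mb = (x$right - x$left) / 1e6, peak = x$peak)
}

#' Tidy a simulated cross
#'
#' @param x A `segmap_sim` from [simulate_cross()].
#' @param ... Unused.
#' @return The per-site tibble with true pool fractions.
#' @export
tidy.segmap_sim <- function(x, ...) {
  x$sites
}

#' @rdname tidy.segmap_sim
#' @export
glance.segmap_sim <- function(x, ...) {
  tibble(
    n_sites = nrow(x$sites),
    n_indels = sum(x$sites$type == "indel"),
    causative_chrom = x$truth$chrom,
    causative_pos = x$truth$pos,
    causative_frac_mut = x$truth$frac_mut,
    causative_frac_wt = x$truth$frac_wt
  )
}

#' Plot a SNP-index track
#'
#' Raw index (points) and moving average (line), faceted by chromosome,
#' with optional interval shading and causative-locus marker.
#'
#' @param object A SNP-index track tibble (from [snp_index()], with or
#'   without the `ma` column).
#' @param interval Optional `mapped_interval` to shade.
#' @param locus Optional true/confirmed locus (list or tibble with
#'   `chrom`, `pos`) drawn as a dashed vertical line.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot snp_index_track
autoplot.snp_index_track <- function(object, interval = NULL, locus = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = center / 1e6)) +
    ggplot2::geom_point(ggplot2::aes(y = snp_index),
                        alpha = 0.25, size = 0.4, colour = "grey50") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "SNP index") +
    ggplot2::theme_minimal()
  if ("ma" %in% names(object)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = ma), colour = "#2166ac")
  }
  if (!is.null(interval)) {
    p <- p + ggplot2::geom_vline(
      data = tibble(chrom = interval$chrom,
                    x = c(interval$left, interval$right) / 1e6),
      ggplot2::aes(xintercept = x), linetype = "solid", colour = "#b2182b"
    )
  }
  if (!is.null(locus)) {
    p <- p + ggplot2::geom_vline(
      data = tibble(chrom = locus$chrom, x = locus$pos / 1e6),
      ggplot2::aes(xintercept = x), linetype = "dashed"
    )
  }
  p
}

#' Plot SNP-index mapping results
#'
#' Convenience wrapper that classes a track tibble and calls
#' [autoplot.snp_index_track()].
#'
#' @param track SNP-index track tibble.
#' @inheritParams autoplot.snp_index_track
#' @return A ggplot.
#' @export
plot_snp_index <- function(track, interval = NULL, locus = NULL) {
  class(track) <- c("snp_index_track", class(track))
  autoplot(track, interval = interval, locus = locus)
}

#' Plot homozygous-point density
#'
#' @param density Density tibble from [point_density()].
#' @return A ggplot of per-bin counts, faceted by chromosome.
#' @export
plot_point_density <- function(density) {
  ggplot2::ggplot(density,
                  ggplot2::aes(x = (win_start + win_end) / 2e6, y = count)) +
    ggplot2::geom_col(width = (density$win_end[1] - density$win_start[1]) / 1e6,
                      fill = "#2166ac") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "homozygous points / bin") +
    ggplot2::theme_minimal()
}
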