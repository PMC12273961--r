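#' Write a windowed track as bedGraph
#'
#' Emits a 4-column bedGraph (`chrom`, 0-based half-open window span, value).
#' Internal coordinates are 1-based inclusive; the conversion to bedGraph is
#' `start - 1`, `end`. Values are rendered with 6 decimals.
#'
#' @param track A tibble with columns `chrom`, `win_start`, `win_end`
#'   (1-based inclusive) and the value column named by `value`.
#' @param path Output path.
#' @param value Name of the value column (default `"snp_index"`).
#' @return `path`, invisibly.
#' @export
write_track_bedgraph <- function(track, path, value = "snp_index") {
  stopifnot(all(c("chrom", "win_start", "win_end", value) %in% names(track)))
  lines <- sprintf("%s\t%d\t%d\t%.6f",
                   track$chrom,
                   as.integer(track$win_start - 1),
                   as.integer(track$win_end),
                   track[[value]])
  writeLines(lines, path)
  invisible(path)
}

#' Write a mapped interval as BED
#'
#' BED is 0-based half-open: a 1-based inclusive interval `[left, right]`
#' becomes `left - 1`, `right`.
#'
#' @param interval A one-row tibble with `chrom`, `left`, `right`
#'   (1-based inclusive), e.g. from [select_interval()].
#' @param path Output path.
#' @param name Optional feature name (4th BED column).
#' @return `path`, invisibly.
#' @export
write_interval_bed <- function(interval, path, name = "mapped_interval") {
  lines <- sprintf("%s\t%d\t%d\t%s",
                   interval$chrom,
                   as.integer(round(interval$left - 1)),
                   as.integer(round(interval$right)),
                   name)
  writeLines(lines, path)
  invisible(path)
}

.candidate_cols <- c("chrom", "pos", "ref", "alt", "ro_mut", "ao_mut",
                     "ro_wt", "ao_wt", "gene", "transcript", "region",
                     "effect", "cdna_change", "protein_change", "sift")

#' Write and read candidate variant tables
#'
#' Candidates are exchanged as a tab-separated table with a fixed column
#' set (`chrom`, `pos`, `ref`, `alt`, `ro_mut`, `ao_mut`, `ro_wt`, `ao_wt`,
#' `gene`, `transcript`, `region`, `effect`, `cdna_change`,
#' `protein_change`, `sift`). Writing then re-reading reproduces the table.
#'
#' @param candidates Candidate tibble (missing columns are filled with NA).
#' @param path Output path.
#' @return `path` (write) or the candidate tibble (read).
#' @export
write_candidates_tsv <- function(candidates, path) {
  for (col in .candidate_cols) {
    if (!col %in% names(candidates)) candidates[[col]] <- NA
  }
  out <- candidates[, .candidate_cols]
  out$sift <- ifelse(is.na(out$sift), NA_character_, sprintf("%.6f", out$sift))
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' @rdname write_candidates_tsv
#' @export
read_candidates_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, na = "",
                  col_types = readr::cols(
                    chrom = readr::col_character(),
                    pos = readr::col_double(),
                    ref = readr::col_character(),
                    alt = readr::col_character(),
                    ro_mut = readr::col_integer(),
                    ao_mut = readr::col_integer(),
                    ro_wt = readr::col_integer(),
                    ao_wt = readr::col_integer(),
                    gene = readr::col_character(),
                    transcript = readr::col_character(),
                    region = readr::col_character(),
                    effect = readr::col_character(),
                    cdna_change = readr::col_character(),
                    protein_change = readr::col_character(),
                    sift = readr::col_double()
                  ))
}

#' Write an indel marker table
#'
#' @param markers Marker tibble from [extract_indel_markers()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_markers_tsv <- function(markers, path) {
  cols <- c("chrom", "pos", "ref", "alt", "indel_len_diff",
            "ro_mut", "ao_mut", "ro_wt", "ao_wt")
  for (col in cols) {
    if (!col %in% names(markers)) markers[[col]] <- NA
  }
  readr::write_tsv(markers[, cols], path, na = "")
  invisible(path)
}
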