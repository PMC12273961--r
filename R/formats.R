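#' Read a samtools FASTA index (.fai)
#'
#' The `.fai` index carries the ordered sequence names and lengths that drive
#' genome windowing. Only the first two columns are used.
#'
#' @param path Path to a `.fai` file (5 tab-separated columns:
#'   name, length, offset, linebases, linewidth).
#' @return A tibble with columns `chrom` and `length`, in file order.
#' @export
read_genome_index <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- stringr::str_split(lines, stringr::fixed("\t"))
  bad <- which(lengths(fields) < 2)
  if (length(bad) > 0) {
    abort(paste0("malformed .fai line ", bad[1], " in '", path, "'"))
  }
  chrom <- purrr::map_chr(fields, 1)
  len <- suppressWarnings(as.numeric(purrr::map_chr(fields, 2)))
  if (anyNA(len) || any(len < 1)) {
    abort(paste0("malformed .fai line ", which(is.na(len) | len < 1)[1],
                 " in '", path, "': length is not a positive number"))
  }
  if (anyDuplicated(chrom)) {
    abort(paste0("duplicate sequence name in '", path, "': ",
                 chrom[duplicated(chrom)][1]))
  }
  tibble(chrom = chrom, length = len)
}

#' Build a genome index from chromosome lengths
#'
#' Convenience constructor for the tibble [read_genome_index()] returns,
#' for genomes defined in code (simulations, fixtures).
#'
#' @param lengths Named numeric vector of chromosome lengths in bp.
#' @return A tibble with columns `chrom`, `length`.
#' @export
genome_index <- function(lengths) {
  stopifnot(!is.null(names(lengths)), all(lengths >= 1),
            !anyDuplicated(names(lengths)))
  tibble(chrom = names(lengths), length = unname(as.numeric(lengths)))
}

#' Read transcript gene models
#'
#' Reads gene models used for variant consequence annotation, either from a
#' refFlat-style TSV (UCSC convention, 0-based half-open coordinates,
#' converted on read) or from GFF3 (via rtracklayer). All returned
#' coordinates are 1-based inclusive. Models failing validation (inverted
#' coordinates, exon count mismatch, CDS length not a multiple of 3) are
#' dropped with a warning.
#'
#' @param path Path to the gene model file.
#' @param dialect `"refflat"` or `"gff3"`.
#' @return A tibble of gene models; see [gene_models()] for the schema.
#' @export
read_gene_models <- function(path, dialect = c("refflat", "gff3")) {
  dialect <- match.arg(dialect)
  models <- switch(dialect,
    refflat = .read_refflat(path),
    gff3 = .read_gff3(path)
  )
  validate_gene_models(models)
}

.read_refflat <- function(path) {
  cols <- c("gene", "transcript", "chrom", "strand", "tx_start", "tx_end",
            "cds_start", "cds_end", "exon_count", "exon_starts", "exon_ends")
  df <- readr::read_tsv(path, col_names = cols, comment = "#",
                        show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  parse_blocks <- function(x) {
    purrr::map(x, ~ as.numeric(strsplit(.x, ",")[[1]]))
  }
  tibble(
    gene = df$gene,
    transcript = df$transcript,
    chrom = df$chrom,
    strand = df$strand,
    tx_start = as.numeric(df$tx_start) + 1, # 0-based -> 1-based inclusive
    tx_end = as.numeric(df$tx_end),
    cds_start = ifelse(df$cds_start == df$cds_end, NA_real_,
                       as.numeric(df$cds_start) + 1),
    cds_end = ifelse(df$cds_start == df$cds_end, NA_real_,
                     as.numeric(df$cds_end)),
    exon_count = as.integer(df$exon_count),
    exon_starts = purrr::map(parse_blocks(df$exon_starts), ~ .x + 1),
    exon_ends = parse_blocks(df$exon_ends)
  )
}

.read_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading GFF3 gene models requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  typ <- tolower(as.character(df$type))
  tx <- df[typ %in% c("mrna", "transcript"), , drop = FALSE]
  ex <- df[typ == "exon", , drop = FALSE]
  cds <- df[typ == "cds", , drop = FALSE]
  get_parent <- function(d) {
    p <- d$Parent
    if (is.null(p)) rep(NA_character_, nrow(d)) else purrr::map_chr(p, ~ .x[1] %||% NA_character_)
  }
  ex$parent <- get_parent(ex)
  cds$parent <- get_parent(cds)
  purrr::map_dfr(seq_len(nrow(tx)), function(i) {
    id <- tx$ID[i]
    exi <- ex[!is.na(ex$parent) & ex$parent == id, , drop = FALSE]
    cdsi <- cds[!is.na(cds$parent) & cds$parent == id, , drop = FALSE]
    if (nrow(exi) == 0) {
      exi <- tx[i, , drop = FALSE] # single-exon transcript without exon rows
    }
    ord <- order(exi$start)
    gene <- tx$gene_id[i] %||% tx$Name[i] %||% id
    if (is.na(gene)) gene <- id
    tibble(
      gene = as.character(gene),
      transcript = as.character(id),
      chrom = as.character(tx$seqnames[i]),
      strand = as.character(tx$strand[i]),
      tx_start = as.numeric(tx$start[i]),
      tx_end = as.numeric(tx$end[i]),
      cds_start = if (nrow(cdsi)) min(cdsi$start) else NA_real_,
      cds_end = if (nrow(cdsi)) max(cdsi$end) else NA_real_,
      exon_count = length(ord),
      exon_starts = list(as.numeric(exi$start[ord])),
      exon_ends = list(as.numeric(exi$end[ord]))
    )
  })
}

#' Construct gene models in code
#'
#' Builds the validated gene-model tibble consumed by
#' [annotate_variants()]. Coordinates are 1-based inclusive; exons must be
#' sorted and non-overlapping; for coding models the exon-intersected CDS
#' length must be a multiple of 3.
#'
#' @param gene,transcript,chrom,strand Character scalars per model.
#' @param exon_starts,exon_ends Numeric vectors of exon spans.
#' @param cds_start,cds_end CDS bounds (1-based inclusive), or `NA` for a
#'   non-coding model.
#' @return A one-row gene-model tibble.
#' @export
gene_models <- function(gene, transcript, chrom, strand,
                        exon_starts, exon_ends,
                        cds_start = NA_real_, cds_end = NA_real_) {
  m <- tibble(
    gene = gene, transcript = transcript, chrom = chrom, strand = strand,
    tx_start = min(exon_starts), tx_end = max(exon_ends),
    cds_start = as.numeric(cds_start), cds_end = as.numeric(cds_end),
    exon_count = length(exon_starts),
    exon_starts = list(as.numeric(exon_starts)),
    exon_ends = list(as.numeric(exon_ends))
  )
  validate_gene_models(m)
}

#' Validate a gene-model tibble
#'
#' Drops models with inverted coordinates, exon-count mismatches,
#' CDS outside the transcript span, or a coding length that is not a
#' multiple of 3, each with a warning naming the transcript.
#'
#' @param models Gene-model tibble (see [gene_models()]).
#' @return The validated tibble (possibly with rows dropped).
#' @export
validate_gene_models <- function(models) {
  keep <- rep(TRUE, nrow(models))
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    es <- m$exon_starts[[1]]
    ee <- m$exon_ends[[1]]
    tag <- m$transcript
    if (length(es) != length(ee) || length(es) != m$exon_count) {
      warn(paste0("gene model ", tag, ": exon count mismatch; model skipped"))
      keep[i] <- FALSE
      next
    }
    if (any(es > ee) || m$tx_start > m$tx_end) {
      warn(paste0("gene model ", tag, ": inverted coordinates; model skipped"))
      keep[i] <- FALSE
      next
    }
    if (length(es) > 1 && any(diff(es) <= 0 | es[-1] <= ee[-length(ee)])) {
      warn(paste0("gene model ", tag, ": exons unsorted or overlapping; model skipped"))
      keep[i] <- FALSE
      next
    }
    if (!is.na(m$cds_start)) {
      if (m$cds_start < m$tx_start || m$cds_end > m$tx_end ||
          m$cds_start > m$cds_end) {
        warn(paste0("gene model ", tag, ": CDS outside transcript; model skipped"))
        keep[i] <- FALSE
        next
      }
      cds_len <- sum(pmax(0, pmin(ee, m$cds_end) - pmax(es, m$cds_start) + 1))
      if (cds_len %% 3 != 0) {
        warn(paste0("gene model ", tag, ": CDS length ", cds_len,
                    " not a multiple of 3; model skipped"))
        keep[i] <- FALSE
      }
    }
  }
  models[keep, ]
}

#' Read a SIFT score table
#'
#' Reads a TSV of precomputed SIFT deleteriousness scores (header columns
#' `chrom`, `pos`, `ref`, `alt`, `sift`; scores in \[0,1\], lower = more
#' likely damaging). Rows with scores outside \[0,1\] are rejected with a
#' warning.
#'
#' @param path Path to the TSV.
#' @return A tibble keyed on (`chrom`,`pos`,`ref`,`alt`) with column `sift`,
#'   suitable for joining onto candidate tables.
#' @export
read_sift_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          chrom = readr::col_character(),
                          pos = readr::col_double(),
                          ref = readr::col_character(),
                          alt = readr::col_character(),
                          sift = readr::col_double()
                        ))
  bad <- is.na(df$sift) | df$sift < 0 | df$sift > 1
  if (any(bad)) {
    warn(paste0(sum(bad), " SIFT row(s) with score outside [0,1] rejected"))
    df <- df[!bad, ]
  }
  df
}
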