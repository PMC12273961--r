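#' Read pooled variant calls from a VCF file
#'
#' Parses a VCF (v4.x, plain or bgzip) produced by a freebayes-style caller
#' and returns one row per (record, alternate allele) with the
#' reference-observation (`RO`) and alternate-observation (`AO`) read counts
#' the downstream mapping statistics are built on. Multi-allelic records are
#' decomposed: each row carries exactly one alternate allele with its
#' per-allele `AO` and the record's shared `RO`.
#'
#' `RO`/`AO` are taken from the INFO column when present, falling back to the
#' first sample's FORMAT fields (both dialects occur in freebayes-derived
#' pipelines). Records below `min_qual`, records with symbolic alternate
#' alleles (`<DEL>`, breakends) and records lacking both `RO` and `AO` are
#' skipped; skip tallies are attached as the `"skipped"` attribute.
#'
#' @param path Path to a VCF file (`.vcf` or `.vcf.gz`).
#' @param min_qual Minimum QUAL to keep a record; records with missing QUAL
#'   are kept. Default 0.
#' @return A tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `ro`, `ao`, `qual`, in file order, with a `skipped` attribute (named
#'   integer vector: `low_qual`, `symbolic_alt`, `no_counts`).
#' @examples
#' vcf <- tempfile(fileext = ".vcf")
#' writeLines(c(
#'   "##fileformat=VCFv4.2",
#'   "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
#'   "chr1\t100\t.\tC\tA\t50\t.\tRO=0;AO=15",
#'   "chr1\t200\t.\tG\tA,T\t50\t.\tRO=9;AO=4,6"
#' ), vcf)
#' read_variant_calls(vcf)
#' @export
read_variant_calls <- function(path, min_qual = 0) {
  if (!file.exists(path)) {
    abort(paste0("VCF file not found: ", path))
  }
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort(paste0("failed to parse VCF '", path, "': ",
                                     conditionMessage(e)))
  )
  fix <- v@fix
  empty <- tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), ro = integer(), ao = integer(), qual = double()
  )
  if (is.null(fix) || nrow(fix) == 0) {
    attr(empty, "skipped") <- c(low_qual = 0L, symbolic_alt = 0L, no_counts = 0L)
    return(empty)
  }

  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  keep_qual <- is.na(qual) | qual >= min_qual
  n_low_qual <- sum(!keep_qual)

  info <- fix[, "INFO"]
  ro_info <- .info_field(info, "RO")
  ao_info <- .info_field(info, "AO")

  # FORMAT fallback: per-record values from the first sample column
  ro_fmt <- ao_fmt <- rep(NA_character_, nrow(fix))
  if (ncol(v@gt) >= 2) {
    gt <- v@gt
    ro_fmt <- .format_field(gt, "RO")
    ao_fmt <- .format_field(gt, "AO")
  }
  ro_str <- ifelse(is.na(ro_info), ro_fmt, ro_info)
  ao_str <- ifelse(is.na(ao_info), ao_fmt, ao_info)

  if (all(is.na(ro_str)) && all(is.na(ao_str)) && nrow(fix) > 0) {
    abort(paste0(
      "no RO/AO allele observation counts found anywhere in '", path, "'. ",
      "segmapr needs freebayes-style RO/AO fields in INFO or FORMAT; ",
      "re-call variants with a caller that reports allele observation counts."
    ))
  }

  alt_field <- fix[, "ALT"]
  symbolic <- stringr::str_detect(alt_field, "[<\\[\\]]")
  no_counts <- is.na(ro_str) & is.na(ao_str)
  keep <- keep_qual & !symbolic & !no_counts
  n_symbolic <- sum(symbolic & keep_qual)
  n_no_counts <- sum(no_counts & keep_qual & !symbolic)

  if (!any(keep)) {
    attr(empty, "skipped") <- c(
      low_qual = n_low_qual, symbolic_alt = n_symbolic, no_counts = n_no_counts
    )
    return(empty)
  }

  alt_split <- stringr::str_split(alt_field[keep], stringr::fixed(","))
  ao_split <- stringr::str_split(ao_str[keep], stringr::fixed(","))
  n_alt <- lengths(alt_split)

  ao_per_alt <- purrr::map2(ao_split, n_alt, function(a, n) {
    a <- suppressWarnings(as.integer(a))
    if (length(a) == n) a else rep(a[1], n)
  })

  out <- tibble(
    chrom = rep(fix[keep, "CHROM"], n_alt),
    pos = rep(as.integer(fix[keep, "POS"]), n_alt),
    ref = rep(toupper(fix[keep, "REF"]), n_alt),
    alt = toupper(unlist(alt_split)),
    ro = rep(suppressWarnings(as.integer(ro_str[keep])), n_alt),
    ao = unlist(ao_per_alt),
    qual = rep(qual[keep], n_alt)
  )
  out$ro[is.na(out$ro)] <- 0L
  out$ao[is.na(out$ao)] <- 0L
  attr(out, "skipped") <- c(
    low_qual = n_low_qual, symbolic_alt = n_symbolic, no_counts = n_no_counts
  )
  out
}

# extract a single INFO key's raw string value (NA where absent)
.info_field <- function(info, key) {
  m <- stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]+)"))
  m[, 2]
}

# extract a FORMAT field from the first sample column
.format_field <- function(gt, key) {
  fmt_keys <- stringr::str_split(gt[, 1], stringr::fixed(":"))
  sample_vals <- stringr::str_split(gt[, 2], stringr::fixed(":"))
  purrr::map2_chr(fmt_keys, sample_vals, function(k, v) {
    i <- match(key, k)
    if (is.na(i) || i > length(v)) NA_character_ else v[i]
  })
}
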