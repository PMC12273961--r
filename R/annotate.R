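#' Gene-model-based variant consequence annotation
#'
#' Classifies each variant against every overlapping transcript, producing
#' the consequence classes used for candidate filtering: region
#' (`exonic`, `splicing`, `intronic`, `utr5`, `utr3`, `intergenic`) and,
#' for coding exonic variants, effect (`synonymous`, `nonsynonymous`,
#' `stopgain`, `stoploss`, `startloss`, `frameshift`, `nonframeshift`).
#' For substitutions the affected codon is rebuilt from the spliced CDS
#' (reverse-complemented for minus-strand models) and translated with the
#' standard nuclear code. cDNA changes are reported in CDS coordinates with
#' coding-strand bases (`c.C2475A`), protein changes with one-letter codes
#' and `X` for stop (`p.C825X`).
#'
#' A variant within `splice_window` bp of an exon/intron boundary on the
#' intronic side, or spanning a boundary, is classified `splicing` (region
#' only). Two-base substitutions crossing a codon boundary are decomposed
#' per codon and the most severe consequence reported.
#'
#' @param calls Variant-call tibble (`chrom`, `pos`, `ref`, `alt`, ...).
#' @param models Gene-model tibble (see [gene_models()]).
#' @param genome Reference sequence: a named character vector or a
#'   `Biostrings::DNAStringSet` keyed by chromosome.
#' @param splice_window Intronic distance from a boundary that counts as
#'   splicing-relevant (default 2 bp).
#' @return A tibble with one row per (variant, overlapping transcript):
#'   `chrom`, `pos`, `ref`, `alt`, `gene`, `transcript`, `region`,
#'   `effect`, `exon`, `cdna_change`, `protein_change`. Variants
#'   overlapping no transcript get a single `intergenic` row.
#' @export
annotate_variants <- function(calls, models, genome, splice_window = 2) {
  seqs <- .as_seq_list(genome)
  ctx <- purrr::map(seq_len(nrow(models)), ~ .transcript_context(models[.x, ], seqs))
  purrr::map_dfr(seq_len(nrow(calls)), function(i) {
    call <- calls[i, ]
    hits <- which(models$chrom == call$chrom &
                    models$tx_start <= call$pos + nchar(call$ref) - 1 &
                    models$tx_end >= call$pos)
    if (length(hits) == 0) {
      return(tibble(
        chrom = call$chrom, pos = call$pos, ref = call$ref, alt = call$alt,
        gene = NA_character_, transcript = NA_character_,
        region = "intergenic", effect = NA_character_, exon = NA_integer_,
        cdna_change = NA_character_, protein_change = NA_character_
      ))
    }
    purrr::map_dfr(hits, function(h) {
      ann <- .annotate_one(call, ctx[[h]], splice_window)
      tibble(
        chrom = call$chrom, pos = call$pos, ref = call$ref, alt = call$alt,
        gene = models$gene[h], transcript = models$transcript[h],
        region = ann$region, effect = ann$effect, exon = ann$exon,
        cdna_change = ann$cdna_change, protein_change = ann$protein_change
      )
    })
  })
}

.as_seq_list <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    setNames(as.character(genome), names(genome))
  } else if (is.character(genome)) {
    toupper(genome)
  } else {
    abort("genome must be a named character vector or a DNAStringSet")
  }
}

# Precompute per-transcript structures used by every annotation:
# exon spans, CDS-intersected exon spans, spliced CDS sequence (coding
# strand), and cumulative CDS offsets in transcription order.
.transcript_context <- function(model, seqs) {
  es <- model$exon_starts[[1]]
  ee <- model$exon_ends[[1]]
  strand <- model$strand
  coding <- !is.na(model$cds_start)
  ctx <- list(
    strand = strand, chrom = model$chrom,
    exon_starts = es, exon_ends = ee, n_exons = length(es),
    cds_start = model$cds_start, cds_end = model$cds_end,
    coding = coding, cds_seq = NULL, cds_exons = NULL
  )
  if (!coding) return(ctx)
  keep <- ee >= model$cds_start & es <= model$cds_end
  ce_s <- pmax(es[keep], model$cds_start)
  ce_e <- pmin(ee[keep], model$cds_end)
  seq_chr <- seqs[[model$chrom]]
  if (is.null(seq_chr)) {
    ctx$coding <- FALSE
    warn(paste0("no reference sequence for ", model$chrom,
                "; coding effects unavailable for this transcript"))
    return(ctx)
  }
  pieces <- substring(seq_chr, ce_s, ce_e)
  cds_plus <- paste(pieces, collapse = "")
  ctx$cds_exons <- list(starts = ce_s, ends = ce_e)
  ctx$cds_seq <- if (strand == "-") .revcomp(cds_plus) else cds_plus
  ctx
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.comp_base <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

# CDS coordinate (1-based, transcription order) of a genomic position,
# or NA when the position is outside the CDS
.cds_position <- function(ctx, gpos) {
  ce <- ctx$cds_exons
  hit <- which(ce$starts <= gpos & ce$ends >= gpos)
  if (length(hit) == 0) return(NA_integer_)
  plus_off <- sum(ce$ends[seq_len(hit - 1)] - ce$starts[seq_len(hit - 1)] + 1) +
    (gpos - ce$starts[hit] + 1)
  if (ctx$strand == "-") {
    nchar(ctx$cds_seq) - plus_off + 1L
  } else {
    as.integer(plus_off)
  }
}

.translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

.annotate_one <- function(call, ctx, splice_window) {
  pos <- call$pos
  ref <- call$ref
  alt <- call$alt
  span_end <- pos + nchar(ref) - 1
  es <- ctx$exon_starts
  ee <- ctx$exon_ends

  res <- list(region = NA_character_, effect = NA_character_,
              exon = NA_integer_, cdna_change = NA_character_,
              protein_change = NA_character_)

  exon_hit <- which(es <= pos & ee >= pos)
  in_exon <- length(exon_hit) > 0
  # crossing an exon/intron boundary
  crosses <- in_exon && span_end > ee[exon_hit]
  if (crosses) {
    res$region <- "splicing"
    res$exon <- .exon_number(ctx, exon_hit)
    return(res)
  }

  if (!in_exon) {
    # intronic: splicing if within splice_window of a boundary
    prev_end <- max(ee[ee < pos], -Inf)
    next_start <- min(es[es > pos], Inf)
    near <- min(pos - prev_end, next_start - span_end)
    if (near <= splice_window) {
      res$region <- "splicing"
      # exon number of the nearer exon
      if (pos - prev_end <= next_start - span_end) {
        res$exon <- .exon_number(ctx, which(ee == prev_end)[1])
      } else {
        res$exon <- .exon_number(ctx, which(es == next_start)[1])
      }
    } else {
      res$region <- "intronic"
    }
    return(res)
  }

  res$exon <- .exon_number(ctx, exon_hit)
  if (!ctx$coding) {
    res$region <- "exonic"
    res$effect <- "unknown"
    return(res)
  }
  if (span_end < ctx$cds_start || pos > ctx$cds_end) {
    upstream <- span_end < ctx$cds_start
    res$region <- if (xor(upstream, ctx$strand == "-")) "utr5" else "utr3"
    return(res)
  }

  res$region <- "exonic"
  if (nchar(ref) != nchar(alt)) {
    # indel in CDS
    diff <- abs(nchar(ref) - nchar(alt))
    res$effect <- if (diff %% 3 == 0) "nonframeshift" else "frameshift"
    cpos <- .cds_position(ctx, max(pos, ctx$cds_start))
    if (!is.na(cpos)) {
      kind <- if (nchar(ref) > nchar(alt)) "del" else "ins"
      res$cdna_change <- paste0("c.", cpos, kind, diff)
    }
    return(res)
  }

  # substitution of 1-2 bp: evaluate per affected base, grouped by codon
  offs <- seq_len(nchar(ref)) - 1
  base_info <- purrr::compact(purrr::map(offs, function(o) {
    gp <- pos + o
    if (gp < ctx$cds_start || gp > ctx$cds_end) return(NULL)
    cp <- .cds_position(ctx, gp)
    if (is.na(cp)) return(NULL) # intronic base of an MNV
    rb <- substr(ref, o + 1, o + 1)
    ab <- substr(alt, o + 1, o + 1)
    if (ctx$strand == "-") {
      rb <- .comp_base(rb)
      ab <- .comp_base(ab)
    }
    list(cds_pos = cp, ref_base = rb, alt_base = ab)
  }))
  if (length(base_info) == 0) {
    res$region <- if (pos < ctx$cds_start) {
      if (ctx$strand == "-") "utr3" else "utr5"
    } else {
      if (ctx$strand == "-") "utr5" else "utr3"
    }
    return(res)
  }

  cds <- ctx$cds_seq
  # reference check against the spliced CDS
  for (b in base_info) {
    if (substr(cds, b$cds_pos, b$cds_pos) != b$ref_base) {
      warn(paste0("reference allele mismatch at ", call$chrom, ":", pos,
                  " (expected ", substr(cds, b$cds_pos, b$cds_pos),
                  " on the coding strand); annotation attempted anyway"))
    }
  }

  codon_idx <- unique(ceiling(purrr::map_dbl(base_info, "cds_pos") / 3))
  per_codon <- purrr::map(codon_idx, function(ci) {
    start <- (ci - 1) * 3 + 1
    ref_codon <- substr(cds, start, start + 2)
    alt_codon <- ref_codon
    involved <- purrr::keep(base_info, ~ ceiling(.x$cds_pos / 3) == ci)
    for (b in involved) {
      off <- b$cds_pos - start + 1
      substr(alt_codon, off, off) <- b$alt_base
    }
    ref_aa <- .translate_codon(ref_codon)
    alt_aa <- .translate_codon(alt_codon)
    effect <- if (ci == 1 && ref_codon == "ATG" && alt_codon != "ATG") {
      "startloss"
    } else if (!is.na(ref_aa) && ref_aa == "*" && !is.na(alt_aa) && alt_aa != "*") {
      "stoploss"
    } else if (!is.na(alt_aa) && alt_aa == "*" && (is.na(ref_aa) || ref_aa != "*")) {
      "stopgain"
    } else if (!is.na(ref_aa) && !is.na(alt_aa) && ref_aa == alt_aa) {
      "synonymous"
    } else {
      "nonsynonymous"
    }
    cds_pos_first <- min(purrr::map_dbl(involved, "cds_pos"))
    refs <- paste(purrr::map_chr(involved, "ref_base"), collapse = "")
    alts <- paste(purrr::map_chr(involved, "alt_base"), collapse = "")
    list(
      effect = effect,
      cdna = paste0("c.", refs, cds_pos_first, alts),
      prot = paste0("p.",
                    if (is.na(ref_aa)) "?" else sub("\\*", "X", ref_aa),
                    ci,
                    if (is.na(alt_aa)) "?" else sub("\\*", "X", alt_aa))
    )
  })
  sev <- purrr::map_dbl(per_codon, ~ severity_rank(.x$effect))
  best <- per_codon[[which.max(sev)]]
  res$effect <- best$effect
  res$cdna_change <- best$cdna
  res$protein_change <- best$prot
  res
}

# exon number in transcription order (1-based)
.exon_number <- function(ctx, genomic_idx) {
  if (ctx$strand == "-") ctx$n_exons - genomic_idx + 1L else as.integer(genomic_idx)
}

#' Severity ranking of consequence classes
#'
#' Total order used to pick the most severe class when a variant is
#' annotated against several transcripts (or an MNV spans two codons):
#' stopgain > startloss > stoploss > splicing > nonsynonymous >
#' frameshift > nonframeshift > synonymous > unknown > UTR/intronic/intergenic.
#'
#' @param class Character vector of effect or region labels.
#' @return Integer ranks (higher = more severe). Unknown labels error.
#' @export
severity_rank <- function(class) {
  ranks <- c(
    stopgain = 100L, startloss = 90L, stoploss = 80L, splicing = 70L,
    nonsynonymous = 60L, frameshift = 50L, nonframeshift = 40L,
    synonymous = 30L, unknown = 20L, exonic = 15L, utr5 = 10L, utr3 = 10L,
    intronic = 5L, intergenic = 1L
  )
  out <- ranks[class]
  if (anyNA(out)) {
    abort(paste0("unknown consequence class: ",
                 paste(unique(class[is.na(out)]), collapse = ", ")))
  }
  unname(out)
}
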