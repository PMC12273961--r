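#' Run the full mapping pipeline
#'
#' Single-command orchestration: reads both pool VCFs and the genome
#' index, computes the windowed heterozygosity tracks and SNP index,
#' smooths, selects the zero-bounded interval, filters candidates
#' (annotated when gene models and a reference FASTA are supplied),
#' extracts indel markers, and writes all outputs plus a run log to
#' `out_dir`.
#'
#' @param mut_vcf,wt_vcf Paths to the mutant and wild-type pool VCFs.
#' @param fai Path to the genome `.fai` index.
#' @param out_dir Output directory (created if needed).
#' @param gene_models_path Optional gene models (refFlat TSV or GFF3).
#' @param gene_models_dialect `"refflat"` (default) or `"gff3"`.
#' @param fasta Optional reference FASTA (required for consequence
#'   annotation).
#' @param sift_path Optional SIFT TSV.
#' @param cfg An [index_config()].
#' @param thr A [segregation_thresholds()].
#' @param min_qual Minimum VCF QUAL (default 0).
#' @param min_marker_len Minimum indel marker length difference
#'   (default 4).
#' @return Invisibly, a list: `index_track`, `interval`, `candidates`
#'   (list of `unfiltered`/`filtered`), `markers`, `paths`.
#' @export
run_map <- function(mut_vcf, wt_vcf, fai, out_dir,
                    gene_models_path = NULL,
                    gene_models_dialect = "refflat",
                    fasta = NULL, sift_path = NULL,
                    cfg = index_config(),
                    thr = segregation_thresholds(),
                    min_qual = 0, min_marker_len = 4) {
  for (p in c(mut_vcf, wt_vcf, fai, gene_models_path, fasta, sift_path)) {
    if (!is.null(p) && !file.exists(p)) abort(paste0("input file not found: ", p))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(paste0("segmapr map run ", format(Sys.time())))
  log <- function(...) {
    msg <- paste0(...)
    inform(msg)
    log_lines <<- c(log_lines, msg)
  }

  genome <- read_genome_index(fai)
  mut_calls <- read_variant_calls(mut_vcf, min_qual)
  wt_calls <- read_variant_calls(wt_vcf, min_qual)
  log("mutant pool: ", nrow(mut_calls), " calls (skipped: ",
      paste(names(attr(mut_calls, "skipped")), attr(mut_calls, "skipped"),
            sep = "=", collapse = ", "), ")")
  log("wild-type pool: ", nrow(wt_calls), " calls (skipped: ",
      paste(names(attr(wt_calls, "skipped")), attr(wt_calls, "skipped"),
            sep = "=", collapse = ", "), ")")

  het_mut <- window_heterozygosity(mut_calls, genome, cfg)
  het_wt <- window_heterozygosity(wt_calls, genome, cfg)
  log("windows: ", nrow(het_wt), " across ",
      length(unique(het_wt$chrom)), " chromosome(s)")
  track <- snp_index(het_wt, het_mut) %>% moving_average(cfg)
  interval <- select_interval(track, genome)
  log("interval: ", interval$chrom, ":",
      format(interval$left, scientific = FALSE), "-",
      format(interval$right, scientific = FALSE),
      " (peak MA ", sprintf("%.4f", interval$peak), " at ",
      format(interval$argmax, scientific = FALSE), ")")

  annotations <- NULL
  if (!is.null(gene_models_path) && !is.null(fasta)) {
    models <- read_gene_models(gene_models_path, gene_models_dialect)
    genome_seq <- Biostrings::readDNAStringSet(fasta)
    names(genome_seq) <- sub("\\s.*$", "", names(genome_seq))
    inside <- mut_calls$chrom == interval$chrom &
      mut_calls$pos >= interval$left & mut_calls$pos <= interval$right
    annotations <- annotate_variants(mut_calls[inside, ], models, genome_seq)
    log("annotated ", sum(inside), " interval variants against ",
        nrow(models), " transcripts")
  }
  sift <- if (!is.null(sift_path)) read_sift_table(sift_path) else NULL

  cands <- filter_candidates(mut_calls, wt_calls, interval,
                             annotations = annotations, sift = sift,
                             thr = thr)
  tally <- class_tally(cands$filtered)
  log("candidates: ", nrow(cands$unfiltered), " unfiltered, ",
      nrow(cands$filtered), " filtered (",
      paste(names(tally), unlist(tally), sep = "=", collapse = ", "), ")")

  markers <- extract_indel_markers(mut_calls, wt_calls, interval, thr,
                                   min_len_diff = min_marker_len)
  log("indel markers: ", nrow(markers))

  paths <- list(
    snp_index = file.path(out_dir, "snp_index.bedgraph"),
    snp_index_ma = file.path(out_dir, "snp_index_ma.bedgraph"),
    interval = file.path(out_dir, "interval.bed"),
    unfiltered = file.path(out_dir, "candidates.unfiltered.tsv"),
    filtered = file.path(out_dir, "candidates.filtered.tsv"),
    markers = file.path(out_dir, "markers.tsv"),
    log = file.path(out_dir, "run.log")
  )
  write_track_bedgraph(track, paths$snp_index, value = "snp_index")
  write_track_bedgraph(track, paths$snp_index_ma, value = "ma")
  write_interval_bed(interval, paths$interval)
  write_candidates_tsv(cands$unfiltered, paths$unfiltered)
  write_candidates_tsv(cands$filtered, paths$filtered)
  write_markers_tsv(markers, paths$markers)
  writeLines(log_lines, paths$log)

  invisible(list(index_track = track, interval = interval,
                 candidates = cands, markers = markers, paths = paths))
}

#' Refine an interval from a marker genotype table file
#'
#' @param interval_bed Path to a BED file with the mapped interval
#'   (first line used; 0-based half-open, converted on read).
#' @param genotypes_path Path to a wide genotype TSV
#'   (see [read_genotype_table()]).
#' @param out_dir Output directory.
#' @param sp A [species_params()].
#' @param infer_missing Fill inferable unknown genotypes first
#'   (default FALSE).
#' @return Invisibly, a list: `refinement` (from [refine_interval()]),
#'   `estimates` (per-marker Rf/distance tibble), `locus` (position
#'   estimate), `paths`.
#' @export
run_refine <- function(interval_bed, genotypes_path, out_dir,
                       sp = species_params(), infer_missing = FALSE) {
  bed <- readr::read_tsv(interval_bed, col_names = FALSE,
                         show_col_types = FALSE)
  interval <- tibble(chrom = bed[[1]][1], left = bed[[2]][1] + 1,
                     right = bed[[3]][1])
  table <- read_genotype_table(genotypes_path)
  if (infer_missing) table <- infer_missing_genotypes(table)
  est <- recombination_frequency(table) %>% distance_estimate(sp)
  refinement <- refine_interval(interval, table)
  locus <- locus_position_estimate(est, refinement$interval)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    refined = file.path(out_dir, "interval.refined.bed"),
    estimates = file.path(out_dir, "marker_estimates.tsv")
  )
  write_interval_bed(refinement$interval, paths$refined, "refined_interval")
  readr::write_tsv(est, paths$estimates)
  invisible(list(refinement = refinement, estimates = est,
                 locus = locus, paths = paths))
}

#' Annotate a VCF against gene models
#'
#' @param vcf,fasta,gene_models_path Input paths.
#' @param out_dir Output directory.
#' @param gene_models_dialect `"refflat"` or `"gff3"`.
#' @param min_qual Minimum VCF QUAL.
#' @return Invisibly, a list with the annotation tibble and output path.
#'   The TSV adds a `notation` column in the combined
#'   `exonNN: c.<change>: p.<change>` form.
#' @export
run_annotate <- function(vcf, fasta, gene_models_path, out_dir,
                         gene_models_dialect = "refflat", min_qual = 0) {
  calls <- read_variant_calls(vcf, min_qual)
  models <- read_gene_models(gene_models_path, gene_models_dialect)
  genome_seq <- Biostrings::readDNAStringSet(fasta)
  names(genome_seq) <- sub("\\s.*$", "", names(genome_seq))
  ann <- annotate_variants(calls, models, genome_seq)
  ann$notation <- format_annotation(ann)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(out_dir, "annotations.tsv")
  readr::write_tsv(ann, path, na = "")
  invisible(list(annotations = ann, path = path))
}

#' Combined exon/cDNA/protein notation
#'
#' Formats annotations in the conventional
#' `exonNN: c.<ref><pos><alt>: p.<aa><pos><aa>` form used in candidate
#' reports (e.g. `exon17: c.C2475A: p.C825X`). NA where the variant has no
#' coding consequence.
#'
#' @param ann Annotation tibble from [annotate_variants()].
#' @return Character vector.
#' @export
format_annotation <- function(ann) {
  ifelse(
    !is.na(ann$exon) & !is.na(ann$cdna_change) & !is.na(ann$protein_change),
    paste0("exon", ann$exon, ": ", ann$cdna_change, ": ", ann$protein_change),
    NA_character_
  )
}

#' Simulate a cross and write its pooled VCFs
#'
#' @param out_dir Output directory.
#' @param cfg A [sim_config()].
#' @param seed Integer seed (drives both the cross and read sampling).
#' @param write_reference Also write a random reference FASTA.
#' @return Invisibly, the list of written paths.
#' @export
run_simulate <- function(out_dir, cfg = sim_config(), seed = 1,
                         write_reference = FALSE) {
  sim <- simulate_cross(cfg, seed = seed)
  reads <- simulate_reads(sim, seed = seed + 1)
  paths <- write_simulation(sim, reads, out_dir,
                            write_reference = write_reference, seed = seed)
  invisible(paths)
}

#' Homozygous-point density mapping
#'
#' Runs the comparator method: extracts mutant-homozygous points
#' (optionally sibling-heterozygous) and writes the points plus their
#' per-bin genome-wide density.
#'
#' @param mut_vcf Path to the mutant pool VCF.
#' @param fai Path to the genome `.fai`.
#' @param out_dir Output directory.
#' @param wt_vcf Optional wild-type pool VCF; when given, points are
#'   restricted to sibling-heterozygous sites.
#' @param hom_threshold Alternate-fraction threshold (default 0.9).
#' @param binwidth Density bin width in bp (default 1e6).
#' @param min_qual Minimum VCF QUAL.
#' @return Invisibly, a list: `points`, `density`, `paths`.
#' @export
run_bsa_density <- function(mut_vcf, fai, out_dir, wt_vcf = NULL,
                            hom_threshold = 0.9, binwidth = 1e6,
                            min_qual = 0) {
  genome <- read_genome_index(fai)
  mut_calls <- read_variant_calls(mut_vcf, min_qual)
  wt_calls <- if (!is.null(wt_vcf)) read_variant_calls(wt_vcf, min_qual)
  points <- extract_homozygous_points(
    mut_calls, wt_calls,
    hom_threshold = hom_threshold,
    require_wt_het = !is.null(wt_calls)
  )
  density <- point_density(points, genome, binwidth)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    points = file.path(out_dir, "homozygous_points.tsv"),
    density = file.path(out_dir, "homozygous_density.bedgraph")
  )
  readr::write_tsv(points, paths$points)
  write_track_bedgraph(density, paths$density, value = "count")
  invisible(list(points = points, density = density, paths = paths))
}
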