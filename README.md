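# segmapr

Mapping-by-sequencing of pooled segregants for forward genetic screens.

## The problem

A recessive mutant recovered from a chemical mutagenesis screen (ENU in
zebrafish, EMS in plants) has to be mapped before the causative gene can be
named. Bulked segregant analysis (BSA) does this without building a mapping
panel: phenotypically mutant and wild-type siblings from a segregating
incross are pooled, each pool is whole-genome sequenced, and the genome is
scanned for the region where the mutant pool has lost heterozygosity — the
homozygous block inherited around the causative allele.

segmapr takes the two pooled VCFs (freebayes/POLCA-style records carrying
reference-observation `RO` and alternate-observation `AO` read counts) and
carries the analysis from raw variant calls to a short candidate list:

1. **Homozygosity mapping.** Heterozygous points (sites with both alleles
   read-supported at a balanced ratio) are counted in sliding windows
   (default 10 kb) for both pools, giving `Het_wt(C)` and `Het_mut(C)` at
   window centers `C`. The SNP index

   ```
   SNP_index(C) = (Het_wt(C) - Het_mut(C)) / (2 + Het_mut(C))
   ```

   is large and positive where the mutant pool is depleted of
   heterozygosity. A 750 kb moving-average filter (1 cM in zebrafish)
   smooths the index, and the candidate interval is taken around the
   genome-wide maximum, bounded on each side where the smoothed index
   first returns to zero.

2. **Candidate filtering.** Variants inside the interval are kept when
   they are near-fixed in the mutant pool (`RO < 2`, `AO >= 2`),
   heterozygous or absent in the sibling pool (`1 < RO/AO < 4`),
   mutagen-like (1–2 bp substitutions), and — when gene models and a
   reference FASTA are supplied — coding-relevant (nonsynonymous,
   stop-gain/loss, start-loss, splicing), with optional SIFT scores
   attached.

3. **Recombinant mapping.** Segregating indels inside the interval are
   emitted as PCR-genotypable markers. Genotyping individual mutants at
   these markers yields recombination frequencies (`Rf = recombinants /
   genotyped`), physical distance estimates (`Rf x 100 x 0.74` Mb in
   zebrafish), and a refined interval that excludes everything beyond the
   innermost recombinant markers.

A synthetic incross simulator (`simulate_cross()`) with Haldane-model
crossovers and Poisson/binomial read sampling provides ground-truth data
at desk scale, so the entire pipeline is testable without real WGS.

## Worked example

Simulate a cross (two 25 Mb chromosomes, causative substitution planted at
chr1:12,000,000, 3 clutches x 10 animals per pool, 30X coverage), then map
it:

```r
library(segmapr)

sim     <- simulate_cross(sim_config(), seed = 42)
reads   <- simulate_reads(sim, seed = 43)
genome  <- genome_index(sim$cfg$chrom_lengths)
cfg     <- index_config()

het_mut <- window_heterozygosity(reads$mut_calls, genome, cfg)
het_wt  <- window_heterozygosity(reads$wt_calls,  genome, cfg)
track   <- snp_index(het_wt, het_mut) |> moving_average(cfg)

interval <- select_interval(track, genome)
tidy(interval)
#> # A tibble: 1 × 6
#>   chrom  left    right   argmax  peak size_mb
#>   <chr> <dbl>    <dbl>    <dbl> <dbl>   <dbl>
#> 1 chr1      1 25000000 12085000 0.270    25.0
```

The smoothed index peaks at 12,085,000 — 85 kb from the planted locus —
and stays positive across the linked chromosome, so the zero-bounded
interval covers chr1. Filtering the interval and extracting markers:

```r
candidates <- filter_candidates(reads$mut_calls, reads$wt_calls, interval)
markers    <- extract_indel_markers(reads$mut_calls, reads$wt_calls, interval)
nrow(candidates$filtered)   #> 125
nrow(markers)               #> 16
sim$truth
#> # A tibble: 1 × 6
#>   chrom      pos ref   alt   frac_mut frac_wt
#>   <chr>    <dbl> <chr> <chr>    <dbl>   <dbl>
#> 1 chr1  12000000 G     A            1    0.35
```

The planted variant (fixed in the mutant pool, ~1/3 in the siblings) is
one of the 125 filtered candidates. Marker genotypes of the pooled mutant
animals give recombination-based distance estimates that can refine the
interval further:

```r
est <- recombination_frequency(sim$genotypes) |> distance_estimate()
```

`plot_snp_index(track, interval, locus = sim$truth)` draws the standard
index-vs-position figure with interval bounds and the true locus.

The same steps run from the shell via `exec/segmap`
(`segmap simulate`, `segmap map`, `segmap refine`, `segmap annotate`,
`segmap bsa-density`), and `run_map()` performs steps 1–3 as a single call
writing bedGraph tracks, a BED interval, candidate TSVs, a marker TSV and
a run log.

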