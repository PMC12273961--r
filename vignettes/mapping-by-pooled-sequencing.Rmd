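---
title: "Mapping causative mutations from pooled segregant sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping causative mutations from pooled segregant sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segmapr)
library(dplyr)
```

# The model

A recessive mutant from a phenotype-driven screen segregates in an
F2-style incross: both parents carry the causative allele on a haplotype
that is identical by descent through the carrier lineage. Offspring
selected for the mutant phenotype are homozygous for that haplotype at the
causative locus, and — because recombination is rare over short genetic
distances — homozygous for the surrounding linked block. Their wild-type
siblings are not. Pooling each phenotype class and sequencing the pools
turns this into a coverage-weighted genome scan: within the linked block
the mutant pool loses heterozygosity while the sibling pool keeps it.

## The SNP-index statistic

For each pool, a site is counted as a *heterozygous point* when both
alleles are supported by at least `het_min_each` reads (default 2) and the
reference/alternate ratio `RO/AO` lies in `[0.25, 4]` (inclusive). These
are counted in windows of `window_width` (default 10 kb) tiled along each
chromosome, giving `Het_wt(C)` and `Het_mut(C)` at window centers `C`. The
statistic

$$\mathrm{SNPindex}(C) = \frac{Het_{wt}(C) - Het_{mut}(C)}{2 + Het_{mut}(C)}$$

is near zero where both pools are equally heterozygous, and large and
positive inside the mutant-homozygous block. The `+2` offset keeps the
value finite in empty windows and bounds it in $(-1,\ Het_{wt}/2]$. Unlike
allele-frequency statistics, this count-based index depends only weakly on
local sequencing depth, which is what makes it robust near centromeres and
in repetitive regions.

A centered moving average of width `ma_width` (default 750 kb, about 1 cM
in zebrafish) smooths the raw index. The candidate interval is placed
around the genome-wide maximum of the smoothed index and extends on each
side to the first window center where the smoothed index drops to zero or
below; the bound is the midpoint between that center and its
interval-side neighbour, or the chromosome end when no zero crossing
exists.

## Candidate filtering

Variants inside the interval are reported unfiltered, and filtered by
three orthogonal criteria:

* *segregation*: near-fixed in the mutant pool (`RO < 2`, `AO >= 2`) and,
  in the sibling pool, either heterozygous (`1 < RO/AO < 4`, strict) or
  not reported at all. A pooled sibling sample is expected to be 1/3
  `+/+` and 2/3 `+/-`, i.e. alternate fraction 1/3 and `RO/AO` about 2,
  comfortably inside the open interval;
* *mutagen likeness*: length-preserving substitutions of at most 2 bp,
  the signature of ENU/EMS point mutagenesis;
* *consequence*: when gene models and a reference sequence are available,
  only nonsynonymous, stop-gain, stop-loss, start-loss and splicing
  variants are reported. A variant hitting several transcripts is counted
  once under its most severe class (stopgain > startloss > stoploss >
  splicing > nonsynonymous > frameshift > nonframeshift > synonymous),
  with all transcript-level calls retained in an auxiliary column.

Consequence annotation rebuilds the affected codon from the spliced CDS
(reverse-complemented for minus-strand models) and translates it with the
standard nuclear code. Splice-relevant means within 2 bp of an exon/intron
boundary on the intronic side (the conventional window), configurable.
Two-base substitutions crossing a codon boundary are decomposed per codon
and the most severe consequence reported. No HGVS right-shifting or UTR
sub-classification is attempted.

## Recombinant mapping

Insertion/deletion variants inside the interval that pass the same
segregation test are emitted as PCR markers; the default minimum ref/alt
length difference of 4 bp keeps the product-size shift resolvable on an
agarose gel (configurable down to 1 bp for capillary or sequencing-based
genotyping). Genotyping individual mutant animals at these markers yields,
per marker, the recombination frequency `Rf = recombinants / genotyped`
and a physical distance estimate `Rf x 100 cM x mb_per_cM` (0.74 Mb/cM in
zebrafish). No Haldane/Kosambi map-function correction is applied: at
within-interval distances the correction is negligible and raw `Rf`
matches how such distances are conventionally reported.

Interval refinement treats each animal's genotypes, ordered by marker
position, as crossover evidence. A run of heterozygous markers anchored at
the left end of the order places the locus to the right of the innermost
such marker, so `[interval_left, marker]` is excluded (inclusively at the
marker's own position — the segment between a heterozygous marker and its
homozygous neighbour is conservatively retained); right-anchored runs are
handled symmetrically. A heterozygous marker strictly between homozygous
markers would require a double crossover; such animals are flagged and
excluded from refinement rather than erroring, since real gel genotypes
mis-call. An animal heterozygous at *every* genotyped marker is
side-ambiguous — one crossover outside the marker span on either side
explains it — and is assigned to whichever side is consistent with the
interval refined from the unambiguous animals, or flagged when neither or
both are. Unknown genotypes can optionally be imputed when both nearest
known flanking markers agree (`infer_missing_genotypes()`), mirroring how
failed gel lanes are scored in practice.

The per-marker distances combine into a locus point estimate: each marker
proposes `position ± distance`, the candidate inside (or nearest) the
refined interval is kept, and the mean ± sample standard deviation over
markers is reported. The screen-design helpers compute the probability
that `n` blind incrosses of an F2 family pair two carriers,
$1 - (1 - f^2)^n$ with carrier fraction $f = 1/2$, and its sum over
families (expected genomes screened).

# The simulator and what it does (and does not) emulate

`simulate_cross()` generates the statistical structure the mapping
assumes, with known ground truth:

* **Founders.** Candidate polymorphic sites are laid down per chromosome
  as a uniform random set at twice the nominal density; each founder
  haplotype draws the alternate allele with probability 1/2, so each
  parent is heterozygous at the nominal density in expectation (default
  300 SNPs/Mb and 50 indels/Mb, a polymorphism level typical of
  laboratory zebrafish strains). Both parents of a clutch share one
  *mutagenized* founder haplotype — identical by descent through the
  carrier lineage — carrying the causative substitution.
* **Meiosis.** Gametes are founder-haplotype mosaics generated by a
  Markov walk along each chromosome with switch probability between loci
  $d$ Mb apart of $r = \tfrac12(1 - e^{-2d/(100\,\cdot\,mb\_per\_cM)})$ —
  the Haldane map function, i.e. crossovers without interference. This is
  the standard minimal recombination model; organisms with strong
  interference will show somewhat sharper linkage decay than simulated.
* **Pools.** Clutches are independent parent pairs (default 3) whose
  founder alleles are drawn independently, reproducing the observation
  that multi-clutch bulks carry more background heterogeneity. Mutant
  animals are conditioned homozygous at the causative locus; siblings are
  drawn uniformly from the three non-mutant locus genotypes. Pool allele
  fractions are exact means over the pooled chromosomes.
* **Reads.** Per site and pool, depth is Poisson(`coverage`) and
  alternate reads Binomial(depth, fraction); sites with zero alternate
  reads are omitted from that pool's VCF, as a variant caller would omit
  them. This exercises the "not observed in the sibling pool" filter
  branch. There is no sequencing-error model, no mapping artefacts, no
  phenotype mis-sorting, and no incidental induced mutations — so passing
  recovery tests demonstrates the statistical machinery, not robustness
  to real-data artefacts.

Default study conditions are a 2 x 25 Mb genome, 30 animals per phenotype
pool in 3 clutches, and 30X mean coverage. At this scale the linked block
spans much of the 25 Mb causative chromosome (25 Mb is only ~34 cM at
0.74 Mb/cM), so the zero-bounded interval frequently covers the whole
chromosome — proportionally similar to the 10–50 Mb intervals seen on
real ~60 Mb chromosomes. These sizes keep a full 20-replicate,
three-coverage recovery study in the low minutes on one CPU; they are the
package's chosen desk-scale conditions, not estimates of any particular
real dataset.

```{r recovery, eval = FALSE}
sim   <- simulate_cross(sim_config(), seed = 42)
reads <- simulate_reads(sim, seed = 43)
g     <- genome_index(sim$cfg$chrom_lengths)
cfg   <- index_config()
track <- snp_index(
  window_heterozygosity(reads$wt_calls, g, cfg),
  window_heterozygosity(reads$mut_calls, g, cfg)
) |> moving_average(cfg)
interval <- select_interval(track, g)
plot_snp_index(track, interval, locus = sim$truth)
```

# Numerical and design choices

* **Window geometry.** Windows tile by default (`step = width`): the
  description "sliding" is ambiguous, tiling makes the heterozygosity
  counts a partition of the calls, and the moving-average filter does the
  smoothing; overlapping windows (`step < width`) are supported. Window
  `k` spans `[(k-1)·step + 1, (k-1)·step + width]` (1-based inclusive)
  with center `(k-1)·step + width/2`; a chromosome of length `L` has
  `floor((L - width)/step) + 1` windows.
* **Moving-average edges** use a truncated mean (no zero padding), so
  chromosome ends are not dragged artificially toward zero.
* **Interval bounds** are placed at the midpoint between the last
  positive and first non-positive window centers: symmetric, and exactly
  testable. Ties at the global maximum break deterministically by
  chromosome name then coordinate.
* **Heterozygous-point definition.** The ratio window `[0.25, 4]` with a
  2-read-per-allele floor mirrors the sibling-pool segregation bounds; it
  is a package convention (configurable) since "heterozygous point" has
  no universal read-level definition.
* **Pool matching** between the mutant and sibling VCFs is exact on
  (chrom, pos, ref, alt); no left-alignment or normalization is
  attempted, because both VCFs are expected to come from one caller run
  against one reference. "Not observed in the sibling pool" means no
  record at that key, with no depth guard — a low-coverage sibling site
  can therefore pass the filter spuriously; users mapping shallow data
  should treat absent-in-sibling candidates with more suspicion.
* **Multi-allelic records** are decomposed into one call per alternate
  allele (per-allele `AO`, shared `RO`); symbolic alleles (`<DEL>`,
  breakends) are skipped and counted. `RO`/`AO` are read from INFO first,
  then from the first sample's FORMAT fields.
* **Chromosome filter.** Sequences shorter than 1 Mb (configurable) are
  excluded from windowing so unplaced scaffolds do not generate spurious
  peaks.
* **Coordinates.** Everything internal is 1-based inclusive (VCF
  convention); bedGraph/BED outputs are 0-based half-open.
* **Degenerate inputs.** An all-non-positive smoothed index is a hard
  error ("no positive signal") rather than an arbitrary interval; a
  refinement that excludes the entire interval errors listing the
  incompatible animals; gene models failing structural validation (exon
  count mismatches, inverted spans, CDS length not a multiple of 3) are
  skipped with warnings rather than annotated wrongly.

# Known limitations

* The interval is the single global maximum; secondary peaks (e.g. two
  linked modifiers) are not reported.
* Consequence annotation covers the reported classes only — no UTR
  sub-classes, no canonical-transcript selection, no protein-level
  prediction beyond the codon table; SIFT scores are consumed, never
  computed.
* Marker extraction applies no sequence-complexity filter, so some
  emitted markers will sit in regions where unique primers cannot be
  designed; ±500 bp context coordinates are emitted for external primer
  design.
* Genetic distance uses a single genome-wide Mb/cM scale; local
  recombination-rate maps, where available, would sharpen both the
  moving-average width and the distance estimates.
* The simulator's idealisations listed above mean simulated recovery
  rates are upper bounds on real-data performance.
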