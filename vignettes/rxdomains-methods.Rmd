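---
title: "Quantitative comparison of histone-mark domains with spike-in normalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative comparison of histone-mark domains with spike-in normalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxdomains)
```

## The problem

Diffuse midline gliomas carrying the H3K27M oncohistone show a drastic
redistribution of the Polycomb-deposited marks H3K27me3 and H3K27me2.
H3K27M inhibits PRC2, and the residual H3K27me3 is confined to sharp peaks
at large unmethylated CpG islands — the high-affinity PRC2 nucleation sites
— instead of the broad domains that spread from those sites in cells with
wild-type H3. H3K27me2, in turn, spreads outward and comes to occupy the
territory that H3K27me3 covers in the wild-type state.

Detecting and quantifying this redistribution is impossible with ordinary
ChIP-seq, because per-library read counts are relative: a genome-wide loss
of a mark renormalizes away. `rxdomains` implements the quantitative
framework needed to see it: exogenous spike-in (ChIP-Rx) normalization,
focality statistics, difference-plot categorization of CpG islands and
promoters, spread-correlation windows, aggregate profiles and clustered
signal matrices, a partially-methylated-domain (PMD) caller for WGBS data,
and decile/category summaries of differential expression — together with a
fully deterministic synthetic-data generator that emulates both regimes
with known ground truth.

## ChIP-Rx normalization

Spike-in chromatin from a foreign genome is added to each ChIP in fixed
proportion to target chromatin. For a ChIP sample with target-genome
mapped-read fraction $s$ and spike-in fraction $s_{spike}$, and an input
with fractions $i$, $i_{spike}$, the ChIP-Rx ratio is

$$Rx = \frac{s / s_{spike}}{i / i_{spike}}.$$

Because the spike-in amount per cell is constant, $Rx$ is proportional to
the genome-wide abundance of the immunoprecipitated mark, and ratios of
$Rx$ between conditions estimate true abundance ratios. Tracks are made
comparable by scaling per-bin counts to
$(\mathrm{count}/\mathrm{total}) \cdot Rx \cdot 10^{10}$; the common factor
$10^{10}$ only avoids very small values.

Input normalization of bin $i$ with counts $S_i$ (ChIP, total $TS$) and
$N_i$ (input, total $TN$) uses a pseudocount $c = 1$ added to raw counts:

$$S_{i,\mathrm{norm}} = \log_2 \frac{(S_i + c)/TS}{(N_i + c)/TN},$$

and the Rx-combined form multiplies the ChIP numerator by $Rx$, which is
algebraically an offset of $\log_2 Rx$ — a property the test suite asserts
to machine precision. Inputs themselves are never Rx-scaled: the formulas
apply $Rx$ to the target sample only, and we follow that convention
everywhere, including in browser-style track scaling.

## Focality and redistribution statistics

**Top-1% bin score.** RPKM is computed per 1-kb bin for ChIP and input
(using each bin's true width, so the short last bin of a chromosome is not
inflated), the input is subtracted, and the mean of the top
$\lceil N/100 \rceil$ bins is returned. `ceiling` guarantees a non-empty
selection on small partitions; ties are resolved by a stable sort in
genomic order, which cannot change the mean but makes the selection
deterministic. A focal mark concentrates its reads in few bins and scores
high; a spread mark scores near the genome average.

**Feature proportions.** The fraction of reads (5′ tag coordinates) falling
in the union of a feature set — SUZ12 peaks, CGIs, promoters. Features are
merged first so overlapping annotations cannot double-count a read.

**Difference plots.** Each CGI or promoter is mapped to
$x$ = log2 enrichment in the wild-type state over input and
$y$ = log2 difference K27M − wild-type, computed on "processed counts":
(region count + 1)/library total, times the sample's $Rx$ for ChIP samples.
With two wild-type replicates both terms average the replicates. Regions
overlapping blacklist intervals are removed first. The pseudocount of 1 raw
read reuses the global convention; without it the log of empty regions is
undefined. Categories (Gained, Absent, Lost, Retained) are conjunctions of
half-plane bounds shipped as presets (`BT245-CGI`, `DIPGXIII-CGI`,
`BT245-promoter`). The DIPGXIII Gained and Retained regions overlap, so
assignment is first-match-wins in the fixed order Gained → Absent → Lost →
Retained; points matching no region stay `Unclassified` rather than being
forced into a class, because the published bounds are deliberately not
exhaustive.

**Spread-correlation windows.** 1-kb bins are ranked by input-normalized
K27M H3K27me2 (descending, matching the usual left-to-right decreasing
presentation) and grouped into 1000 contiguous rank windows whose sizes
differ by at most one (larger windows first). Per-window means of K27M me2,
WT me3 and WT me2 are returned; a stronger across-window correlation of
K27M me2 with WT me3 than with WT me2 is the signature of me2 spreading
into the former me3 footprint.

**Aggregate profiles and signal matrices.** Signals are averaged in 500-bp
offset bins around anchor midpoints (±50 kb around SUZ12 peaks; ±100 kb
around PMDs, optionally rescaling the region body to a fixed number of bins
while flanks stay absolute), with missing values discarded from each mean.
Region-by-offset matrices are clustered with standard k-means (k = 3 by
default, fixed seed, 10 restarts, squared-error objective); rows with
missing values are imputed as 0 before clustering, and rows are ordered by
cluster then decreasing mean signal.

## PMD calling

CpGs covered by fewer than 5 reads, overlapping supplied SNP positions, or
inside blacklist regions are removed. The caller then slides a 10-kb window
in 10-kb steps; windows whose unweighted mean CpG methylation is below 0.70
seed candidates. The mean is unweighted (each CpG counts once, regardless
of coverage) because the statistic is a property of positions, not reads.

Extension proceeds rightward in 10-kb increments and stops at the first
increment whose own mean methylation reaches the threshold; that
terminating increment is excluded, and increments containing no CpGs are
neutral — they neither stop extension nor alter the region mean. We stop on
the increment mean rather than on the cumulative region mean deliberately:
with flanking methylation near 0.85 and a domain mean near 0.5, a
cumulative rule keeps the running mean below 0.70 for roughly two domain
lengths past the true edge, dragging every boundary deep into the
methylated flank; the increment rule places boundaries within one window of
the methylation transition, which is the behaviour the recovery tests pin
down. Because the region is assembled entirely from sub-threshold windows,
the cumulative mean of every reported domain is still below the threshold.
Seeds falling inside an already-extended candidate are skipped, overlapping
or bookended candidates are merged, and merged regions strictly longer than
1 Mb are reported. Extension is rightward-only; since every window is also
tried as a seed, leftward extension would only re-cover ground an earlier
seed already claimed.

## Transcriptome summaries

DE labels follow the standard rule: Up if log2FC > 1 and adjusted p < 0.05,
Down if log2FC < −1 and adjusted p < 0.05, otherwise NS (strict
inequalities; records with missing p-values are counted and skipped).
Deciles are equal-count groups over the parental expression of *all* genes
— not DE genes only — so a decile's DE count is interpretable as enrichment
against a uniform baseline; ties at a boundary go to the lower decile. Any
monotone transform of expression (rlog, normalized counts) yields identical
deciles, so the choice of expression measure is immaterial here. The
category × DE cross-tab counts Up/Down genes per promoter category and
conserves totals. Cell-viability percentages use the two-wavelength Alamar
Blue formula with extinction coefficients O1 = 80586 (570 nm) and
O2 = 117216 (600 nm); the result is invariant under common scaling of all
absorbances.

## What the synthetic generator emulates

The generator is the package's test bed: every stage runs against data
whose ground truth is known exactly, and the whole dataset is a pure
function of the configuration seed (each stage draws from its own derived
sub-seed, so regenerating any piece in isolation is bit-identical).

Defaults describe a desk-scale caricature of the biology: two 5-Mb
chromosomes; 200 non-overlapping CGIs placed one per equal-width slot, the
widest 20% flagged as nucleation sites with DNA methylation ~0.05 (others
~0.65); SUZ12 peaks equal to the nucleation set; one 1.5-Mb PMD at 0.5 mean
methylation; 2 × 10^5 expected target reads per sample with a 5% expected
spike-in fraction; and a 2000-gene expression table with 102 upregulated
and 12 downregulated genes whose identities are drawn with weights decaying
in expression rank, concentrating upregulation in low deciles. The DE gene
counts mirror the shared DE sets reported for the cell-line comparisons
this framework was built around; the genome, read depth and gene count are
scaled down by roughly three orders of magnitude so the full suite
simulates in about a second.

Rate maps implement the two regimes directly: WT me3 is enriched over the
nucleation CGIs ±100 kb plus PMDs (the "WT-me3 footprint"), K27M me3 only
over nucleation CGIs ±4 kb, WT me2 over the complement of the footprint,
and K27M me2 over the footprint itself — so the WT-me3/K27M-me2 identity
holds by construction. Tags are Poisson per 100-bp generation bin
(mean = rate × width) and placed uniformly within the bin; overdispersion
is deliberately out of scope. The enrichment:background rate ratio defaults
to 40:1, and the map is rescaled so the expected target total equals
`depth` — the two rates therefore act through their ratio, with `depth`
authoritative for library size. Global mark loss is modelled by scaling the
K27M me3 target rates by `abundance_ratio` (default 0.25) at a fixed
expected spike-in count, which is exactly how loss manifests in ChIP-Rx;
spike-in reads are abstract totals, never placed on a genome, because the
Rx formula consumes only mapped-read fractions.

The methylome places one CpG per 100 bp with Poisson(30) coverage,
Beta-distributed methylation (mean 0.85 outside planted PMDs, the
configured mean inside, concentration 20), and a configurable 10% of CpGs
at coverage below 5 to exercise the filter.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: mappability artefacts and blacklist-scale
anomalies, fragment-length effects, GC bias, overdispersed counts,
replicate-to-replicate biological variability, strand structure, and
bisulfite conversion error. The statistics are validated for correctness of
computation and for qualitative regime discrimination, not for robustness
to these real-data failure modes.

## Numerical choices and degenerate inputs

* Intervals are handled as `GRanges` (1-based closed) internally; BED and
  bedGraph files use 0-based half-open coordinates, converted only at the
  IO boundary. BED3 files round-trip byte-identically.
* A read is assigned to a bin by its 5′ coordinate (point assignment), so
  counting over any disjoint tiling conserves the library total exactly.
* Promoters are 5-kb regions centered on the TSS irrespective of strand
  (the TSS of a minus-strand transcript is its larger genomic coordinate);
  identical TSSs are deduplicated, and intervals are clipped at chromosome
  bounds. Genic regions take the transcript span maximizing |TES − TSS|,
  with ties broken toward the lower start coordinate.
* Blacklist removal uses any-overlap (≥1 bp), the conservative common
  practice.
* Empty tracks, empty anchor lists, zero library totals, zero spike-in
  reads, mismatched partitions and unsorted CpG input are rejected with
  specific errors rather than propagating NaN.

## Problem sizes

The shipped test-suite and acceptance checks run the full generator at its
defaults (10-Mb genome, eight samples, 10^5 CpGs, 2000 genes), plus smaller
2-Mb configurations for unit tests, and randomized oracle comparisons at
10^3–10^4 elements over 20 seeds; the complete suite takes well under a
minute on one core.

## Known limitations

* The PMD caller assumes CpG-resolution input that has already been
  strand-collapsed; it does not perform methylation calling.
* Difference-plot presets encode published thresholds for specific cell
  lines; applying them to other systems requires custom `bounds`.
* The aggregate-profile body-scaling variant interpolates by bin lookup,
  not by exact base-pair averaging within scaled bins.
* DE statistics are consumed, not fitted: the package does not replace a
  count-model fit, and `padj` correctness is the caller's responsibility.
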