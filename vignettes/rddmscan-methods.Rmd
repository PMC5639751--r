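---
title: "Methods: statistics and design choices in rddmscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistics and design choices in rddmscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rddmscan)
```

`rddmscan` implements the comparative statistics used to characterise a
plant RdDM (RNA-directed DNA methylation) mutant transcriptome against wild
type: how much of the genome is transcribed, how expression distributions
shift, how transposable-element (TE) proximity stratifies those shifts, and
how 24-nt siRNA loci and cytosine methylation pattern gene flanks. This
vignette records the statistical definitions, the tunable parameters, and
the design decisions taken where more than one reasonable choice existed.

## Coordinates and interval arithmetic

All intervals are 0-based half-open (BED convention); GFF3 input (1-based,
fully closed) is converted once at the reader boundary. Overlap is strict
(`a.start < b.end` and `b.start < a.end`): abutting intervals do not
overlap. Distance is the edge-to-edge gap, `max(0, b.start − a.end,
a.start − b.end)`, which is 0 exactly when intervals overlap or abut; this
matches the `distanceToNearest` semantics used by genomic-region
permutation frameworks, and we rejected midpoint distance because a long
TE abutting a gene would otherwise look distant. Strand is required for
genes (TSS and TTS are strand-dependent); TEs and siRNA loci may be
unstranded. Gene-body coordinates (not primary transcripts) are used for
all distances. Overlap and nearest-neighbour queries are delegated to
GenomicRanges/IRanges internally; the unit tests check them against
all-pairs brute force.

Oriented windows follow one convention throughout: an oriented offset
$o$ relative to an anchor (TSS or TTS) maps to genomic position
`anchor + o` on the + strand and `anchor − o` on the − strand. A window of
oriented offsets $[-w, +w)$ is therefore the exact mirror image across
strands, and every windowed statistic in the package is invariant under
reflecting all coordinates and flipping all strands (a property test).
"Upstream" always means 5′ of the gene.

## Transcribed fraction of the genome

`transcribed_fraction()` down-samples the alignment-footprint set to a
fixed count (uniform, without replacement, seeded), computes per-base
depth with a difference-array (run-length) algorithm, and counts positions
with depth at least `min_reads` (default 2). Down-sampling and counting are
repeated (default 3 replicates) and the mean count is reported, rounded
down to an integer bp, with the full-precision fraction kept alongside.
Down-sampling operates on alignments, not reads: multi-mapping is upstream
of this package's inputs. `compare_transcribed_fraction()` requires both
reports to share the genome, threshold and down-sampling target, and
reports the relative increase `100·(b − a)/a` at full precision plus a
headline value rounded half-up to the nearest integer percent.

## Expression-distribution comparison

The expression filter keeps rows whose differential-test status is `OK` in
at least one analysis; when no status columns exist, the fallback keeps
rows with FPKM ≥ 1 in at least one genotype. Zeros are never binned or fed
to the K-S test: the frequency of zero-FPKM genes is compared between
genotypes by a two-sided Fisher exact test on the 2×2 zero/non-zero table
(`zero_fraction_test()`), with p-values floored at 1e−15 and flagged
rather than reported as 0.

`ks_compare()` computes the two-sample statistic
$D_\mathrm{obs} = \sup_t |\hat F_x(t) − \hat F_y(t)|$ over the pooled
sample (invariant to the log2 display transform, asserted by test), the
critical distance $D_\mathrm{crit} = c(\alpha)\sqrt{(n_1+n_2)/(n_1 n_2)}$
with $c(\alpha) = \sqrt{-\ln(\alpha/2)/2}$ (1.62762 at α = 0.01 — the
standard two-sample asymptotic coefficient; the source analyses never
print it), and the asymptotic Kolmogorov p-value (alternating series for
large argument, Jacobi-theta dual series below 1 for numerical
stability). The two distributions are declared different only under the
conjunction rule: $D_\mathrm{obs} > D_\mathrm{crit}$ **and** $p < \alpha$.
The test is run on raw (unbinned) values; the integer-centred log2 bins of
`binned_distribution()` (bin $k$ covers $\log_2$ FPKM in $[k−0.5, k+0.5)$,
so bin 0 is FPKM = 1 and bin 2 is FPKM = 4) are presentation only.
`max_cumulative_distance()` reports the maximum vertical separation of two
binned cumulative curves in percent, on the union bin grid.

`rank_compare()` (Mann–Whitney) uses exact enumeration when
$n_1 n_2 \le 400$ and the pooled sample is tie-free, otherwise the normal
approximation with average ranks, tie-corrected variance and continuity
correction.

## TE context and distance stratification

The TE annotation filter keeps class I retroelements strictly longer than
1 kb and class II DNA elements strictly longer than 50 bp ("longer than"
read literally), dropping labelled low-complexity/tandem-repeat records.
Context flags are strand-aware and non-exclusive: 1-kb upstream flank of
the TSS, gene body, 1-kb downstream flank of the TTS, and the oriented
TSS −500/+500 bp window; one element may set several flags. Flank windows
running past the chromosome start are clipped at 0 rather than the gene
discarded. The TSS of a − strand gene is its rightmost base.

Nearest-TE distance is measured from the gene body edges (not the TSS), 0
for body overlap; genes on chromosomes without a TE are reported `NA` and
excluded from means with a count. Distance-binned expression uses bin 0
for body overlaps and bins $((k−1)·500, k·500]$ bp otherwise; upper edges
are closed (a 500-bp distance shares bin 1 with 1 bp; 501 bp opens bin 2).
Frequency-table percentages round half-up to two decimals, matching the
printed tables they are checked against. TE-transcript classification
applies strict thresholds: high-confidence TE transcripts need bit score
> 500 and coverage > 50%; putative/relic TE transcripts are the remainder
with bit score > 250 or coverage > 30%; ties among hits resolve by bit
score, then coverage, then subject id.

## Window co-localization

The genome is tiled into non-overlapping 100-kb windows (last window
truncated). Each gene is assigned to the single window containing its 5′
end, so a window-spanning gene counts once — a deliberate deviation from
plain interval intersection, which would double-count spanning genes.
Per-window gene content is normalised by the chromosome's gene count and
per-window DE content by the window's gene count. The null resamples
same-size gene sets (no duplicates) from the expressed-gene universe; the
empirical p is one-sided with add-one correction, treating *fewer occupied
windows* (more clustering) as extreme. A two-sided Wilcoxon rank-sum p
comparing observed per-window query counts against the pooled null counts
is exposed alongside, as one defensible reading of an under-specified
published comparison; both outputs are reported so users can choose.

## Permutation tests and methylation profiles

`permutation_test()` resamples gene *identities* from the universe (the
`resampleRegions`-style null), not coordinates; the query set is included
in the universe, matching the quoted use of the full gene set as universe.
Because each permutation only re-indexes precomputed per-gene scores, the
evaluator factories (`evaluator_mean_distance()`,
`evaluator_mean_methylation()`) precompute per-gene values once and make
each permutation a constant-time mean. The alternative is chosen by the
observed deviation's direction, with one-sided add-one p
$(1 + \#\{\text{null at least as extreme}\})/(n_\mathrm{perm}+1)$ and a z
score against the null mean and SD (z is `NA` for a constant evaluator).
One consequence worth stating: because the direction is adaptive, the
p-value is uniform only *conditional on a direction* — the probability of
a directional call at threshold $t$ is $t$, but $P(p \le t)$ overall is
about $2t$. Calibration tests therefore assert the nominal rate on
directional calls.

Fold-change bins filter to |log2FC| > 1 and FDR < 0.05 (both strict), then
split each direction at its magnitude quartiles (type-7 linear
interpolation): bin 1 below Q1, bin 3 above Q3, boundary values in bin 2;
down-regulated bins are −1/−2/−3. Directions with fewer than four genes
are an error (quartiles undefined).

Methylation tracks are per-position levels in [0, 1], one context each
(CG/CHG/CHH). The permutation evaluator uses the mean of per-gene flank
means (each gene weighted equally); the metaplot
(`flank_methylation_profile()`) pools positions across genes per 100-bp
window (position-weighted). Both are documented because the source
procedure specifies neither; the evaluator choice keeps genes
exchangeable under identity resampling, while pooling gives stable curves
from sparse tracks. Default flanks are 2 kb for CG/CHG and 1 kb for CHH.
Upstream windows are indexed −flank/window … −1 relative to the TSS and
downstream +1 … +flank/window relative to the TTS, strand-oriented.

## Subgenome and siRNA occupancy

Subgenome frequency reports use dual-scale denominators: singleton and
duplicate percentages are computed over genes assigned to a subgenome,
while nonsyntenic (and unassigned) percentages are over all genes of the
set. Each category is compared against a reference set by a 2×2 Fisher
exact test. The recessive-paralog fraction among DE homeolog pairs counts
pairs where *only* the subgenome-2 member is DE, divided by pairs with at
least one DE member — the reading forced by the printed 40/64 = 62.5%
arithmetic. siRNA occupancy profiles are per-position coverage fractions
(a gene either is or is not covered at an offset, regardless of how many
loci cover it) over oriented offsets [−flank, −1] from the TSS and
[+1, +flank] from the TTS. The TSS-association flag uses the oriented
window [TSS − 1000, TSS + 1000).

## The synthetic-data generator

`simulate_dataset()` builds a toy genome whose defaults are the study
conditions the pipeline is exercised under: two 5-Mb chromosomes, 1,000
non-overlapping genes on a 10-kb slot grid, 2,000 TEs, 600 siRNA loci.
Each gene independently receives a dedicated TSS-proximal TE with
probability `te_near_gene_prob` (default 0.66, the published fraction of
maize genes within 1 kb of a TE); that TE is centred within ±400 bp of
the TSS so it always spans the TSS ±500 bp window, making
`te_near_gene_prob` also the expected fraction of genes carrying the
expression effect. Background TEs are placed uniformly but rejected out
of all TSS ±1-kb neighbourhoods, so the per-gene near-TE fraction stays
binomial around its target. Expression is log-normal
(`log2 FPKM = μ_g + ε`, gene effect `μ_g ~ N(1.5, 2)`) with independent
per-genotype noise (`ε ~ N(0, 0.25)`); the noise term is what makes the
two genotypes identical in law but not identical numbers under the null,
so null calibration tests are meaningful. The mutant adds 1 log2 unit at
TE-effect genes (a free parameter — the source quantifies the effect only
through cumulative-curve separations — chosen as a clearly detectable but
not overwhelming doubling) and 2 log2 units at injected cluster genes (20
clusters of 5 consecutive gene slots). Zeros are injected at 2% (wild
type) and 0.1% (mutant), a 20-fold silenced-gene asymmetry. siRNA loci
fall in 1-kb upstream flanks of genes sampled with weight 2 for
subgenome-2 genes. Methylation tracks carry CG/CHG sites every 20 bp
inside TE bodies at levels 0.9/0.7, sparse background sites every 200 bp
at 0.05 (excluded from TE bodies for CG/CHG, which carry their own grid),
and CHH islands of level 0.6 at oriented offsets −600…−401 bp upstream of
the TSS for half the genes. Alignments are duplicated 50-bp footprints on
a non-overlapping slot grid, so the ≥2-read covered fraction equals
`50·n_pairs/genome` exactly and hits the configured targets (8.45% wild
type, 8.90% mutant — the published uniquely-mapped fractions) to within
the grid granularity. One FPKM value per gene per genotype is generated
(conditions pooled per genotype); per-sample replicates, read sequences,
mapping ambiguity and stress conditions are not simulated.

What passing recovery tests therefore show is that the pipeline detects
clean multiplicative effects, exact coverage targets and hard-edged
methylation islands at realistic sizes — not that it is robust to
overdispersed counts, annotation errors, mappability artefacts or
covarying confounders, none of which the generator emulates.

## Problem sizes and numerical choices

The test suite runs the statistics at deliberately modest sizes chosen to
make Monte-Carlo bounds tight enough to be meaningful: oracle-equivalence
loops use 100 random instances per operation; K-S null calibration uses
500 replicates of 250-gene samples against the α = 0.01 conjunction rule;
permutation calibration uses 300 null runs of 99 permutations;
parameter-recovery runs use 5,000 genes × 100 seeds (K-S detection), 40
seeds of 1,000 genes (cluster detection), and the default 10-Mb genome
(coverage recovery within 0.5 percentage points). Acceptance thresholds
(≥ 95% detection, binomial 99% CIs) come from the recovery contract, not
from observed outcomes. Random number use is localised: every stochastic
function takes a seed and restores the caller's RNG state, so results are
reproducible record-for-record across platforms.

Known limitations: the Fisher and Wilcoxon machinery is delegated to
base R (`fisher.test`, `wilcox.test`) and inherits their conventions; the
asymptotic K-S p-value is unreliable below eight observations per sample
(a warning is attached, the result still returned); `empirical_p` can
never fall below `1/(draws + 1)`, so 100-draw nulls bottom out at ~0.0099;
and the co-localization `ranksum_p` compares against pooled null counts,
which treats null draws as exchangeable and slightly understates
between-draw variance.
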