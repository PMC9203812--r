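---
title: "Methods and design of chromenrich"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of chromenrich}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

chromenrich implements the bespoke computational steps of chromatin-profiling
studies of euchromatin-bound remodellers such as ATRX: consensus peak
filtering across replicates and antibodies, feature-overlap enrichment
against a matched-size random-fragment null with exact testing, putative
G-quadruplex (PQS) scanning, read-depth and spike-in (ChIP-Rx) coverage
normalization, expression-stratified metagene profiling, and a single-cell
relative-activity analysis that detects a stochastically silenced
subpopulation of erythroid cells. A synthetic-data module generates every
input with planted ground truth, so the whole pipeline is testable offline.
This vignette records the models, the parameters that matter, and the design
choices made where the methods literature leaves the design open.

## Coordinates and interval algebra

All in-memory regions are `GRanges` (1-based, closed), the native
Bioconductor convention; BED files on disk are 0-based half-open and are
converted at the reader/writer boundary (`read_intervals()`,
`write_intervals()`). Keeping a single in-memory convention removes an
entire class of off-by-one errors; the package never mixes dialects
internally. "Overlap" always means at least one shared base, so abutting
BED intervals do not overlap, and chromosome names are compared as exact
strings (no "chr" aliasing). The TSS of a minus-strand gene is its `end`
coordinate. The promoter window for peak classification is
TSS−1000/+500 bp by default, oriented by strand and configurable — there
is no universal promoter definition, so the window is an explicit
parameter rather than a hidden constant.

## Consensus peak filtering

Peak callers are run per sample upstream; chromenrich formalizes the
retention rule. Peaks from all samples are pooled and chained into
connected components by ≥ 1 bp overlap; a component is retained iff it
carries peaks from at least `min_samples` distinct samples (default 3) and,
when `require_antibody_agreement` is set, from at least two distinct
antibody labels. The component union is the reported footprint. This
component-level reading of "present in N samples" is order-invariant and
matches common practice; the overlap rule itself is rarely printed in
methods sections, so it is pinned here explicitly. Retained components
overlapping a blacklist by ≥ 1 bp are removed, as are components whose
mean input/gDNA background signal exceeds a threshold. The background
threshold defaults to mean + 3 SD over the background track's bins —
studies typically use "a set threshold" without printing it, so the
default is a conventional outlier rule and fully configurable. Manual
curation of artefacts by browser inspection is out of scope.

With 6 replicates observing each true peak independently with probability
r = 0.9, the fraction of true peaks retained at `min_samples = 3` has the
closed form $\sum_{k\ge 3}\binom{6}{k}0.9^k 0.1^{6-k} \approx 0.99873$;
the acceptance suite verifies the implementation against this form at
2,000 latent peaks.

## The matched-size random-fragment null and exact testing

Every enrichment claim reduces to: how often do the observed intervals
overlap a feature, compared to random intervals of exactly the same
lengths? `matched_random_fragments()` draws one fragment per observed
interval, preserving the length multiset exactly; each fragment is placed
uniformly over all genome positions where it fits entirely outside the
excluded regions (blacklist by default), which makes chromosome choice
proportional to eligible placement count. One null draw per test is the
default (published odds ratios are single numbers, not permutation
distributions); `n_draws > 1` additionally reports an empirical
permutation p across draws.

The 2×2 table (observed/null × overlap/no-overlap) is tested with a
two-sided exact test written in the package: the p-value sums central
hypergeometric probabilities of all tables with the observed margins whose
probability does not exceed that of the observed table, with a relative
tie tolerance of 1e−7 (the probability-mass ordering must be pinned for
oracle equality; the tolerance guards floating-point ties). The odds ratio
is the conditional maximum-likelihood estimate of the noncentral
hypergeometric odds parameter, obtained by solving
$E_\psi[a] = a_{obs}$ with a bracketed root-finder at tolerance 1e−12.
This is the convention under which published odds ratios from standard
statistical environments are computed; the raw cross-product ratio is also
reported for transparency. `stats::fisher.test` is used only as an
independent cross-check in the tests, never as the implementation; the
test suite additionally checks the p-value against a full fixed-margin
enumeration for every table with total ≤ 60 and the estimate against a
10⁴-point likelihood grid. Reported p-values are exact — a printed
"< 2.2e−16" in the literature is a display floor, not a computed value.
No multiple-testing correction is applied across features: the number of
tests per analysis is small and correction is deliberately left to the
caller.

`window_association()` covers gene-set versus peak-proximity tables: a
gene "has a peak" iff a peak overlaps the gene body extended by a window
on both sides (window 0 is the intragenic rule), and the table contrasts
set genes with the background universe. Counts are non-decreasing in the
window by construction.

## PQS scanning

The PQS rule is the canonical Quadparser pattern: `n_runs` (4) runs of at
least `min_run` (3) guanines separated by loops of `loop_min`–`loop_max`
(1–7) non-N bases, plus the reverse-complement (C-run) mirror for the
minus strand. All four numbers are configurable; studies citing "PQS"
rarely restate the motif, so the rule is documented here rather than
assumed. Matching is leftmost-greedy and non-overlapping per strand
(implemented on the base regular-expression engine; an independent
backtracking enumerator serves as the test oracle), N never matches, and
soft-masked lowercase matches only when requested. Overlap statistics use
the merged PQS footprint so nested or overlapping hits count once, making
peak-overlap fractions insensitive to the within-strand counting policy.
Sliding-score methods (G4Hunter) and imperfect/bulged quadruplexes are out
of scope.

## Coverage normalization and metagene profiles

`normalize_per_reads()` scales a binned track by `denominator /
mapped_reads` (default per 100 million mapped reads); the mapped-read
count may be genome-wide or restricted to peak regions — both denominators
appear in practice, so the caller supplies the count. Re-normalizing an
already-normalized track errors rather than silently compounding.

ChIP-Rx spike-in normalization uses the ratio-of-ratios form
$$\gamma = \frac{s_{input}/h_{input}}{s_{chip}/h_{chip}}\times\frac{10^8}{h_{chip}}$$
with h/s the mapped target/spike read counts in ChIP and input. The
spike-in literature states the adjustment verbally; the formula is written
out here so its invariances are testable: doubling ChIP depth halves
γ and leaves the normalized track unchanged, and two samples with
identical biology and identical true spike:target cell ratios (the study
design uses 1:4) yield equal normalized signal regardless of depth.

`metagene_profile()` averages track signal over genes on a common axis,
TSS-centered or length-scaled (default 100 body bins, 2 kb flanks, 50 bp
bins; figure axes in the literature rarely print theirs, so these are
declared defaults, not inferences). Minus-strand genes are
coordinate-reversed so the axis reads 5′→3′; genes truncated by chromosome
ends, or shorter than the body bin count in scaled mode (interpolation
would be undefined), are dropped and counted. The flank must be a multiple
of the bin size so bin arithmetic stays exact. Strata come from
`stratify_by_expression()`: either the four expression-status classes
(expressed in both cell types, A-only, B-only, repressed) or equal-count
quantile bins of expressed genes, with ties broken by gene id so the
partition is deterministic.

## Single-cell analysis

QC follows the study conditions exactly: ATAC cells are kept when
`passed_filters > 500` (strict inequality) and subsampled to exactly
4,000 per sample; RNA cells are kept when `pct_mito ≤ 7.5` and
`800 ≤ nFeature ≤ 4000` and subsampled to 4,400; subsampling is seeded and
performed on id-sorted cells so it is invariant to input row order. RNA
counts are log-normalized as ln(1 + count × 10,000 / cell_total), and
HBA1 + HBA2 normalized values are summed into a `sumHBA` row. ATAC
gene-activity scores count fragments per cell overlapping the gene body
extended 2,000 bp upstream (strand-aware; one fragment counts once per
gene), then are depth-normalized per cell (counts per 10,000, log1p)
before ratios — the transform behind published per-cell accessibility
boxplots is typically unstated, so it is fixed and documented here.

The silenced-subpopulation statistic replaces a visual t-SNE gate with an
explicit, reproducible rule. Per cell, the anchor locus (HBB-like) level
and each target locus (HBA-like, HBM-like) level are stored with
target:anchor ratios on the linear normalized scale (cells with anchor 0
get an undefined ratio and are excluded from ratio summaries). Cells are
anchor-high above the fixed threshold 8 on the RNA log-normalized scale
(the scale implied by published scatter axes) or in the top anchor
quartile for ATAC. A cell is flagged as silenced when it is anchor-high
and its ratio falls below the cutoff for *every* target, each cutoff being
the 35th percentile of the control group's ratios among anchor-high cells.
Requiring all targets reflects the biology — the silencing phenotype is a
coordinated loss of accessibility across the α-globin and μ-globin loci
while β-globin is spared — and makes the flag far more specific than any
single-ratio rule. The cutoff percentile trades specificity against the
stability of the case/control odds ratio: a narrower gate (for example the
25th percentile) flags so few cells in an unaffected experiment that the
odds ratio of a 4,000-cell-per-sample comparison is not estimable within
±25% in 95% of experiments, while the 35th-percentile default keeps both
the per-cell precision of the flag and the null calibration of the
enrichment test; both the gate and the anchor-high quantile are
configurable. The case/control × flagged/not table is tested with the
package's exact test, and per-sample tables are reported alongside the
pooled one. The t-SNE embedding itself is optional output, not part of the
statistic; cisTopic-style topic modelling is not reimplemented — the
gene-activity route is the supported path.

Two-group comparisons of per-cell accessibility use a two-sided rank-sum
test; the pairing/alternative behind published Wilcoxon values is not
stated, so this is a documented convention rather than a claim of
equivalence.

## The synthetic-data generators

`make_genome()` plants PQS motifs (runs of G with loops drawn from
{A,C,T} so planted runs never fuse), non-overlapping genes with strand,
CpG islands and blacklist regions on random sequence; `make_peak_replicates()`
draws a latent true peak set — a configurable fraction centered on TSSs,
the rest uniform outside the blacklist and non-overlapping so latent peaks
remain identifiable — and observes it independently per sample with
probability r, adding Poisson spurious peaks; `make_chiprx_experiment()`
shares one binding-intensity profile across samples and draws Poisson bin
counts at each sample's depth with spike-in counts at the configured cell
ratio; `make_sc_experiment()` generates the two-sample (control/case)
single-cell experiment. Everything is deterministic under the spec seed,
with per-stage seeds derived by name hashing so stages are independently
reproducible.

Counts are Poisson rather than negative binomial: the analyses under test
(quantile gates, rank tests, exact 2×2 tests) assume nothing about
dispersion, and Poisson is the simplest model that exercises them; an
overdispersion robustness knob was considered and deliberately left out to
keep the planted ground truth analytically tractable.

The single-cell generator encodes erythroid differentiation as a per-cell
maturity equal to the cell's depth rank: mature cells are deeper and their
globin loci gain accessibility weight (weight ∝ 1 + 9 × maturity), so the
HBB-normalized level identifies late cells, mirroring the real marker
structure. Target loci (HBA-like, HBM-like) carry twice the anchor's
weight, reflecting that the α-globin region aggregates two genes plus
their enhancer while μ-globin sits in a broader accessible region; this
also means the two target ratios share most of their sampling noise
through the common anchor denominator, which is what makes the
all-targets flag rule well calibrated. Silencing is confined to the most
mature cells: silencing probability is proportional to depth rank raised
to the power `silencing_rank_power` (default 6). A rank-proportional rule
(power 1) was considered but spreads silenced cells across the maturity
range, which contradicts the observation that the phenotype appears in
highly differentiated, globin-dominated cells and makes the silenced set
unrecoverable through any anchor-high gate; the steep default encodes
"late-stage silencing" directly. With effect size 0 the silenced cells'
target counts are exactly zero; with effect ≥ 1 the generator warns that
no detectable effect is planted.

What the generators do not emulate: read-level data (no FASTQ), GC or
mappability bias, fragment-size structure, doublets, batch effects, or
overdispersion. Passing tests therefore demonstrate the correctness and
calibration of the statistical machinery under its stated assumptions,
not robustness to every artefact of real sequencing data. RNA QC fields
(pct_mito, nFeature) are synthetic per-cell metadata emulating upstream
pipeline outputs, since the small synthetic gene panel cannot produce
realistic transcriptome-wide feature counts.

## Numerical choices and problem sizes

Default synthetic conditions: a 2 × 2 Mb genome, 200 genes, 100 CpG
islands, 20 blacklist regions, 50 planted PQS; 2,000 latent peaks across
6 samples at reproducibility 0.9 with 5% spurious peaks; spike-in samples
at 1:4 cell ratio with a 3× depth difference; 4,000 cells per single-cell
sample with a 20% silenced fraction at effect size 0.2. These sizes give
every test enough events for its stated statistical band while keeping
the full suite and the acceptance script fast on a single CPU. Quantile
ties are broken by stable id order; empty margins in 2×2 tables return
p = 1 with an undefined-odds-ratio flag; degenerate inputs (zero-total
cells, unstranded genes with upstream extension, fragments that fit
nowhere) raise informative errors rather than propagating NaN.

## Known limitations

The consensus overlap rule, PQS motif, background threshold, promoter
window, ChIP-Rx formula, metagene axes and subpopulation gate are all
points where the underlying studies leave the design open; chromenrich
pins each one explicitly and exposes it as configuration, but other
reasonable pinnings exist and would change absolute numbers (not the
qualitative behavior verified by the tests). The matched null is
length-matched only — GC- or mappability-matched nulls are out of scope.
Exact tests on a single null draw inherit that draw's sampling noise; use
`n_draws` for a permutation p when that matters.
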