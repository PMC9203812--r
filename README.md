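# chromenrich

Tools for the bespoke computational steps behind chromatin-profiling
studies of euchromatin-bound remodellers (ATRX-style ChIP-seq/ATAC-seq
studies), for bioinformaticians who need the statistics those studies rely
on as tested, reusable functions rather than one-off scripts:

- **Consensus peak filtering** — peaks pooled across replicates are chained
  into ≥ 1 bp overlap components; a component is kept iff supported by
  ≥ `min_samples` distinct samples (optionally ≥ 2 antibodies), then
  blacklist-overlapping and high-background components are removed.
- **Matched-size random-fragment enrichment** — the core statistic: for an
  observed interval set, a null set with exactly the same length multiset
  is placed uniformly in the allowed genome; the 2×2 overlap table is
  tested with a two-sided exact test, p = Σ P(tables with the observed
  margins at most as probable), and the odds ratio is the conditional MLE
  of the noncentral hypergeometric odds parameter ψ solving E_ψ[a] = a_obs.
- **PQS scanning** — the Quadparser motif G₃₊(N₁₋₇G₃₊)₃ and its C-strand
  mirror, leftmost-greedy and non-overlapping, with merged-footprint
  overlap fractions.
- **Coverage normalization** — per-100-million-reads scaling and ChIP-Rx
  spike-in factors γ = (s_in/h_in)/(s_chip/h_chip) × 10⁸/h_chip, plus
  expression-stratified metagene/TSS profiles.
- **Single-cell analysis** — scATAC gene-activity scoring, the study's QC
  rules (passed_filters > 500, 4,000 cells/sample; pct_mito ≤ 7.5,
  800–4,000 features, 4,400 cells/sample), ln(1 + 10⁴·count/total)
  normalization with sumHBA, and a reproducible threshold gate that flags
  the stochastically silenced (HBB-high, HBA/HBM-low) subpopulation and
  tests its case/control enrichment exactly.
- **Synthetic data** — generators for every input with planted ground
  truth (genomes with planted PQS/genes/CpG/blacklist, replicate peak
  sets with tunable reproducibility, spike-in experiments, single-cell
  matrices with a planted silenced subpopulation), so the whole pipeline
  runs and is tested without any download.

## Worked example

```r
library(chromenrich)
library(GenomicRanges)

spec <- synthetic_spec(seed = 1)          # study-condition defaults
g    <- make_genome(spec)                 # 2 x 2 Mb, 200 genes, 50 planted PQS
pk   <- make_peak_replicates(g$genome, spec)  # 6 samples, r = 0.9

cons <- consensus_filter(pk$samples,
         consensus_config(min_samples = 3, require_antibody_agreement = TRUE,
                          blacklist = g$genome$blacklist))
length(cons)
#> [1] 1183

er <- feature_enrichment(cons, tss_of(g$genome$genes), g$genome,
                         exclude = g$genome$blacklist, seed = 7)
er
#> EnrichmentResult: table (a=195 b=988 c=14 d=1169)
#>   odds ratio (CMLE) = 16.47, p = 3.024e-45
```

The consensus call keeps ~1,200 of 2,000 latent peaks (the antibody rule
discards components seen by one antibody only), and the TSS enrichment
mirrors the study's headline pattern: peaks overlap TSSs an order of
magnitude more often than matched random fragments, with an exact p far
below any display floor. On the single-cell side:

```r
sc  <- make_sc_experiment(spec, modalities = "atac")   # 4,000 cells/sample
act <- normalize_atac_activity(sc$atac$counts)
ann <- relative_activity(act, sc$atac$annotation, anchor = "HBB",
                         targets = c("HBA", "HBM"), modality = "atac")
sub <- subpopulation_enrichment(ann)
sub$result
#> EnrichmentResult: table (a=871 b=3129 c=210 d=3790)
#>   odds ratio (CMLE) = 5.023, p = 8.205e-110
mean(sc$truth$atac_silenced %in% sub$flagged)   # sensitivity vs planted truth
#> [1] 0.97
```

An end-to-end demonstration (`run_pipeline()`, or the
`inst/scripts/chromenrich.R` shim with subcommands `simulate`, `pqs`,
`consensus`, `enrich`, `normalize`, `metagene`, `sc-atac`, `sc-rna`,
`run-all`) writes BED/TSV/bedGraph/MTX outputs plus a JSON manifest of
files, hashes and per-stage seeds; identical configs reproduce
byte-identical outputs.

See `vignettes/chromenrich-methods.Rmd` for the models, parameter
defaults, and the design decisions behind each statistic.

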