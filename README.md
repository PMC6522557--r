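# fusionscreen

Most gene fusions detected in tumour RNA-seq are passengers — artifacts
of error-prone fusion calling or by-products of genomic instability —
yet fusions are used clinically for diagnosis, risk stratification and
targeted therapy. `fusionscreen` is an R package for the computational
triage that separates functional fusions from the rest in panels of
cancer cell lines, aimed at cancer genomicists and functional-screening
analysts working with multi-caller fusion calls, drug-sensitivity panels
and pooled CRISPR-Cas9 drop-out screens.

The package implements five linked analyses:

1. **Consensus catalog.** Fusion transcripts are kept when called by ≥ 2
   algorithms with ≥ 4 junction-spanning reads and absent from a
   normal-tissue blacklist; transcripts collapse to per-cell-line fusion
   *events* and cohort-level *unique/recurrent* fusions.
2. **Recurrence permutation test.** The binary gene × sample occurrence
   matrix is rewired by checkerboard switches that preserve all row and
   column sums; per (gene, cancer type),
   `p = (1 + #{null ≥ N}) / (1 + R)` with Benjamini–Hochberg FDR.
3. **Expression association.** Per recurrently fused gene end, OLS of
   log2 RPKM: `G = β_cov·X_cov + β_fusion·X_fusion + ψ` with cancer
   type, MSI and CNA-category covariates; the fusion term is tested by
   type-II ANOVA. Rare fusions are triaged by 95th-percentile 3′-gene
   overexpression without amplification.
4. **Two-stage drug ANOVA.** Stage 1 finds cancer-functional-event (CFE)
   confounders per drug (FDR < 25%, p < 0.001, both Glass Deltas > 1);
   stage 2 tests recurrent fusions against log IC50 with those
   confounders as covariates, gated on FDR < 25% and dual Glass Deltas
   `Δ_pos = |m_pos − m_neg| / s_pos`, `Δ_neg = |m_pos − m_neg| / s_neg`.
5. **Fusion essentiality score (FES).** sgRNAs are split into
   fusion-*mapping* and *non-mapping* by strand and breakpoint; after
   scale-to-essentials normalization (non-essential median → 0,
   essential median → −1) and per-guide Z-normalization,
   `FES = mean over partner genes of (mean Z_mapping − mean Z_non-mapping)`,
   with significance from 10,000 within-cell-line randomizations and a
   −0.45 minimum raw mapping/non-mapping difference. A pre-ranked
   running-sum enrichment statistic tests whether transcript classes
   concentrate among the top FES hits.

A synthetic-study generator (`sim_config()`, `simulate_study()`) plants
known fusions, expression shifts, drug sensitizations, a confounded
fusion–CFE pair and CRISPR depletions, and records them in a truth
manifest, so every stage is testable end to end without controlled-access
data.

## Worked example

```r
library(fusionscreen)
cfg <- sim_config(seed = 1)                    # 60 lines, 120 genes, planted truth
out <- run_pipeline(file.path(tempdir(), "demo"), cfg,
                    n_perm_recurrence = 1000, n_perm_fes = 1000)
out$summary
#> Fusion catalog summary
#>   transcripts:       50
#>   fusion events:     50
#>   unique fusions:    20
#>   recurrent fusions: 12 (60%)
#>   in-frame events:   32.0%
#>   median events per cell line: 1
```

All 20 planted fusion pairs (and none of the ~50 noise or blacklisted
calls) survive the consensus filter; 12 pairs were planted in ≥ 2 lines,
hence 60% recurrent. Genes planted as recurrent within one cancer type
top the permutation test:

```r
head(out$recurrence, 3)
#>   gene cancer_type observed_n     p_value       fdr
#> 1 G003       type1          4 0.000999001 0.0148423
#> 2 G035       type1          4 0.000999001 0.0148423
#> 3 G017       type4          4 0.001998002 0.0148423
```

The expression screen recovers the planted +3 log2 (oncogene-like, 3′)
and −2 (TSG-like, 5′) shifts with the right signs
(`beta_fusion` 3.08, 2.88, −2.55 at FDR < 3e-4), and the drug screen
flags the planted sensitizing fusion on its drug
(`G065--G072 / D01`, effect −2.4 log IC50, FDR 8.5%) while the planted
*confounded* association vanishes once its coincident CFE enters as a
stage-1 covariate. The FES stage finds 19 of 50 testable transcripts
significant — the planted functional transcripts, which also rank at the
top of the enrichment test:

```r
print(out$enrichment)
#> running-sum enrichment: ES = 1.000 (set 20 of 50), p = 0.000999 (1000 permutations)
```

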