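# pdlsig

Donor-blocked transcriptomic analysis of PD1-ligand **reverse signalling**
in fibroblast-like synoviocytes (FLS).

When soluble PD1 (sPD1) engages PD-L1 or PD-L2 on a TNF-primed fibroblast,
the *ligand-bearing* cell changes its transcriptional program. `pdlsig` is
for analysts of that kind of experiment: a five-condition design per donor
cell line — control, TNF, TNF+sPD1, and TNF+sPD1 on PD-L1- or
PD-L2-knockout cells — run in rheumatoid-arthritis (RA) and
non-inflammatory (NI) donor groups with few cell lines per group, where
donor variability exceeds the treatment effects and every inference must be
made *within* cell lines.

## What it computes

Per disease group, for gene-wise log2-CPM values **y** with TMM
normalization and mean-variance precision weights, the package fits

> y_g = X beta_g + e_g,  Cov(e_g) = sigma_g^2 D_g^{1/2} [(1 − rho) I + rho Z Z'] D_g^{1/2}

a generalized least-squares model with a single consensus intra-donor
correlation `rho` (donor as a random effect; Z indicates same-donor pairs,
D_g the inverse precision weights), followed by empirical Bayes moderation
of sigma_g^2 and moderated-t contrasts with Benjamini–Hochberg correction.
On top of that sit the design's bespoke statistics:

- **Dampening**: per-gene Δlog2FC = log2FC(TNF+sPD1 vs control) −
  log2FC(TNF vs control); fraction with Δ ≤ −0.5 (dampened) and Δ ≥ 0.5
  (amplified).
- **sPD1-responsive genes**: |log2FC| ≥ 0.585 with raw p ≤ 0.05 versus TNF,
  *and* |log2FC| < 0.585 with raw p ≥ 0.5 in at least one ligand-knockout
  arm, with PD-L1 / PD-L2 / both attribution.
- **Bootstrap stability**: donors resampled with replacement, the full
  pipeline refit, Spearman correlation of replicate versus original log2FC
  rankings; median > 0.9 stable, < 0.8 unstable.
- **ΔΔCt qPCR validation** with the Ct ≥ 30 exclusion gate and
  cross-platform Spearman agreement.
- **Cohort utilities**: single-cell QC (≥ 1000 genes, ≤ 25% mitochondrial),
  percent-expressing, pseudobulk log2-CPM with Mann–Whitney comparisons,
  kernel-CDF random-walk gene-set scores, and marker correlations with
  strength bands at |rho| = 0.2 / 0.4 / 0.6 / 0.8.

Every generator (bulk NB counts with donor random effects, qPCR Ct tables,
structured single-cell matrices) records its ground truth in a
`SyntheticTruth` object so recovery can be tested.

## Worked example

```r
library(pdlsig)

design <- fiveConditionDesign(nDonorsPerGroup = 3, groups = c("NI", "RA"))
truth  <- simulateTruth(design, nGenes = 2000, nResponsive = 150,
                        responsiveLfc = 1.5, dampenFrac = 0.2,
                        dampenLfc = -1, dampenGroups = "NI",
                        libSize = 2e6, seed = 42)
se  <- simulateBulkCounts(truth, design)
res <- fitContrasts(se, group = "NI")

res$ebayes
#> EBayesState: d0 = 21.05 , s0^2 = 1
#>   consensus intra-donor correlation: 0.361

res$tables$TNFsPD1_vs_TNF
#> ContrastTable: TNFsPD1_vs_TNF - 1983 genes, 183 DEGs at FDR 0.05

calls <- callResponsive(res$tables$TNFsPD1_vs_TNF,
                        res$tables$KO_PDL1_vs_TNF,
                        res$tables$KO_PDL2_vs_TNF)
calls
#> ResponsiveCalls: 75 responsive of 1983 genes (PD-L1: 36 , PD-L2: 33 , both: 6 )

deltaLog2Fc(res$tables$TNFsPD1_vs_control, res$tables$TNF_vs_control)
#> DampeningSummary (NI): 9.3% dampened (delta <= -0.5), 8.3% amplified

unlist(recoverTruth(calls, truth))[1:3]
#>         sensitivity           precision attributionAccuracy
#>           0.3466667           0.6933333           0.9615385
```

Reading the output: the moderation state reports the shared intra-donor
correlation (0.36 here — donor effects are real but modest at this
simulation's settings) and the variance prior. 183 genes move under sPD1 on
the TNF background at FDR 0.05; 75 survive the compound knockout filter,
most attributed to a single ligand. The planted NI-only dampening scenario
shows up as an excess of dampened over amplified genes. Recovery against
the recorded truth illustrates the filter's character: attribution is
nearly always right (0.96), but sensitivity sits near 0.35 — criterion 2
requires p ≥ 0.5 on a true-null knockout contrast, which a calibrated test
satisfies only about half the time, so the filter is a high-confidence,
low-recall screen (see the methods vignette for the analysis).

The full chain — simulation, per-group contrasts, dampening, responsive
calls, optional bootstrap, qPCR arm, manifest — runs via
`runPipeline(runConfig(...))` or the wrapper
`inst/scripts/run_pipeline.R`.

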