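# driftrescue

Endothelial cells taken straight from the umbilical cord and placed in
culture change a large part of their transcriptome — a *transcriptional
drift* away from the in-vivo state. Part of that drift can be reversed
(*rescued*) by restoring environmental cues the dish lacks: laminar shear
stress, or heterotypic contact with smooth-muscle cells. `driftrescue`
implements the full analysis for quantifying this, for bulk (and
pseudobulked single-cell) expression matrices:

* a **seeded synthetic-data generator** with planted ground truth (drifted
  genes, flow- and co-culture-rescued subsets with time-monotone decay,
  block-correlated co-expression modules, additive batch effects, an
  imperfectly correlated protein layer), so every downstream stage is
  testable without any data download;
* **preprocessing**: `log10(x + 1)` transform, gene-wise scaling to zero
  mean and unit variance, empirical-Bayes batch adjustment (parametric and
  Monte-Carlo nonparametric modes, intercept-only model), and sample-space
  PCA;
* a per-gene **drift screen**: Welch's *t* between environments with
  Welch–Satterthwaite degrees of freedom, the biweight midcorrelation
  against the condition indicator, a Bonferroni rule (`p < α/m`; at
  `α = 0.05`, `m = 20000` this is the transcriptome-wide `2.5e-6`) and
  Benjamini–Hochberg FDR control;
* **rescue classification** by sign concordance: a drifted gene is rescued
  by a perturbation when the perturbation response is significant
  (FDR < 0.05) and moves cultured cells back toward cord, i.e.
  `sign(t_perturb) = sign(t_cord)`; the transcriptome partition
  (drifted = flow-only + co-culture-only + both + unrescued) holds exactly;
* **time-course analysis**: the correlation across genes between the
  cord-vs-culture statistic and the flow(t)-vs-static statistic, which
  rises with hours under flow when rescue accumulates;
* from-scratch **signed-hybrid weighted co-expression analysis**:
  `A_ij = max(bicor_ij, 0)^β` (default β = 3), topological overlap
  `ω_ij = (ℓ_ij + A_ij) / (min(k_i, k_j) + 1 − A_ij)`, average-linkage
  clustering of `1 − ω` with a deterministic dynamic tree cut, module
  eigengenes (first PC per module), eigengene merging, and module–trait
  bicor with FDR;
* **cross-omic concordance** (Pearson correlation of matched RNA and
  protein t-statistics), expression-bin-matched **gene-set scores**, and
  the **time-profile engine**: per-gene per-timepoint averages with OLS
  origin/slope and a similarity/divergence band search (`s ∈ [0, 2]`,
  profiles inside/outside `ref ± s` at every timepoint).

Everything is tidyverse-shaped: results are tibbles, fitted objects have
`tidy()` / `glance()` methods and `autoplot()` figures.

## Worked example

```r
library(driftrescue)

params <- sim_params(n_genes = 4000, seed = 1)   # defaults: 43% drift,
study  <- generate_study(params)                 # 17% flow / 9% cc rescue
expr   <- eb_batch_adjust(study$expr, study$samples$batch)
drift  <- drift_screen(expr, study$samples)
glance(drift)
#>   n_genes n_expressed n_drifted fraction_drifted rule       alpha m_tests
#> 1    4000        3999      1717            0.429 bonferroni  0.05    3999

flow   <- generate_timecourse(params, study$truth)
fexpr  <- eb_batch_adjust(flow$expr, flow$samples$batch)
sel    <- flow$samples$timepoint_h %in% c(0, 48)
de_flow48 <- de_contrast(expr_matrix(unclass(fexpr)[, sel], "log10"),
                         flow$samples[sel, ], "flow", "static")
cls    <- concordance_classify(drift, de_flow48)
de_cc  <- de_contrast(expr, study$samples, "co_culture", "mono_culture")
part   <- rescue_fractions(cls, concordance_classify(drift, de_cc), drift)
dplyr::select(part, drifted, rescued_by_flow, rescued_by_cc, unrescued)
#>   drifted rescued_by_flow rescued_by_cc unrescued
#> 1   0.429           0.168         0.082      0.18
```

42.9% of expressed genes drift in culture; 16.8% of the transcriptome is
rescued by 48 h of flow and 8.2% by smooth-muscle co-culture, recovering
the planted 43% / 17% / 9% within sampling and test error. The correlation
to the cord signature grows monotonically with time under flow:

```r
hours <- c(0.5, 8, 24, 48)
de_t  <- lapply(hours, function(h) {
  s <- flow$samples$timepoint_h %in% c(0, h)
  de_contrast(expr_matrix(unclass(fexpr)[, s], "log10"),
              flow$samples[s, ], "flow", "static")
})
names(de_t) <- hours
timecourse_correlation(drift, de_t)
#>   timepoint_h       r         p n_genes
#> 1         0.5 0.00481 7.61e-  1    4000
#> 2         8   0.324   2.43e- 98    4000
#> 3        24   0.519   2.17e-275    4000
#> 4        48   0.569   0           4000
```

`run_pipeline(pipeline_config(params = sim_params(seed = 1), out_dir = "out"))`
chains every stage (drift → rescue → co-expression → profiles) and writes
per-gene TSV artifacts plus a JSON run report.

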