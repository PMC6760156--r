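# toothrqa

Recurrence quantification of elemental biomarker time-series from teeth.

Deciduous teeth archive elemental exposure along their growth increments:
laser-ablation ICP-MS transects yield, per element, a metal:Ca ratio series
datable relative to birth (~152 sampling locations spanning late gestation
through early infancy). Elemental metabolism cycles, and neurodevelopmental
phenotypes (ADHD, ASD, their comorbid presentation) have been associated
with disruptions of those cycles. `toothrqa` is for biostatisticians
analysing such profiles. It provides:

* **RQA / CRQA** — time-delay embedding, auto- and cross-recurrence
  matrices with per-matrix threshold calibration to a target recurrence
  rate, and the four line-based dynamical features

  `DET = Σ_{l≥l_min} l·P(l) / Σ_{l≥1} l·P(l)` (cycle regularity),
  `MDL = Σ_{l≥l_min} l·P(l) / Σ_{l≥l_min} P(l)` (cycle duration),
  `ENTR = −Σ p(l) ln p(l)` (cycle-duration complexity), and
  type-2 recurrence time `RT` (mean white vertical line length — the
  interval between cycles), with a compiled run-length kernel.
* **Feature pipeline** — a 60-column cohort table: DET/MDL/ENTR/RT for 8
  single-element pathways (Zn, Cu, Pb, Co, V, Li, Sn, Mn) and 7
  zinc-centred cross-recurrences (Zn–Cu, Zn–Pb, Zn–Co, Zn–V, Zn–Li, Zn–Sn,
  Zn–Ca).
* **Twin-clustered inference** — per-feature linear mixed models
  `y ~ ADHD + sex + gestational days + birth weight + ASD + (1 | pair)`
  (REML, Wald z on the ADHD indicator), ±2 SD outlier screening, and
  Benjamini–Hochberg FDR stratified by pathway.
* **Phenotype signatures** — correlation-matrix PCA with the joint
  eigenvalue-greater-than-1 / 80%-cumulative-variance retention rule and
  per-component group contrasts; 4-class Fisher LDA (diagonal-shrinkage
  regularized) with standardized loadings defined as feature–axis
  correlations.
* **Synthetic cohort generator** — twin cohorts (default: 30 pairs, 1
  triplet, 11 singletons; TD 41 / ADHD 13 / ASD 8 / COMORBID 12) with
  quasi-periodic element series whose single *regularity* knob injects
  diagnosis-specific cycle deficits at the generative level, making every
  downstream stage testable without clinical data.

## Worked example

```r
library(toothrqa)

## one synthetic tooth profile and its recurrence features
s <- generate_element_series(signal_params(), rng_seed = 1,
                             subject_id = "S001", element = "Co")
s
#> <element_series> S001 / Co: 144 points, days -120.0..200.0
rqa(s)
#> <rqa_features> RR=0.100 DET=0.832 MDL=3.71 ENTR=1.734 RT=9.39

## a full cohort: simulate, featurize, scan, reduce
coh  <- generate_cohort(cohort_config(seed = 20))
ft   <- compute_feature_table(coh$series, coh$subjects)   # 74 x 60
scan <- run_feature_scan(ft, coh$subjects)
head(subset(scan, p_fdr <= 0.05,
            select = c(feature, beta_adhd, se, p_fdr)), 4)
#>   feature beta_adhd      se    p_fdr
#> 5  Cu_DET   -0.0328 0.00674 1.52e-06
#> 6  Cu_MDL   -0.3042 0.05191 1.53e-08
#> 7 Cu_ENTR   -0.1473 0.02550 1.53e-08
#> 9  Pb_DET   -0.0362 0.00605 6.12e-09
```

Under the default generator, ADHD (and comorbid) subjects carry a
regularity deficit in the Co/Pb/V/Cu pathways, and the scan recovers it:
negative ADHD effects on determinism (β ≈ −0.03, i.e. about three
percentage points of DET), mean diagonal length and entropy in exactly
those pathways, surviving the pathway-stratified FDR. The zinc-pair rows
(Zn–Cu, Zn–Pb, …) respond through the perturbed partner elements.

```r
pca <- pca_fit(ft)
length(pca$retained)                       # 11 components retained
#> [1] 11
round(100 * pca$cum_share[max(pca$retained)], 1)   # 81.7 % of variance
#> [1] 81.7

lda <- lda_fit(ft, coh$subjects)           # 3 discriminant axes, 74 subjects
head(sort(abs(lda_loadings(lda, ft)[, "LD1"]), decreasing = TRUE), 3)
#> Zn-Pb_DET    Pb_DET Zn-Cu_ENTR
#>      0.86      0.85       0.82
```

The retained-component count and LD1's top loadings are in-sample
descriptions of this synthetic cohort — the package deliberately provides
no cross-validated classifier.

`run_pipeline(run_config(...), "out/")` chains the stages and writes
stamped CSV/TSV artifacts (`features.csv`, `scan.tsv`, `pca_*`,
`lda_*`, a run log and a summary), each carrying the seed and a config
hash in a `#` header; `read_run_config()` loads the same settings from a
YAML file, and `read_series_csv()` / `read_subjects_csv()` accept measured
data in place of the simulator.

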