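---
title: "Recurrence quantification of tooth elemental biomarkers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recurrence quantification of tooth elemental biomarkers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Deciduous teeth record elemental exposure along their growth increments:
laser-ablation ICP-MS sampling along the dentine produces, for each element,
a metal:calcium ratio time-series datable relative to birth through the
neonatal line. Elemental metabolism is not constant over development — many
essential and toxic elements cycle — and neurodevelopmental conditions such
as ADHD and ASD have been associated with disruptions of those cycles rather
than of mean exposure levels. `toothrqa` implements the analysis chain for
such data: recurrence quantification of per-subject elemental series,
twin-clustered inference on the derived dynamical features, and
dimensionality reduction of the feature space into phenotype signatures.
Because no clinical tooth dataset ships with the package, a synthetic cohort
generator stands in for the data source; every downstream stage treats its
output exactly as it would treat measured series read from CSV.

## Recurrence quantification

A series $x_1,\dots,x_N$ is delay-embedded into
$\mathbf{x}_i = (x_i, x_{i+\tau}, \dots, x_{i+(m-1)\tau})$ and the
recurrence matrix is $R_{ij} = \mathbf{1}[\,d(\mathbf{x}_i,\mathbf{x}_j)
\le \varepsilon\,]$. Diagonal runs of 1s mark stretches where the
trajectory repeats itself — cycles. From the histogram $P(l)$ of maximal
diagonal run lengths (Theiler-masked for auto-recurrence) the package
reports:

* **DET** $= \sum_{l \ge l_{\min}} l P(l) \big/ \sum_{l \ge 1} l P(l)$ —
  the fraction of recurrence points on qualifying diagonals; cycle
  regularity.
* **MDL** $= \sum_{l \ge l_{\min}} l P(l) \big/ \sum_{l \ge l_{\min}} P(l)$
  — mean cycle duration.
* **ENTR** $= -\sum_l p(l)\ln p(l)$ over the qualifying line-length
  distribution — cycle-duration complexity (0 when a single length
  dominates).
* **RT** — type-2 recurrence time, the mean length of white vertical runs
  bounded by recurrence points within columns: the interval between cycles.

Cross-recurrence replaces $d(\mathbf{x}_i,\mathbf{x}_j)$ with distances
between two different series' embedded states, after restricting both to
their overlapping day interval, interpolating onto a shared uniform grid of
length $\min(N_A, N_B)$, and z-scoring each series. The z-scoring is what
makes the construction invariant to the order-of-magnitude scale
differences between elements; the interpolation is the minimal alignment
that makes two unequal-length series comparable.

### Parameter choices

No published parameterisation exists for these short biomarker series, so
the defaults are declared, not inferred, and all are exposed in
`embedding_params()`:

| parameter | default | rationale |
|---|---|---|
| embedding dimension `m` | 3 | common recurrence-toolbox practice for short noisy series |
| delay `tau` | 1 sample | increments are already coarse (~2 days/sample) |
| threshold | target recurrence rate 0.10 | calibrated per matrix, so features are comparable across subjects whose ratio units differ by orders of magnitude; a fixed radius is available instead |
| norm | Euclidean | conventional default |
| Theiler window | 1 (auto), 0 (cross) | exclude only the line of identity; cross plots have no trivial diagonal |
| `l_min` | 2 | shortest run that can be called a cycle |
| minimum usable length | 50 embedded points | shorter series yield missing features rather than unstable estimates |

Two conventions deserve a note. The DET denominator counts *all* recurrence
points ($l \ge 1$), the standard convention; a variant that excludes
vertical structures exists but is not implemented. Recurrence time is the
type-2 variant (mean white vertical line length, counting only gaps bounded
by recurrences on both sides); "the interval between cycles" admits a
type-1 reading too, and the choice matters for absolute values though not
for group contrasts. Features whose supporting histogram is empty are
reported as missing (`NA`), never coerced to 0.

## The synthetic cohort generator

`generate_element_series()` draws
$$v(t) = b\,f_s + A \sin\!\big(2\pi t / T + \varphi(t)\big) + \eta(t),
\qquad v(t) \leftarrow \max(v(t), 0),$$
where $\varphi$ is a Brownian phase walk with per-interval step standard
deviation $\sigma_\varphi (1 - r)\sqrt{\Delta t}$ and $\eta$ is AR(1) noise
with innovation standard deviation $\sigma_\eta (2 - r)$. The single knob
$r \in [0,1]$ (*regularity*) maps monotonically onto the recurrence
features: at $r = 1$ the phase walk freezes and the cycle is exact; lowering
$r$ both diffuses the phase and inflates the noise, degrading DET, MDL and
ENTR together — the qualitative signature reported for affected phenotypes.
This is deliberately the simplest generative model with that property; it
is not a model of enamel biochemistry.

Defaults: baseline ratio 1 (arbitrary units — the threshold calibration and
z-scoring make all features scale-free), amplitude 0.4, period 15 days,
regularity 0.85, phase jitter 0.5 rad/√day, noise 0.12, AR coefficient 0.3,
and a Poisson-distributed sampling count with mean 152 locations (the
reported average for LA-ICP-MS tooth transects) spanning −120 to +200 days
around birth. The period sits comfortably above the ~2-day sampling
interval so cycles are resolvable at `m = 3, tau = 1`; the marginal
distribution is additive by default with a multiplicative (log-scale)
variant available via `signal_params(log_scale = TRUE)`, since the true
marginal shape of ratio signals is not characterised.

`generate_cohort()` builds the twin structure: by default 30 complete
pairs, one triplet group and 11 singletons (74 subjects) with diagnosis
counts TD 41 / ADHD 13 / ASD 8 / COMORBID 12. Twin members share a latent
exposure factor and a latent regularity deviation, mixed with weight
`twin_correlation` (default 0.7) for MZ pairs and half that for DZ pairs;
gestational age is shared within a pair
($\mathcal{N}(246, 24^2)$ days truncated to [180, 300]); birth weight is
subject-level ($\mathcal{N}(2.4, 0.7^2)$ kg truncated at 0.5). Diagnosis
effects are injected as shifts on *regularity* — a generative knob, not an
RQA feature — so parameter-recovery tests are non-circular. The default
effect magnitude is −0.2, chosen once as a moderate deficit (about a
quarter of the usable regularity range) applied to the pathways with
reported deficits: Co, Pb, V and Cu for ADHD; Zn and zinc-pair pathways for
ASD; both sets for the comorbid phenotype. A pair-keyed effect (e.g.
`Zn-Cu`) perturbs the *partner* element's series, degrading the
cross-recurrence without touching zinc itself.

What the generator does **not** emulate: instrument physics and drift,
enamel/dentine geometry, non-uniform increment spacing, measurement
censoring at the detection limit, age-dependent amplitude, or any real
covariance between elements beyond the shared subject factor. Passing tests
therefore demonstrate that the pipeline recovers what the generative model
encodes — not that real teeth carry these signals.

## Per-feature inference

Each of the 60 feature columns (15 pathways × DET/MDL/ENTR/RT) is analysed
with a linear mixed model fitted by REML (`lme4`):

$$y = \beta_0 + \beta_{\text{ADHD}}\,\mathbf{1}[\text{ADHD or comorbid}]
+ \beta_{\text{sex}} + \beta_g\,\text{gest} + \beta_{bw}\,\text{bw}
+ \beta_{\text{ASD}}\,\mathbf{1}[\text{ASD or comorbid}] + u_{\text{pair}} + \varepsilon$$

with a pair-level random intercept (singletons are singleton clusters) and
non-exclusive ADHD/ASD indicators, so the comorbid phenotype carries both.
The ADHD effect is tested with a Wald z statistic; degrees-of-freedom
corrections (Satterthwaite, Kenward–Roger) are not applied, and the
acceptance suite verifies that the resulting type-I error at 30 pairs stays
within [0.03, 0.07]. Female is the reference level for sex. Zygosity and IQ
are excluded from the default model (they are recorded in the subject table
for users who want them).

Before modelling, values beyond ±2 SD are excluded — a single pass, with the
mean and SD taken over the original non-missing values. Which columns are
screened is controlled by `outlier_mode`: the default `"auto"` screens
exactly the columns failing a Shapiro–Wilk normality check at 0.05, and
`"all"`/`"none"` force either extreme, since the source procedure for
"some variables" cannot be recovered.

Raw ADHD p-values are Benjamini–Hochberg adjusted **within each pathway
stratum** (each pathway's four measures form one stratum), so a pathway's
adjustment is not diluted by tests on other pathways. Per-feature failures
(constant columns, too few complete pairs) become flagged rows with an
error message; the scan never aborts.

## Dimensionality reduction

PCA is performed on the correlation matrix (columns centred and scaled) of
the complete-case feature rows. Components are retained when their
eigenvalue exceeds 1 *and* they fall within the smallest leading set whose
cumulative variance share exceeds 80% — the conjunction rule, applied
literally. Retained component scores are compared between diagnoses with
ordinary linear models (TD reference, three indicator contrasts); these are
deliberately plain linear models, not mixed models, which mirrors the
analysis this stage reproduces but does ignore twin clustering — a known
inconsistency with the per-feature scan, documented rather than resolved.

The 4-class LDA is a Fisher discriminant: the three axes are generalized
eigenvectors of the between-class scatter (priors proportional to class
sizes) in the pooled within-class metric. Because the feature count (60)
is comparable to realistic cohort sizes, the pooled within-class covariance
is shrunk toward its diagonal with a fixed coefficient of $10^{-4}$ before
inversion; this is small enough to be inert on well-conditioned problems
(the test suite checks agreement with an unregularized reference
implementation) while keeping the solve defined when features outnumber
degrees of freedom. Subjects with any missing feature are excluded
(complete-case, also adopted for PCA); an exclusion that empties a class is
an explicit error naming the class. Variable importance is reported as
*standardized loadings*: Pearson correlations between each raw feature
column and each axis's scores, bounded in [−1, 1] regardless of feature
units. Every PCA and LDA axis is oriented so that its largest-|loading|
feature loads positively, making outputs reproducible across linear-algebra
backends.

## Numerical and degenerate-input conventions

* Threshold calibration takes the `target_rr` empirical quantile
  (order statistic $\lceil q\,M \rceil$) of pairwise distances, excluding
  $i = j$ for auto-recurrence and pooling all cross pairs for
  cross-recurrence; the achieved recurrence rate is within one
  order-statistic step of the target.
* Constant (zero-variance) trajectories are errors at the matrix level and
  missing cells at the pipeline level; constant feature columns are dropped
  from PCA/LDA with a warning.
* Series with fewer than 50 embedded points yield missing features.
* Wald p-values are floored at the smallest positive double so the
  (0, 1] contract of the FDR step holds under extreme separation.
* All generators are deterministic given their seed and restore the
  caller's RNG state; a cohort is bitwise-reproducible from its config.

## Problem sizes used by the test suite

Unit tests run on reduced series (about 90 points over −60..+90 days) and
cohorts of 2–12 subjects. The acceptance-style checks use the study-scale
defaults: 74-subject cohorts with 152-point series for structural checks;
1,000 simulated teeth for the sampling-count average; 500 null replicates at
30 pairs and 200 recovery replicates at 200 pairs for mixed-model
calibration; 20 replicate cohorts of 200 pairs for end-to-end effect
recovery; and 200 random matrices for oracle equivalence. These sizes were
chosen to make Monte-Carlo error small relative to the tested margins.

## Known limitations

* Absolute RQA feature values depend on the declared embedding defaults;
  only within-cohort contrasts computed under a fixed configuration are
  meaningful.
* The Wald z test is mildly anti-conservative in very small cohorts; at the
  74-subject scale the calibration check bounds the distortion, but users
  fitting far smaller cohorts should not rely on nominal levels.
* Cross-validated classification is intentionally absent: with ~74 subjects
  and 60 features, LDA reclassification accuracy is an in-sample
  description, not a generalization estimate.
* The synthetic generator's independence assumptions (between elements,
  between noise and phase) make it a test harness, not a biological model.
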