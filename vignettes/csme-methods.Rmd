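---
title: "Methods: linear-regression cell-subtype methylation estimation and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linear-regression cell-subtype methylation estimation and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csme)
```

## The problem

Whole-blood DNA methylation measurements are averages over a mixture of
leukocyte subtypes. When the quantity of interest is a *cell-subtype
specific* methylation level — not a phenotype association corrected for
composition — one must recover per-type signal from mixed-cell beta values
plus per-sample composition estimates (e.g. from FACS). `csme` implements
and stress-tests the simplest such estimator: a per-CpG simple linear
regression of mixed-cell beta on the target type's proportion.

## The model

Beta values lie in $[0,1]$. The mixed-cell value for sample $i$ at CpG $j$
is assumed to be the composition-weighted average of static per-type
profiles plus Normal noise:

$$y_{ij} = \sum_k p_{ik} x_{jk} + e_{ij}, \qquad e_{ij} \sim N(0,
\sigma_j).$$

Writing $x_{j(-k)}$ for the pooled methylation of all non-target types,
this collapses to a simple regression in the target proportion $p_{ik}$:

$$y_{ij} = \beta_{0jk} + \beta_{1jk}\,p_{ik} + e_{ij}, \qquad
\beta_{0jk} = x_{j(-k)},\; \beta_{1jk} = x_{jk} - x_{j(-k)}.$$

The slope $\hat\beta_{1jk}$ — the *LR estimate* — targets the difference
between the target type's methylation and the rest. It is judged against
the *cell-sorted estimate*, a difference of means computed from purified
(flow-sorted) samples: the mean over the $N$ target-sorted samples minus
the pooled mean over the $N(K-1)$ other sorted samples, every sample
weighted equally. Lineage groupings (sets of base types) are handled by
summing member proportions and pooling member samples.

Normal noise on the beta scale is a deliberate simplification shared by
the estimators being evaluated: beta values are bounded, so the generator
clips to $[0,1]$ and counts every clip rather than hiding the violation.
M-values are not used anywhere because the logit transform destroys the
linear-mixing identity.

## Pipeline stages and their parameters

1. **Candidate panels** (`select_candidate_panel`). Per CpG, a two-sided
   equal-variance pooled t-test of target-sorted versus other-sorted
   samples; Benjamini–Hochberg step-up control at a nominal FDR of
   $10^{-4}$ (flag `--fdr`). The strict default reflects that candidate
   CpGs should carry unambiguous cell-association signal.
2. **LR estimation** (`estimate_panel`). Ordinary least squares per CpG;
   the slope standard error is $\hat\sigma_j / \sqrt{\sum_i (p_i - \bar
   p)^2}$ with $\hat\sigma_j^2 = \mathrm{RSS}/(N-2)$. Slopes are *not*
   constrained to $[-1,1]$: they are regression coefficients, and
   out-of-range values are themselves diagnostic of failure. A post-hoc
   `truncate_slopes` option exists but is off by default and outside the
   evaluated method.
3. **Calibration** (`fit_calibration`, `calibrate`). LR estimates may be
   affinely distorted (correlated profiles shift and inflate them), so
   the LR estimates are regressed on the cell-sorted estimates over the
   *candidate* panel — before any filtering — and each estimate is mapped
   through $(\hat\beta_1 - \hat\alpha)/\hat\beta$, with standard error
   scaled by $1/|\hat\beta|$. By construction the calibrated estimates
   regress on the references with slope 1 and intercept 0.
4. **D screen** (`d_statistic`, `d_test`, `build_robust_panel`). The
   standardized discrepancy
   $D = (\text{calibrated} - \text{cell-sorted})/\mathrm{SE}(\text{calibrated})$
   is referred to a Student $t(N-2)$ distribution ($D$ is a regression
   slope up to sign); CpGs with $2P(T \ge |D|) < 0.05$ (flag `--d-alpha`)
   are discarded as inaccurately estimated. The survivors form the
   *robust panel*. No multiplicity correction is applied by default (the
   screen is a fixed per-CpG 5% rule); `d_fdr = TRUE` enables BH as an
   option.
5. **Reporting** (`summarize_panel`, `run_csme`). Per panel: size, MAE of
   calibrated estimates against references, MMCE (mean $|$reference$|$ —
   the zero-estimator baseline), $R^2$ between LR estimates and
   references, and the count/percentage of CpGs with absolute error below
   0.05 (flag `--ae-threshold`; 0.05 matches the "accurate within 5%"
   convention).

## What the synthetic generator states

The generator emulates the design of the benchmark experiment: 6
subjects, 7 flow-sortable leukocyte types (Neutrophil, Eosinophil, CD4⁺T,
CD8⁺T, CD19⁺B, CD56⁺ NK, CD14⁺ Monocyte), one sorted sample per (subject,
type), one whole-blood sample per subject. Defaults, fixed once:

* **Mean proportions** — published FACS means (Neutrophil 65.0%, CD4⁺T
  13.4%, CD8⁺T 6.1%, NK 2.4%, B 3.0%, Monocyte 5.4%, Eosinophil 3.8%).
  The printed percentages sum to 99.1 due to rounding; the generator
  renormalizes them to sum to 1.
* **Baseline betas** — drawn per CpG from levels $\{0.1, 0.5, 0.9\}$ with
  weights $(0.4, 0.2, 0.4)$, mimicking the bimodal beta distribution of
  methylation arrays.
* **Differential signal** — per type, a disjoint 5% of CpGs shifted by
  $\pm 0.4$ beta (fair-coin direction, seeded); disjointness makes each
  planted CpG's target-vs-rest contrast exactly the effect size.
  Optionally (`include_groupings = TRUE`) lineage-level sets are planted
  where all member types shift jointly, so grouping targets have genuine
  candidates; this is off by default because the base contract plants
  per-type signal only.
* **Noise** — 0.02 sd on the beta scale for both mixed samples
  (`noise_sd`) and sorted samples (`within_subject_sd`), a typical
  technical-replicate scale for 450K arrays. Values are clipped to
  $[0,1]$ with counts reported.

Two proportion designs are offered. `fixed_remainder` varies the target
fraction uniformly in $[0.5m, \min(0.95, 1.5m)]$ around its mean $m$ and
splits the remainder equally across the other types. With equal splitting
the non-target pool is *exactly* the unweighted mean of the other
profiles, so the regression estimand coincides with the cell-sorted
reference — the analytically clean world in which exact-recovery and
operating-characteristic tests are run. This design is necessarily
per-target: the non-target fractions must be affine in the target
fraction, which cannot hold for two targets at once, hence the `target`
field in the configuration. `dirichlet` draws each row from a Dirichlet
with the configured mean and concentration (default 100, giving realistic
inter-individual spread); it deliberately exposes the mismatch between
the abundance-weighted remainder in real mixtures and the unweighted
cell-sorted reference.

What a green test does **not** establish: the generator has no probe
chemistry, normalization artefacts, batch effects, SNP-collocated probes,
subject-level profile variation, or correlated noise — the main sources
of the failure modes seen on real arrays. Green means the statistical
machinery is correct under its own assumptions, not that the estimator
works on any given dataset.

## Numerical choices

* **Exact fits.** On noiseless data OLS residuals are rounding-level, not
  zero, so residuals are computed explicitly (not by the cancelling
  $S_{yy} - \hat\beta_1^2 S_{xx}$ shortcut), and a standard error below
  $10^{-10}$ is treated as an exact fit: the D statistic is 0 when the
  discrepancy is below $10^{-8}$ and $\infty$ (always rejected)
  otherwise. Without this convention D would be a ratio of rounding
  errors.
* **Degenerate t-tests.** Zero pooled variance with equal means gives
  $t = 0, p = 1$; with unequal means, an infinite statistic flagged
  `degenerate` with $p = 0$ (such CpGs are genuinely separated).
* **Calibration floor.** $|\hat\beta| < 0.05$ flags the panel
  uncalibratable (calibration would amplify noise more than 20-fold); the
  panel is then reported with every CpG unretained rather than silently
  guessed.
* **Proportion hygiene.** Percent-scale tables are auto-detected by row
  sums near 100; row sums within $10^{-6}$ of 1 pass, deviations up to
  0.02 are renormalized with a warning, larger ones error.
* **Missing betas.** A CpG with any missing value in the samples a
  computation needs is dropped from that computation with a logged count.

## Open design points resolved here

* The t-tests treat sorted samples as independent even though subjects
  are paired across types, matching the stated unpaired pooled test.
* The pooled non-target mean weights every *sample* equally (identical to
  the mean of type means only in balanced designs); formula fidelity was
  preferred.
* Calibration is fitted per target on the full candidate panel, not the
  robust subset, since the screen happens after calibration.
* Grouping candidate panels can be empty under the default per-type
  planted world (a per-type shift is diluted 1-in-$n_C$ inside a grouping
  contrast and rarely passes FDR $10^{-4}$); an empty panel yields a
  size-0 report row with `NA` metrics rather than an error.

## Limitations

Performance claims from this package are claims about the model-true
synthetic world. In particular the D screen's rejection rate is checked
against its nominal 5% level in the equal-weight design with exact
references; with noisy references or Dirichlet mixing the screen is
conservative in some regimes and anti-conservative in others, which is
precisely the sensitivity the evaluation is designed to expose.
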