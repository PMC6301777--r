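# csme — cell-subtype specific methylation estimation from mixed blood

Whole-blood DNA methylation is a composition-weighted average over
leukocyte subtypes. `csme` implements and evaluates the simplest route to
*cell-subtype specific* methylation: at each CpG, regress the mixed-cell
beta value on the target cell type's measured proportion,

```
y_ij = β0 + β1 · p_ik + e_ij ,    β1 = x_jk − x_j(−k) ,
```

so the slope estimates the difference between the target type's
methylation `x_jk` and the pooled remainder `x_j(−k)`. The package is for
epigenomics researchers who want to know *where and for which cell types*
this estimator can be trusted before using it in a cell-type-specific
EWAS.

It provides, as a tested pipeline:

* a **seeded synthetic-data generator** for paired cell-sorted /
  whole-blood beta-value datasets (6 subjects × 7 leukocyte types by
  default, linear mixing, Normal beta-scale noise, clipping counted);
* **candidate CpG panels** per cell type or lineage grouping
  (Lymphocyte-I/II, Myeloid-I/II, Pan-T) by pooled two-sample t-tests on
  sorted samples with Benjamini–Hochberg control at FDR 1e-4;
* **per-CpG OLS estimation** of the methylation difference from mixed
  data, with slopes deliberately unconstrained;
* **calibration** of the estimates against cell-sorted references and a
  **D screen** — the standardized discrepancy referred to a Student
  t(N−2) distribution — yielding a robust panel of accurately estimable
  CpGs;
* **evaluation reports**: MAE versus the MMCE zero-baseline, R², counts
  of CpGs with absolute error < 0.05, panel overlap between datasets, and
  hierarchical clustering of sorted samples on panel CpGs.

## Worked example

```r
library(csme)

cfg <- simulation_config(n_cpgs = 10000, n_subjects = 6,
                         proportion_mode = "dirichlet",
                         include_groupings = TRUE, seed = 20)
bundle <- generate_dataset(cfg)
res <- run_csme_bundle(bundle)
res$report
```

```
        target candidate_size panel_size    mae  mmce r_squared pct_accurate
    Neutrophil            779        739 0.1018 0.297     0.870        28.01
    Eosinophil            776        746 0.4527 0.290     0.217         6.57
          CD4T            794        748 0.1175 0.284     0.821        26.07
          CD8T            784        721 0.2125 0.290     0.604        14.84
         CD19B            500        478 0.3734 0.284     0.337         9.21
            NK            500        473 0.4509 0.278     0.244         8.03
      Monocyte            500        476 0.3876 0.286     0.299         7.35
  Lymphocyte-I           1982       1858 0.0996 0.238     0.829        31.38
 Lymphocyte-II           1994       1896 0.0897 0.220     0.838        33.18
     Myeloid-I           1982       1858 0.0996 0.238     0.829        31.38
    Myeloid-II           2186       2017 0.1174 0.223     0.754        24.84
         Pan-T           1671       1581 0.1017 0.223     0.801        30.87
```

Reading the report: each row is one estimation target. `candidate_size`
CpGs passed the cell-association t-test screen; `panel_size` of them
survived the D accuracy screen. `mae` is the mean absolute error of the
calibrated estimates against the cell-sorted references; `mmce` is the
error of calling every difference zero, so `mae < mmce` means the
regression beats the trivial baseline. With realistic (Dirichlet)
composition spread, the abundant Neutrophil target and the large lineage
groupings are estimated well (MAE ≈ 0.10, R² > 0.75), while rare types
such as NK and Eosinophil fail to beat the baseline (MAE ≈ 0.45 > MMCE)
— the composition signal for a 2–4% cell type is simply too weak at
N = 6. That contrast is the central behaviour this package exists to
measure. Clustering the sorted samples on the per-type candidate panels
(`cluster_sorted_samples`) recovers the cell types perfectly here
(nearest-neighbour purity 1.0).

The same pipeline is scriptable:

```sh
Rscript inst/cli/csme.R simulate --config config.yaml --out-dir bundle/
Rscript inst/cli/csme.R evaluate --sorted bundle/betas_sorted.tsv \
    --mixed bundle/betas_mixed.tsv --proportions bundle/proportions.tsv \
    --fdr 1e-4 --d-alpha 0.05 --out-dir report/
```

## Methods

See `vignettes/csme-methods.Rmd` for the model and its assumptions, the
generator's stated world, numerical conventions (exact-fit handling,
degeneracy floors, renormalization tolerances) and known limitations.
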