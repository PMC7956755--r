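# protean

Experimental-null calibrated discovery and classification of altered
proteins in label-free quantitative proteomics.

## What it is for

`protean` implements the quantitative analysis of a four-group,
two-tissue animal proteomics design — sham control (SH), mild injury
(TM), severe injury (TS), and severe injury with low-dose
methamphetamine treatment (TSm) — measured by MS1 ion-current label-free
quantification.  It is aimed at analysts who have a peptide × sample
intensity table (plus a sample annotation) and want to:

1. roll peptide ion currents up to protein-group intensities
   (dataset-wide median normalization, outlier-peptide removal,
   sum-of-ion-current aggregation, ≥2-peptides-per-protein rule);
2. call **altered proteins (APs)** with a joint fold-change / p-value
   rule whose false-positive behaviour is *measured on the data*: the
   **experimental null (EN)** splits the control group into balanced
   halves and re-runs the identical comparison, and the **false
   altered-protein discovery rate**

   `FADR(t) = mean null AP count / case AP count` at `FC ≥ t, p < 0.05`

   is evaluated over the threshold grid t ∈ {1.2, 1.3, 1.4, 1.5, 2.0}
   to pick the fold-change cutoff;
3. classify each AP by how the treated group relates to the untreated
   ones, using a row-standardized **fold-of-significance** score
   `s = log2FC × (−log10 p)` per contrast (TM/SH, TS/SH, TSm/SH) and
   Ward hierarchical clustering: **sustained** (TSm tracks TS),
   **MA-induced** (TSm tracks TM — treatment normalized the change),
   **MA-unique** (TSm resembles neither — treatment-specific);
4. produce dataset-level reports: PCA of group-ratio vectors, pairwise
   R², AP-set overlaps, volcano exports.

A first-class synthetic-data generator (`simulate_dataset()`) emulates
the study design — 39 animals per tissue (10/11/9/9), ~6500 protein
groups, 16.7% median biological CV, 5% technical CV, <0.5% protein-level
missingness, planted null/sustained/MA-induced/MA-unique patterns — and
returns a ground-truth table, so the whole pipeline is testable without
raw LC-MS data.  See the methods vignette
(`vignettes/altered-protein-discovery.Rmd`) for the model, parameter and
design discussion.

## Worked example

```r
library(protean)

cfg <- sim_config(n_proteins = 1000, n_tissues = 1, seed = 42)
sim <- simulate_dataset(cfg)
sim
#> sim_dataset: 4460 peptides / 1000 proteins x 39 samples in 1 tissue(s)
#> ma_induced  ma_unique       null  sustained
#>        100        100        700        100

res <- run_ap_pipeline(sim$peptides, sim$annotation,
                       fc_cutoff = 1.4, seed = 1)$cortex
res$cutoff
#> selected FC cutoff: 2
#>  fc_threshold worst_fadr total_case_aps qualifies
#>           1.2 0.27924528            510     FALSE
#>           1.3 0.19123711            477     FALSE
#>           1.4 0.14065934            461     FALSE
#>           1.5 0.09666667            456     FALSE
#>           2.0 0.04468085            232      TRUE
```

The FADR grid shows the trade-off the cutoff selection works with: at a
1.2-fold threshold about 28% as many APs appear in control-vs-control
splits as in the real comparison, falling to 4.5% at 2-fold.  The
half-sized null comparisons make the estimate conservative (see the
vignette), so the auto-selected threshold errs high; here the study's
calibrated 1.4-fold cutoff is fixed with `fc_cutoff = 1.4`.

```r
vapply(res$aps, function(a) nrow(a$members), integer(1))
#>  TM  TS TSm
#>  91  95 275
table(res$classes$category)
#> ma_induced  ma_unique  sustained
#>         86        110         86

ap_recall(res$aps, sim$truth)$recall            # planted effects found
#> [1] 0.896
category_recovery(res$classes, sim$truth)$recovery_of_planted
#> [1] 0.847

res$validation$summary[, c("category", "n", "mean_abs_log2_tsm_tm",
                           "mean_abs_log2_tsm_ts", "pass")]
#>     category   n mean_abs_log2_tsm_tm mean_abs_log2_tsm_ts pass
#> 1  sustained  86            0.9812538           0.09752571 TRUE
#> 2 ma_induced  86            0.1155008           1.01230623 TRUE
#> 3  ma_unique 110            0.9694233           0.91598331 TRUE
```

TSm is the most altered group (275 APs) because all three planted
patterns touch it.  About 90% of planted effects are recalled at the
1.4-fold cutoff and ~85% of planted proteins land in their true
category.  The validation table shows the expected scatter geometry:
sustained APs move almost entirely in the TSm/TM dimension (treatment
did not move them off the severe pattern), MA-induced APs in the TSm/TS
dimension (treatment pulled them back toward mild), MA-unique APs in
both.

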