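# metabrsvd

Robust identification of metabolomic biomarkers from two-group
(disease/control) intensity matrices that contain **both missing values and
outlying cells** — the two defects that mass-spectrometry metabolomics data
almost always carry at the same time, and that standard imputation methods
handle one at a time at best.

## What it does

Given a metabolite × sample matrix `X` with missing cells and a two-group
sample design, the pipeline:

1. **Partitions** `X = (X₁ X₂)` by sample group, so group differences are
   never mistaken for outliers or smeared by a global fit.
2. **Flags outlying cells** per metabolite within each group by the IQR rule
   (outside `[Q1 − 1.5·IQR, Q3 + 1.5·IQR]`), with a second, median/MAD-based
   pass against robust-fit residuals that keeps working when a metabolite's
   contamination overwhelms its quartiles.
3. **Fits a robust SVD** `X_g ≈ U Λ Vᵀ` to each group by sequential
   alternating L1 (least-absolute-deviation) regression — every update is a
   weighted median over observed cells, so isolated gross values carry no
   leverage — treating missing ∪ flagged cells as unobserved. The rank `r`
   is the smallest number of components explaining ≥ `(1 − α)·100%` of the
   variation (α = 0.05), after a permutation-based noise floor removes
   components indistinguishable from chance.
4. **Reconstructs** `X̂ = (X̂₁ X̂₂)`: clean observed cells pass through
   bit-identical; missing and flagged cells are replaced by their rank-r
   approximation `λ₁u₁v₁ᵀ + … + λ_r u_r v_rᵀ`.
5. **Calls differential metabolites** on `X̂` by a pooled-variance Student
   t-test with Bonferroni threshold `α/p` and an absolute fold-change cut
   (`|log₂ FC| ≥ 1`); direction (up/down in disease) follows the FC sign.
6. **Ranks the DE set** by linear-SVM recursive feature elimination and
   selects a biomarker panel (top up- and downregulated markers), scored by
   stratified five-fold cross-validated SVM classification.

Baseline imputers (zero, k-nearest-neighbour, iterative random forest), the
ANOVA-model simulation generator, and RMSE/ROC/AUC benchmarking utilities
are included, so the method can be compared against the usual alternatives
on data with known truth.

## Worked example

```r
library(metabrsvd)

sim <- simulate_dataset(sim_config(missing_rate = 0.10, outlier_rate = 0.05,
                                   seed = 1))
fit <- identify_biomarkers(sim$matrix, sim$design, log2_data = TRUE, seed = 1)
print(fit)
```

```
Robust metabolomic biomarker identification
groupwise robust-SVD reconstruction: 500 x 80
  ranks: control = 1, disease = 1
  cells replaced: 6238 (4000 missing, 2238 flagged as outliers)
de_table: 500 metabolites, 30 called DE ( 15 up, 15 down); Bonferroni threshold 1e-04
 metabolite_id  t_stat      p_value fold_change  log2_fc direction is_de
            m1  -7.610 5.344469e-11       3.119 1.640903        up  TRUE
            m2 -10.508 1.343531e-16       5.540 2.469959        up  TRUE
 ...
biomarker panel:
  up:   m2, m15, m6, m13
  down: m122, m135
5-fold CV: accuracy 100.00%, sensitivity 100.00%, specificity 100.00%, PPV 100.00%, NPV 100.00%, balanced 100.00%
```

The generator plants 15 upregulated (rows 1–15) and 15 downregulated
(rows 121–135) metabolites among 470 equally expressed ones; here the
pipeline reconstructs the matrix at rank 1 per group, recovers all 30
planted metabolites at the Bonferroni + fold-change thresholds, and the
selected six-marker panel separates the 45 control from the 35 disease
samples perfectly in cross-validation.

The same steps run from a shell:

```sh
Rscript inst/cli/metabrsvd.R simulate --missing-rate 0.1 --outlier-rate 0.05 \
    --seed 1 --out-dir sim/
Rscript inst/cli/metabrsvd.R identify --matrix sim/matrix.csv \
    --design sim/design.csv --log2-data --seed 1 --out-dir results/
```

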