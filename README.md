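# hemomil

Attention-based multiple-instance learning (MIL) for peripheral blood smear
cytomorphology in R.

## The problem

A blood smear yields hundreds of single-cell images per patient, but the
diagnosis — acute leukemia, MDS, MDS/MPN, MPN, lymphoma, plasma cell
neoplasm, reactive changes, or healthy — is a property of the patient, not
of any single cell. hemomil treats each patient as a *bag* of single-cell
embedding vectors (produced by an external image encoder) and learns a
permutation-invariant set-transformer aggregator:

* a learnable aggregation token attends over the cell tokens across
  pre-norm transformer layers (no positional encodings — cells are a set);
* a multi-task head predicts probabilities for the 8 coarse diagnostic
  classes plus the patient's hemoglobin (auxiliary regression, z-scored on
  the training folds), trained with
  `CE(class) + w_hb * squared_error(hb)`;
* the **malignancy probability** is the sum over the six malignant classes
  (equivalently `1 − p(reactive) − p(healthy)`); a bone marrow biopsy is
  recommended when it strictly exceeds a tunable threshold (default 0.5);
* the aggregation token's final-layer attention row (head-averaged,
  renormalized over cells) is exported as per-cell diagnostic relevance.

Around the model the package provides a configurable three-level label
hierarchy (raw label → detailed class → coarse class, with malignancy
flags), stratified k-fold cross-validation with probability-level
ensembling, a triage threshold sweep (malignancy sensitivity/specificity,
unnecessary-aspiration FDR, acute-leukemia sensitivity), a full evaluation
suite (confusion analysis, top-k accuracy, rank-based AUROC, top-label
expected calibration error, hemoglobin agreement,
probability-vs-cell-ratio correlations), per-cell attention explanations,
and a synthetic cohort generator with class-conditioned cell-type mixtures
so the whole pipeline runs end to end without any clinical data. The
forward and backward passes of the transformer are implemented directly in
base-R matrix algebra (no autograd dependency) and verified against finite
differences in the test suite.

## Worked example

```r
library(hemomil)

h <- default_hierarchy()
map_label(h, "ET")
#> $detailed
#> [1] "ET"
#> $coarse
#> [1] "MPN"
#> $malignant
#> [1] TRUE

# synthetic cohort: 120 patients, 100 cells per bag, 32-dim embeddings
cohort <- generate_cohort(120, n_cells = 100, seed = 1,
                          embedding_dim = 32, separation = 5)

cfg <- mil_config(embedding_dim = 32, latent_dim = 64, n_heads = 4,
                  n_layers = 2, dropout = 0.1)
fit <- hemomil(cohort$manifest, cohort$bags, cfg, k = 2,
               params = train_params(epochs = 25, bag_size = 64), seed = 1)
fit
#> <hemomil> ensemble of 2 transformer aggregator(s)
#>   2-fold cross-validation, 120 patients, 8 classes
#>   config: dim 32 -> latent 64, 2 layer(s) x 4 head(s)

report <- evaluate_predictions(predict(fit, oof = TRUE), cohort$manifest, h)
report
#> Evaluation report (120 patients)
#>   accuracy 0.733  top1 0.733  top2 0.883
#>   malignancy AUROC 0.954   ECE 0.045
#>   hemoglobin: Pearson 0.752, MAE 1.25 g/dL
#>   Spearman(acute-leukemia prob, blast ratio) 0.581
#>   largest threshold with full acute-leukemia sensitivity: 0.99 (FDR 0.000)
#>   per-class sensitivity:
#>     acute leukemia         1.000
#>     MDS                    0.111
#>     ...
```

The out-of-fold accuracy is the fraction of patients whose true coarse
class tops the predicted probability vector when predicted by the one
ensemble member that never saw them; the AUROC scores the summed
malignancy probability against the true malignant/non-malignant split; the
threshold line reports how far the biopsy threshold can be raised before
an acute-leukemia patient would be missed on this cohort, and the
aspiration FDR (fraction of recommended biopsies whose true class is
non-malignant) achieved there. At this deliberately small scale (120
patients, 2 folds, 25 epochs) the rare and composition-overlapping classes
(MDS, plasma cell neoplasm) are still poorly resolved; the acceptance
study below trains the full 400-patient, 5-fold configuration where
overall accuracy reaches ~0.93.

Per-cell explanation of one patient:

```r
explain(fit, cohort$bags[[3]], h)
#> <attention_report> patient P0003
#>   top class: lymphoma (0.904); malignancy probability 0.988
#>   predicted hemoglobin 11.35 g/dL
#>   100 cells; attention entropy 4.55 nats (uniform = 4.61)
#>   most-attended cells:
#>     cell   80  attention 0.0228  lymphocyte -> lymphoma
#>     cell   96  attention 0.0193  promyelocyte -> MDS/MPN
#>     cell   74  attention 0.0187  lymphocyte -> lymphoma
#>     cell   39  attention 0.0183  monocyte -> MDS/MPN
#>     cell    4  attention 0.0175  lymphocyte -> lymphoma
```

`top_cells(rep, m)` returns the `m` most-attended cell indices (ties by
ascending index); the entropy line shows how far the attention
distribution is from uniform.

A command-line front end over the same functions lives at
`inst/cli/hemomil.R`:

```sh
Rscript inst/cli/hemomil.R simulate --out sim --patients 64 --cells 100 --dim 32 --seed 1
Rscript inst/cli/hemomil.R train --manifest sim/manifest.csv --bags sim/bags.rds \
    --out run --latent 64 --heads 4 --folds 5 --seed 1
Rscript inst/cli/hemomil.R evaluate --predictions run/oof_predictions.csv \
    --manifest sim/manifest.csv --out eval
```

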