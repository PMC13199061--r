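# cmsurv — contrastive multimodal survival modelling for glioma cohorts

Lower-grade (WHO grade 2/3) glioma outcomes depend jointly on tissue
morphology, somatic mutations and clinical factors. `cmsurv` is an R
implementation of a contrastive multimodal survival framework for such
cohorts, built for methodologists and biostatisticians who want to
study, stress-test or extend this class of model without GPU
infrastructure or access to patient data:

- **Encoders** — hierarchical MLP encoder for binary mutation vectors
  plus clinical covariates; gated attention pooling of per-patient
  histopathology tile embeddings (any external tile encoder can be
  plugged in through a plain-text embedding store; a deterministic stub
  encoder for RGB images is included).
- **Three-stage training** — stage 1 fits each modality with the Cox
  negative log partial likelihood
  `-(1/N_event) Σ_i [ h(x_i) − log Σ_{j∈R(T_i)} exp(h(x_j)) ]`
  (Breslow risk sets `R(T_i) = {j : T_j ≥ T_i}`); stage 2 aligns the
  modalities with a symmetric InfoNCE objective over unit-norm
  projections combined as `InfoNCE + λ·Cox`; stage 3 trains a fused
  risk head on the concatenated pre-projection embeddings.
- **Evaluation** — event-stratified, leakage-safe 5-fold
  cross-validation; Harrell's c-index (C++ kernel) with percentile
  bootstrap CIs and paired bootstrap model comparison; median-split
  Kaplan–Meier with log-rank; silhouette of embeddings by 5-year
  survival status with a paired fold t-test; rank-standardised fold
  ensembling; zero-shot versus 20%/10-epoch fine-tuned evaluation on
  external cohorts.
- **Interpretation** — LASSO selection followed by OLS with Wald
  t-tests on the fused model's predicted risk (p-values labelled
  post-selection, nominal).
- **Synthetic cohorts** — `generate_cohort()` produces multimodal
  cohorts with known ground-truth hazard structure (exponential
  proportional hazards, numerically calibrated independent censoring,
  latent image risk classes as embedding clusters), so every stage of
  the pipeline is testable end to end.

## Worked example

```r
library(cmsurv)

cohort <- generate_cohort(high_signal_config(seed = 1))
cohort
#> <cms_cohort> 500 patients, 300 genes, 3 clinical variables, 37.2% events

cfg <- training_config(epochs = c(stage1 = 40, stage2 = 15, stage3 = 40),
                       seed = 1, early_stopping_patience = 8)
cv <- cross_validate(cohort, cfg, make_folds(cohort$outcomes, 5, seed = 1))
cv
#> <cms_cv_result> 5 folds (contrastive)
#>   mean val c-index: fused 0.761 | image 0.73 | non-image 0.666

ens <- ensemble_risk(cv, cohort)
median_split_logrank(ens, cohort$outcomes)$p_value
#> [1] 4.639586e-56
```

Reading the numbers: the fused 5-fold validation c-index (0.761) beats
both unimodal models (image-only 0.730, non-image-only 0.666) — a
c-index of 0.5 is random ranking, 1.0 perfect — on a cohort whose
generating linear predictor tops out near 0.9. The log-rank p-value
confirms that splitting patients at the median ensemble risk separates
the survival curves. Matched-pair cross-modal cosine similarity rises
from 0.011 to 0.081 over the contrastive stage (`cv$cosine`).

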