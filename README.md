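# cicradiomics

Radiogenomic texture analysis of **CIC mutation status in lower-grade
glioma (LGG)**, as a tested, reusable R pipeline.

CIC — the human homolog of Drosophila *capicua*, a transcriptional
repressor on 19q — is mutated in roughly a fifth of LGG, almost
exclusively within the IDH-mutant, 1p/19q-codeleted (oligodendroglioma)
genotype, and carries prognostic value. The package asks whether whole-
tumor 3D texture statistics computed from multi-sequence MR volumes
(T1W, T1CE, T2W, FLAIR) predict CIC status, and provides every stage
needed to study that question end to end:

* **genomics** — mutation calling from MAF-like variant tables
  (missense/frameshift/nonsense qualify), arm-level deletion from
  SEG-like copy-number tables (segment mean < −0.2, length-weighted
  majority per arm), 1p/19q codeletion and the 2016 WHO class;
* **statistics** — Pearson chi-square (no continuity correction),
  exact/normal Mann-Whitney U, Kaplan-Meier with median OS, log-rank,
  multivariate Cox (Efron ties);
* **image transforms** — white-stripe intensity normalization, one-level
  Coiflet-1 wavelet sub-bands (LLL…HHH), monotone pointwise maps,
  gradient magnitude, rotation-invariant 2D/3D local binary patterns;
* **texture features** — first-order statistics plus the GLCM, GLSZM,
  GLDM and NGTDM families over a discretized tumor ROI, every matrix
  builder verified against brute-force oracles;
* **stability selection** — Lasso on the 0/1 label, penalty chosen by
  stratified 5-fold CV, repeated 100× with re-shuffled folds; features
  ranked by selection count and truncated to the top `round(√n)`;
* **prediction** — class-weighted logistic regression
  (`w = n/(2·n_class)`), evaluated over 1,000 stratified 80/20 splits
  with averaged ROC/PR curves, corner-distance optimal cutoffs,
  coefficient-sum importance, U-test screening and exemplar selection;
* **synthetic cohort** — a generator of genomic/clinical tables,
  proportional-hazards survival, and co-registered multi-sequence NIfTI
  volumes with label-dependent tumor texture (mutant = larger, more
  heterogeneous), so the whole pipeline is testable with no downloads.

The core prediction model is plain logistic regression,
`h_θ(x) = 1 / (1 + e^(−z))` with `z = θ₀ + Σ θᵢ xᵢ` on z-scored
radiomics features, with class weights `n_samples / (n_classes · n_class)`
correcting the ~4:1 wild-type/mutant imbalance.

## Worked example

```r
library(cicradiomics)

cfg <- sim_config(n_patients = 80, seed = 11)      # synthetic LGG cohort
gen <- generate_genomic_cohort(cfg)
mean(gen$truth$cic)                                 # 0.225 (target 22.8%)

# genomic calling recovers the simulated truth exactly
st <- genomic_status_table(gen$variants, gen$segments, gen$cohort$patient_id)
all(st$cic == gen$truth$cic)                        # TRUE

# survival by CIC status
km_estimate(gen$cohort$os_days[gen$cohort$cic == 1],
            gen$cohort$os_event[gen$cohort$cic == 1])$median   # 1628 days
km_estimate(gen$cohort$os_days[gen$cohort$cic == 0],
            gen$cohort$os_event[gen$cohort$cic == 0])$median   # 1183 days

# images -> features -> stability selection -> repeated-split evaluation
imgs <- generate_image_cohort(cfg, gen$truth$cic)
X <- extract_feature_table(imgs, transforms = "original")
X <- X[, apply(X, 2, sd) > 0]                       # 268 features, 80 patients
sel <- repeat_selection(X, gen$truth$cic, repetitions = 25, master_seed = 12)
keep <- truncate_top_sqrt_n(sel, nrow(X))           # round(sqrt(80)) = 9
ev <- repeated_split_evaluate(X[, keep], gen$truth$cic,
                              repetitions = 100, master_seed = 13)
round(ev$summary, 4)
#>             mean ci_low ci_high
#> accuracy       1      1       1
#> sensitivity    1      1       1
#> specificity    1      1       1
#> roc_auc        1      1       1
#> pr_auc         1      1       1
```

The synthetic generator's default texture/size coupling is strong by
design, so the classifier saturates on clean synthetic data — the means
and their 95% CIs above are exactly 1. The U-test screen then keeps the
top-third significant features (here three, all with p ≈ 1.3e−10):

```r
ut <- u_test_and_top_third(X[, keep], gen$truth$cic, ev$importance)
ut[ut$kept, c("feature", "p", "rank")]
```

Feature names encode provenance, e.g.
`T2-wavelet-LHL_glszm_SizeZoneNonUniformityNormalized` = T2 sequence,
wavelet LHL sub-band, GLSZM family, size-zone nonuniformity (normalized);
lower SZNN means a more homogeneous zone structure.

The one-call version of all of the above, with artifacts and a hashed
manifest:

```r
cfg <- pipeline_config(sim = sim_config(n_patients = 60), seed = 1)
run_pipeline(cfg, "artifacts/")   # cohort.csv, features.csv, selection.tsv,
                                  # evaluation.json, exemplars.json, ...
```

A small CLI wrapper lives at `inst/cli/cicradiomics.R`
(`simulate`, `run-all`, `config` subcommands).

## Methods

See `vignettes/methods.Rmd` for the models, parameter conventions,
degenerate-case rules, what the synthetic generator does and does not
emulate, and known limitations.
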