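# pdmedit

Instance selection and ensemble classification for tabular biomedical
feature data in which each subject contributes many samples of uneven
quality — the situation typical of dysphonia-based Parkinson's disease
screening, where every person records dozens of short speech samples
(sustained vowels, numbers, sentences, words) and each recording is
summarized as an acoustic feature vector. Two statistical obstacles
dominate: some samples do not reflect their subject's class and mislead
classifiers trained on them, and samples are strongly clustered by
subject, so naive cross-validation leaks within-subject information.

`pdmedit` provides:

- **MENN editing** (`multi_edit()`): iterative multi-edit
  nearest-neighbor instance selection. The training samples are randomly
  split into *s* subsets; each subset is classified by a k-NN trained on
  the next subset (circularly), misclassified samples are deleted, and the
  procedure repeats with fresh partitions until a pass removes nothing.
  The edited reference set approaches one on which the NN rule attains the
  Bayes floor: with posteriors *p* and *M* editing stages the conditional
  error is `1 - sum(p^(2^M + 1)) / sum(p^(2^M))`, monotonically decreasing
  from the classical `1 - sum(p^2)` toward `min(p)`
  (`asymptotic_edit_error()`).
- **A closed-form decorrelated RVFL ensemble** (`dnne_train()`): *M*
  random-hidden-layer networks whose output weights are solved jointly
  from the hidden-correlation system `H_corr B_ens = T_h`, where same- and
  cross-network co-activation blocks are weighted by
  `C1 = 1 - 2λ(M-1)²/M²` and `C2 = 2λ(M-1)/M²`. The decorrelation
  strength λ trades individual fit against ensemble diversity; λ = 0
  decouples into independent least squares. No gradient descent anywhere.
- **Pipelines** (`train_pipeline()`): MENN editing composed with a
  backend — `dnne`, random forest (500 trees), linear/RBF SVM, or
  deterministic k-NN — with one master seed determining everything.
- **Subject-aware evaluation** (`run_loo()`, `run_loso()`,
  `run_independent()`): leave-one-out, leave-one-subject-out (LOO
  predictions aggregated per subject by majority vote), and the
  subject-independent protocol that excludes the test subject's samples
  from training entirely; plus repeated-run Mean/Std/Best summaries
  (`repeated_runs()`) and Welch t-tests between algorithms
  (`compare_algorithms()`).
- **A subject-clustered synthetic generator** (`generate_synthetic()`)
  emulating the reference data's 2 × 20 × 26 × 26 shape with a
  controllable fraction of contaminated, non-discriminative samples.
- **Readers for the public UCI speech-feature tables** (`read_sakar()`)
  with configurable column layouts.

## Worked example

```r
library(pdmedit)

# Synthetic cohort shaped like the reference data: 20 patients + 20
# controls, 26 samples each, 26 features, 15% contaminated samples.
ds <- generate_synthetic(synthetic_config(seed = 42))
ds
#> pd_dataset: 1040 samples, 40 subjects, d = 26 features
#>   subjects per class: healthy 20, patient 20

# MENN editing + decorrelated RVFL ensemble
cfg <- pipeline_config("dnne", use_menn = TRUE,
                       backend_params = list(M = 5L, L = 20L, lambda = 0.5),
                       seed = 42)
fit <- train_pipeline(ds, cfg)
fit
#> pd_pipeline [MENN + dnne]: trained on 911/1040 samples (healthy 520->459, patient 520->452)
fit$edit_trace
#> menn_trace: 911/1040 samples retained after 10 iteration(s); converged

# Subject-independent cross-validation: per-subject folds, so the model
# never sees any sample of the subject it predicts.
run_independent(ds, cfg, level = "subject")
#> cv_result [independent_subject], 1040 samples
#>   sample  metrics: ACC 0.8125  SEN 0.8288  SPE 0.7962  (TP 431 FN 89 TN 414 FP 106)
#>   subject metrics: ACC 0.9250  SEN 1.0000  SPE 0.8500  (TP 20 FN 0 TN 17 FP 3)
```

Editing converged after removing 129 samples (heavily enriched for the
generator's contaminated ones), and majority voting lifts 81% per-sample
accuracy to 92.5% per-subject accuracy — voting suppresses the errors
caused by each subject's few non-discriminative samples.

A command-line wrapper ships at
`system.file("cli", "pdmedit.R", package = "pdmedit")` with `simulate`,
`edit`, `evaluate` and `compare` subcommands; every output carries a
provenance sidecar (resolved config, seeds, digests) sufficient to
reproduce it.

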