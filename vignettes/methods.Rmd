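---
title: "Instance selection and decorrelated ensembles for subject-clustered biomedical data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Instance selection and decorrelated ensembles for subject-clustered biomedical data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdmedit)
```

## The problem

Dysphonia-based screening for Parkinson's disease records many short speech
samples per person — sustained vowels, numbers, sentences, words — and
summarizes each recording as a fixed-length acoustic feature vector. Two
properties of such data dominate the statistics:

1. **Not every sample is informative.** Some recordings of a patient sound
   healthy and some recordings of a healthy speaker look pathological in
   feature space. These non-discriminative samples sit inside the opposite
   class's region and systematically mislead classifiers trained on them.
2. **Samples are clustered by subject.** Inter-speaker variability is large
   relative to within-speaker variability, so two samples of one person are
   far more alike than two samples of two people. Any evaluation that lets
   a subject's samples appear on both sides of a train/test split inherits
   a large optimistic bias.

`pdmedit` addresses the first problem with multi-edit nearest-neighbor
instance selection, couples it to ensemble classifiers (including a
closed-form decorrelated RVFL ensemble), and addresses the second with
subject-aware evaluation protocols.

## Multi-edit nearest-neighbor editing

`multi_edit()` iterates three steps until a pass removes nothing:

1. randomly partition the current samples into `s` subsets (default
   `s = 4`), sizes differing by at most one;
2. classify each subset with a k-NN classifier (default `k = 1`, the
   classical multi-edit choice) trained on the *next* subset, circularly,
   and mark every misclassified sample;
3. delete the marked samples and merge the survivors.

Because validation and training subsets are disjoint, no sample judges
itself; repeatedly removing cross-subset misclassified points empties the
class-overlap regions, and the retained set approaches one on which a
nearest-neighbor rule behaves like the Bayes-optimal rule. The package
exposes this asymptotic argument as `asymptotic_edit_error()`: with class
posteriors $p = (p_1, p_2)$ at a point and $M$ editing stages, the
conditional error of the edited NN rule is

$$P_M(e \mid x) = 1 - \frac{\sum_i p_i^{\,2^M + 1}}{\sum_i p_i^{\,2^M}},$$

which equals the classical asymptotic NN error $1 - \sum_i p_i^2$ at
$M = 0$, decreases monotonically in $M$, and converges to the Bayes floor
$\min(p_1, p_2)$. A variant exponent ($2^{M+1}$ in the numerator) that
appears in some published accounts is available as `form = "printed"`;
that form tends to 1 rather than to the Bayes floor (for equal posteriors
it gives $1 - 0.5^{2^M}$), so the limit-consistent form is the default and
the other is provided for comparison only. Since $p^{2^M}$ underflows
double precision long before the limit regime, evaluation shifts by the
dominant posterior before exponentiating; doubling the exponent is then
exact in binary floating point, which is what makes the monotonicity
testable at machine precision.

Numerical and degenerate-input choices:

* **Tie rules.** Distance ties resolve to the lowest training index; even-k
  vote ties resolve toward the patient class. Both are arbitrary but fixed,
  making every trace bit-reproducible.
* **Fresh partitions.** Each outer iteration draws a new partition with a
  seed derived from the trace seed and the iteration index; "repeat the
  steps" includes the partition step.
* **Viability guard.** On heavily overlapped data the pure stopping rule
  ("iterate until no removals") can empty a class. A pass that would do so
  is not applied; the trace is flagged and marked unconverged. The
  iteration cap (`max_iter = 20`) bounds runtime the same way.
* **Standardization.** Editing is Euclidean, so features are z-scored
  (population-sd convention; constant features get scale 1) before
  distances are computed. This matters: scaling is fitted per training
  fold, never on test data.

## The decorrelated RVFL ensemble

`dnne_train()` fits `M` single-hidden-layer networks whose hidden weights
and biases are drawn once from Uniform(−1, 1) and never trained (random
vector functional link networks). Only the output weights are learned, and
they are learned *jointly*: a negative-correlation penalty with strength
$\lambda \in [0, 1]$ couples the networks, trading each network's
individual fit against ensemble diversity. Setting the gradient of the
penalized least-squares objective to zero collapses the problem to one
linear system

$$H_{corr} \, B_{ens} = T_h,$$

where, with co-activation sums
$\varphi(i,j,k,l) = \sum_n g_{ij}(x_n)\, g_{kl}(x_n)$ and
$\varphi(i,j) = \sum_n g_{ij}(x_n)\, y_n$, the entry of $H_{corr}$ for flat
indices $p, q$ is $C_1 \varphi$ when both indices belong to the same
network and $C_2 \varphi$ otherwise, with

$$C_1 = 1 - 2\lambda \frac{(M-1)^2}{M^2}, \qquad
  C_2 = 2\lambda \frac{M-1}{M^2}.$$

The flat ordering is network-major ($m = \lceil p/L \rceil$,
$n = ((p-1) \bmod L) + 1$; `index_map()` / `flatten_index()`), and the
matrix admits the structural identity

$$H_{corr} = (C_1 - C_2)\,\mathrm{blockdiag}(G_i^\top G_i)
  + C_2\, G^\top G,$$

which the test suite uses as an independent construction oracle. Two
consequences are worth noting. `C1 + (M-1)*C2 = 1` identically — the
implementation groups the arithmetic so the identity holds *exactly* in
floating point. And $C_1 < 0$ for large $\lambda$ and $M$, so $H_{corr}$
can be indefinite or near-singular; `solve_output_weights()` therefore
tries a direct dense solve first (trusted when the reciprocal condition
number exceeds `1e-12`), escalates through ridge jitter
$\varepsilon \cdot \overline{\mathrm{diag}(H)} \cdot I$ with
$\varepsilon = 10^{-8} \ldots 10^{-2}$, and falls back to a Moore–Penrose
pseudo-inverse, recording every step in the model's `solver_note`.

Choices the equations do not dictate:

* Targets are the 0/1 class codes used as regression responses; the
  ensemble score of a point is the *mean* of the base-network outputs and
  the decision threshold is 0.5 (configurable). At $\lambda = 0$ the system
  is block-diagonal and the joint solution equals `M` independent
  per-network least-squares fits — a second oracle used by the tests.
* Hidden parameters are drawn independently per (network, neuron) pair;
  sharing weights across networks would make decorrelation meaningless.
* No direct input–output links are included: the correlation system
  contains hidden-neuron terms only.
* An optional per-network bagging mode (`bag_fraction < 1`) restricts each
  network's correlation sums to a row subsample; the default is the shared
  full training set, because the joint system sums over a single sample
  set.
* `dnne_grid_search()` scans `M` in 2–15, `L` in 5–50 and `lambda` in
  0–1 by 0.1 (the conventional ranges) under subject-grouped inner CV,
  breaking score ties toward the smallest `M`, then `L`, then `lambda`.
  The full grid is 7084 cells; the package accepts any sub-grid and the
  examples use small ones.

## The composite pipeline

`train_pipeline()` chains editing and classification: MENN runs on the
training fold (always on standardized features), removed samples are
dropped, and one of five backends is trained on the survivors — `dnne`,
`rf` (random forest, 500 trees, $\sqrt{d}$ features per split), libsvm
`svm_linear` / `svm_rbf`, or the package's deterministic `knn`. Trees are
scale-invariant, so `rf` defaults to raw features while the distance- and
sigmoid-based backends standardize. A single config seed deterministically
fans out (via a fixed affine congruence, `derive_seed()`) into the MENN
partition stream, the backend seed, and per-fold seeds, so a
(dataset, config) pair fully determines every prediction, random-forest
and DNNE included.

Subject decisions are majority votes over a subject's sample predictions
(`predict_subjects()`). With an even per-subject sample count a 13–13 tie
is possible; the default tie rule calls the subject a patient (favoring
sensitivity in a screening context), with `healthy` and `by_mean_score`
variants available.

## Evaluation protocols

`run_loo()` retrains the *entire* pipeline — editing included — inside
every fold; editing the full dataset before splitting would leak selection
information. `run_loso()` aggregates the per-sample LOO predictions per
subject by majority vote: training folds still contain the test sample's
subject-mates, which is precisely the leakage that makes LOSO optimistic.
`run_independent()` removes it by holding out all samples of one subject
per fold. The contrast between the two is a measurement, not a nuisance:
on synthetic data with strong subject effects the LOO-minus-independent
accuracy gap is large and strictly positive, and it vanishes when the
subject effect is switched off (`sigma_subj = 0`).

Metrics treat patient as the positive class. Zero-denominator rates (e.g.
specificity on an all-patient test set) propagate as `NA` and are excluded
from summaries with a logged count, never coerced to 0.
`repeated_runs()` re-randomizes both the editing partitions and the
backend per run (seeds `base_seed + 1 ... + n_runs`) and reports the
conventional Mean/Std/Best layout; `compare_algorithms()` applies Welch's
two-sided t-test to run-level metrics. The choice of Welch over a paired
or rank test is a documented default — run-level metric lists are short
(typically 10), unpaired by construction when seeds differ, and
heteroscedastic across algorithms. When both run sets are constant the
statistic is undefined; equal constants report p = 1, unequal p = 0, both
flagged degenerate. Its type-I error at the 5% level, measured by
comparing independent run sets of the same stochastic pipeline 200 times,
sits at the nominal rate (the acceptance script recomputes this).

## The synthetic generator

`generate_synthetic()` emulates the structure of the reference dysphonia
dataset: 2 classes × 20 subjects × 26 samples × 26 features. Class 1
subjects' centers are displaced by `delta_sep` along the first coordinate;
subject centers get an isotropic Gaussian offset (sd `sigma_subj`), samples
an isotropic within-subject noise (sd `sigma_noise`). A fraction `rho` of
each subject's samples (rounded down, so 3 of 26 at the default
`rho = 0.15`) is *contaminated*: drawn from the opposite class's marginal
distribution — fresh subject effect included — while keeping the subject's
label. This models non-discriminative recordings rather than label noise,
and gives editing a removable target population whose ground truth the
generator records in an `is_contaminated` column.

Default calibration, chosen once: `sigma_subj = 1.5`, `sigma_noise = 1`,
`delta_sep = 9`. The subject effect dominating the within-subject noise
reflects inter-speaker variability in acoustic features, and the
separation is set so the package's classifiers operate in the reference
accuracy band — subject-independent 1-NN around 60–70% sample accuracy,
with editing converging while retaining most samples and the removals
strongly enriched for contaminated ones. A geometry this generator does
*not* reproduce: real acoustic features spread class signal over many
correlated coordinates, while here it lives on one coordinate of 26. With
the separation scaled to a single-sample Bayes error of 0.25, a
finite-sample Euclidean NN on 26 dimensions is blind to it (accuracy
~50%), so small Bayes-error calibrations are useful for testing the
generator's geometry but not for exercising the classifiers. Passing
tests on this generator therefore demonstrate the algorithms' contracts
and qualitative behavior (editing benefit, leakage gap, voting gain), not
performance on real speech features. Other unmodeled features of real
data: per-feature scale heterogeneity (handled by the scalers, untested
by isotropic data), sample-kind structure (vowels vs words), and
class-imbalanced subject counts.

## Problem sizes used by the tests and acceptance script

Simulation sizes are chosen to estimate each property with adequate
precision at interactive runtimes: 20 replicate seeds × 800 training
samples for the 1-D Gaussian editing study (Bayes floor
$\Phi(-1) = 0.1587$); the full 1040-sample default generator shape for
the contamination and editing studies (5–10 paired seeds); 10 subjects ×
10 samples × 10 features for the leakage-gap study (where leave-one-out
is 200 pipeline fits per run); and 200 null repetitions of 6-vs-6 run
comparisons for the calibration study. The acceptance script
(`scripts/acceptance.R`) recomputes all headline quantities from scratch
at these sizes from a single `--seed`.

## Known limitations

* Binary classification only; no probability calibration, no ROC/AUC.
* No feature selection or transformation stages; inputs are assumed to be
  precomputed feature vectors (no audio processing).
* The editing classifier is Euclidean k-NN; data whose scale structure is
  not captured by per-feature z-scoring (heavy tails, strong feature
  correlation) may edit poorly.
* The closed-form ensemble solve is $O((ML)^3)$; the conventional grid
  upper corner ($M = 15$, $L = 50$) means a 750 × 750 solve per fit,
  which is fine alone but expensive across the 7084-cell full grid with
  inner CV.
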