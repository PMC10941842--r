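---
title: "Fuzzy-state analysis of dynamic functional connectivity: models and methods"
author: "fuzzyconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy-state analysis of dynamic functional connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Dynamic functional network connectivity (dFNC) analysis summarizes a
resting-state fMRI recording as a sequence of short-time correlation
patterns between brain components, and then describes each participant by
the "states" those patterns visit. The common pipeline hard-clusters all
windows (k-means) and extracts occupancy and transition features from the
resulting label sequence. Hard assignment discards how strongly each window
expresses a state: two windows near each other in connectivity space can be
split across distant centroids, and a participant who never expresses a
state crisply contributes nothing to that state's features. `fuzzyconn`
implements the fuzzy alternative: fuzzy c-means assigns every window a
probability of belonging to each state, explainability metrics quantify
which connectivity pairs drive the clustering, and a family of dynamical
features summarizes the resulting probability trajectories. Everything is
validated end-to-end on synthetic data with planted ground truth.

## Windowed connectivity

Connectivity is the Pearson correlation of component time courses inside a
tapered sliding window: a rectangle of `rect_len` TRs convolved with a
Gaussian of standard deviation `sigma` TRs, truncated at `truncation` TRs
on each side, normalized to sum to one. Defaults are `rect_len = 20`
(40 s at TR = 2 s), `sigma = 3` and `truncation = 7`, so the window spans
34 TRs and a 157-frame recording stepped by 1 TR yields 124 windows. The
rectangle width and Gaussian scale are the field's standard choices; the
truncation is a package parameter (the convolution support has to end
somewhere), chosen so the window spans the rectangle plus roughly two
Gaussian standard deviations of taper on each side. Weighted means and
variances use the taper weights (`stats::cov.wt`, maximum-likelihood
normalization). A window in which a component is constant has no defined
correlation; such degenerate windows return 0 with a warning rather than
failing, since they carry no connectivity signal. With `C` components the
`C(C-1)/2` pairs are vectorized in strict lower-triangle row order,
labelled `IC<i>/IC<j>` with `i > j` (the pair label is symmetric: `IC1/IC2`
and `IC2/IC1` name the same feature).

## Fuzzy c-means and model selection

For windows pooled across all subjects, fuzzy c-means minimizes
\(J_m = \sum_i \sum_j u_{ij}^m d_{ij}^2\) over memberships \(u\) and
centroids, with Euclidean distance \(d\) and fuzziness \(m > 1\);
\(m \to 1\) recovers k-means, larger \(m\) softens memberships. The
implementation is the standard alternating optimization from a random
row-stochastic membership matrix (drawn per seed), iterated until the
largest membership change falls below `tol = 1e-6` or `max_iter = 1000`.
The objective is checked to be non-increasing at every iteration. A sample
at exactly zero distance from a centroid gets membership one there; if two
centroids collapse the fit is re-initialized once and then refused.

The number of states defaults to `K = 5`, the convention in dFNC studies of
this size, and is deliberately a parameter rather than something optimized
internally. Fuzziness and initialization seed are selected by maximizing
the fuzzy partition coefficient \(\mathrm{FPC} = \frac{1}{N}\sum_{ij}
u_{ij}^2\) (1 = crisp, \(1/K\) = uniform) over
`m_grid = {1.1, 1.3, 1.5, 1.7, 2, 2.5}` and `seed_grid = 0:9`; ties break
toward smaller `m`, then smaller seed, so selection is deterministic. The
grids are package defaults spanning the range used across the fuzzy
clustering literature. FPC rewards crisp partitions, so on well-separated
data it tends to select the smallest `m` in the grid; the grid is exposed
precisely because this preference is data-dependent.

## Perturbation explainability

Both explainability methods ask how much the clustering depends on each
connectivity pair by permuting that pair's column across samples and
re-predicting memberships against the frozen centroids.

* **G2PC** (global permutation percent change): the percentage of samples
  whose argmax state switches. It registers only the minority of samples
  near a cluster boundary.
* **P2D** (permutation-based distribution divergence): the Kullback-Leibler
  divergence between each sample's membership distribution before versus
  after permutation, \(D(u^{\text{before}} \| u^{\text{after}})\). The
  asymmetric direction follows the before-versus-after phrasing of the
  method's definition; natural logarithms (nats) throughout. Global
  summaries (**GP2D**) are the total and the median KLD across samples;
  the local map (**LP2D**) keeps per-sample values, averaged over repeats.

Memberships are strictly positive in exact arithmetic but can underflow, so
both vectors are floored at `eps = 1e-12` and renormalized before the
divergence; rows untouched by the permutation are assigned exactly zero.
Each of the `repeats = 30` repeats draws one fresh permutation per feature;
GP2D aggregates by the mean over repeats (pooling repeats before
summarizing would be the alternative; the mean keeps repeats exchangeable
and the estimator unbiased for the per-permutation summary). Because a
permutation moves essentially every sample's value, LP2D registers a
non-zero divergence for essentially 100% of samples on continuous data —
the occasional exception being a sample the random permutation happens to
map to itself — whereas G2PC's switch percentages stay low. Ranking
agreement between methods is measured with Kendall's tau
(`stats::cor.test`, exact p-values on small tie-free vectors, normal
approximation otherwise).

## Dynamical and stability features

From each subject's \(T \times K\) membership matrix \(U\):

* **OCR / NST** (hard-cluster classics): windows are argmax-assigned (ties
  to the lowest state index, logged); occupancy rate is the percentage of
  windows per state (sums to 100), NST counts consecutive-window label
  changes.
* **Average / Variance / Range**: mean, population (\(1/T\)) variance, and
  max-minus-min of each state's membership trace — 3 per state.
* **Cumulative difference**: \(\sum_t |u_k(t) - u_k(t-1)|\) per state.
* **Entropy over time**: each state's trace is normalized to a distribution
  over time points and its Shannon entropy taken. This per-state "when is
  the state expressed" reading is used rather than per-timepoint entropy
  averaged over \(T\), which would collapse to a single feature instead of
  one per state.
* **KLD across states**: the divergence between consecutive membership
  rows, \(d(t) = D(u(t-1) \| u(t))\), summarized by mean, median, standard
  deviation, minimum and maximum — the only time-resolved reading of
  "divergence across states" that yields exactly five dynamics features.
* **Non-uniformity**: mean squared deviation of each state's trace from the
  uniform level \(1/K\).
* **State correlations**: Pearson correlation between each pair of state
  traces (Spearman would be the alternative; Pearson is chosen to match the
  linear trade-of-probability interpretation). For \(K = 2\) the single
  correlation is \(-1\) by complementarity, a useful self-check.
* **LP2D stability**: each subject's windows' LP2D values averaged per
  connectivity pair — higher means the subject's state probabilities are
  less stable to perturbation of that pair.

Features are grouped into families (`nst_ocr`,
`nonuniformity_kld_entropy`, `average`, `variance`, `range`,
`correlation`, `cumulative_difference`, `lp2d`); the family is the unit of
multiple-testing correction and of per-family classification.

## Group inference, classification, regression

Each feature is compared between groups with a pooled-variance two-sample
t-test (Student rather than Welch, exposed as `var_equal`), computed as
group 0 minus group 1 so that a negative statistic means the patient analog
scored higher. Benjamini-Hochberg FDR runs within each family separately at
`alpha = 0.05`, and both uncorrected and corrected flags are reported.

Per-family classification uses elastic-net logistic regression
(`glmnet`) under nested cross-validation: 10 stratified outer folds; inside
each outer training set, features are z-scored with training statistics
only and 5 stratified inner folds select the L1 ratio
(`0.1, ..., 0.9, 1`) and regularization strength (10 points log-spaced over
\(10^{-3}..10^{3}\)) by inner AUC. The winner is refit on the outer
training set and evaluated once on the outer test fold. AUC, sensitivity
and specificity (threshold 0.5) are reported as mean ± SD over outer folds
on the 0-100 scale. Labels are 0 = patient analog, 1 = control analog, so a
negative coefficient means higher feature values push toward the patient
class; sensitivity is the patient detection rate. Standardization and
hyperparameter selection never see outer-test rows, which the tests verify
indirectly through reproducibility and separability checks.

Symptom regression fits, per feature, ordinary least squares of the
*feature* on age, gender, one-hot site (first level dropped) and the
symptom score within the scored group, reporting the symptom coefficient
with per-family FDR. Regressing the feature on the score (rather than the
reverse) keeps one model per feature with a common covariate set, the
standard formulation for "is this feature related to severity after
adjusting for demographics".

## The synthetic generator

The generator plants everything downstream stages estimate:

* **Centroids**: `K` vectorized symmetric correlation patterns with entries
  in \([-0.9, 0.9]\), rejection-sampled to pairwise Euclidean distance at
  least `separation` (default 1.5). Infeasible requests error rather than
  silently crowding centroids.
* **Membership trajectories**: `K` independent Gaussian random walks,
  smoothed by a moving average of width `ceiling(smoothness)` (default 10
  windows), scaled by `concentration` and passed row-wise through a
  softmax. This gives temporally smooth, occasionally switching probability
  traces rather than the white-noise memberships a per-window Dirichlet
  draw would produce. `concentration = 0.5` is the default scale: at
  trajectory lengths around 100-150 windows it puts dominant-state
  probabilities mostly in 0.7-0.98 with soft transitions, which is what
  fuzzy membership traces of real dFNC look like.
* **Windows**: \(x(t) = \sum_k u_k(t)\,c_k + \varepsilon(t)\) with i.i.d.
  Gaussian noise (`noise_sd = 0.1`), clipped to \([-1, 1]\) since the
  values represent correlations.
* **Cohorts**: two groups (defaults 160 controls / 151 patients, 124
  windows, 7 components, 7 sites — the shape of a typical multi-site
  clinical resting-state study), ages \(N(38, 11^2)\), gender
  Bernoulli(0.75), site uniform. An *occupancy* effect adds a logit bias on
  the target state for group 1, scaled by the across-subject SD of the
  subject-mean state logit so the planted effect size is a standardized
  mean difference on that scale (the realized effect on the occupancy-rate
  feature is close to nominal because the softmax is locally monotone). A
  *transition* effect multiplies group 1's random-walk innovation SD by
  \(1 + d/2\), increasing switching. The *symptom* score is
  `15 + beta * z + N(0,1)` where `z` is the standardized subject-mean
  membership of the target state — the simplest structure that makes the
  covariate-adjusted regression testable — with scores present only in the
  patient group.
* **Component time series** (for testing the window stage end-to-end):
  blocks of multivariate Gaussian draws with per-regime covariances.

What the generator does **not** emulate: hemodynamics, scanner and
physiological noise spectra, head motion, ICA unmixing error, spatial
structure among components, autocorrelated measurement noise within a
window, or site effects on the features themselves. Tests passing on this
generator therefore establish that the estimators and their calibration are
correct under the stated model — convex state mixing with independent
Gaussian noise — not that real acquisitions satisfy that model.

## Numerical choices and validation scale

Ties in hard assignment go to the lowest state index; FPC ties in model
selection to the smallest `m`, then seed. All generators and fits are
bit-reproducible given their seed arguments, and the package never touches
the caller's RNG stream (seeds are applied in a save/restore wrapper).
Pipeline outputs are tab-separated text with provenance comment headers
(package version, a hash of the analysis parameters, the seed); timings go
to a separate log so numeric outputs are byte-identical across reruns.

The validation suite works at sizes chosen to exercise the estimators
meaningfully while staying desk-scale: planted-state recovery uses roughly
10,000 pooled windows over 21 pairs and 5 states and requires
best-assignment cosine similarity of at least 0.95 between fitted and
planted centroids at separation \(3\sigma\sqrt{P}\); statistical
calibration uses 200 null-cohort repeats (binomial 95% bands around
\(\alpha = 0.05\)) and 100 repeats for power at a planted occupancy effect
of \(d = 1.5\) with 50 subjects per group. Under the global null with
correlated features inside a family, BH's any-rejection probability equals
\(\alpha\) only under independence and is deflated under positive
dependence, so calibration is asserted two-sided on the uncorrected
per-test rate and one-sided (control) on the per-family FDR rate.

## Limitations

Fuzzy c-means shares k-means' sensitivity to outliers and to `K`; no
robust or sparse variants are provided. The FPC criterion prefers crisp
solutions and should be read as a selection device, not a goodness-of-fit
test. Site enters the symptom regression only as fixed dummies (no
location/scale harmonization or mixed effects), and the classifier reports
in-cohort cross-validated performance, not external validity. The
explainability scores are defined relative to the fitted centroids:
features important to a differently-initialized clustering may differ when
states are poorly separated.
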