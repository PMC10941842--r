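# fuzzyconn

Explainable fuzzy clustering of dynamic functional network connectivity
(dFNC) in R.

Resting-state fMRI dFNC analysis summarizes a recording as the sequence of
connectivity "states" it visits. The standard pipeline hard-clusters
windowed correlations with k-means, which throws away how strongly each
window expresses a state and makes participants who never crisply enter a
state invisible to that state's features. `fuzzyconn` implements the fuzzy
alternative for researchers working with component-based connectivity
(e.g., default-mode-network components in clinical case-control studies):

* **Windowed connectivity** — Pearson correlation in a tapered sliding
  window (rectangle of 20 TRs, i.e. 40 s at TR = 2 s, convolved with a
  σ = 3 Gaussian); 7 components give 21 pair features, 157 frames give 124
  windows.
* **Fuzzy states** — fuzzy c-means: memberships
  u<sub>ij</sub> = 1 / Σ<sub>l</sub> (d<sub>ij</sub>/d<sub>il</sub>)<sup>2/(m−1)</sup>,
  centroids c<sub>j</sub> = Σ<sub>i</sub> u<sub>ij</sub><sup>m</sup> x<sub>i</sub> / Σ<sub>i</sub> u<sub>ij</sub><sup>m</sup>,
  with the fuzziness m and the initialization seed selected by the fuzzy
  partition coefficient FPC = (1/N) Σ<sub>ij</sub> u<sub>ij</sub>².
* **Explainability** — permute one connectivity pair at a time and
  re-predict memberships: G2PC reports the percent of samples whose argmax
  state switches; P2D reports the Kullback-Leibler divergence
  D(u<sup>before</sup> ‖ u<sup>after</sup>) per sample (LP2D) and its
  total/median across samples (GP2D), registering the effect of
  perturbation on essentially every sample instead of the switching
  minority.
* **Dynamical features** — occupancy rate and state transitions plus
  fuzzy-native features per state: mean/variance/range of membership,
  cumulative membership change, entropy over time, consecutive-window KLD
  summaries, non-uniformity, between-state correlations, and per-subject
  LP2D stability.
* **Inference** — pooled two-sample t-tests with per-family
  Benjamini–Hochberg FDR; per-family elastic-net logistic regression under
  10-fold nested cross-validation (AUC/sensitivity/specificity); OLS
  symptom-severity regression adjusted for age, gender and site.
* **Synthetic ground truth** — a generator that plants centroids, smooth
  membership trajectories, group effects and a symptom score, so the whole
  pipeline is testable without any data download.

## Worked example

```r
library(fuzzyconn)

# plant 5 connectivity states and simulate 10 subjects x 124 windows
centroids   <- generate_centroids(K = 5, C = 7, separation = 1.5, seed = 1)
memberships <- lapply(1:10, function(i)
  generate_membership_trajectories(124, K = 5, seed = i))
dfnc <- generate_dfnc(memberships, centroids, noise_sd = 0.1, seed = 2)
X    <- do.call(rbind, lapply(dfnc, function(d) d$values))

fit <- fcm(X, K = 5, m = 2, seed = 0)
fit
#> Fuzzy c-means model
#>   K = 5  m = 2  seed = 0
#>   N = 1240 samples, 21 features
#>   FPC = 0.6018 (uniform floor 1/K = 0.200)
#>   36 iterations, converged

imp <- p2d(X, fit, repeats = 10, seed = 0)
imp
#> P2D importance: 1240 samples x 21 features, 10 repeats
#>   top features by total GP2D: IC5/IC4 (120), IC4/IC3 (101), IC4/IC1 (89.8), ...

head(pct_nonzero_lp2d(imp), 3)
#> IC2/IC1 IC3/IC1 IC3/IC2
#>     100     100     100

U1 <- predict(fit, dfnc[[1]]$values)   # one subject's state probabilities
round(subject_features(U1)[c("ocr_state1", "nst", "entropy_state1",
                             "cumulative_difference_state1")], 3)
#>                   ocr_state1                          nst
#>                       39.516                        9.000
#>               entropy_state1 cumulative_difference_state1
#>                        4.641                        5.886
```

The FPC of 0.60 sits well above the uniform floor 0.20, i.e. the fitted
partition is substantially crisp. Every connectivity pair perturbs 100% of
samples under LP2D (`pct_nonzero_lp2d`), while the same model's G2PC switch
percentages stay in the low tens — the motivating contrast between
divergence-based and switch-based explainability. The per-subject features
read directly: this subject spends 39.5% of windows in state 1, makes 9
hard transitions, and state 1's membership is spread broadly over the scan
(entropy 4.64 against the maximum log 124 ≈ 4.82).

A full cohort analysis (simulate → cluster → explain → features → stats →
classify → regress) runs from one configuration:

```r
cfg <- default_config()
cfg$paths$output_dir <- "my_run"
results <- run_pipeline(cfg)
```

or from the shell via the thin CLI wrapper:

```sh
Rscript inst/cli/fuzzyconn.R run-all --config my_config.yaml
```

Every stage writes tab-separated tables with provenance headers; reruns
with the same configuration are byte-identical.

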