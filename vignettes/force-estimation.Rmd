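---
title: "Estimating hand force from surface EMG: models, simulator and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating hand force from surface EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semgforce)
```

## The problem

Myoelectric prosthetic hands are driven by surface electromyography (sEMG):
voltages recorded from electrodes on the residual limb's skin. Decoding the
*type* of an intended movement is well studied; decoding its *force* —
continuously, so a prosthesis can grasp gently or push firmly — is the harder
and less explored half of the problem. `semgforce` implements a complete
force-estimation pipeline for two tasks: nonnegative **grip force** (a grasp,
bounded below 30 N in the design conditions) and signed **3D push–pull
force** at a handle (components along x, y, z, bounded at 20 N in magnitude,
with negative values meaning the reverse direction).

The pipeline is: sliding-window time-domain feature extraction per EMG
channel → a Generalized Regression Neural Network (GRNN) mapping the feature
vector to force → k-fold cross-validated accuracy metrics → ANOVA / Tukey HSD
comparisons of the candidate features.

## Time-domain features

For a window of $N$ samples ending at sample $i$, the four descriptors are

$$\mathrm{MAV}_i = \tfrac1N \sum_j |x_j|, \qquad
  \mathrm{VAR}_i = \tfrac1N \sum_j x_j^2,$$
$$\mathrm{ZC}_i = \sum_j \mathrm{sgn}(x_j x_{j-1}), \qquad
  \mathrm{WA}_i = \sum_j f(x_j - x_{j-1}),\; f(u) = \mathbf 1\{|u| > \theta\}.$$

Two conventions here deserve comment, because the package deliberately keeps
them in their classical printed form rather than "fixing" them:

* **VAR is the raw mean square**, not the mean-centered sample variance: a
  constant window $c$ scores $c^2$. With per-window offset removal enabled
  (the default) the two coincide up to the $1/N$ vs $1/(N-1)$ factor.
* **ZC uses the step function $\mathrm{sgn}(u)=1$ for $u>0$, else $0$**, so
  it counts *same-sign* adjacent pairs — the opposite of the conventional
  zero-crossing count. A strictly alternating window scores 0. Whether that
  convention is intentional cannot be resolved from its source, so the
  printed form is the default and the conventional count is available as
  `zc_variant = "sign_change"`. Both are positive-scale-invariant, which is
  what matters to the regressor after standardization.

The printed ZC sum references $x_{j-1}$ outside the window at the first
index; we restrict both ZC and WA to the $N-1$ in-window pairs.

Tunables and defaults:

| parameter | default | units | rationale |
|---|---|---|---|
| `window_len` | 200 | samples | 200 ms at 1 kHz — a standard myoelectric latency budget |
| `step` | 50 | samples | 4 estimates/s of overlap; keeps training sets modest |
| `wa_threshold` | adaptive | V | 3× median absolute successive difference of a rest segment (first 0.5 s); noise-adaptive, override with an absolute voltage |
| `remove_offset` | `TRUE` | — | acquisition chains level-shift signals (here to 1.5 V); features should reflect EMG activity, not the shift |

Window targets are the synchronized force at each window's **final** sample —
a causal labelling, matching the online use of a trained model.

## The GRNN

The GRNN is instance-based Gaussian-kernel regression (a Nadaraya–Watson
estimator with a neural-network reading): one pattern unit per training
sample $(x_i, y_i)$, and

$$\hat y_j(x) = \frac{\sum_i y_{ij}\, P_i}{\sum_i P_i}, \qquad
  P_i = \exp\!\left(-\frac{\lVert x - x_i \rVert^2}{2\sigma^2}\right).$$

There is no iterative training. Every prediction is a convex combination of
training outputs, so estimates can never leave the observed force range — a
desirable property for a prosthesis controller. Two limits anchor intuition
and are asserted as tests: $\sigma \to 0$ recovers the nearest neighbour,
$\sigma \to \infty$ the global mean.

Design choices where the classical formulation is silent:

* **Sign of the exponent.** The source formulation of the pattern-layer
  transfer function is sometimes printed with a positive exponent, which
  diverges; we use the standard negative Gaussian exponent of the GRNN
  literature.
* **Feature standardization.** Inputs are centered and scaled by training
  statistics before distances are computed (default on). VAR (V²),
  MAV (V) and ZC (counts) live on incommensurate scales; unscaled Euclidean
  distances would be dominated by one coordinate. $\sigma$ is then in
  standardized units, shared across dimensions.
* **Underflow policy.** Kernel weights are computed in the log domain and
  shifted by their maximum before exponentiation, so a probe far from all
  training points degrades gracefully to the nearest neighbour's output
  instead of returning 0/0 = NaN. A prosthesis must output *some* defined
  force.
* **$\sigma$ selection.** `select_sigma()` minimizes k-fold cross-validated
  mean absolute error over a grid, default 10 log-spaced points on
  $[0.05, 2]$ (standardized units), seeded fold assignment.

## Accuracy metrics and cross-validation

Per output dimension, with estimate $\tilde f$ and measurement $f$ over $N$
windows:

$$\mathrm{MAVE} = \tfrac1N \sum |\tilde f_i - f_i|, \qquad
  \mathrm{RMS} = \sqrt{\tfrac{1}{N-1} \sum (\tilde f_i - f_i)^2}, \qquad
  \rho = \frac{\mathrm{cov}(\tilde f, f)}{\sigma_{\tilde f}\,\sigma_f}.$$

RMS keeps its $N-1$ denominator as classically printed. $\rho$ is stored as
a fraction and displayed in percent. Evaluation uses k-fold cross-validation
with $k = 2$ by default (the protocol of the benchmark study): the windowed
set is split into two seeded halves, each held out once, and the fold
metrics averaged.

## Comparing features: ANOVA and Tukey HSD

Given a per-subject accuracy table (subjects × features, optionally ×
directions), `compare_features()` runs, per metric:

* grip design — **one-way ANOVA** with EMG feature as the factor and
  subjects as replicates;
* 3D design — **main-effects two-way ANOVA** (force direction + feature, no
  interaction term), reported in the full layout with corrected-model,
  intercept, error, total and corrected-total rows. The no-interaction model
  is what the benchmark tables' degrees of freedom imply (corrected-model
  df 5 for a 3×4 layout), and in a balanced design its Type III sums of
  squares equal the sequential ones.

When the feature effect is significant at $\alpha = 0.05$, **Tukey HSD**
follows: pairwise studentized-range tests using the ANOVA's error mean
square and df, and the familiar homogeneous-subset table. Subsets are built
by the standard sweep over sorted means: a subset is a maximal run of
consecutive means whose extremes are not significantly different; its
reported significance is the p-value of that extreme-pair range test (with
the full number of groups as `nmeans`). p-values are reported at full
precision, never truncated to "0.000".

The package ships the benchmark per-subject accuracy tables
(`reference_accuracy("grip")`, 24 rows; `reference_accuracy("force3d")`,
72 rows) as delimited text; the acceptance script and the worked README
example recompute all published statistics from them.

## The synthetic session simulator

No public raw recordings exist for this problem, so the simulator is a
first-class module that emulates the acquisition chain the estimator
assumes:

* 1–8 electrode channels (4 for grip, 8 for 3D), 1 kHz/channel sampling
  (configurable 200–2000 Hz), 10–500 Hz EMG band, 10-bit ADC over 0–3 V
  with a 1.5 V level shift;
* grip episodes: raised-cosine bursts of 1–2 s, peaks drawn uniformly in
  [4.5, 28.5] N; 3D episodes: ~1 s, one signed component each, magnitudes
  uniform in [4, 19] N; episodes separated by ≥ 0.5 s of rest;
* each channel is **amplitude-modulated band-limited Gaussian noise**: the
  envelope is `noise_floor + gain %*% g(drive)`, the carrier is unit-RMS
  Gaussian noise confined to the pass-band by FFT masking, then the DC
  shift, optional 50 Hz mains tone, clipping and grid quantization are
  applied. Identical configuration + seed gives bit-identical output.

Unstated physical constants were fixed once at realistic values: channel
gains of 0.004–0.012 V/N (peak envelopes ≈ 0.34 V RMS, comfortably inside
the converter range at 3–4 carrier SDs), and a 0.02 V RMS noise floor
(≈ 6 % of peak envelope — moderate noise). The amplitude law `g` is linear
in |force| by default, with a saturating square-root option, because the
true EMG-amplitude-vs-force law varies by subject and muscle; it is a
configuration point, not an assertion. For the 3D task each signed component
is split into positive/negative half-wave drives against a full-rank 8×6
gain matrix, otherwise a rectified envelope could not identify force
direction. 50 Hz interference is off by default (the emulated sensor has a
notch filter) and switchable on for robustness experiments.

What the surrogate *does not* model: motor-unit physiology, electrode
shift, muscle fatigue, nonstationary baselines, or cross-talk beyond the
linear gain matrix. Passing tests on synthetic sessions therefore
demonstrate the pipeline's correctness and its ability to invert the
simulator's force→envelope map under quantization and noise — not
real-subject accuracy, which depends on data no simulator supplies.

## Numerical and procedural choices

* Problem sizes in the test-suite and acceptance runs: sessions of ~8
  episodes (≈ 20 s, ≈ 400 windows), 2-fold CV, 3 seeds — small enough to run
  everywhere, large enough that held-out correlation above 0.9 is a
  meaningful bar.
* Text serialization uses 17 significant digits everywhere, which
  round-trips IEEE doubles exactly; session/feature/model round-trips are
  asserted bit-exact.
* Degenerate inputs error loudly rather than guess: zero-variance inputs to
  $\rho$, unequal group sizes in Tukey, unbalanced two-way layouts, windows
  longer than the recording, episodes that cannot fit the session.
* Ties in $\sigma$ selection resolve to the first grid minimum;
  `kfold_split` assigns remainders so fold sizes differ by at most one.

## Known limitations

* Tukey HSD requires equal group sizes (the balanced designs used here);
  unbalanced post-hoc comparisons are out of scope.
* The two-way ANOVA fits main effects only; interaction and
  repeated-measures/mixed models are out of scope.
* The GRNN stores every training window (lazy learner); sessions of many
  minutes would warrant condensed pattern layers, which this version does
  not implement.
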