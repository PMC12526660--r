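---
title: "Methods: age-adjusted RMSSD typicality and its model benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: age-adjusted RMSSD typicality and its model benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvpipe)
```

`hrvpipe` turns single-lead ECG into an age-adjusted heart-rate-variability
(HRV) typicality target and benchmarks regression models on it. This
vignette is the package's account of the science: the model, its
assumptions, the tunable parameters, the deliberately open design choices
we had to close, and what the synthetic cohort does and does not establish
about real data.

## From waveform to HRV features

R-peaks are detected with the classic Pan–Tompkins cascade: a zero-phase
2nd-order Butterworth band-pass at 5–15 Hz (the QRS energy band),
differentiation, squaring, a 150 ms centered moving-window integration,
adaptive signal/noise thresholds with a 200 ms refractory period, and
RR-interval-driven search-back. These constants are the algorithm's
canonical published values; none is data-tuned here. Two details matter in
practice. First, each fiducial is refined to the raw-signal maximum within
±50 ms, so reported times sit on the R apex. Second, when two
supra-threshold candidates fall within one refractory period the *larger*
integrated peak wins — without this replacement rule, a noise bump just
ahead of a QRS can "consume" the refractory window and veto the true beat,
which is exactly the failure mode we observed at 5% additive noise before
adopting it.

From the peak times, `RR_i = t_{i+1} − t_i` in milliseconds, and the three
per-record features are RMSSD (`sqrt(mean(diff(RR)^2))`), mean heart rate
(`60000/mean(RR)`) and the R-peak count. Internally HRV is computed in
milliseconds; feature tables store RMSSD in seconds, the convention used
for cohort-level summaries, and the labeler converts back. No
ectopic-beat or artifact filtering is applied before RMSSD — a deliberate
fidelity choice, since the procedure this package operationalizes applies
none.

## The typicality target

Each age decade from 20–29 to 80–89 years carries a normative RMSSD
reference: a *median range* and a wider *total range*, in seconds. Two
decades are anchored by published values (20–29: median 0.0041–0.0048,
total 0.0013–0.0161; 60–69: median 0.00204–0.00207, total 0.0005–0.0104);
the remaining decades are linear interpolations/extrapolations of the
median midpoint, the median width and the range endpoints. Two data
caveats are handled explicitly and surfaced in logs rather than silently
edited: the 60–69 median upper bound is published with a misplaced
decimal (0.000207 s would invert the bounds; we read 0.00207 s), and the
extrapolated median *width* would cross zero for the 70+ bands, where it
is clamped at zero (the midpoint, mode of the fit, is unaffected).

A third caveat is scientific rather than typographic: these normative
ranges sit at a few milliseconds, an order of magnitude below common
physiological RMSSD norms, so most realistic records score through the
out-of-range branch. The reference table is data, not code — it is
preserved as printed, fully overridable via a CSV (`reference_bands()`
with a file path), and the package makes no clinical claim for the
defaults.

### Fitting a distribution to a band

The construction requires a normal distribution that (a) is centered on
the band's published medians and (b) encloses 96% of its mass inside the
band's total range. A single symmetric normal cannot do both, because the
median midpoint is not the range midpoint (for 20–29: 4.45 ms vs 8.7 ms);
centering a symmetric normal on the medians would put only ≈81% of its
mass in range. We therefore fit a **two-piece (split) normal**: mode
`mu` at the median midpoint and per-side deviations

```
sigma_low  = (mu − range_low) / q,   sigma_high = (range_high − mu) / q,
q = qnorm((1 + coverage)/2)          # 2.0537 at coverage = 0.96
```

Under the two-piece normal (side weights proportional to the side sigmas,
the continuous-density convention), the in-range probability is *exactly*
`coverage` for every band, while both range boundaries sit at
standardized distance `|z| = q` from the mode. The reported `sigma_ms` is
the mean of the side sigmas, which equals the symmetric fit's
`width/(2q)` — so the asymmetric fit preserves the familiar summary
value (3.603 ms for the 20–29 band) while restoring the coverage
property. `fit_band_normal()` errors on degenerate (zero-width) ranges.

### Scoring

With `z = (x − mu)/sigma_side` for RMSSD `x` (side sigma chosen by which
side of the mode `x` falls on):

- **in range**, default `two_sided` mode: `2·min(Φ(z), 1 − Φ(z))` — 1 at
  the mode, symmetric in `z`, exactly `2(1 − (1+coverage)/2) = 0.04` at
  either boundary;
- **in range**, `literal_cdf` mode: the raw `Φ(z)`;
- **out of range**: `s_b · exp(−λ·d/sigma_side)` where `d` is the
  distance (ms) beyond the nearer boundary and `s_b` the within-range
  score evaluated at that boundary.

Three choices here were genuinely open and are worth recording. The
two-sided reading is the default because a raw CDF is monotone across the
range: it would call low-RMSSD maximally *atypical* and high-RMSSD
maximally *typical*, which contradicts the meaning of "how typical for
the age group"; the literal reading is nevertheless retained behind
`mode = "literal_cdf"` so both interpretations are testable. The decay
rate `λ` has no published value; the default of one e-fold per side-sigma
of exceedance is scale-free in the band's own units and configurable.
Anchoring the decay at the boundary score is our addition to guarantee
continuity (asserted in tests to be below a 1e-6 jump at either
boundary); without an anchor the two branches need not meet. Scores are
clamped to [0, 1]; sex plays no role in labeling.

## The synthetic cohort

`generate_cohort()` emulates the population the pipeline is meant for:
ages from a truncated normal (mean 58.0, SD 13.98 years, bounds 20–89),
balanced sex, per-record mean heart rate from a truncated normal (mean
50.8, SD 15.42 bpm, bounds 30–180), two recording sites, 500 Hz sampling,
60 s records. The truncation bounds are ours (published moments alone
admit impossible values); the parent parameters are *moment-calibrated*
by numerically inverting the truncated-normal moment equations, so that
the truncated draws — not the parent — reproduce the target mean and SD.
Without this, truncation bias would shift the SD by ≈7%.

Each record's RMSSD target is a mixture: with probability `p_inlier`
(default 0.8) a draw from its age band's fitted two-piece normal, else a
heavy-tailed lognormal with mean 78.9 ms (the published cohort-level
RMSSD mean). The mixture is invented — the source procedure never states
how typical and atypical records are distributed — and exists so that
both scorer branches occur in every cohort; because the normative bands
sit far below the lognormal's scale, outliers land deep in the decay
branch and score near 0. RR series are generated as independent Gaussian
perturbations around the mean RR with interval SD `rmssd/sqrt(2)`, which
makes the expected RMS of successive differences equal the target RMSSD
exactly; waveforms place an ≈80 ms Ricker pulse at each cumulative R time
plus optional white noise, and the exact R times are kept as ground
truth.

Default record duration is 60 s rather than the ≈10 s the published mean
R-peak count (12.64) would suggest: that count's published SD (37.62) is
inconsistent with 10 s records anyway, and RMSSD from fewer than ten
intervals is statistically unusable; 10 s records remain available via
`duration_s`. Consequently the cohort's R-peak counts (≈50 per record)
and RMSSD mixture mean are *not* fidelity claims about the published
per-record statistics — the generator matches the age/HR moments, the
sampling rate, the site structure and the label mechanics, not every
marginal.

What the synthetic cohort cannot show: real ECG morphology (P/T waves,
arrhythmia, baseline wander), respiratory sinus arrhythmia, real
age–RMSSD correlation structure, or site effects (sites are exchangeable
labels here). Passing benchmarks on this cohort validates the pipeline's
mechanics and internal consistency, not clinical performance.

## Preprocessing

Stages run in a fixed order — winsorize, collinearity merge, standardize —
with the label computed *before* any capping, so targets reflect measured
RMSSD. Outlier treatment defaults to percentile capping at the 5th/95th
percentiles (linear-interpolation definition); a Tukey 1.5×IQR fence mode
exists for comparison, since the two are often conflated in prose
descriptions and they are not the same operation. The Spearman screen
(average-rank ties) flags pairs with |ρ| > 0.85 — read as a correlation
threshold; a p-value reading of that cutoff would be incoherent for
flagging *strong* correlation — and replaces each flagged pair by the
mean of the two columns' z-scores. With the default features this merges
`r_peaks` and `mean_hr` (structurally correlated: count ≈ rate ×
duration on fixed-length records, ρ ≈ 0.9996 here) into
`r_peak_mean_hr`, whose variance is `(1+ρ)/2` ≈ 1 — bell-shaped and
unit-scale, which is why mean-of-z-scores was chosen over right-skewed
alternatives like products or ratios.

Standardization uses the population-SD convention (divisor *n*), and the
**target is standardized for regression**: the benchmark's published-style
R²/RMSE pair satisfies `RMSE² = 1 − R²` exactly, which is only possible on
a unit-variance response, so the package adopts that convention and keeps
the raw [0, 1] target alongside (`target_raw`) for classification. The
full-table fit is recorded in a replayable report (`apply_preprocess()`
reproduces the processed table bit for bit), and `standardize()` accepts a
stored scaler so held-out data can be transformed with training-set
parameters when leakage discipline matters.

## Models and evaluation

The suite: ordinary least squares, a CART tree, a random forest (ranger,
impurity importances), and two gradient-boosting variants — xgboost's
gbtree and DART boosters, two genuinely different boosting algorithms
from one library. The forest's default architecture is the tuned
configuration of 111 trees with maximum depth 26. Splits are 80/20,
stratified on target quantiles; cross-validation is 5-fold; both ratios
are community defaults, stated here because the source procedure states
neither. All fits are single-threaded and seeded, and the entire
benchmark is asserted byte-reproducible under a fixed seed.

Classification metrics binarize *both* truth and prediction at 0.5 on the
raw probability scale, with Positive = atypical = score < 0.5 — the only
symmetric, parameter-free rule available when a continuous target is
reported with classification metrics and no threshold; the threshold used
is recorded in every result. Regression predictions are mapped back
through the stored target scaler and clamped to [0, 1] before
thresholding.

`optimize_rf()` is sequential model-based optimization: a maximin Latin
hypercube (plus the incumbent default, so the search can never end worse
than where it started) seeds the design, a Gaussian-process surrogate
(`kernlab::gausspr`, RBF kernel with fixed bandwidth on the unit cube —
fixed, rather than auto-estimated, to keep runs deterministic) models
cross-validated MSE, and expected improvement picks each next point from
a candidate pool. The search space spans 50–300 trees and depths 5–40.

`federated_fit()` trains one model per site on that site's rows only and
averages predictions uniformly. Prediction-level aggregation is the
honest choice for tree ensembles, which have no averageable parameters;
the structural guarantee — no raw rows cross sites — is what the design
asserts, and a single-site federation reduces exactly to centralized
training.

## Numerical choices and degenerate inputs

- At 500 Hz the sample grid quantizes peak times to ±1 ms. This is
  irrelevant for heart rate but material for RMSSD targets of a few
  milliseconds (the normative-band regime), so the detector-path
  self-consistency checks are run at targets ≥ 20 ms, where the 10%
  agreement bound is physically meaningful. Cohort-scale feature tables
  are computed from ground-truth R times; the detector is validated
  separately (recall and precision ≥ 0.99 at ±40 ms, noise-free and at 5%
  noise).
- Empty detector output is a warning, not an error; flat or undetectable
  records are flagged and excluded downstream with a log entry, so batch
  runs survive bad records.
- Constant columns: undefined Spearman correlations are recorded as 0
  with a warning; standardizing a constant column is an error naming the
  column.
- A single top-level seed derives all per-stage seeds deterministically;
  reruns of `run_pipeline()` with the same config are asserted
  byte-identical.

## Problem sizes

The package's own acceptance checks run the regression benchmark on a
10,000-record cohort (≈20 s single-threaded), the structural correlation
on 5,000 records, the coverage check on 100,000 draws, and the property
suites on hundreds of randomized cases each — sizes chosen so the full
chain, including the tent-shaped score's hardest regions, is exercised at
desk scale. Under those conditions the tuned forest's held-out R² is
≈0.96–0.97 with RMSE ≈0.16–0.18 on the standardized target, and forest
importances rank `rmssd > age > r_peak_mean_hr > sex`, the expected
ordering given that the label is an age-conditional function of RMSSD.

## Known limitations

Published cell values from the external clinical database (exact
correlation entries, importance scores, classification percentages) are
dataset-specific and are not reproduction targets; only structural
quantities are. The typicality score inherits whatever biases the
normative table carries, including its surprising millisecond scale. The
federated variant models site partitioning only — no communication
rounds, stragglers or privacy accounting. And all benchmark numbers are
synthetic-cohort numbers: they demonstrate that the machinery is correct
and stable, not that it predicts clinical events.
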