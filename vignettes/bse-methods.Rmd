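---
title: "Models and numerical choices in bse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical choices in bse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bse)
```

`bse` implements, end to end, the analysis of depictive and metric body
size estimation (BSE) experiments with parallel MEG/EEG: psychometric
modelling of binary size judgments, sensor preprocessing, distributed
source estimation on a spherical shell, and mass-univariate
cluster-permutation statistics. This vignette explains the models, their
assumptions, the tunable parameters, and the design decisions that were
genuinely open — i.e. everything a methods-minded user should know before
trusting a number the package prints.

## The psychometric model

A subject judging whether a pictured body is "narrower" or "wider" than a
reference is modelled as a Weibull observer,

$$P(\text{wider} \mid x) = f(x) = 1 - e^{-(a x)^\beta},$$

where $x$ is the stimulus BMI (kg/m²), $a > 0$ a scale parameter
(1/(kg/m²)) and $\beta > 0$ the slope. `fit_weibull()` maximises the
Bernoulli likelihood of the trial-level responses. Binary data carry no
residual variance term, so maximum likelihood is the statistically proper
estimator; a least-squares fit to per-stimulus proportions was the main
alternative and is deliberately not the default (it weights extreme
proportions incorrectly).

Open choices, and what we picked:

* **The "fitted BMI" criterion.** The fitted curve must be reduced to one
  number per subject and task. We use the point of subjective equality
  (PSE), $f(x) = 0.5$, the standard psychophysical definition of the
  subjective match; `fitted_bmi(fit, criterion)` exposes the criterion.
  Closed form: $x = (-\ln(1 - c))^{1/\beta}/a$.
* **Optimisation.** Parameters are optimised on the log scale (enforcing
  positivity) with L-BFGS-B from a fixed grid of starts: candidate PSEs at
  five quantiles of the presented BMI range crossed with
  $\beta \in \{1, 3, 6, 12\}$. The grid makes the fit deterministic for
  given data; the test suite checks that dispersed start grids reach the
  same optimum.
* **Direction coding.** Which response counts as "success" is
  task-dependent in principle; the fit computes the response–BMI
  correlation and flips the coding when negative, flagging `inverted`.
* **Degenerate data.** All-identical responses leave the likelihood
  maximal at a parameter boundary; the fit returns a non-converged record
  with a diagnostic note instead of a silent estimate.
* **Lapse rate.** The response *generator* supports a lapse parameter
  (`p = lapse/2 + (1 - lapse) f(x)`), a standard robustness knob in
  psychophysics; it defaults to 0 and the *fitting* model deliberately
  omits it, matching the two-parameter analysis model.

The body perception index is `BPI = estimate/reference × 100`
(overestimation > 100). References: the subject's actual BMI (body task),
the BMI of the picture matching the comparison bar, 19.61 (bar task; the
stimulus set also contains a median-BMI picture at 19.79 — both constants
are exposed in the config, 19.61 being the default because it is the
constant conventionally entered into the bar-task BPI formula), and the
measured circumference
per body part (metric task, per-part indices averaged over waist, upper
arm and thigh). The AN median split labels `bpi <= median` as AN1
("slight overestimation") and `bpi > median` as AN2; the tie rule is a
package decision and configurable.

For group inference the metric BPIs get an independent-samples t-test with
Cohen's d, Welch-corrected when Levene's test (mean-centred, the SPSS
convention) rejects equal variances at 0.05 — this reproduces the
fractional degrees of freedom familiar from the literature. The depictive
BPIs get a 2 (task: body, bar) × 2 (group) split-plot ANOVA computed from
sum and difference scores with unweighted group means (the Type III
solution), so unbalanced groups are handled the way SPSS reports them.

## The synthetic-data generator

No patient data are distributable, so the generator is a first-class,
tested module that emulates the study design:

* 66 body pictures, 11 per category, BMIs uniform within the six category
  ranges A [12.19, 14.74] … F [32.46, 56.26];
* 3 repetitions → 198 trials per task, 800 ms stimulus duration,
  ISI 1250 ± 500 ms; trial order is a constrained shuffle with bounded
  random repair: at most 3 consecutive same-category trials, transitions
  statistically uniform (a χ² test in the suite checks this at α = 0.01).
  An exact balanced-transition design was rejected as stronger than
  "pseudo-randomised";
* Weibull observers whose latent PSE encodes a true BPI per task: group
  distributions default to AN body-task BPI 125 ± 15 vs. HC 108 ± 12
  (Cohen's d ≈ 1.25), bar-task 100 ± 6 in both groups, metric-task
  135 ± 20 vs. 103 ± 13 — values chosen once to emulate the reported
  behavioural pattern of strong self-referential overestimation in AN
  with intact non-self-referential estimation;
* sensor recordings built from shell dipole sources: every trial adds a
  Hanning-windowed source time course per effect component, scaled by the
  (task, category, group) multiplier, projected through the analytic
  leadfield, plus white sensor noise (default 1 pT at MEG sensors for
  20 nAm sources) and optional 60 Hz line noise to exercise the band-stop.
  The default effect specification injects (i) a posterior "visual"
  component (100–500 ms) with task ordering body > bar > viewing and a
  quadratic-plus-slight-linear picture profile, and (ii) a left-parietal
  group × picture component restricted to ≥ 200 ms in which only the AN
  group carries a descending linear picture profile. Amplitudes default to
  generous effect sizes (interaction component 12 nAm against a 20 nAm
  visual component) because the generator's purpose is end-to-end
  recovery testing, not power realism. Per-subject multiplicative gain
  (log-normal, σ = 0.15) provides between-subject variability.

What the generator does *not* emulate: realistic spatially correlated
brain noise and noise covariance, eye/muscle artifacts, head movement,
individual anatomy, or reaction times. Passing recovery tests therefore
demonstrates the correctness and calibration of the *analysis machinery*,
not expected sensitivity on real recordings.

## Preprocessing

The chain follows the acquisition narrative: band-pass filter → downsample
600 → 300 Hz → epoch (−200..600 ms, 240 samples at 300 Hz) → 150 ms
baseline correction → artifact screening → condition averaging.

The filters are specified as zero-phase Butterworth designs: third-order
high-pass at 0.1 Hz, fourth-order low-pass at 48 Hz, fourth-order
band-stop 60 ± 1.5 Hz. A forward-backward pass of an order-$n$ Butterworth
filter has the purely real transfer function $|H(f)|^2 = 1/(1 +
\Omega(f)^{2n})$ (with $\Omega$ the band transform) and zero phase; the
package applies exactly that gain in the frequency domain in a single FFT
per direction, with zero padding against circular wrap-around. This is
numerically equivalent to time-domain forward-backward filtering away from
the record edges, has *exactly* zero group delay, and is an order of
magnitude faster — the property tests (passband gain within 2%, 60 Hz
residual < 5%, DC removal, bump-latency preservation, linearity) pin the
behaviour. Filtering precedes downsampling so the 48 Hz low-pass doubles
as the anti-alias filter; `resample_recording()` nevertheless applies its
own 8th-order low-pass at 80% of the new Nyquist so the operation is safe
in isolation. Only integer decimation factors are supported.

Artifact screening is a transparent simplified stand-in for full
statistical artifact-control procedures: per trial, peak-to-peak
amplitude, maximum gradient and variance (worst channel each) are z-scored
across trials and a trial exceeding the threshold (default z = 4) on any
feature is rejected; channels are flagged analogously via cross-trial
median features and can be repaired by nearest-neighbour averaging
(`interpolate_bad_channels()`, a stand-in for spline interpolation). The
interface (an epochs object with a rejection mask and a TSV-exportable
rejection log) is designed so a more elaborate method can drop in.

## Source model

The source space is a spherical shell of 350 sites at 87% of the head
radius (approximately grey-matter depth), sampled with a deterministic
Fibonacci lattice — no RNG, so source spaces are bit-reproducible, and
nearest-neighbour distances stay within ±30% of their mean. Each site
carries an orthonormal tangential basis: MEG uses the two tangential
orientations ("dipole pairs"; radial dipoles are silent in a spherical
conductor), EEG all three ("triples").

Forward models are the analytic spherical-conductor solutions: the Sarvas
field for MEG (magnetometers oriented radially) and the Legendre-series
potential of a homogeneous sphere for EEG (σ = 0.33 S/m, series truncated
at n = 120 where terms decay like $0.87^n$; columns are average-referenced
so they sum to zero over electrodes). The tests verify the physics rather
than re-deriving the formulas: radial-dipole silence, linearity, the exact
identity that the radial field component outside a spherical conductor
equals that of the primary (Biot–Savart) dipole alone, and the
central-dipole closed form $V = 3\,\mathbf{p}\cdot\hat r/(4\pi\sigma R^2)$
for EEG.

The inverse is the classical L2 minimum-norm estimate
$W = L^\top (L L^\top + \lambda s I)^{-1}$ with $s =
\operatorname{tr}(LL^\top)/n_{\text{sensors}}$, which makes $\lambda$
dimensionless so the conventional values 0.1 (MEG) and 0.2 (EEG) apply
regardless of units. No depth weighting or noise normalisation is applied
(plain L2-MNE). At $\lambda = 0$ with full sensor rank, $W$ is the
Moore–Penrose pseudoinverse; the suite checks this against an independent
implementation and verifies the minimum-norm property against the KKT
solution of the equality-constrained quadratic programme. Source activity
is the Euclidean length of each site's moment vector (in nAm), which is
invariant to rotations of the tangential basis — also tested.

## Cluster statistics

At every (site, time) point the package computes the univariate
mixed-design ANOVA for the 3 (task) × 6 (picture) within × 2 (group)
between design — seven effects. Implementation: orthonormal polynomial
contrast scores per within effect; the averaged univariate F on those
scores equals the classical split-plot F (verified against multistratum
`aov()` fits to 1e-6 in the suite) and, with unweighted group means,
yields the Type III solution for unbalanced groups. Greenhouse–Geisser
epsilon is estimated per point from the pooled within-group covariance of
the contrast scores and applied when ε < 0.75 (a common operationalisation
of "corrected if necessary"); for k = 2 within levels ε is identically 1.

Multiple comparisons over the 50–550 ms × whole-shell grid are controlled
by cluster-based permutation: threshold the pointwise map at p < 0.05,
form spatiotemporal clusters (spatial neighbour at the same sample, or
same site at an adjacent sample), score each cluster by its mass (sum of
F; a maximum-F alternative is available via `cluster_stat = "max"`), and
compare against the permutation distribution of the maximal cluster
score, $p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{perm})$.
Design decisions worth stating:

* **Adjacency.** Spatial neighbourhood on the shell is a symmetrised
  k-nearest-neighbour graph (k = 6, deterministic). On a quasi-uniform
  Fibonacci lattice this gives essentially the same neighbourhoods as a
  surface triangulation while depending on nothing beyond a distance
  matrix.
* **Permutation schemes.** Group labels are exchangeable under the null
  for the between effect *and* for every interaction involving group once
  the data are reduced to per-subject contrast scores — so all
  group-involving effects permute group labels (exact). Within main
  effects permute the factor's levels within each subject; the
  task × picture interaction permutes cell labels of the per-subject
  residualised data (task and picture margins removed).
* **Threshold inside the loop.** The cluster-forming threshold uses the
  uncorrected parametric pointwise p — equivalently a fixed F quantile —
  applied identically to observed and permuted data. Any consistent
  thresholding statistic yields a valid permutation test; recomputing a
  per-point sphericity correction inside every permutation would buy no
  additional validity. The Greenhouse–Geisser-corrected p-maps are
  reported by `pointwise_rm_anova()` for descriptive use.
* **Cluster merging.** Clusters of the same effect that are adjacent in
  space/time are merged for reporting (masses add, the merged p is the
  minimum); merging is idempotent and order-independent.

The family-wise error rate of the whole procedure is measured, not
assumed: the acceptance suite runs 200 replicate pure-noise datasets
(40 sites × 30 samples, 10 subjects per group, 300 permutations) through
the full pipeline for the picture × group family and requires the fraction
with any cluster p < 0.05 to stay within binomial tolerance of 0.05. The
guarantee is per effect family — that is what the permutation scheme
calibrates — so the simulation evaluates one family rather than pooling
seven tests into an uninterpretable compound rate.

Post-hoc analysis extracts each cluster's mean activity per subject and
condition; task comparisons use paired t-tests (Cohen's d from the
difference SD), picture profiles use planned polynomial contrasts with the
classical integer weights (linear −5…5, quadratic 5, −1, −4, −4, −1, 5 for
six levels), tested against zero within groups (`F = t²`, df 1, N−1) and
between groups for interaction trends (df 1, N−2).

## Problem sizes and runtime

The `"full"` preset pins the full study-scale design (29 + 30 subjects, 64 sensors,
350 sites, 1000 permutations). The `"desk"` preset — the default for
examples and the test suite — keeps every analysis parameter identical but
runs 6 + 6 subjects, 24 sensors, 60 shell sites and 199 permutations,
which completes in a few minutes on one CPU; the end-to-end recovery test
uses 5 + 5 subjects, 16 sensors, 40 sites and 159 permutations per seed.
These sizes are the package's choice of a desk-scale experiment: large
enough that every stage (including cluster geometry on the shell) is
non-trivial, small enough to iterate on.

## Known limitations

* The spherical forward models are desk-scale stand-ins for realistic
  BEM/FEM head models; localisation statements are about shell sites, not
  anatomy, and no brain-region naming is attempted.
* The artifact screen is a simplified feature-z-score procedure, not a
  full statistical artifact-control implementation.
* The behavioural and neural generators share a cohort but not a common
  latent trait model; correlations between BPI and neural effects are not
  emulated, so secondary analyses (AN1/AN2 contrasts) exercise machinery
  rather than reproduce effect sizes.
* The permutation ANOVA assumes a complete within-subject crossing; cells
  emptied by artifact rejection must be handled upstream (the averaging
  stage refuses empty cells explicitly).
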