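---
title: "Dynamic connectivity states: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic connectivity states: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Resting-state fMRI decomposed by group ICA yields, for every subject, a
matrix of component time courses (here 207 TRs by 37 independent
components). Static functional connectivity summarises each subject by a
single 37 x 37 correlation matrix; dynamic functional network
connectivity (dFNC) instead asks how that correlation structure moves
through a small repertoire of recurring whole-brain *states*. `dfnc`
implements the complete state-analysis pipeline — time-series cleaning,
tapered sliding-window covariance with graphical-LASSO regularisation,
k-means state clustering with elbow-based model selection, temporal
state metrics, group statistics, and exploratory SVM classification —
together with a synthetic cohort generator that plants known states and
group differences so every stage can be validated against ground truth.

## Time-series cleaning

Each component time course is cleaned in the fixed order

1. **Detrending**: the least-squares polynomial of degree 1 is removed
   (degree configurable), eliminating slow scanner drift.
2. **Despiking**: a robust spike compressor in the style of AFNI's
   3dDespike. A quartic polynomial baseline is fit; residuals are
   standardised by the MAD-based sigma (1.4826 x median absolute
   residual); standardised residuals `s > c1 = 2.5` are replaced by
   `c1 + (c2 - c1) tanh((s - c1)/(c2 - c1))` with `c2 = 4`, and
   symmetrically for negative spikes. The quartic baseline is this
   package's deterministic stand-in for a generic slow-trend fit; the
   tanh cap guarantees no output residual exceeds `c2` robust sigmas.
   Repeated application is a contraction, not an identity: residuals
   compressed into the band `(c1, c2)` shrink slightly again on a second
   pass, so the cleaner is applied exactly once in the pipeline.
3. **Low-pass filtering**: a fifth-order Butterworth with 0.15 Hz cutoff
   applied forward and backward (`signal::filtfilt`). Zero-phase
   filtering avoids phase distortion of the windowed covariance, at the
   cost of squaring the magnitude response: the effective gain at the
   cutoff is 0.5, not the single-pass 0.707. This trade is deliberate
   and documented rather than hidden.

Component quality metrics use a plain periodogram (no taper): the
low/high power ratio integrates power below 0.10 Hz against power above
0.15 Hz (both edges configurable), and the dynamic range is the drop
from the spectral peak to the minimum power above the peak frequency.
The "dynamic range" of an IC time course is sometimes described
ambiguously as a difference of frequencies; this package reads it as a
difference of spectral *powers*, which is the reading under which the
metric separates signal-like from noise-like components.

## Windowed connectivity

Sliding windows use the taper obtained by convolving a rectangle of
`w = 22` TRs with a unit-area Gaussian of `sigma = 3` TRs (truncated at
4 sigma). The step is 1 TR, and the window count convention is
`positions = T - w` — 185 windows for T = 207 — with window `p` covering
samples `p .. p + w - 1`; taper mass clipped at the edges of the time
axis is renormalised. The alternative `T - w + 1` convention is rejected
because the package anchors on the 185-window count for this geometry.

Within each window the weighted covariance

\[ \Sigma_{ij} = \frac{\sum_t w_t (x_{ti}-\mu_i)(x_{tj}-\mu_j)}{1 - \sum_t w_t^2} \]

is regularised by the graphical LASSO: minimise over precision matrices

\[ -\log\det\Theta + \mathrm{tr}(S\Theta) + \lambda \sum_{i \ne j} |\Theta_{ij}| \]

with the penalty on off-diagonal entries only. The solver is a
block coordinate-descent implementation in C++ (one column's lasso
subproblem per block, residuals maintained incrementally), capped at 100
sweeps with tolerance 1e-4 on the average absolute change of the working
covariance; hitting the cap flags the window rather than failing. At
`lambda = 0` the solution is the plain inverse and is computed directly.
The default penalty is `lambda = 0.1`; it is exposed as a parameter
because no principled universal value exists at ~22 effective samples
per window, and an analysis should report sensitivity to it.

Connectivity is read from the regularised covariance `W` (not from the
partial correlations in `Theta`): `r = W_ij / sqrt(W_ii W_jj)` clamped
to `|r| <= 1 - 1e-7`, then Fisher-transformed, `z = atanh(r)`. Edges are
ordered row-major over the strict upper triangle — 666 edges for 37
components — and that ordering is fixed across the whole package.

## State clustering and the elbow

All subjects' windowed z-vectors are pooled and clustered by Lloyd
k-means (Euclidean distance, k-means++ seeding, 300-iteration cap,
best of 100 restarts by within-cluster sum of squares; restarts make the
fit reproducible under a fixed seed). States are relabelled by
descending pooled occupancy, ties broken by centroid norm, so state
numbering is stable across runs.

The number of states is selected by an elbow criterion on the curve
`ratio(k) = within-dispersion / between-dispersion` for k = 2..10.
The selected k is the interior argmax of the second difference of
`log ratio(k)`. The log scale matters: while genuine cluster structure
is being resolved, the ratio decays roughly geometrically, and the
second difference of a geometrically decaying curve peaks *before* the
flattening point — on ideal data with four perfectly separated,
equidistant clusters, the raw-scale curvature criterion selects three.
The log-scale curvature peaks exactly where the curve flattens and
selects four on the same data. Degenerate input is detected separately:
when no second difference of the log *within*-dispersion exceeds 0.05,
the curve has no kink (a single Gaussian cloud behaves this way) and the
function warns and falls back to the smallest candidate k. A data set
whose structure is already resolved at the smallest candidate k is flat
over the interior in the same way, and the fallback is then the correct
answer.

Cross-run state correspondence (`matchStates`) maximises total matched
centroid Pearson correlation by exact assignment (dynamic programming
over label subsets). Correlation compares connectivity *patterns*; two
states that differ only in overall magnitude have collinear patterns
and tie under any correlation-based matcher, which is why the validation
archetypes (below) are built with heterogeneous block structure.

## Temporal metrics and group statistics

From each subject's window-state sequence the package computes
fractional windows (occupancy), mean dwell time (mean maximal-run
length, in windows; 0 for unvisited states), and the transition count.
Unvisited-state dwell times enter group tests as zeros — mirroring
common toolbox behaviour — but are treated as missing in correlation
analyses to avoid zero-inflation; both behaviours are explicit in the
code.

Group inference uses:

* Mann-Whitney U with tie-corrected normal z and no continuity
  correction (matching typical toolbox output); exact enumeration is
  reported alongside for small samples.
* Pearson chi-square without continuity correction for sex ratios and
  for the k x 2 pooled window-count table of state occupancy. Pooled
  windows are not independent observations, so the occupancy chi-square
  is a descriptive contrast, not a calibrated test; it is reported at
  the pooled-window level because that is the level at which state
  percentages are defined.
* Welch t-tests (default) for demographic summaries and for edgewise
  contrasts of subject-level state connectivity, the latter corrected by
  Benjamini-Hochberg FDR across the 666 edges *within* each state.
  Subject-level state connectivity is the mean z-vector over the
  subject's windows in the state; subjects that never visit a state are
  excluded from that state's tests. Welch is the default because the
  pooled and unequal-variance conventions genuinely differ at these
  group sizes and the unequal-variance form is the safer default.
* Partial correlation between clinical scores and temporal metrics:
  residualise both on the covariates (age, sex, education by default;
  configurable) with an intercept, correlate the residuals, and test
  with `t = r sqrt((n-2-k)/(1-r^2))`.

## Classification

The exploratory MVPA trains a linear SVM (cost C = 1, no kernel, no
class weighting) on subject-level state connectivity with leave-one-out
cross-validation. Inside each fold, features are standardised by the
training fold's mean and SD and ranked by absolute Welch t on the
training fold only — the held-out subject contributes nothing to its own
fold's ranking or scaling, and a test asserts this by injecting an
outlier. The positive class is the patient group; decision values are
pooled across folds for the rank-based (tie-aware) ROC AUC. Permutation
significance re-runs the entire LOOCV, including re-ranking, on label
permutations: `p = (1 + #(permuted >= observed)) / (nPerm + 1)` with
1000 permutations by default (tests use 19-99). Consensus features are
the intersection of the per-fold selections. Feature ranking by
within-fold |t| is a declared design choice: it is the standard
deterministic MVPA filter for this setting.

## The synthetic cohort generator

The generator defines the study conditions the pipeline is validated
under. Each subject is a hidden-Markov chain over K = 4 connectivity
states with multivariate-Gaussian emissions:

* **Archetypes.** States are correlation matrices built from a 7-block
  network partition (visual 9, sensorimotor 5, auditory 2, default-mode
  8, cognitive-executive 8, cerebellar 3, basal-ganglia 2 components;
  37 total). The four defaults follow the canonical state descriptions:
  I — moderate within-network coupling with negative
  sensory-to-associative correlations; II — globally strong coupling;
  III — sparse, near-diagonal; IV — strong visual/sensorimotor blocks
  with negative basal-ganglia coupling. Any spec that is not positive
  definite is repaired by flooring eigenvalues at 1e-6 and rescaling to
  unit diagonal; a spec still indefinite after repair errors out.
* **Chains.** Transition matrices are lazy chains
  `P = diag(1-q) + q r'`, whose stationary law is exactly
  `pi_s ∝ r_s / q_s`; given target occupancies and per-state laziness
  the jump distribution is solved in closed form, so occupancy
  expectations are exact rather than simulated. Group defaults pin the
  stationary occupancies to the observed group state percentages
  (control-like 13.45/19.03/48.70/18.82%, patient-like
  16.21/16.75/59.16/7.88%), with the patient-like chain more persistent
  in sparse state III and less persistent in state IV.
* **Emissions.** Zero-mean Gaussian draws with the current state's
  covariance plus isotropic noise (default sd 0.1), drawn from the
  stationary distribution at t = 1. Observations are temporally
  independent given the state by default, keeping occupancy checks
  exact; an AR(1) coefficient (suggested value 0.3) is available for
  smoother, more fMRI-like series, with innovations scaled by
  `sqrt(1 - ar^2)` so the stationary marginal covariance stays the
  archetype. TR defaults to 2.24 s so that 207 TRs span roughly eight
  minutes; no claim is made that this equals any particular scanner's
  TR, and it only matters to frequency-domain operations.
* **Covariates and scores.** Age ~ N(65, 9^2), education ~ N(8, 4.6^2),
  sex Bernoulli(0.45) — cosmetic inputs for covariate adjustment. The
  planted clinical score is
  `score = 5 - 10 x (true state-III occupancy) + noise`. The noise sd
  (default 4.8) was calibrated once from the sd of true state-III
  occupancy under the patient-like chain at 207 TRs (about 0.168),
  targeting a population correlation near -0.33 — strong enough that a
  two-sided test at n = 100 recovers the association in at least 90% of
  cohorts, while staying in the weak-to-moderate range typical of
  score-connectivity effects.

### What the generator does and does not emulate

It emulates the latent-state structure the sliding-window analysis
assumes: piecewise-stationary covariance, group-specific switching, and
score-occupancy coupling. It does not emulate hemodynamic convolution,
1/f noise, motion, spatial maps, or ICA estimation error. Passing the
planted-recovery tests therefore shows the *estimators* are correct and
well-calibrated under their own model; it does not certify performance
on real fMRI, where window non-stationarity within states and slow
autocorrelation blur state boundaries further.

### The validation regime

Window-level covariance estimates at w = 22 carry per-edge noise of
roughly 0.2 on the z scale, so recovery guarantees are only meaningful
when planted states are strongly separated. `validationCohortConfig`
plus `validationArchetypeSpec` define that regime: amplified contrasts
with deliberately heterogeneous between-block levels (uniform levels
make two states' patterns exactly collinear, and correlation-based
matching cannot distinguish them), chains with mean dwell around 50-90
TRs so most windows fall inside a single state run, and observation
noise 0.02. Under this regime the elbow selects k = 4, matched
centroid-archetype correlations exceed 0.9, and window-label agreement
reaches ~95%; the tests assert exactly these properties. The default
(realistic) configuration, with its fast switching and magnitude-only
II/III separation, is intentionally *not* a regime where k is cleanly
identifiable at 185 windows per subject — that mirrors the practical
difficulty of model selection in dFNC, and is why the validation regime
exists as a separate, documented object.

## Numerical choices

* Correlations are clamped to `|r| <= 1 - 1e-7` before `atanh`.
* PD repair floors eigenvalues at 1e-6 then rescales to unit diagonal.
* The glasso inner lasso iterates to 1e-8 on coefficient changes, capped
  at 200 passes; the outer loop stops at 1e-4 relative change or 100
  sweeps. Symmetry of the precision matrix is enforced by averaging the
  two column solves. Because sweep order follows variable order, results
  under component relabelling agree only to the convergence tolerance.
* k-means ties in `topEdges` and in feature ranking break by index;
  state relabelling ties break by centroid norm. Both are deterministic.
* All randomness descends from one root seed through a fixed integer
  hash, so every result is bit-reproducible; per-restart and per-subject
  seeds stay below 2^31.

## Problem sizes in the test-suite and validation runs

The packaged tests validate at deliberately compact sizes: recovery
cohorts of 8-30 subjects at 207 TRs and 37 components, elbow searches
over k = 2..10 with 4-10 restarts per k against a 100-restart default
for final fits, 200-replicate Monte-Carlo loops for score-recovery and
type-I-error calibration run on 4-component cohorts where only the
chains matter, and permutation tests at 19-99 permutations against a
1000-permutation default. These sizes are the package's chosen
validation design: each property is tested at the smallest scale at
which it is expected to hold with margin.

## Known limitations

* The occupancy chi-square treats pooled windows as counts; its p-value
  ignores within-subject dependence (documented above).
* Exact Mann-Whitney enumeration is restricted to small samples
  (`n1 + n2 <= 10` by default); beyond that only the tie-corrected
  normal approximation is reported.
* The despiking baseline is polynomial, not AFNI's L1 Fourier fit;
  results differ in detail from 3dDespike on real data.
* `lambda` is fixed per run (default 0.1), not tuned per subject;
  per-subject cross-validated tuning is a possible extension, and the
  estimator interface already isolates the penalty as a parameter.
* Classification accuracies on real cohorts depend on the real data's
  separability; the package asserts behaviour (perfection on separable
  cohorts, chance on permuted labels, valid permutation p-values), not
  any particular real-data accuracy.
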