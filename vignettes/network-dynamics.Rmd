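---
title: "Time-averaged and transient oscillatory network analysis with netdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-averaged and transient oscillatory network analysis with netdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

netdyn characterises large-scale cortical networks in parcellated
electrophysiological (MEG/EEG) recordings from two complementary
perspectives: a *time-averaged* (static) description — band-specific
power maps and coherence networks — and a *transient* (dynamic)
description, in which a hidden Markov model segments the recording into
recurring network states with their own spectra, connectivity and
dynamics. A group-level permutation GLM then relates either description
to subject covariates such as age or cognitive performance while
controlling for confounds. This vignette explains the models, the
parameters that matter, the synthetic cohort generator used for
validation, and the numerical choices behind the implementation.

## Input data

Every stage consumes `ParcelTimeSeries` objects: one numeric matrix per
subject with one row per cortical parcel and one column per sample, plus
the sampling rate (250 Hz by default throughout). The package assumes
source reconstruction, parcellation and artefact cleaning happened
upstream; parcel time courses are z-scored per parcel before any
spectral estimation, so all power quantities are relative (fractions of
each parcel's unit variance), which is also why a multiplicative "gain"
effect in the generator surfaces as a redistribution of spectral mass
rather than a change in total power.

## Time-averaged networks

**Multitaper P/CSD.** `multitaperSpectra()` averages tapered
periodograms over DPSS (Slepian) tapers and windows. Defaults: 2 s
windows (0.5 Hz resolution), 0% overlap, time-half-bandwidth product
NW = 4 and `2*NW - 1 = 7` tapers — standard resting-state MEG settings.
The "4 Hz time half bandwidth" phrasing common in the field is
dimensionally ambiguous; with 2 s windows only the dimensionless reading
NW = 4 is consistent with 7 tapers, so that is what the package
implements. Densities are one-sided and normalised so that the PSD
integrates to the signal variance; a white-noise input therefore has the
analytic level `2/fs`, which the tests exploit. The trailing partial
window is dropped, not zero-padded. DPSS tapers are computed from the
classical symmetric tridiagonal eigenproblem and verified against an
independent reference implementation in the tests.

**Coherence.** `coherenceFromSpectra()` forms
`C_xy = |CSD_xy| / sqrt(PSD_x PSD_y)`, bounded in [0, 1], unit diagonal,
symmetric. For a mixture `y = a x + noise` the closed form
`a sx / sqrt(a^2 sx^2 + sn^2)` provides an exact oracle that the
estimator must match within Monte-Carlo tolerance.

**Bands.** Canonical bands are delta 1–4, theta 4–8, alpha 8–13, beta
13–24 and gamma 30–45 Hz. Intervals are half-open `[low, high)` so
touching limits are not double counted; the 24–30 Hz gap is deliberate
(an artefact-prone range excluded from analysis). `bandCollapse()` takes
the simple mean over bins whose centre falls in the band.

**Maps, networks, referencing.** Band power per parcel gives a power
map; band coherence per parcel pair gives a network, and averaging each
parcel's off-diagonal edges gives a coherence map. For *display*,
band-specific values are referenced against the weighted average across
bands — weights proportional to each band's retained bin count, the
natural weighting on a uniform frequency axis — and networks are
thresholded to the top 3% of edges by absolute referenced value
(deterministic tie-breaking by parcel index). All statistics are
computed on unreferenced, unthresholded values; referencing is a
reporting aid only.

## Transient networks

**Preparation.** `prepareTrainingData()` time-delay embeds each parcel
(±7 lags by default, i.e. a ±28 ms window at 250 Hz; 52 parcels give
780 embedded channels), reduces to 120 channels with group-level PCA and
z-scores the result. The embedding trims `2L` boundary samples rather
than zero-padding, avoiding artificial covariance at the edges. The
group PCA is computed from a covariance accumulated subject by subject
(bounded memory) and is defined to equal PCA of the concatenated data;
component signs are fixed (largest-magnitude loading positive) so runs
are comparable. Standardisation happens after the PCA projection, i.e.
the chain is embed, project, z-score.

**Model.** The HMM assumes, at each sample, a categorical hidden state
`theta_t` in 1..K with first-order Markov transitions `A[i, j]`, and
state-conditional observations `x_t | theta_t = k ~ N(0, D_k)`. Means
are pinned at zero so states are *covariance* patterns — on time-delay
embedded data, covariance encodes spectra and cross-spectra, so states
are spectrally distinct transient networks. K defaults to 10, the usual
choice in this literature.

**Inference.** The default is full-batch Baum–Welch EM with
maximum-likelihood M-steps: it is deterministic given a seed, exactly
matches the generative model, and its log-likelihood is provably
nondecreasing, which the tests assert. Forward–backward runs in C++
with per-sample rescaling, so sequences beyond 1e5 samples do not
underflow. A diagonal regulariser (`covReg`, default 1e-5 of the mean
state variance) guards against singular accumulated covariances;
genuinely degenerate data produce an error advising a positive value. A
stochastic mini-batch mode (`method = "stochastic"`) is available for
large cohorts: it blends batch sufficient statistics with a
Robbins–Monro step size `(i + delay)^-forgetRate`; its defaults
(batch size 2, forget rate 0.7, delay 5) are this package's documented
choices. Because restarts land in different local optima, `fitHMM()`
trains `nRuns = 5` models by default and keeps the one with the lowest
final objective (negative log-likelihood — lower is better), with ties
going to the earliest run.

**Dynamics.** `mapStates()` collapses posteriors to a mutually
exclusive state sequence (argmax per sample, ties to the lowest index).
`summaryStats()` computes, per state: fractional occupancy, mean
lifetime (ms), mean interval (s) and switching rate (Hz, visit onsets
per second, the first visit counting as an onset). Two interval
conventions exist in the literature; the default measures the exclusive
gap between the end of one visit and the next onset, with
`intervalMode = "onset"` for onset-to-onset. Lifetime means include the
possibly censored first and last visits by default (`censorEdges`
excludes them). Never-visited states get occupancy 0, switching rate 0
and *missing* (not zero) lifetime and interval; missingness propagates
into the GLM stage, where affected subjects are dropped per feature with
a reported count. `subjectTransitionMatrix()` counts all pairwise
transitions including self-transitions, so its diagonal is the per-state
stay probability.

**Dual estimation.** Per subject and state, the standardised parcel
data are multiplied by the state's binary MAP indicator (soft posterior
weighting is deliberately not used: the post-hoc analyses are defined on
the mutually exclusive sequence), the multitaper P/CSD is recomputed
with the same settings over 1–80 Hz, coherence is formed, and the PSD is
rescaled by the inverse fractional occupancy to undo the masking
amplitude bias. Coherence self-normalises and needs no rescaling.
Windows straddling state boundaries are retained with zeros inserted —
the resulting leakage is accepted and small at realistic lifetimes; the
tests verify that the occupancy-weighted state PSDs reconstruct the
static PSD within 5%. When the state sequence is shorter than the
recording by the embedding trim, the recording is trimmed symmetrically
and re-standardised before masking — that trim-then-standardise order is
this package's contract. State maps average over the full retained
range rather than a hand-picked band, since each state carries its own
characteristic spectrum; display referencing uses the uniform mean
across states.

## Group-level inference

**Cognitive score reduction.** `reduceScoresPCA()` z-scores each task,
applies PCA across subjects and keeps the first component, with the sign
fixed so the mean loading is positive (higher score = better
performance across tasks).

**Design.** `buildDesign()` assembles constant + interest + confounds,
z-scoring all non-constant columns. The full design used in the
pipelines has 11 columns: constant, age, sex, total brain volume,
relative grey- and white-matter volume, head size, three head-position
coordinates and the reduced cognitive score. For cognition analyses age
is included as a confound, so cognitive effects are not indirect age
effects. Exact collinearity is rejected with the offending pair named.

**Permutation test.** `maxstatSignflipTest()` fits the GLM to all
features jointly, then builds a single null distribution by repeatedly
flipping the sign of each interest-regressor entry with probability 1/2,
refitting, and recording the maximum absolute statistic across features.
This max-statistic construction controls the family-wise error rate
across all features simultaneously; the tests verify calibration on
fully null cohorts against the exact binomial interval. P-values use the
`(1 + count) / (1 + nPerm)` estimator, so they are never exactly zero
and the identity permutation need not be forced into the null. The
statistic is the raw coefficient by default; for feature sets with
heterogeneous scales (the dynamics statistics) the t-statistic is used.
The flipped interest column is re-standardised before refitting: every
regressor in a design is z-scored, and leaving the permuted column
unstandardised would inflate null coefficients relative to the observed
ones, making the test needlessly conservative.

Two calibration findings from validation are worth knowing. Even with
re-standardisation, the raw-coefficient variant stays slightly
conservative in multi-regressor designs (family-wise rejection around
0.035-0.04 at nominal 0.05): a flipped column picks up random in-sample
correlation with the confounds, inflating its coefficient's sampling
variance in the null fits. The t-statistic standardises by the
design-dependent standard error and is near-exact; it is the variant to
reach for when exact calibration matters. Conversely, with a *strongly*
confound-correlated interest regressor (|r| around 0.7) the
raw-coefficient variant turns mildly anticonservative — the observed
coefficient's variance is inflated by the true collinearity that
sign-flipping destroys — while the t-statistic again stays calibrated.
At the moderate correlations typical of age and brain-volume covariates
(|r| around 0.4) both variants behave well.

## The synthetic cohort generator

Real resting-state cohorts cannot ship with a package, so validation
runs on `simulateCohort()`, which emulates the features the pipeline is
sensitive to:

- **Markov-switching oscillations.** Each state specifies per-parcel
  resonance frequencies and gains. Oscillators are damped AR(2)
  resonators (pole radius fixed at 0.95, giving clear spectral peaks at
  desk scale) driven by white noise; frequency 0 or gain 0 yields
  broadband noise. States switch abruptly sample-wise, matching the
  HMM's piecewise assumption; an optional short crossfade exists but is
  off by default.
- **Coherence.** Parcels in a coupling group share a configurable
  fraction of their driving innovation variance, inducing coherence
  concentrated at the state's resonance.
- **Covariates.** Ages are uniform on 18–88 years; brain volumes and
  head geometry are Gaussians with configurable correlation to age
  (defaults: total brain volume -0.4, grey -0.5, white -0.2), so
  confound regression is exercised non-trivially. Ten cognitive task
  scores load positively on a latent factor whose age slope defaults to
  -0.5; the latent residual sd is `sqrt(1 - slope^2)`, making the factor
  unit-variance for |slope| <= 1 and fully age-determined at |slope| = 1.
- **Effects.** Covariate effects are applied on the logit scale for
  stay probabilities and coupling strengths (rows remain stochastic,
  strengths remain in (0, 1)) and multiplicatively on gains (which stay
  nonnegative). The exact per-subject transition matrices, gains and
  couplings are returned as ground truth.
- **Heterogeneity.** Per-subject log-normal gain jitter (sd 0.1)
  emulates inter-subject spectral variability; no published generative
  account of that heterogeneity exists, so this random-gain model is one
  plausible choice among several.

Defaults define the study conditions: K = 10 states with stay
probability 0.94 (mean lifetimes near 70 ms, the time scale typical of
MEG network states), 250 Hz sampling and 10 cognitive scores. What the
generator does *not* emulate: source leakage and field spread, head
movement, non-stationary vigilance drifts, 1/f background shape and
sensor-level artefacts. Passing tests therefore demonstrate the
pipeline's internal correctness and statistical calibration, not
robustness to those real-data complications.

## Numerical choices and problem sizes

- Degenerate inputs error early and informatively: constant channels in
  standardisation, zero PSD bins in coherence, non-stochastic transition
  matrices, rank-deficient designs (with the offending pair named).
- Ties are broken deterministically everywhere: argmax state selection
  and run selection take the lowest index, edge thresholding orders by
  (|value|, parcel, partner).
- All stochastic stages consume explicit seeds, and one pipeline seed
  fans out to derived per-stage seeds, so a rerun with the same
  configuration is bit-identical.
- Validation problem sizes were chosen as desk-scale study conditions:
  HMM recovery uses 5 channels, 3 states and 10 subjects of 2e4 samples;
  permutation calibration uses 200 null cohorts of 40 subjects with 500
  sign flips; end-to-end recovery uses 20 seeds of 50–60-subject cohorts
  at 12–16 s per subject. At these sizes the full validation suite runs
  in minutes on a single CPU while leaving narrow Monte-Carlo margins.

## Known limitations

- The HMM assumes zero-mean Gaussian emissions; amplitude
  non-Gaussianity in real recordings is absorbed into the covariances.
- The number of states K is fixed, not inferred; model comparison across
  K is out of scope.
- Only magnitude coherence is implemented — no imaginary coherence,
  phase-locking or amplitude-envelope variants, so zero-lag leakage in
  real source-space data will inflate connectivity unless orthogonalised
  upstream.
- The sign-flip test assumes the interest regressor's sign symmetry
  under the null; see the calibration caveat above for strongly
  correlated confounds.
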