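---
title: "Movement HMMs for fine-scale crab telemetry: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement HMMs for fine-scale crab telemetry: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crabHMM)
```

This vignette is the package's own account of the statistical machinery:
what is modelled, which knobs matter, what the synthetic generator does
and does not emulate, and where genuinely open design choices were
resolved.

## The data-generating picture

An acoustically tagged crab transmits at independent uniform random
intervals (150–210 s). A receiver array converts time differences of
arrival into planar position estimates with low, right-skewed error
(median around 1.26 m in a well-performing array); each transmission also
carries an RMS acceleration summary on 0–3.4 m s⁻². Detections are lost
to burial, emigration and collisions, so the series is irregular with
occasional long gaps.

Discrete-time HMMs need regular observations, which motivates the
two-stage design: a continuous-time movement model absorbs the
irregular timing and positional error, and the behavioural model works
on its regular-grid predictions.

## Track regularization (CTCRW)

Per track, position integrates an Ornstein–Uhlenbeck velocity,
$dv = -\beta v\,dt + \sigma\,dW$, with observations
$z_t = x_t + \varepsilon_t$, $\varepsilon_t \sim N(0, R)$. `fit_ctcrw()`
maximizes the Kalman-filter likelihood over $(\log\beta, \log\sigma^2)$;
`predict_regular()` runs the RTS smoother over the union of detection
and grid times.

Choices a maintainer should know about:

* **Splitting before smoothing.** Gaps longer than 4 interpolation
  intervals are never interpolated across (predictions there would be
  straight, artificially confident lines); segments under 100 detections
  are discarded as numerically and behaviourally uninformative. The gap
  rule is strictly "greater than", which the tests pin down at the
  boundary.
* **Initial state.** Diffuse position prior (10⁶ m² per axis — a 1 km
  SD, diffuse at array scale while keeping the likelihood numerically
  well conditioned against the direct joint-normal evaluation used as a
  test oracle) and the stationary velocity prior $\sigma^2/2\beta$.
* **Restarts.** 50 by default, log-normal multiplicative perturbations
  (SD 0.5 on the log scale) around moment-based starts; the count
  follows the field's multi-restart convention, the perturbation law is
  a package choice.
* **Smoother, not filter.** Grid predictions are interior to a track, so
  two-sided information is the defensible default.
* **Grid anchoring.** The grid starts at the first detection time
  rounded up to the interval — a convention; nothing downstream depends
  on the phase of the grid.
* **Error covariance.** Defaults to the isotropic covariance implied by
  a reference-tag audit (`audit_reference_tag()`); per-detection
  covariances are not currently propagated.
* **Time units.** Hours internally, so $\beta$ is h⁻¹; at the 3-min
  median transmission spacing this keeps both parameters O(1).

## Observation streams

Step length and interval-mean RMS acceleration are zero-inflated gamma
(gamma parameterized by mean and SD; an atom at exactly zero carries the
no-movement probability). Turning angle is wrapped Cauchy with the mean
direction fixed at 0 — behaviourally, persistence versus tortuosity is
carried by the concentration $\rho \in [0, 1)$, and freeing the mean
mostly soaks up noise. The first/last angle and last step of each track
are undefined and enter the likelihood as unit factors, as does any
interval without a transmission (missing acceleration).

A zero mass is estimated only for streams in which exact zeros occur in
the data; otherwise it is fixed at 0 rather than pushed to a logit
boundary.

## Transition model and random effects

Off-diagonal transition probabilities follow a multinomial logit in
time-varying covariates; the design row at $t-1$ governs the transition
into $t$. Tide height and Δ-tide enter only together (with their
interaction when requested) — `fit_hmm()` enforces this and
`covariate_formulas()` enumerates candidate formulas under the same
constraint. Δ-tide is a backward difference over a fixed 15-min lag at
every interpolation interval, so its units and interpretation (flood
positive, magnitude ∝ current strength) do not drift with the grid.
Hour-of-day enters through one harmonic pair with a 24 h period, on
local clock time (diel behaviour follows solar time, so UTC would
misalign the phase). Habitat polygons are dilated by a 1.26 m buffer
(the positioning error scale); overlaps resolve by the fixed priority
seagrass > mangrove > saltmarsh — a convention, stated rather than
derived.

The discrete random effect follows the mixed-HMM construction: each of
K transition-coefficient sets has a weight, an individual's tracks share
one latent set, and the marginal likelihood sums over sets per
individual (log-sum-exp stabilized). K = 1 is the ordinary HMM; the AIC
comparison across K is how individual variation is assessed.

Per track the initial state distribution is the stationary distribution
of its first realized transition matrix — the equilibrium reading that
also underlies the stationary-probability curves; the alternative
(estimating free initial distributions) spends parameters on a nuisance.

## Fitting

Everything is estimated on a working scale (log means/SDs, logit zero
masses and concentrations, raw transition coefficients, multinomial
weight logits) by BFGS from data-driven starts: k-means on
(log1p step, log1p accel) gives per-cluster moments, the mean resultant
length gives concentration starts, and restarts add standard-normal
working-scale noise (the first restart is unperturbed). The objective
subtracts an N(0, 100) log-prior on the working-scale SD parameters —
pure boundary insurance; between working values 0 and 1 it changes the
objective by 5×10⁻⁵, and the tests verify the closed form. AIC uses the
unpenalized log-likelihood at the penalized optimum, treating the prior
as the numerical device it is. States are relabelled so state 1 has the
largest step mean, which makes parameters comparable across fits and
resolves label switching.

Convergence is reported from the optimizer plus the central-difference
gradient norm at the optimum; the restart log (objective and convergence
per restart) is kept in the fit object, and the best-of-restarts
contract is asserted in the tests.

## Post-fit inference

* **Viterbi** decodes the global MAP path in log space (ties toward the
  lower state index); forward–backward supplies smoothed per-interval
  probabilities. With K > 1, an individual is decoded under its MAP
  mixture component.
* **Stationary curves** solve $\pi P(x) = \pi$ along one covariate with
  the others fixed at their mean/mode (default) or averaged over
  observed rows; 95% CIs come from a finite-difference delta method on
  the transition coefficients through the stationary solve, truncated to
  [0, 1]. The CI construction is a package choice.
* **Pseudo-residuals** are one-step-ahead (forecast) probability
  integral transforms per stream through $\Phi^{-1}$; the forecast state
  weights condition on all streams up to $t-1$. Zero atoms get
  randomized quantile residuals — a seeded uniform draw within the
  atom's forecast mass — the standard device for mixed
  discrete/continuous forecasts.
* **The 12 h diagnostic** replaces a visual judgement with a number: the
  periodogram ordinate nearest the semidiurnal frequency relative to the
  median of its flanking ordinates. White noise scores ≈ 1 (the max of
  three exponential ordinates over a flank median stays well below 10),
  so 10 is used as the detection threshold; an injected semidiurnal
  signal scores in the hundreds.
* **Occupancy** is the pooled fraction of Viterbi-decoded intervals per
  state, matching the usual "time spent per behaviour" summary (not the
  mean smoothed probabilities).

## The synthetic generator

`simulate_hmm_data()` / `simulate_observations()` /
`simulate_detections()` emulate the study conditions this package is
built around: uniform 150–210 s transmissions, two-state switching with
self-transitions 0.91/0.96, and the published state-dependent
parameters as defaults — state 1: step 13.98 ± 18.10 m,
concentration 0.51, acceleration 0.59 ± 0.63 m s⁻², Pr(0) = 0.006;
state 2: step 0.75 ± 0.93 m, Pr(0) = 0.014, concentration 0.70,
acceleration 0.04 ± 0.02 m s⁻², Pr(0) = 0.002. Two reported values need
a decision: the state-1 step zero mass is published only as
"« 0.001" (5×10⁻⁴ is used), and the state-2 acceleration SD is printed
as 0.02 in the parameter table but 0.01 in the accompanying text (the
table value is used). Acceleration draws are clipped at the 3.4 m s⁻²
sensor ceiling; at the default parameters the clipped mass is ~0.5%, far
inside estimation tolerance.

Positional error defaults to isotropic Gaussian with a 1.07 m per-axis
SD, chosen so the Rayleigh radial error has median ≈ 1.26 m — the scale
of a real array audit. Real array error is right-skewed, not Rayleigh;
a log-normal radial option exists for skewness studies, and the audit
op characterizes whichever is produced. Dropout is Bernoulli thinning by
default, with an optional two-state on/off chain for temporally
clustered loss (burial); the real detection probability and dropout
structure of an array are unknown, so both are free parameters, not
asserted values. The TDOA module assumes a constant Coppens sound speed
and ideal spherical propagation — no multipath, attenuation or
code-collision physics.

Consequently, passing tests show the estimation machinery is correct
and well calibrated *under the assumed model*; they cannot show that
real crab telemetry satisfies those assumptions (skewed positioning
error, non-Poisson dropout, behaviour outside the two-state repertoire,
tag effects).

## Problem sizes and numerical settings

The test suite runs parameter recovery at 20 tracks × 2,000 15-min
intervals (the scale at which all state-dependent means, SDs and
concentrations are recoverable within a few percent) and keeps
unit-level fits at a few hundred intervals, which is where the
likelihood surface is already well behaved for well-separated states.
Exhaustive-enumeration oracles cover T ≤ 8, N ≤ 3 (forward likelihood
and Viterbi, tolerance 10⁻¹⁰); the CTCRW Kalman likelihood is checked
against a directly assembled joint-normal density on 4-point tracks
(10⁻⁸). Quadrature confirms unit mass of both emission families
(10⁻⁶ / 10⁻⁸); realized transition matrices are row-stochastic to
10⁻¹². BFGS uses a relative tolerance of 10⁻⁹ with up to 300
iterations; optimizer excursions that overflow the natural scale are
mapped to a large objective value rather than propagating NaNs.

## Known limitations

* Discrete-time HMM on an interpolated grid: positional smoothing
  correlates adjacent observations slightly, which the conditional
  independence assumption ignores (visible as mild residual
  autocorrelation at short intervals — one reason coarser grids can
  diagnose better).
* Per-detection error covariances are not propagated from the TDOA
  stage into the CTCRW.
* Stationary-curve CIs treat emission parameters as fixed
  (delta method on transition coefficients only).
* The mixture random effect covers transition dynamics only; emission
  parameters are shared across individuals.
* No continuous-time HMM, hierarchical multi-timescale states, or
  Bayesian posterior sampling.
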