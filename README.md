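# crabHMM

Behavioural-state classification for fine-scale acoustic telemetry of
estuarine crustaceans.

Giant Mud Crab (*Scylla serrata*) and similar benthic animals are tracked
in estuaries with accelerometer-equipped acoustic tags and hyperbolic
(time-difference-of-arrival) positioning arrays. The resulting data are
irregularly timed, noisy point estimates of position plus an RMS
acceleration summary per transmission. `crabHMM` implements the full
analysis chain that turns such detections into decoded behavioural states
and their environmental drivers:

1. **Track preparation** — detections are split into gap-free tracks
   (cut where the gap exceeds 4× the interpolation interval; tracks with
   fewer than 100 detections dropped) and regularized to a 5/10/15-min
   grid with a continuous-time correlated random walk (CTCRW): position
   integrates an Ornstein–Uhlenbeck velocity,
   dv = −β v dt + σ dW, observed with bivariate Gaussian positional
   error, fitted by maximum likelihood via the Kalman filter with 50
   perturbed restarts and predicted with the RTS smoother.
2. **Observation streams and covariates** — step length s_t (m), turning
   angle θ_t ∈ (−π, π] and mean RMS acceleration a_t per interval; tide
   height, Δ-tide (15-min backward difference; + flood, − ebb), the
   harmonic pair cos(2πt/24), sin(2πt/24), and habitat category with a
   1.26 m buffer.
3. **Hidden Markov model** — an N-state multivariate HMM (N ∈ {2, 3}):
   s_t and a_t are zero-inflated gamma, θ_t wrapped Cauchy with mean
   fixed at 0 and estimated concentration ρ_i; transition probabilities
   follow a multinomial logit in the covariates,
   P_ij(t) = exp(η_ij(t)) / (1 + Σ_j′ exp(η_ij′(t))); an optional
   discrete mixture of K transition-coefficient sets (K ∈ {1..4}) acts
   as an individual-level random effect. Fitting maximizes a penalized
   likelihood (N(0, 100) working-scale prior on the log-SDs) from 50
   random restarts.
4. **Inference** — Viterbi decoding, smoothed state probabilities,
   stationary state probabilities π(x) solving πP(x) = π with
   delta-method 95% CIs, forecast pseudo-residuals (randomized at the
   zero atoms), AIC model ranking across covariate sets and K, a
   periodogram diagnostic for unmodelled ~12 h periodicity, and pooled
   state occupancy.

A synthetic-data module generates tide series, state sequences,
state-dependent observations, transmission/detection processes
(uniform 150–210 s intervals, Bernoulli or burial-style dropout,
isotropic Gaussian or log-normal positional error) and TDOA positioning
(Coppens sound speed, multilateration, clock-skew correction), so the
whole pipeline is testable without field data.

## Worked example

```r
library(crabHMM)

# simulate 5 tracks x 500 15-min intervals from the default two-state
# behaviour (rare fast "foraging", common near-sessile "inactive")
d <- simulate_hmm_data(n_tracks = 5, n_intervals = 500, seed = 42)

fit <- fit_hmm(d, n_states = 2, n_restarts = 5, seed = 1)
fit
#> Movement hidden Markov model (2 states, K = 1)
#>   transition formula: ~1
#>   log-likelihood -3556.94, 16 parameters, AIC 7145.87
#>                     state 1 state 2
#> step_mean            13.015   0.750
#> step_sd              16.768   0.940
#> step_zeromass         0.001   0.017
#> angle_concentration   0.531   0.681
#> accel_mean            0.609   0.041
#> accel_sd              0.658   0.020
#> accel_zeromass        0.004   0.005

dec <- viterbi(fit)
occupancy(dec)
#> state1 state2
#> 0.2984 0.7016
mean(dec$state == d$state)  # decoding accuracy against simulated truth
#> [1] 0.9944
```

State 1 is the fast state by construction (states are relabelled by
descending step mean): here ~13 m per 15 min with acceleration
~0.6 m s⁻², against sub-metre steps and ~0.04 m s⁻² in state 2 — the
estimates recover the generating parameters, and the Viterbi decode
assigns 99.4% of intervals to the true state. `summary(fit)` adds the
transition coefficients and the realized transition matrix;
`plot(fit)` overlays the state-dependent densities on the observation
histograms; `stationary_probabilities(fit, "tide")` traces equilibrium
state probabilities along a tidal gradient when tidal covariates are in
the model.

For raw detection tables, `run_pipeline()` orchestrates everything from
CSV inputs (detections, tide gauge, optional GeoJSON habitat layer) to
written artefacts — model ranking, decoded states, residual
diagnostics, occupancy — from a single YAML/list config; reruns with
the same config and seed are byte-identical.

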