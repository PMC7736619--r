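---
title: "Models and methods behind voltdecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind voltdecode}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(voltdecode)
```

voltdecode reconstructs, on fully synthetic data with known ground truth,
the computational chain used to study sub-second dopamine (DA) and
serotonin (5-HT) signaling during human perceptual decision-making:
fast-scan cyclic voltammetry (FSCV) measurement, a range-grid elastic-net
decoder from voltammograms to concentrations, a factorial random-dot-motion
task with staircase calibration, and event-locked encoding statistics.
This vignette documents the models, the tunable parameters and the design
choices; nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The FSCV forward model

A measurement consists of a triangular voltage excursion (by default
−0.6 V to +1.4 V at 400 V/s: a 10 ms sweep digitised at 100 kHz into 1000
samples, repeated at 10 Hz with a 90 ms hold; a 6.67 ms hold gives the
60 Hz conditioning protocol). The induced current trace — the
voltammogram — carries analyte information.

The synthetic probe model treats the current as

current(s, t) = baseline(s) + g_DA·DA·T_DA(s) + g_5HT·5HT·T_5HT(s)
  + g_pH·(pH − 7.4)·T_pH(s) + drift(t) + ε,

with `s` the sample index, affine gains `g` (zero response at zero
concentration for the monoamines, and at pH 7.4), unit-response templates
`T`, and i.i.d. Gaussian current noise ε. Current units are arbitrary: the
decoder differentiates every sweep and all downstream analyses z-score
per trial, so only relative structure matters. A saturating gain is
deliberately not modelled; the calibrated range (0–4500 nM) is treated as
the affine regime, consistent with the overall-linear
predicted-versus-known relationship the method is known to produce.

**Templates.** Each analyte responds with two smooth Gaussian lobes at
distinct positions along the sweep (a main oxidation-like feature plus a
secondary lobe), so information is distributed over the sweep rather than
confined to a single peak. Pairwise template cosines stay well below the
0.95 identifiability bound, and a least-squares inversion of a noiseless
sweep recovers (DA, 5-HT, pH deviation) to numerical precision — the test
suite asserts both.

**Probe-to-probe variation.** Probes drawn from one construction process
vary mainly in surface kinetics and sensitivity, so variation is
structured as electrode-level common modes — a shared shift of every
feature along the sweep (SD 0.0015 sweep fractions), a shared width scale
(SD 1.5%), a baseline scale (SD 5%) and per-analyte gains (SD 10%) — plus
small per-feature residuals (centre SD 0.0015, width SD 1.5%, lobe
amplitude SD 4%). These magnitudes were calibrated once so that the
emulated probe population reproduces the behaviour the real system is
reported to have: models trained on a handful of probes generalise to
withheld probes with high sensitivity (predicted-vs-known R² around
0.9–0.95 at default noise) and high specificity (pH-induced spurious
monoamine excursions a few percent of a 900 nM step response). Under
large independent per-analyte template jitter the cross-electrode
transfer that defines the method would be impossible by construction,
which would make the generator a caricature rather than an emulation.

**Noise and drift.** Per-sample current noise defaults to `noise_sd =
0.25` (arbitrary units), chosen so naive-probe decoding R² lands near
0.9. Baseline drift is a smooth quasi-periodic function of recording time
(two slow sinusoids, periods 300 s and 97 s, probe-specific phases). A
deterministic function of `t` was preferred over a stateful random walk
so any sweep can be regenerated byte-identically in isolation; because
drift shifts a whole sweep additively, it is annihilated by the
differentiation step, exactly like the slow drift the real measurement
tolerates.

**In vitro timelines.** The flow-cell dwell structure has no canonical
quantitative specification, so the timing here is this package's invention:
each concentration level is held for `dwell` sweeps (default 40) and the
ladder repeated (3 passes for the monoamines, 5 for pH), so that the
third quarter of each level's dwell — the part kept for training, to
avoid equilibration and flow artifacts — supports the per-probe sampling
budget of 2500 DA + 2500 5-HT + 500 pH rows.

## The decoder

Training pools differentiate every sweep (1000 samples → Q = 999
features) and label it with (DA, 5-HT, pH). The 0–4500 nM range of each
monoamine is split into five 900 nM intervals, a 5 × 5 grid; cell (i, j)
trains on DA-protocol rows in range i, 5-HT-protocol rows in range j and
the full pH data (identical in every cell). Per cell, multi-response
Gaussian models are fitted under the elastic-net penalty
P_α(β) = (1 − α)·½‖β‖₂² + α‖β‖₁ for α ∈ {0, 0.1, …, 1} with 10-fold
cross-validation (`glmnet::cv.glmnet`, `family = "mgaussian"`, the standard
implementation of this algorithm family); within α the λ minimising
mean CV error is kept, then the α with the lowest CV error wins the cell.
Fold assignment is seeded and stratified by probe so no electrode leaks
across folds (fold construction is otherwise unconstrained; probe
stratification is the conservative choice). Features are standardized
inside the penalized fit and coefficients returned on the original scale.

For decoding, all 25 cells predict every sweep and the cell minimising

e_ij = Σ_n (Y_DA,n − r̄_i)² + Σ_n (Y_5HT,n − r̄_j)²

is selected, where r̄ are the cell's range midpoints and a cell whose
modal predicted sign for either monoamine is negative is assigned
infinite error. Sign zeros count as their own modal category and ties
break toward admissibility; ties in e break in row-major order; if every
cell is inadmissible the decoder raises an explicit no-admissible-cell
error rather than guessing. Negative selected predictions are not
clipped — per-trial z-scoring makes downstream analyses invariant to
affine miscalibration anyway (a property the tests assert).

One practical caveat discovered with the synthetic rig: on in vitro
evaluation ladders where the *other* monoamine is truly absent, its
predictions hover around zero and the modal-sign rule becomes a coin flip
that is correlated across cells. `evaluate_on_naive_probes()` therefore
restricts selection to the varied analyte (single-analyte ladders) or
disables the sign rule (pH sweeps). In vivo decoding, where tonic levels
keep true concentrations positive, uses the strict rule unchanged.

## The task engine

The task is a continuous-direction random-dot-motion judgement against a
variable reference: motion direction uniform on 1–360°, reference within
±45°, responses counterclockwise/clockwise, confidence probed on about a
third of trials on a 50–100% scale in steps of 10. Coherence (sensory
uncertainty) and distance (decision difficulty) are crossed 2 × 2 and
sampled independently each trial.

The synthetic observer perceives the motion direction with von Mises
noise of concentration κ(C) = 9·C^0.8 (radians⁻¹), decides by the side of
the percept relative to the reference, lapses with probability 0.01,
draws RT from a shifted lognormal decreasing in coherence and distance,
and maps its normalized angular margin onto the discrete confidence
scale. The κ map's shape was chosen so that all three calibration
staircases have interior fixed points within the task's bounds
(coherence ≤ 1, distance ≤ 45°); with steeper maps the low-coherence
distance staircase pins at the 45° display limit. `p_correct()` computes
choice accuracy by direct numerical integration of the von Mises density
— the independent oracle the Monte Carlo tests compare against.

Calibration mirrors the two-down-one-up procedure (steps: coherence
±0.01, distance ±1°; harder after two correct, easier after one error):
coherence and distance blocks alternate (block length 20 trials, a
configurable package default), C_M is staircased at D_M (initialised 0.3 and
20), the two distance staircases run interleaved within distance blocks
(D_L at high coherence 2·C_M, D_H at low coherence C_M/2), and D_M is
re-derived as their midpoint between blocks. The three-staircase system
has no exact joint fixed point (the midpoint of the two calibrated
distances is slightly easier than the distance that would hold the
coherence staircase at threshold), so "convergence" is quasi-stationary;
the stationary property that is exact is the two-down-one-up asymptote
itself, √0.5 ≈ 70.7% correct on staircase trials. Accordingly,
`staircase_stationary_accuracy()` freezes the calibrated coherence pair,
continues the two distance staircases, and measures accuracy over
post-burn-in staircase trials — this is the quantity asserted at 68–74%
and reported by the acceptance script.

## Preprocessing and statistics

Decoded series are cut into stimulus-locked (−1…+5 s, 61 points at
10 Hz) or choice-locked (−4…+4 s, 81 points) snippets by
nearest-timestamp alignment (the decoder output is already on a uniform
10 Hz grid, so interpolation would be cosmetic). Each trial is z-scored
by its own mean and SD (constant rows become zeros and are flagged rather
than erroring, to keep batch runs alive), then smoothed with a causal
running mean over t−4…t (0.5 s); the first columns average the available
prefix. Z-scoring precedes smoothing, and the suite asserts the order
matters. Trials with RT beyond 3 SD of the session mean (raw RT — the
log-transform belongs to the behavioural regressions only) and the first
and last trial of each session are excluded; transition counting uses
original chronological neighbours and drops pairs broken by exclusion
rather than bridging them.

Statistical operations mirror the analysis chain being reconstructed: per-timepoint
equal-variance two-sample and one-sample t tests with an explicit
no-multiple-comparison convention (reports annotate this); a sliding
ordinary-least-squares encoding regression on z-scored coherence and
distance condition codes, their interaction (product of the z-scored
mains, re-z-scored), accuracy and log-RT, with per-participant intercepts
when sessions are pooled (at these trial counts the shrinkage a random
intercept would add is negligible, so fixed per-participant intercepts
realize the same estimate with far less machinery); RT terciles on raw RT
with rank-stable ties; 4 × 4 transition counts row-normalised into
P(type_t | type_t−1), response averaging over 0–1.5 s (16 samples), and
response-on-probability regressions reporting t with df = n − 2 (simple)
and n − 4 (controlled for the marginal probability of the current type
and per-transition accuracy). Behavioural effects are estimated with
lme4 mixed models (logistic for accuracy, linear for z-scored log RT and
confidence) with participant-level slopes and intercepts; fixed-effect p
values for the linear models use the normal approximation, appropriate at
thousands of trials.

## Problem sizes and numerical choices

The default pipeline scale ("reduced") uses 100-sample sweeps, 5 training
and 2 naive probes, 225 + 225 + 50 sampled rows per probe, 3 elastic-net
mixing values and 2 sessions of 120–300 trials — sized to run in minutes
while exercising every stage; `run_config(scale = "paper")` switches to
the full-scale study design (1000-sample sweeps, 20 + 6 probes,
2500 + 2500 + 500 rows, 11 mixing values). The acceptance suite trains
one 11-alpha grid at the reduced pool and shares it across checks; the
staircase and transition checks run at 10,000–100,000 trials. Effect
recovery measures the coherence-coefficient peak on unsmoothed snippets:
the causal 0.5 s window has a known group delay of about 0.2 s that would
otherwise bias the latency estimate by a full tolerance width.

Known limitations: the generator does not model electrochemical physics
(adsorption, fouling, interferent species), dot-level stimulus rendering,
or non-affine gain saturation; passing tests therefore certify the
statistical pipeline under the stated forward model, not the chemistry of
real electrodes. Patient-level statistics from the original recordings
are out of reach by construction; only their degrees-of-freedom
conventions are checked.
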