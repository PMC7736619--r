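# voltdecode

Synthetic fast-scan cyclic voltammetry (FSCV) decoding and perceptual
decision analysis, in R.

Sub-second dopamine (DA) and serotonin (5-HT) signaling can be measured
in the behaving human brain by applying rapid triangular voltage sweeps
to a carbon-fiber microelectrode and decoding analyte concentrations
from the induced current traces (voltammograms). Because a surgical
electrode can never be calibrated on known solutions itself, the decoder
must be trained on *other* electrodes in vitro and transferred — a
statistical problem this package reconstructs end to end, with a
synthetic data generator standing in for both the flow-cell rigs and the
in-surgery recordings so that every stage can be validated against known
ground truth.

The package is aimed at researchers who want a tested, fully simulated
replica of this analysis chain: to study its statistical properties, to
benchmark alternative decoders, or to power-analyse task designs before
collecting data.

## What it implements

- **Forward simulator** (`probe_population()`, `sample_probe_model()`,
  `synthesize_sweep()`, `generate_invitro_dataset()`,
  `generate_invivo_session()`): triangular-waveform FSCV measurement
  (10 ms sweep, 1000 samples, 10 Hz repetition; 60 Hz conditioning),
  probe-to-probe construction variation, drift and noise, concentration
  ladders for DA and 5-HT (0–4500 nM) and pH (6.9–7.8), and 10 Hz
  recordings with trial-locked concentration transients.
- **Range-grid elastic-net decoder** (`assemble_training_pool()`,
  `fit_grid()`, `decode_session()`): differentiated voltammograms
  (Q = 999 features) regressed onto (DA, 5-HT, pH) jointly, in a 5 × 5
  grid of 900 nM training ranges; per cell, 11 elastic-net mixing values
  under the penalty `P_a(b) = (1-a)·½||b||₂² + a·||b||₁` with 10-fold CV;
  in vivo cell selection by minimal squared deviation from the cell's
  range midpoints, `e_ij = e_ij,DA + e_ij,5HT`, with modal-sign-negative
  cells excluded.
- **Task engine** (`run_calibration()`, `generate_session()`): the
  continuous-direction variable-reference random-dot-motion task in a
  2 × 2 coherence-by-distance design, two-down-one-up staircase
  calibration (~70.7% correct asymptote), and a parametric von Mises
  observer producing choices, reaction times and confidence.
- **Preprocessing** (`exclude_trials()`, `preprocess_snippets()`):
  RT-outlier and endpoint exclusion, stimulus-locked (−1…+5 s) and
  choice-locked (−4…+4 s) snippets, per-trial z-scoring, causal 0.5 s
  running average.
- **Encoding statistics** (`timepoint_two_sample()`,
  `sliding_encoding_regression()`, `rt_tercile_profiles()`,
  `transition_probabilities()`, `transition_regression()`,
  `fit_behavior_models()`): per-timepoint tests, the sliding-window
  encoding regression with nuisance covariates and participant
  intercepts, RT terciles, trial-type transition statistics, and
  hierarchical behavioural regressions.

## Worked example

Calibrate the stimulus for a synthetic observer and verify the staircase
asymptote:

```r
library(voltdecode)
obs <- observer_params()
params <- run_calibration(obs, list(n_trials = 1200), seed = 1)
unlist(unclass(params)[c("c_l", "c_m", "c_h", "d_l", "d_m", "d_h")])
#>   c_l    c_m    c_h    d_l    d_m    d_h
#> 0.255  0.510  1.000  5.000 13.500 22.000

st <- staircase_stationary_accuracy(obs, params, n_trials = 10000, seed = 2)
#> stationary accuracy: 70.7% (C_L*D_H: 70.8%, C_H*D_L: 70.7%)
```

The calibrated coherence pair `{0.26, 1.0}` and distance pair
`{5°, 22°}` are the observer's individualized stimulus levels; accuracy
on continued staircase trials sits at the two-down-one-up fixed point,
√0.5 ≈ 70.7%, in both the low-coherence/high-distance and
high-coherence/low-distance conditions — the design's target of ~71%.

The full simulation-to-analysis chain is scripted under `analysis/`
(each stage caches its outputs under `results/`):

```sh
Rscript analysis/01_simulate_invitro.R      # probes, ladders, pooled training set
Rscript analysis/02_train_decoder.R         # 5x5 grid fit + naive-probe evaluation
Rscript analysis/03_calibrate_task.R        # staircase calibration
Rscript analysis/04_simulate_and_decode.R   # sessions, recordings, decoding
Rscript analysis/05_encoding_analyses.R     # time-point tests, encoding profile, terciles
Rscript analysis/06_transitions_and_behavior.R
```

or in one call, `run_full_pipeline(run_config(seed = 1))`.

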