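# clampdyn

Single-molecule FRET analysis of RNA polymerase clamp conformational
dynamics.

The clamp of bacterial RNA polymerase swings between open, partly closed and
closed conformations. With a FRET pair spanning the DNA-binding cleft, the
per-frame apparent FRET efficiency `E* = I_DA / (I_DD + I_DA)` reports clamp
closure, and the three conformations appear as states with mean E* near
0.20, 0.30 and 0.42. `clampdyn` is for biophysicists who have such camera
time traces (or want to simulate them) and need the standard analysis chain
with reproducible, scriptable parts:

* **Preprocessing** — E* and stoichiometry `S = (I_DD + I_DA) / (I_DD +
  I_DA + I_AA)` from ALEX intensity triplets; automated photobleach /
  blinking screening; truncation at the first bleach; stoichiometry-gated
  species sorting.
* **Inference** — pooled variational-Bayes hidden Markov model with
  Gaussian emissions; state count chosen by the lower-bound-per-series rule
  (smallest K with ΔL < 1.0); forward–backward and Viterbi decoding in
  compiled code.
* **Kinetics** — transition rates as per-frame probabilities × frames per
  second, group-split errors, mean dwells `t_i = 1/Σ_j k_ij`, occupancies,
  static/dynamic census (> 3 transitions = dynamic), long-dwell and
  missed-dwell statistics.
* **Populations** — per-state E* histograms and single-Gaussian fits with
  subpopulation percentages.
* **Simulation** — Monte-Carlo three-state trajectories from a rate table
  (defaults: the 20-ms reference rates in `rnap_clamp_rates()`), with
  10-frame binning to emulate slow acquisition and known ground-truth paths
  for validation.

## Worked example

```r
library(clampdyn)

cfg <- sim_config(rnap_clamp_rates(), emission_spec(c(0.20, 0.30, 0.42), 0.070),
                  frame_time = 0.02, n_traces = 30, n_frames = 470, seed = 3)
ds <- simulate_dataset(cfg)

m <- fit_hmm(ds$traces, K = 3, seed = 5)
m
#> <hmm_model: K = 3, L = 520.97 per series, 36 iterations>
#>   means: 0.198 0.299 0.419
#>   sds:   0.069 0.071 0.069

paths <- decode_paths(m, ds$traces)
round(occupancy(paths, K = 3), 3)
#> state0 state1 state2
#>  0.308  0.522  0.169

round(rates_from_model(m), 2)
#>      [,1] [,2] [,3]
#> [1,] 0.00 1.41 0.17
#> [2,] 0.90 0.00 1.38
#> [3,] 0.09 4.23 0.00
```

The fitted means recover the generator levels (0.20/0.30/0.42), the decoded
occupancies sit near the stationary distribution of the generating rates
(0.300/0.533/0.167), and the fitted rate matrix recovers the generator's
rate table (e.g. closed→partly-closed 4.23 vs 4.32 s⁻¹) — the
simulate→estimate round trip that validates the inference machinery.
`run_reference_simulation("short")` and `run_reference_simulation("binned")` run the
two full-size reference studies (200 traces at 20-ms frames; 10-frame-binned
200-ms frames) end to end and return one summary row of occupancies, rates,
dwells and long-dwell fractions.

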