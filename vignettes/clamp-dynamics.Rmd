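---
title: "Modelling RNA polymerase clamp dynamics from smFRET time traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling RNA polymerase clamp dynamics from smFRET time traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The system and the measurement

The clamp of bacterial RNA polymerase is a mobile domain that swings over the
DNA-binding cleft. With a donor dye at the clamp tip and an acceptor on the
opposite cleft wall, the apparent FRET efficiency per camera frame,

$$E^* = \frac{I_{DA}}{I_{DD} + I_{DA}},$$

reports clamp closure: three conformations — open, partly closed and closed —
appear as states with mean $E^*$ near 0.20, 0.30 and 0.42 under short (20-ms)
frame times. Alternating-laser excitation adds the stoichiometry

$$S = \frac{I_{DD} + I_{DA}}{I_{DD} + I_{DA} + I_{AA}},$$

used purely for molecule sorting: doubly labelled molecules have intermediate
$S$, donor-only molecules $S \approx 1$, acceptor-only $S \approx 0$.

`clampdyn` implements the full trace-level analysis: screening and truncation
of intensity traces, a pooled variational-Bayes hidden Markov model (HMM) on
the $E^*$ traces, kinetic post-processing, per-state histogram fits, and a
Monte-Carlo simulator that generates three-state clamp trajectories with
known ground truth.

## The probabilistic model

Each molecule's $E^*$ trace is one realisation of a shared $K$-state HMM with
Gaussian emissions: state $k$ emits $E^*_t \sim \mathcal N(\mu_k, \sigma_k^2)$
and the hidden state evolves with a per-frame transition matrix $A$. All
traces are fitted jointly (pooled parameters; each trace an independent
chain). Inference is variational-Bayes EM with conjugate priors —
Normal-Gamma on $(\mu_k, \sigma_k^{-2})$, Dirichlet on rows of $A$ and on the
initial distribution. The fit quality is the evidence lower bound divided by
the number of traces, the "lower bound per series" $L$.

The number of states is chosen by fitting $K = 2 \ldots 6$ and taking the
smallest $K$ whose increment $\Delta L = L(K\!+\!1) - L(K)$ falls below 1.0:
an extra state must buy at least one unit of per-series evidence. We read the
rule sequentially from $K = 2$; all per-$K$ fits are returned for audit.

Rates use the linear per-frame convention throughout: the fitted off-diagonal
transition probability times the number of frames per second,
$k_{ij} = p_{ij} / \Delta t$. The simulator discretises the same way,
$p_{ij} = k_{ij}\,\Delta t$, so simulation followed by estimation is an exact
inverse pair. The matrix exponential is deliberately *not* used (it is
available in `build_transition_matrix(method = "expm")` for sensitivity
checks only); the package's contract is the linear convention. Mean dwell in
state $i$ is $t_i = 1 / \sum_{j \ne i} k_{ij}$, an identity asserted in the
tests.

A molecule is *dynamic* when its decoded (Viterbi) path shows more than three
interstate transitions, otherwise *static*. Rate errors come from a seeded
random split of the dynamic molecules into three near-equal groups, refitted
at fixed $K$; the reported rate is the group mean and the error the group SD.
A rate is reported `NA` when its expected transition count is below one in
every group — too rare to estimate.

## The simulator and what it emulates

`simulate_dataset()` draws Markov state paths from the per-frame matrix built
from a rate table (default: the 20-ms reference rates in
`rnap_clamp_rates()`), starts each trace from the stationary distribution
(molecules are observed at equilibrium), and adds i.i.d. Gaussian noise of a
stated SD to the state-mean series. Defaults mirror the reference study
conditions: 200 traces of 470 frames at 20 ms with noise SD 0.070, and state
means (0.20, 0.30, 0.42). $E^*$ values are not clipped to $[0, 1]$, as real
apparent-FRET data also stray outside.

Slow acquisition is emulated by `bin_factor`: the path is simulated at the
fine frame time, the *noiseless* state-mean series is block-averaged (10
frames: 20 ms to 200 ms), and Gaussian noise of SD 0.068 is then added to the
binned frames. Adding the noise after binning is a deliberate choice: binning
noisy 20-ms frames would leave only $0.070/\sqrt{10} \approx 0.022$ of noise,
while 0.068 is the level measured in static traces of real 200-ms recordings;
only noise-after-binning reproduces that level. Users who want the other
convention can bin noisy traces themselves with `bin_trace()`.

The generator does **not** emulate photophysics (bleaching, blinking,
shot-noise), intensity baselines, or molecule-to-molecule variability in
means or rates. Passing recovery tests on these simulations therefore shows
that the inference machinery is correct under the stated model, not that real
data satisfy the model. Bleach/blink fixtures for the screening code are
generated separately by `make_fixtures()`.

## Trace screening

Trace screening is conventionally done by eye; `clampdyn` substitutes a
reproducible windowed-median change-point detector (window 5 frames, drop
ratio 0.5, noise floor $3\times$MAD of the final 20 frames — all
configurable). Donor bleaching is detected on $I_{DD} + I_{DA}$, acceptor
bleaching on $I_{AA}$, standard ALEX practice. Exclusion rules: multi-step
bleaching, any bleach within the first 50 frames (0-based indices 0–49),
blinking, and non-D–A species by stoichiometry gates (default
$0.3 \le S \le 0.8$; species gating is conventionally drawn on 2-D $E^*$–$S$ plots without
stated numeric bounds, so the gates here are explicit decisions). Kept traces are
truncated at the first bleach step and must retain at least 20 frames to
support HMM fitting.

## Numerical choices

* Forward–backward and Viterbi run in scaled space (compiled code), exact to
  enumeration on small instances; no underflow for $10^4$-frame traces.
* VBEM initialises emission means at the pooled $\frac{2i-1}{2K}$ quantiles
  with seeded jitter; `n_restarts = 3` by default, best lower bound wins.
  Convergence when the per-frame change in the lower bound is below $10^{-8}$
  or after 500 iterations. The lower bound is asserted non-decreasing per
  iteration in the tests.
* Viterbi ties break toward the lower (lower-$E^*$) state index.
* States are relabelled by ascending mean $E^*$ after every fit, so state 0
  is always "open".
* Histogram fits use bin width 0.02 $E^*$ units and least squares on binned
  counts (mirroring practice of fitting the plotted histogram, not the raw
  samples); subpopulation percentages $P$ are frame-count shares, with
  Gaussian-area shares reported alongside, since the field's definition of
  $P$ is not formulaic.
* Censored (edge) dwells are excluded from dwell statistics by default.
* One root seed per dataset fans out deterministically to per-trace and
  per-restart seeds, so equal seeds give bit-identical datasets and fits.

## The two reference studies

`run_reference_simulation()` packages the two canonical end-to-end studies:

* `short`: 200 × 470 frames at 20 ms, noise SD 0.070, pooled 3-state fit.
  Expected behaviour: occupancies near 32/52/16% and recovered rates near
  the generator values (e.g. $k_{C\text{-}PC} \approx 4.3\,\mathrm{s}^{-1}$,
  $k_{O\text{-}PC} \approx 1.5\,\mathrm{s}^{-1}$).
* `binned`: the missed-dwell emulation — fine 20-ms paths, 10-frame
  binning, noise SD 0.068, 200 × 600 frames at 200 ms, 3-state fit. Fast
  dwells (the closed state lives ~0.22 s, about one binned frame) are
  systematically missed, so apparent rates drop and apparent dwells stretch.

For the binned study the package reports what its own pipeline computes. Two
caveats are worth stating plainly. First, the apparent closed-state kinetics
depend strongly on the inference machinery: the pooled VB optimum gives a
faster apparent $k_{C\text{-}PC}$ (near 2.2 s$^{-1}$ at these settings) than
hierarchical per-trace methods report on equivalent data; per-trace
empirical-Bayes tiers are out of scope here. Second, the expected fraction of
dwells shorter than one 200-ms frame follows the exponential closed form
$1 - e^{-\Delta t \sum_j k_{ij}}$, giving 28.7%, 36.0% and 60.0% for the
open, partly closed and closed states at the 20-ms reference rates;
`missed_dwell_fraction()` returns both a Monte-Carlo estimate and this
closed form, without forcing agreement with any particular rounding convention.

Problem sizes in the test suite are scaled to what the checks need: tiny
instances (T ≤ 6, K ≤ 3) where exhaustive enumeration is the oracle;
10–30-trace datasets for recovery and selection properties; the two full
200-trace studies only in the end-to-end acceptance checks.

## Worked example

```{r, eval = FALSE}
library(clampdyn)

# simulate a reduced 20-ms study
cfg <- sim_config(rnap_clamp_rates(), emission_spec(c(0.20, 0.30, 0.42), 0.070),
                  frame_time = 0.02, n_traces = 30, n_frames = 470, seed = 3)
ds <- simulate_dataset(cfg)

m <- fit_hmm(ds$traces, K = 3, seed = 5)
paths <- decode_paths(m, ds$traces)

occupancy(paths, K = 3)          # fractions of frames per state
rates_from_model(m)              # s^-1, linear convention
mean_dwell(rates_from_model(m), 1)
population_summary(ds$traces, paths)
```

## Known limitations

* No photon-level emission model, no gamma/crosstalk correction of $E^*$, no
  image analysis: the pipeline starts at extracted intensity or $E^*$ traces.
* No hierarchical per-trace parameter tier; molecules genuinely heterogeneous
  in rates will be averaged.
* The static/dynamic rule (>3 transitions) depends on the observation span;
  it is a census rule, not a property of the molecule.
* Dwell statistics beyond means (survival fits) are out of scope.
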