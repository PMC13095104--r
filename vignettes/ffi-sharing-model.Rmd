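---
title: "Feedforward-inhibition sharing in a spiking striatal microcircuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feedforward-inhibition sharing in a spiking striatal microcircuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The circuit and the question

The striatum is dominated by medium spiny neurons (MSNs, ~95% of the
population), which receive direct cortical excitation and, in parallel, a
relayed copy of that excitation as feedforward inhibition (FFI) through a
very small population of fast-spiking interneurons (FSIs, ~1%). Because
every MSN receives a fixed, modest number of FSI synapses drawn from a tiny
pool, any two MSNs share a large fraction of their inhibitory sources: with
an FSI indegree of 15 and only 25 FSIs, two MSNs share 60% of the pool on
average; with 250 FSIs, 6%. `ffisim` implements this circuit as a
conductance-based leaky integrate-and-fire (LIF) network and asks what the
*sharing* of FFI — as opposed to its strength — does to

1. the trial-to-trial variability of the MSN population rate under a frozen
   stimulus,
2. the pairwise spike-count correlations within and between two MSN groups
   driven by overlapping cortical source pools, and
3. the firing statistics of a downstream pallidal (GPe) readout neuron.

## Model

### Neurons

Each neuron follows

$$C_m \frac{dV}{dt} = -g_L (V - E_L) - \sum_k g_k(t)\,(V - E_k),$$

with a spike-and-reset rule at `V_th`, reset to `V_reset`, and an absolute
refractory period `t_r` during which `V` is clamped while conductances keep
evolving. The synaptic channels `k` are background excitation, cortical
excitation (both at `E_e = 0` mV, `tau_e = 0.2` ms), and MSN and FSI
inhibition (`E_i = -85` mV, `tau_i = 15` ms, GABA-A time scale). Class
parameters (`neuron_params()`):

| class | C_m (pF) | g_L (nS) | E_L | V_th | V_reset | rheobase (pA) |
|-------|---------:|---------:|----:|-----:|--------:|--------------:|
| MSN   | 80 | 10   | -80 | -45 | -70 | 350  |
| FSI   | 70 | 5    | -70 | -40 | -60 | 150  |
| GPe   | 70 | 2.5  | -70 | -45 | -60 | 62.5 |

The closed-form rheobase `g_L (V_th - E_L)` and the deterministic F-I curve
`dc_firing_rate()` serve as independent oracles for the integrator; the
simulated DC rates match them within 2% at the default step, and the
simulated rheobase within 1%. (Published descriptions of these cells often
quote slightly lower rheobases, around 320/140/60 pA; the closed form of
the stated parameters is what the tests pin.)

### Synapses

Each presynaptic spike elicits an alpha-function conductance transient. We
normalise the kernel so that it peaks at exactly the synaptic weight one
time constant after arrival (`alpha_conductance(..., normalize = TRUE)`),
the convention of the major point-neuron simulators; the bare form peaking
at `weight / e` is available for comparison. Weights are lognormal with
log-scale sd 0.5, parameterised so the *arithmetic* mean equals the
tabulated value (log-mean = log(mean) − 0.125): bkg→MSN 2.0 nS (fixed),
bkg→FSI 1.0 nS (fixed), ctx→MSN 4.8 nS, ctx→FSI 0.25 nS (half strength
because FSIs sample both cortical pools), MSN→MSN 0.03 nS, FSI→MSN 0.5 nS,
MSN→GPe 0.02 nS. Delays are uniform: 1 ± 1 ms for excitatory and 2 ± 1 ms
for inhibitory projections, 1–3 ms onto GPe. Because a delay must be a
positive multiple of the step, the cortical jitter is trimmed to ±0.9 ms
(delays in [0.1, 1.9] ms); external-input delays only shift frozen event
times and do not enter any statistic.

### Connectivity

`build_striatum()` draws an explicit synapse list with *exact* per-target
indegrees: 250 recurrent MSN→MSN inputs (autapses allowed) and 15 FSI→MSN
inputs per MSN, presynaptic partners sampled uniformly with replacement
(multapses allowed). There are no MSN→FSI and no FSI→FSI connections.
Varying the FSI count at fixed indegree is the experiment's only knob: it
changes how *shared* the inhibition is without changing how much any MSN
receives. `n_fsi = 0` is the control condition.

### Inputs

All drive is generated internally (`synthetic_inputs` has no external
data). Every neuron receives an independent aggregate Poisson background:
5.95 kHz to MSNs (3.2 kHz in the no-FSI control, which matches the evoked
MSN rate of the FSI conditions — we verified ~5.7 Hz either way at the
reference setting), 5.75 kHz to FSIs, 7 kHz to GPe. The background is
modelled as a single equivalent generator per neuron with a fixed weight;
its nominal 1 ms delay is dropped as a pure time shift of a stationary
train.

The stimulus is carried by two overlapping pools of cortical sources firing
at 10 Hz. Each MSN of group A draws `k_ctx = 100` synapses from pool A
(size `n_ctx`), group B from pool B; `n_ol` sources are common. The sharing
fractions are `w_in = k_ctx / n_ctx` and `b_in = n_ol / n_ctx`, inverted by
`pool_sizes_from_sharing()` with nearest-integer rounding (the realised
fractions are reported). The expected input-count correlations are `w_in`
within a group and `b_in * w_in` between groups — exactly in the large-pool
limit. Sampling with replacement inflates private count variance by
`1 + (k_ctx - 1)/n_ctx`, so the realised correlation is below the nominal
fraction by that factor; at `w_in <= 0.1` the bias is within the sampling
error and the oracle tests (`measure_input_correlation()`) are run in that
regime. FSIs draw 100 synapses from *each* pool (200 total) at half weight;
the alternative reading (100 from the union) is available via
`per_source = FALSE`. The per-source default reproduces the tuned evoked
FSI rate (~17 Hz), which we take as confirmation of that reading.

### Integration

The engine (`run_trials()`, Rcpp core) is clock-driven at `dt = 0.1` ms.
Each alpha channel is the exact solution of its two-state linear ODE; the
membrane uses exponential Euler with the *exact per-step time average* of
each channel's conductance. The averaging matters: `tau_e` (0.2 ms) is
comparable to the step, and an endpoint sample underestimates synaptic
fluctuations enough to drop fluctuation-driven rates by ~30% (FSI
spontaneous 4.6 Hz instead of the dt-convergent 6.3–6.6 Hz). With the
averaged update, halving `dt` changes evoked population rates by under 1%.
Threshold is tested at step end without interpolation; spike times are
step-end times; delays are rounded to the nearest step (ties up). Initial
membrane potentials are drawn uniformly on `[E_L, V_th)` per neuron per
trial (the resting alternative is `v_init = "resting"`); conductances start
at zero and the first 500 ms of every trial are excluded from all
statistics.

### Trial protocol and seeding

A trial set holds `n_trials` repetitions of 2.5 s (the full-scale protocol) in which
the network wiring, the cortical source trains and the cortical wiring are
*frozen*, while the background noise and initial states are redrawn. One
master seed spawns named sub-streams (`sub_seed()`: network, ctx-trains,
ctx-wiring, background[trial], initial-state[trial]), so any component can
be regenerated in isolation and grid points are seeded independently of
execution order.

## Statistics

* **Across-trial population Fano factor** (`across_trial_fano()`): bin the
  population spike count of one MSN group (group A by default; the subset
  is a parameter) at 2 ms, compute `F_i = var/mean` across trials per bin
  (sample variance, zero-mean bins excluded), average over bins. Counts are
  used rather than rates: the population rate is the count divided by a
  constant, which cancels, and the Poisson null is exactly 1.
* **Correlation transfer** (`correlation_transfer()`): Pearson correlation
  of 20 ms binned spike counts for MSN pairs; `w_out` is the mean of the
  two within-group means (identical to the normalised ordered-pair sum for
  equal group sizes) and `b_out` the cross-group mean, per trial, then
  trial-averaged. Zero-variance units are excluded pairwise, not imputed;
  exclusion counts are reported. Pairs are subsampled (default 5000 per
  category, seeded, the same pairs in every trial); `pair_budget = Inf`
  enumerates.
* **Burst index** (`burst_index()`): maximal runs of ISIs < 10 ms; a run
  qualifies as a burst iff it has more than three spikes (the strict
  reading; `min_spikes = 3` gives the inclusive convention). BI = burst
  spikes / total spikes, averaged over non-silent trials.
* **GPe count Fano** (`gpe_count_fano()`): variance/mean of the total
  spike count across trials.

## The downstream readout

A single GPe neuron receives 7 kHz Poisson background and one inhibitory
synapse from each of the 1250 MSNs of one group (lognormal mean 0.02 nS,
delays 1–3 ms), with one frozen wiring per experiment. The background
weight is not tabulated anywhere; it is defined operationally. Calibrating
it with *no* MSN input to a 40 Hz baseline fails on its own terms: the MSN
projection then contributes a mean inhibitory conductance of ~6 nS at
−85 mV, which silences the neuron outright, contradicting the observed
20–50 Hz working range. We therefore calibrate under load:
`calibrate_background()` bisects against a surrogate 6.25 kHz lognormal
inhibitory stream (1250 MSNs at a nominal 5 Hz; `msn_rate = 0` recovers
the isolated reading), and `calibrate_gpe_background()` refines this by
bisecting against actual reference-condition MSN trains (weakly shared
FFI, 250 FSIs) until the readout fires at 40 ± 2 Hz. With that anchor, the
readout spans roughly 23–44 Hz across input-sharing settings, inside the
physiological 20–50 Hz range, and both its across-trial count Fano factor
and its burst index increase when FFI sharing is high (25 FSIs).

## Heterogeneity

`sample_heterogeneous()` draws `C_m`, `g_L`, `V_th`, `t_r` per neuron from
normal distributions with sd equal to 1/30 of the class mean — read as a
*relative standard deviation*, since only then does the stated 3-sigma
range of ±10% hold — and `tau_i` from Normal(15, 0.5 ms²). Invalid draws
are rejected and redrawn rather than clipped, so no mass accumulates at the
bounds. Heterogeneity damps, but does not abolish, the sharing effects.

## What the experiments show, and at what size

`run_experiment()` sweeps `w_in` × `b_in` × `n_fsi` grids for four
experiment families (spontaneous, variability, correlation, downstream)
and emits one tidy row per setting with the seeds needed to regenerate it.
At full scale each setting uses 100 trials of 2.5 s on 2500 MSNs; a full
grid is hours of CPU. The package's test suite runs the same checks at a
reduced size chosen to keep the whole suite in the tens of minutes on one
core: 12 trials of 2.5 s (2 s analysed) per setting, four settings
(`w_in` ∈ {0.05, 0.25} × `b_in` ∈ {0.1, 0.9}), `n_fsi` ∈ {0, 25, 250},
2500 sampled pairs per correlation category, and one master seed per
directional check (the per-setting sign requirement across four settings
is the stricter part of the check). The heterogeneous rerun uses 10 trials
at two settings. Fewer or shorter trials leave the weaker contrasts — the
within-group correlation differences at `w_in = 0.05` and the 10-ish-trial
estimates of the readout's count Fano factor — below their own sampling
noise. At this size the directional results are stable:
variability and correlations increase with FFI sharing in every tested
setting, weakly shared FFI decorrelates relative to the no-FSI control,
and the readout inherits both effects.

What the synthetic inputs do *not* emulate: non-stationary or
rate-modulated cortical signals, spatially structured connectivity, FSI-FSI
coupling (chemical or electrical), D1/D2 MSN asymmetries, and dendritic
placement of synapses. Passing tests therefore speak to the sharing
mechanism in a stationary, randomly wired circuit, not to quantitative
prediction of in vivo striatal statistics.

## Reproducing the numbers

```{r}
library(ffisim)

lay <- population_layout(2500, 250)
net <- build_striatum(lay, seed = 42)

# spontaneous operating point (~1 Hz MSN, ~7 Hz FSI)
spontaneous_state_check(net, sim_config(n_trials = 2, seed = 7))

# evoked operating point (~5-6 Hz MSN, ~17 Hz FSI)
fin <- frozen_input_set(cortical_pool_config(w_in = 0.1, b_in = 0.9),
                        lay, 2500, seed = 7)
ts <- run_trials(net, fin, sim_config(n_trials = 10, seed = 11))
population_rates(ts)

glance(across_trial_fano(ts))
glance(correlation_transfer(ts, seed = 1))
```

`scripts/acceptance.R` recomputes the calibration quantities end to end
from a single master seed.
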