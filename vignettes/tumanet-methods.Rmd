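---
title: "Astrocytic glutamate recycling and synchronous bursts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Astrocytic glutamate recycling and synchronous bursts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumanet)
```

## The scientific question

Cultured cortical networks fire in *synchronous bursts* (SBs): network-wide
epochs of dense, correlated spiking separated by quiescent dormant periods.
Most synaptic glutamate is cleared not by the neurons themselves but by
astrocytes, through GLT-1/EAAT2 transporters, and returned to the
presynaptic terminal only slowly via the glutamate--glutamine cycle. This
package implements a kinetic model of that tripartite arrangement and asks
how the two astrocytic timescales --- fast uptake and slow return --- shape
the statistics of network bursting.

## The synapse model

A synapse tracks the fractions of a conserved glutamate pool in four
states: ready-to-release `X`, active in the cleft `Y`, recovered
presynaptic `Z`, and astrocytic `A`, with `X + Y + Z + A = 1`. Between
release events the flow is linear:

$$
\dot X = Z/\tau_r, \qquad
\dot Y = -Y/\tau_{nu} - Y/\tau_{au}, \qquad
\dot Z = Y/\tau_{nu} + A/\tau_g - Z/\tau_r, \qquad
\dot A = Y/\tau_{au} - A/\tau_g .
$$

A presynaptic spike instantaneously moves a fraction `u` of the ready pool
into the cleft (`X -> X - uX`, `Y -> Y + uX`); an asynchronous
(spontaneous) event moves the smaller fraction `xi_bar`. Setting the
astrocytic pathway aside (`tau_au -> infinity`) recovers the classical
three-state short-term-depression model, which the package also provides
(`mode = "tum"`); this limit is verified in the test suite to 1e-6.

Defaults (all exposed in `synapse_params()`): `u = 0.2`,
`tau_r = 600` ms, `tau_nu = 50` ms, `tau_au = 250` ms, `tau_g = 30` s,
`xi_bar = 0.02`, saturation factor `b = 0`. The release fraction is
constant: the parameter table gives equal lower/upper values and no
facilitation dynamics, so none is implemented. The `(1 - bY)` saturation
factor is implemented and tested but inert at the default `b = 0`,
matching the source analysis that nonlinear postsynaptic effects are
negligible for `Y < 0.1`.

### Clamped astrocytic pool

Two readings of "fixing A" are provided. `mode = "clamp"` (default for the
control experiments) holds `A` at a constant while keeping *every* flux
term: the cleft still loses `Y/tau_au` into the (clamped) pool and the
recovered state still gains `A_fixed/tau_g`; the presynaptic total
`X + Y + Z` then fluctuates around `1 - A_fixed`. `mode = "reduced"` is
the harder reading: a closed three-state system with conserved total
`1 - A_fixed` and combined clearance time `1/(1/tau_nu + 1/tau_au)`. Both
are single-line variants of the same linear flow; the clamp reading is the
minimal intervention and is what the paired control driver
`run_fixed_a()` uses.

## Neuron and calcium dynamics

Each unit is a two-variable Morris--Lecar membrane (potential `V`,
potassium gate `W`) driven by a constant background current, the synaptic
current `G (V_rev - V)`, and the ionic currents with the parameters in
`ml_params()`. A spike is an upward crossing of `V_th = 10` mV,
edge-triggered: no new spike can be registered until `V` falls back below
threshold, which is the only refractory mechanism. Excitatory input
reverses at 0 mV, inhibitory at -90 mV.

Presynaptic residual calcium `R_Ca` follows a saturating pump/influx
balance plus a per-spike impulse `gamma * log(R_Ca0 / R_Ca)`, and sets the
asynchronous release rate through a Hill function
`eta_max R^m / (kappa_a^m + R^m)` (half-maximal at `kappa_a = 0.1` uM,
ceiling `eta_max = 0.32` ms^-1). Rates printed per second in the
conventional parameter table (`beta`, `I_p`, `gamma`) are converted to the
millisecond scale once, at construction.

**Choice of the logarithm reference `R_Ca0`.** The model's source material
leaves the reference concentration of the spike-influx term open while
listing an extracellular calcium concentration of 2 mM that no other
equation uses. We default `R_Ca0` to that extracellular value. The
alternative --- referencing the resting fixed point of the pump equation
--- would make the per-spike influx vanish at rest and turn negative above
it, so spiking could never elevate residual calcium and the
calcium-dependent asynchronous release loop (which this model family
treats as essential for reverberation) would be inert. With the
extracellular reference, each spike adds
`~0.05 * log(2000/0.06) ~ 0.5` uM, successive spikes saturate
logarithmically, and bursts are followed by a seconds-long tail of
elevated asynchronous release, as intended. `R_Ca0` remains a plain
configuration field for users who prefer the other reading.

## Network

`build_random_network()` connects every ordered pair independently with
probability 0.1 (no self-edges), labels exactly `round(0.2 n)` neurons
inhibitory, and draws each weight from a Gaussian with mean 4 truncated at
±20% of the mean (we take the printed "width" as both the standard
deviation and the truncation bound). Every directed edge carries its own
four-state synapse; inhibitory edges follow identical glutamate kinetics
and differ only through their reversal potential, since the parameter
table provides a weight and reversal for them but no separate kinetics.
Asynchronous events are drawn per efferent edge by Bernoulli thinning with
probability `eta * dt` (the configuration enforces `eta_max * dt <= 0.05`),
using the presynaptic neuron's calcium. There are no conduction delays.

## Integration scheme

Time is in milliseconds throughout; the default step is `dt = 0.05` ms.
The membrane uses forward Euler for `V` and exponential Euler for `W`
(the gate relaxes toward its steady state with its voltage-dependent time
constant). Release events are applied as instantaneous jumps at step
boundaries, after the decay update of the step; spike-triggered release
happens in the same step as the threshold crossing.

Because the between-event synapse dynamics are linear with distinct real
eigenvalues (`0`, the combined cleft-clearance rate, `-1/tau_r`,
`-1/tau_g`), the compiled engine stores each edge in the eigenbasis of the
generator and advances it *lazily*: a synapse's state is reconstructed
with exact exponential factors only when an event touches it. The
per-neuron conductances (whose `Y` components all decay at one uniform
rate) and the population state sums evolve by exact per-step recursions.
This is algebraically identical to advancing every synapse each step with
the matrix-exponential propagator --- the test suite checks the compiled
path against a plain R reference step-for-step --- but costs O(neurons +
events) per step instead of O(edges), which is what makes 300-s runs of a
100-neuron, ~1000-synapse network take tens of seconds. One consequence
is machine-precision conservation: the recorded population means of
`X + Y + Z + A` deviate from 1 by ~1e-16 over a full run. Coincident
timescale choices (e.g. `tau_r = tau_g`) would make the generator
defective; the constructor rejects them with an explicit error.

The degenerate-input policy elsewhere: residual calcium is floored at
1e-6 uM so the logarithm stays defined; a non-finite membrane potential
aborts the run naming the step; empty rasters produce all-zero histograms
with a warning; a zero-spike recording makes the burst index an error
rather than a silent 0/0.

## Burst detection and statistics

Detection operates on the firing-rate time histogram (FRTH) of all units
with 10-ms bins. With `R_max` the maximal bin count: bins at or above
`epsilon * R_max` (default `epsilon = 0.04`) mark the network active; runs
of active bins separated by less than `tau_rest = 1` s of quiescence merge
into one candidate; a candidate is a burst only if some bin reaches
`delta * R_max` (default `delta = 0.2`). The burst start is the first
active bin of the candidate --- the prose description of the original
method is ambiguous about this registration point, and this reading
matches the two-threshold intent; all three knobs are exposed because the
original analysis tuned them per recording. `R_max` is taken from the
detection histogram, not from any display histogram at other bin widths.
Spikes exactly on a burst boundary count as inside (closed interval), and
spikes in rejected (never-above-`delta`) candidates do not count toward
the burst index. The detector is verified against an independent
brute-force state-machine scan on 200 random histograms.

`burst_stats()` reports the array-wide firing rate (spikes/s), burst rate
(per minute), mean burst duration (s) and burst index (in-burst fraction
of all spikes). Fluorescence utilities mirror the imaging preprocessing:
polynomial detrending (degree 3 by default; the source names no degree)
followed by `dF/F` scaling by the mean intensity, and transient decay
times computed as the half-decay time over `ln 2`.

## The synthetic raster generator

`generate_fixture()` emulates what an MEA records from a culture: per-unit
Poisson background at a dormant-state rate (default 1 Hz, within the
observed 0.1--4 Hz range), burst epochs arriving as a Poisson process
(default 5 per minute with 0.3-s duration, the reference SB statistics),
and within each epoch per-unit Poisson firing at 500 Hz with 0.9
participation probability, since not every electrode joins every burst.
The in-burst default sits at the top of the observed 10--500 Hz range
deliberately: the detection threshold is *relative* (`epsilon * R_max`),
so the method assumes peak bin counts far above background bin counts;
with the defaults `epsilon * R_max` is ~3.5 spikes per 10-ms bin while
background bins almost never exceed 2, keeping dormant stretches
quiescent for the detector as in real recordings. Ground-truth windows are returned so
detection and statistics can be validated against the generating
parameters; the suite requires recovery of rate and duration within 10%
on 10 minutes of data. What the generator deliberately does not emulate:
electrode noise and spike-sorting artifacts, refractoriness, within-burst
rate envelopes (initiation/maintenance/termination structure), and any
spatial organisation --- so passing these tests validates the analysis
pipeline's arithmetic, not its robustness to real recording artifacts.

## Experiment drivers and problem sizes

`run_sweep()` scans the astrocytic uptake and return timescales (defaults
mirror the interesting region: `tau_au` in 150--350 ms, `tau_g` in 10--40
s), three seeds per cell, and emits a long-format table with an explicit
error column rather than dropping failed cells. `run_fixed_a()` pairs a
free run with its clamped control at the free-run mean astrocytic level.
All network statistics discard the first 20 s as a settling transient:
simulations start from a fully loaded ready pool (`X = 1`), which is far
from the stationary distribution of the slow astrocytic pool. Runs of
300 s per cell with three seeds are the package's default experiment
size; they give machine-checkable trends while keeping a full sweep on a
single CPU in minutes.

## Observed model behaviour, and a known limitation

At the default parameter set the simulated network reproduces the
qualitative SB phenomenology: quiescent dormant phases punctuated by
network bursts ~0.3 s long with a high burst index, an astrocytic pool
near 0.70--0.75 that acts as the glutamate reservoir, cleft glutamate
staying below a tenth of the total, and all four reference trends under
slower astrocytic uptake (firing rate, burst rate and burst duration
increase with `tau_au`; burst index decreases). Clamping `A` at the
free-run mean leaves pooled burst rate and duration within a quarter of
the free-run values, the bipartite-reduction control.

The absolute calibration, however, is marginal at stationarity: once the
astrocytic pool has equilibrated (a ~`tau_g` process), the recovered
excitatory drive sits at the edge of the ignition threshold, so
stationary burst rates average ~1--4 per minute across seeds rather than
~5, and the array-wide firing rate is far below the experimental
reference because bursts recruit only part of the network before
excitatory conductance transiently saturates the membrane (the synaptic
reversal at 0 mV lies below the 10-mV spike threshold, so strong drive
shunts rather than fires). In the first minute after the loaded start ---
before the pool equilibrates --- the same network produces dense,
reference-like bursting. We keep the long-run, post-transient protocol
because it is the better-defined measurement, and record the discrepancy
rather than adjusting any printed parameter.

## Reproducibility

Every stochastic component draws from R's RNG under explicit topology and
dynamics seeds; identical configurations replay bit-for-bit, which the
suite asserts. `run_manifest()` captures the full flattened configuration,
seeds and package version for any driver run.
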