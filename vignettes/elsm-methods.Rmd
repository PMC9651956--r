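---
title: "Extended liquid state machines: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extended liquid state machines: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elsm)
```

A liquid state machine (LSM) is a reservoir-computing model of a cortical
microcircuit: a fixed, random, sparsely connected recurrent network of
spiking neurons (the *liquid*) projects input spike trains into a
high-dimensional transient state, and a simple supervised readout — the only
trained component — classifies a summary of that state. This package
implements the *extended* LSM (ELSM): the classic conductance-based liquid
plus three biologically motivated extensions — excitatory/inhibitory (E/I)
balance of the input drive, spike-frequency adaptation (SFA), and
heterogeneous membrane time constants — together with the audio-style
preprocessing chain, a spike-count logistic-regression readout, low-bit
weight quantization, and a synthetic fixture generator so that every part
can be exercised without downloading benchmark data.

## Neuron and synapse model

Each liquid neuron is a conductance-based leaky integrate-and-fire unit:

$$\tau \frac{dV}{dt} = (E_{rest} - V) + g_e (E_{exc} - V) + g_i (E_{inh} - V)$$

with dimensionless conductances that jump by the synaptic weight when a
presynaptic spike arrives and otherwise decay exponentially,
$\tau_{g_e} \, dg_e/dt = -g_e$ (and likewise for $g_i$). When $V$ reaches
the firing threshold the neuron spikes, resets to $E_{reset}$ and is
refractory for $t_{ref}$. Defaults (all configurable through
`neuron_params()`):

| parameter | value |
|---|---|
| $E_{rest}$, $E_{reset}$ | 13.5 mV |
| $E_{exc}$ | 30 mV (see below) |
| $E_{inh}$ | 0 mV |
| $V_{th,base}$ | 15 mV |
| $\tau$ (membrane) | 30 ms, or U[5, 55] ms per neuron |
| $\tau_{g_e}$, $\tau_{g_i}$ | 3 ms, 10 ms |
| $t_{ref}$ | 3 ms (excitatory), 2 ms (inhibitory) |

The voltage scale is the classic shifted one with rest at 13.5 mV. On this
scale an inhibitory reversal of 0 mV sits well below rest and is genuinely
hyperpolarizing. A 0 mV *excitatory* reversal, however, cannot depolarize a
membrane resting at 13.5 mV, so the package defaults the excitatory
reversal to 30 mV — above threshold, so excitatory input drives the
membrane upward, which is the behaviour the rest of the model requires
(excitatory input raises $V$, inhibitory input lowers it). Both reversals
are plain parameters for users who prefer other conventions.

Initial membrane potentials are uniform on [13.5, 15) mV; conductances,
adaptation and refractory clocks start at zero.

### Spike-frequency adaptation

Adaptation uses the adaptive-threshold formulation rather than an
adaptation current: the effective threshold is
$V_{th} = V_{th,base} + \theta$, each spike of an excitatory neuron adds 1
mV to $\theta$, and $\theta$ relaxes back with
$\tau_{sfa} \, d\theta/dt = -\theta$. Adaptation applies to excitatory
neurons only. $\tau_{sfa}$ is either one shared constant or i.i.d.
U[50, 1050] ms per neuron; the uniform range targets memory over mixed
timescales while keeping the same 550 ms mean as the fixed setting.

## Liquid construction

Neurons occupy distinct sites of a 3D integer lattice, filled in raster
order. The grid shape is a free choice of the model (the reference
2000-neuron liquid uses 10×10×20); `liquid_spec()` defaults to the
smallest box of roughly 1:1:2 aspect that holds the requested neuron
count. 80% of neurons are excitatory, assigned uniformly at random over
sites (no spatial clustering). A directed recurrent synapse from neuron
$i$ to $j$ is realized independently with probability

$$P(i, j) = C \cdot e^{-(D(i,j)/\lambda)^2}$$

where $D$ is Euclidean distance in grid units, $\lambda = 2$, and $C$
depends on the (source, target) populations: 0.3 (EE), 0.2 (EI), 0.4
(IE), 0.1 (II). This yields a sparse reservoir — about 9.5 recurrent
synapses per neuron at $N = 2000$, which `scripts/acceptance.R`
recomputes. Recurrent weights are uniform draws with per-type upper
bounds (EE 0.6, EI 0.4, IE 1.2, II 0.4); delays are 1.5 ms for EE and 0.8
ms otherwise. Weights are non-negative for every synapse type — the
inhibitory action of I-source synapses comes from their reversal
potential, not from a negative sign — and are frozen after construction.

One published description of the recurrent weight bounds lists the "IE"
label twice; we read the four entries in the same order as the
connectivity table (EE, EI, IE, II), giving EI = 0.4 and IE = 1.2. That
reading puts the strongest weights on inhibitory-to-excitatory synapses,
consistent with the emphasis on strong inhibitory signaling; the opposite
assignment remains reachable through `liquid_spec()` for anyone who wants
it.

Every liquid neuron additionally receives exactly 7 input synapses from
distinct, uniformly chosen input channels (exact fan-in, not a Bernoulli
mean — the description is a per-neuron property). Input synapses are
always excitatory-acting with a 1 ms delay; their weights are
U[0, 0.4] onto excitatory targets and U[0, factor × 0.4] onto inhibitory
targets, where `inhib_factor` is the E/I balance knob (0.5 reproduces the
classic U[0, 0.2] baseline).

## Simulation engine

`simulate_liquid()` is clock-driven with a default step of 1 ms. Within a
step: (1) conductance kicks scheduled for this step are applied — each
spike at time $t$ reaches its targets at $t$ + delay, rounded half-up onto
the step grid with a minimum of one step; (2) the membrane is advanced by
exponential Euler using the start-of-step conductances (for the leak-only
case this is the exact exponential, which the tests exploit as an
oracle); (3) conductances and adaptive thresholds decay by their exact
factors $e^{-dt/\tau}$; (4) the threshold test runs at the step end with
an inclusive comparison ($V \ge V_{th}$). Refractory neurons stay clamped
at $E_{reset}$, cannot spike, but still accumulate and decay conductance
— no input drive is lost, only integration is suspended.

At `dt = 1` ms the 1.5 ms EE delay rounds to 2 steps and the 0.8 ms
delays to 1 step. Because downstream inputs are binned at 4 ms anyway,
sub-millisecond delay fidelity is secondary; setting `dt = 0.1` makes all
delays exact at a 10× step cost. Per-neuron net-current accumulators
(mean and variance of $g_e - g_i$ over time) are always maintained
online; full state traces are recorded only on request
(`record = "exc"` or `"all"`) since they dominate memory.

The balance statistic follows the literal "sum of conductances" reading:
$net(t) = g_e(t) - g_i(t)$, not the driving-force product
$g(E - V)$ — the magnitudes reported for the reference model (≈0.15 at
the baseline factor) are on the bare-conductance scale. The driving-force
variant is available via `net_current_stats(trace, driving_force = TRUE)`
for comparison. Network-level balance is summarized over the excitatory
population by default, the population the readout sees; `neurons = "all"`
switches to the whole liquid.

## E/I balance sweep

`sweep_inhib_factor()` scales only the input→inhibitory weight
distribution U[0, factor × 0.4] while the excitatory drive stays at
U[0, 0.4]. Raising the factor recruits more inhibitory spiking, which
lowers the network's time-averaged net current; balance is declared where
that average is closest to zero (`select_balanced_factor()`, ties toward
the smaller factor). Implementation detail worth knowing: changing the
factor multiplies existing input-inhibitory weights by the ratio of
factors. Because the original draws are uniform on the old support, the
rescaled weights are *exactly* the draws the same seed would have produced
at the new factor — topology, delays and all other weights are untouched,
which the tests verify by table diff. The default factor grid is
{0.5, 0.75, 1, 1.5, 2, 2.5, 3} (the published sweep's exact grid is not
printed); sweeps average over 5 liquid initializations by default.

## Preprocessing

For float-matrix inputs (cochleogram-like channels × frames intensities
normalized to [0, 1]), `step_forward_encode()` applies step-forward
encoding per channel: an adapting baseline moves by ±θ whenever the
signal leaves the band baseline ± θ, emitting a ±1 event. The default
θ = 0.005 is the empirical value used for unit-normalized cochleograms.
The baseline initializes at the first frame's value — the common
convention, which avoids a spurious onset burst; zero-initialization is
available. `bipolar_to_unipolar()` splits ±1 events across doubled
channels (positives first half, negatives second half).
`align_and_bin()` cuts/pads event streams to a common duration and marks
each (channel, 4 ms bin) as active on a half-open interval; 1 s at 4 ms
gives the standard 250-step samples. Multiple events in one bin collapse
to a single binary 1; the simulator re-expands each active bin to one
spike at the bin start. The cochlea-model front-end that produces real
cochleograms is out of scope; any precomputed cochleogram works, and
`make_float_signals()` provides smooth synthetic stand-ins (explicitly
non-reproducing of speech acoustics) for demos and tests.

## Readout

`extract_features()` counts each excitatory neuron's spikes over the
sample — a memoryless, timing-free summary, so the feature length equals
the excitatory population size (1600 for the 2000-neuron liquid). Counts
enter the classifier raw (no normalization is applied to the integer
counts; the fitting routine may standardize internally, which does not
change the feature definition). `fit_readout()` fits a multinomial
logistic regression with an L2 penalty via glmnet; only the penalty
strength is tuned, by stratified 5-fold cross-validated accuracy over an
inverse-strength grid C ∈ {0.01, 0.1, 1, 10} mapped to
λ = 1/(C·n). Ties prefer the stronger penalty.

## Synthetic study conditions

`make_template_dataset()` stands in for benchmark spike data: each class
is one fixed random (channel, time) template; a sample is the template
with Gaussian time jitter and independent event deletion. Defaults — 5
classes, 40 channels, 250 ms at ms resolution, 120 events per template,
10 ms jitter, 20% dropout, 12 train / 6 test samples per class — were
chosen once as a moderately hard, realistically sized task matching the
shape of 4 ms-binned audio event data, and the demo liquid for end-to-end
runs has 500 neurons. What the generator emulates is class-structured
spatio-temporal spike patterns with controllable separability (at zero
jitter and dropout a nearest-neighbour count classifier is perfect;
separability degrades with dropout). What it does **not** emulate:
speech-like spectro-temporal correlations, channel crosstalk,
variable-length utterances, speaker variability, or cochlear filtering.
Tests passing on these fixtures therefore validate the machinery —
construction, dynamics, balance behaviour, training — not benchmark-level
recognition accuracy; the headline benchmark accuracies depend on
downloaded datasets and are deliberately not reproduction targets here.
Background Poisson noise is off by default (encoded audio is
deterministic given the waveform) but is the natural extension point for
robustness experiments.

## Quantization

`quantize_weights()` snaps each weight to the nearest of $2^{bits}$
uniformly spaced levels spanning [0, upper] for its synapse type, where
"upper" is the type's sampling bound. The scheme (per-type uniform
levels over the sampling support, round-to-nearest) was chosen for
determinism and testability: it is idempotent, and the error bound
upper/(2·(2^bits − 1)) holds per synapse. `bits >= 53` is an exact
identity. With 4 bits the fixture-task accuracy stays within a few points
of full precision, mirroring the published observation that 4-bit weights
suffice.

## Numerical and degenerate-input choices

* Threshold comparison is inclusive (≥); spike detection happens at step
  end.
* Delays bin by round-half-up with a one-step minimum, so causality is
  never violated at any `dt`.
* Probabilities from the distance kernel are clamped to [0, 1] (relevant
  only for extreme `C`).
* Grid-too-small, channel-count mismatches, in-degree > channels,
  negative weights, single-class training sets and non-finite neuron
  states raise immediate, named errors.
* Empty rasters are legal everywhere (empty liquids produce empty
  features and zero spike counts).
* All randomness flows from explicit integer seeds; identical
  (spec, seed) inputs give bit-identical liquids, rasters and datasets.

## Problem sizes used in the test suite

The suite validates topology statistics on the full 2000-neuron
reference liquid (5 seeds), and runs dynamical and end-to-end checks on
500-neuron liquids with the default fixture task — sizes at which the
complete suite, including the end-to-end ablation over 5 seeds, runs in
a few minutes on a single core while leaving every scientific claim
exercised at its stated tolerance.

## Known limitations

* No event-driven exact simulation; the clock-driven engine is the only
  integrator (delays exact only when `dt` divides them).
* No HDF5 event-file reader; rasters are exchanged as plain CSV (plus
  in-memory tibbles).
* The liquid is static by design: no plasticity, no learned recurrent
  weights, no ensembles, no adaptation-current SFA variant.
* The readout is strictly memoryless; temporal readouts are out of
  scope.
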