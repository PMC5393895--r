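---
title: "Modelling hybrid neuron-astrocyte networks with gliasim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling hybrid neuron-astrocyte networks with gliasim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gliasim` simulates networks that combine two qualitatively different
signalling channels: point-to-point ("wired") synaptic transmission between
Hodgkin-Huxley neurons, and diffuse ("volume-transmitted") modulation of
those synapses by astrocytes, whose only dynamical variable is intracellular
Ca²⁺.  This vignette documents the model, the choices behind every tunable
default, the numerics, and what the accompanying tests do and do not
establish.

## The neuronal layer

Each neuron is a single compartment obeying

$$C_m \dot V = g_{Na} m^3 h (E_{Na}-V) + g_K n^4 (E_K-V) + g_L (E_L-V)
             + g_{exc}(E_{exc}-V) + g_{inh}(E_{inh}-V) + I_{ext}.$$

Two kinetic presets are shipped.  E-cells use the classic squid-axon
constants ($g_{Na}=120$, $g_K=36$, $g_L=0.3$ mS/cm², resting near −65 mV);
i-cells use the Wang-Buzsáki fast-spiking set ($g_{Na}=35$, $g_K=9$,
$g_L=0.1$ mS/cm², $\phi=5$, instantaneous $m$, resting near −64 mV), the
standard interneuron model of hippocampal CA1 gamma studies, which is the
circuit family the default surrogate parameters emulate.  Both presets are
plain parameter lists and can be overridden field by field
(`neuron_params("wb", g_K = 12)`).

Synapses are conductance-based with single-exponential decay
($\tau_{exc} = 2$ ms, $\tau_{inh} = 10$ ms; $E_{exc}=0$, $E_{inh}=-75$ mV).
A presynaptic spike schedules a conductance increment `w` on the target
after a conduction delay $\mathrm{delay}_0 + d/v$ (defaults 1 ms + distance
at 200 µm/ms — a configurable surrogate, as no delay rule is forced by the
biology at this scale), and the increment is delivered only with the
synapse's release probability $p$ (a single Bernoulli draw per spike).

## Geometry and wiring

Populations are placed uniformly on concentric 2-D discs (radii default to
250 µm for e-cells and astrocytes, 200 µm for i-cells).  A disc generalises
a ring; `layout = "ring"` is available.  Distances are Euclidean.  Two
wiring rules are provided per connection class:

* **BSS** — every presynaptic cell contacts exactly
  $\lfloor \text{fraction}\cdot N_{post}\rfloor$ nearest targets (default
  fraction 0.5, ties broken by cell index, autapses excluded), with weight
  $w_{peak}\,e^{-d^2/2\sigma_w^2}$.  Weights are deterministic given
  positions, which the tests exploit: realized weights must match the
  Gaussian-of-distance curve to $10^{-12}$.
* **BSD** — uniform weight, independent connection probability
  $q(d) = q_0 e^{-d^2/2\sigma_d^2}$.  The normalisation $q_0$ is chosen so
  the *population mean* expected out-degree equals `n_out`; this keeps the
  realized density proportional to the Gaussian kernel everywhere (a
  per-cell normalisation would distort the distance profile for cells near
  the rim).  If the requested `n_out` would need $q_0 > 1$ the builder
  fails and reports the achievable maximum for the geometry.

Defaults for the 100 e / 25 i surrogate network: BSD everywhere with
$\sigma_d = 200$ µm, mean out-degrees ee 30, ei 12, ie 40, ii 10, weights
ee 0.003 and ei/ie/ii 0.010 mS/cm².  The asymmetry between ee and ei was
set during design so that pattern-driven e-activity recruits the
i-population (at 0.003 the interneurons stay silent and the surrogate is
not a credible E-I circuit); with it the default network shows ~8–13 Hz
interneuron firing and a pairwise coherence of ~0.4 under a half-field
stimulus.

## The astroglial layer

Astrocyte Ca²⁺ follows a two-variable Li-Rinzel-type scheme
(IP₃-receptor channel release, SERCA uptake, ER leak), the standard minimal
cytosolic Ca oscillator, with the usual constants ($v_1 = 6\,\mathrm{s^{-1}}$,
$v_2 = 0.11\,\mathrm{s^{-1}}$, $v_3 = 0.9\,\mathrm{\mu M\,s^{-1}}$,
$d_1 \ldots d_5$, $a_2$) expressed per millisecond.  IP₃ is an explicit pool:
it relaxes exponentially to a sub-oscillatory baseline (0.16 µM,
$\tau = 7$ s) and jumps by a fixed gain (1.5 nM) for every presynaptic spike
inside the astrocyte's territory, so sustained domain activity pushes the
oscillator into its active range (roughly 0.35–0.6 µM IP₃) and raises
time-averaged Ca.  Gap junctions exchange Ca directly between
nearest-neighbour astrocytes (symmetric k-NN graph, k = 2, rate
$5\times10^{-4}$ ms⁻¹); the exchange term is antisymmetric, so coupling
alone conserves total Ca — asserted to $10^{-10}$ in the tests.  IP₃
exchange instead of (or on top of) Ca is a one-line parameter change.

Territories are defined by proximity to the *presynaptic* e-cell: every
ee/ei synapse belongs to the astrocyte nearest to its source neuron, which
tiles the excitatory synapse population into disjoint domains by
construction.  Calcium maps onto release probability through
$p(Ca) = p_0 + (p_{max}-p_0)Ca^{n_H}/(Ca^{n_H}+K_{Ca}^{n_H})$ with defaults
$p_0 = 0.2$, $p_{max} = 0.8$, $K_{Ca} = 0.3$ µM, $n_H = 2$.  These four
numbers are *surrogates for an explicitly hypothetical relationship* — the
source literature presents the Ca-to-p curve as illustrative, not measured —
and should be refit when experimental dose-response data are available.
Whether modulation targets ee, ei or both is selectable
(`modulate_classes`); the default modulates both, the inclusive reading of
"excitatory synapses".

## Plasticity and the memorization/recall protocol

STDP uses the exponential kernel
$\Delta w = A_+ e^{-\Delta t/\tau_+}$ (post after pre),
$-A_- e^{-|\Delta t|/\tau_-}$ (pre after post), $\Delta w = 0$ at exact
coincidence, with nearest-neighbour pairing (each spike pairs with the most
recent opposite-side spike within 5 time constants).  All-to-all pairing,
triplet rules and homeostasis are deliberately out of scope; stabilisation
comes from hard clipping to $[w_{min}, w_{max}]$ plus finite memorization
duration.  Only ee synapses are plastic by default (the class whose matrix
carries the stored pattern); the set is configurable.  The frequency rule
$\Delta w = \mathrm{gain}\cdot(r - \theta_r)$ applies every 100 ms from the
trailing-window presynaptic rate.  Defaults $A_+ = 5\times10^{-4}$,
$A_-/A_+ = 1.05$ (slight depression bias, the usual stability choice),
$\tau_\pm = 20$ ms, bounds $[0, 0.006]$ mS/cm².

A memorization stage runs the network with an external pattern — a binary
mask of e-cells driven by a constant current (default 10 µA/cm², a clearly
suprathreshold drive) — and plasticity on; a recall stage freezes the
weights and switches the rule off, returning the matrix bit-for-bit.
Recall quality is the cosine similarity of the two phases' per-neuron
spike-count vectors over equal windows (two silent windows count as a
perfect match).  Cosine was chosen over a binned Pearson correlation
because it is scale-free, lives in $[0,1]$, and equals 1 exactly when the
patterns coincide; the Pearson variant can be selected by comparing rate
vectors externally.  Note the protocol compares *whole phases*: because the
plastic phase evolves its weights while the recall phase holds them fixed,
the two rasters can differ by a handful of boundary spikes even under
identical seeds, so C is 1 to three-four decimals rather than bitwise —
the tests assert C = 1 at that printed precision.

## Numerics

* **Integrator.**  The membrane/gating system is advanced by classic RK4 at
  `dt = 0.05` ms.  This is a deliberate choice over first-order
  exponential-Euler schemes: near rheobase the Wang-Buzsáki cell's firing
  rate converges very slowly in `dt` for first-order methods (51.8 Hz at
  `dt = 0.05`, 57.9 Hz at `dt = 0.01`, against a converged 59.5 Hz), while
  RK4 at `dt = 0.05` reproduces the converged rate to 0.4%.  The CA1
  interneuron-network literature the defaults emulate used RK4 at this very
  step size.  Gating variables are clamped to $[0,1]$ after each step;
  synaptic conductances decay analytically ($g \cdot e^{-\Delta/\tau}$) and
  enter the RK stages with their within-step decay.
* **Astrocytes** are updated every `astro_stride` neuronal steps (default
  every step; Ca dynamics are three orders of magnitude slower, so strides
  of 10–100 are safe) with exponential-Euler for the IP₃R gate, exact
  relaxation for IP₃, and forward Euler for Ca.  Against an adaptive
  reference integration at `rtol = 1e-10` the oscillation period at a 1-ms
  step agrees to $4\times10^{-5}$ relative; the test tolerance is 5%.  A
  literal fixed-step reference at 0.001 ms is not meaningful here: the
  oscillation period is ~12.8 s, i.e. >10¹⁰ reference steps per cycle.
* **Determinism.**  Every synaptic release draw is a pure hash of
  (seed, synapse id, presynaptic event index) — a murmur3-style
  counter-based stream — and all remaining randomness (placement, wiring,
  initial-voltage jitter U(−70, −60) mV) is drawn once, globally, before
  the loop.  Consequently the trajectory is bit-identical for any worker
  partition, and checkpoints resume bit-exactly.  Spike detection is an
  upward crossing of 0 mV with a 1-ms absolute refractory period;
  simultaneous spikes are ordered by cell index everywhere sums are
  accumulated.
* **Degenerate inputs.**  Zero-duration runs return empty rasters and
  untouched weights; an empty population simply contributes nothing; a
  coherence over fewer than two active cells returns `NA` (undefined)
  rather than 0; negative Ca, non-finite membrane state and |V| > 500 mV
  raise named errors.

## Parallel execution model

The engine partitions cells into contiguous index blocks and steps them
block by block, exchanging spikes globally once per `dt` (delays ≥ `dt`
make this exact).  The decomposition runs inside one R process: the
membrane update is elementwise and event accumulation is done in a fixed
global order, so the worker count is a pure partitioning parameter and the
partition-invariance contract is testable rather than vacuous.  True
multi-process execution would add per-step IPC without changing any number
in the result — which is precisely the contract — so it was left out of
scope; `worker_scan()` (Mode I) therefore measures the overhead curve of
the decomposition itself and picks `k_opt = argmax(1/runtime)` with
smallest-k tie-breaking, while Mode II is simply `simulate_network()` with
a pinned worker count.  On a single CPU the curve is typically flat-to-
decreasing in k, consistent with Amdahl-style saturation; this is logged,
not asserted.

## What the synthetic conditions do and do not show

The default generator emulates a CA1-like surrogate circuit: 100 e-cells /
25 i-cells / 9 astrocytes on 250/200/250 µm discs, BSD wiring, the
parameters above, 400-ms protocol stages with the stimulus on during
[50, 350] ms.  The test suite runs this network (and a 500-cell version
for the partition checks, 60–100 ms probes; a 60-cell, 1.5-s run for the
glia-coupling direction check) — sizes chosen so the full suite completes
in minutes on one CPU.  Passing tests establish the *mechanisms*: exact
wiring laws, integrator accuracy against independent references,
bit-reproducibility, metric identities, sign-correct plasticity, and a
positive Ca-versus-domain-rate association (Spearman ≈ 0.9 across 9
astrocytes under heterogeneous drive).  They do not establish biological
realism of the surrogate constants: real CA1 has orders of magnitude more
cells, structured lamination rather than uniform discs, short-term synaptic
dynamics, NMDA-type voltage dependence, and astrocyte territories hosting
~10⁵ synapses.  Conclusions about real tissue require refitting the
parameter blocks to data; the package's contribution is the reproducible
machinery, not the constants.

## Known limitations

Single-compartment neurons only; no spatial Ca waves within an astrocyte;
gliotransmitter kinetics reduced to the p(Ca) sigmoid; no structural
plasticity; the checkpoint object is in-memory (results, configurations and
connectivity serialize to plain text, the live checkpoint does not).
Mechanism sets are config-selected — adding a genuinely new channel type
means editing `gating_rates()`, not plugging in a file.
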