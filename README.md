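# gliasim

Desk-scale simulation of **hybrid neuronal–astroglial networks** in R.

Classical network simulators model only the "wired" side of brain circuits:
spiking neurons coupled by point-to-point synapses.  Astrocytes — the
non-excitable glial cells that tile the tissue into non-overlapping
territories — act on circuits through a second, diffuse channel: their
intracellular Ca²⁺ dynamics modulate the neurotransmitter release probability
of the synapses inside each territory.  `gliasim` implements both channels in
one small, fully reproducible engine, aimed at computational and experimental
neuroscientists who want to explore neuron–glia interactions, pattern
memorization and recall, and network rhythms at desk scale, without cluster
infrastructure.

## The model

**Neurons.**  Excitatory (e) and inhibitory (i) populations live on
concentric 2-D discs of radius $R_e$, $R_i$.  Each cell follows
Hodgkin–Huxley dynamics

$$C_m \frac{dV}{dt} = \sum_n I_n + I_{syn}, \qquad
\sum_n I_n = g_{Na} m^3 h (E_{Na}\!-\!V) + g_K n^4 (E_K\!-\!V) + g_L (E_L\!-\!V),$$

with classic squid-axon kinetics for e-cells and Wang–Buzsáki fast-spiking
kinetics for i-cells (all overridable).  Synapses are conductance-based
($I_{syn} = g_{exc}(E_{exc}\!-\!V) + g_{inh}(E_{inh}\!-\!V)$), delayed, and
probabilistic: each presynaptic spike releases with probability $p$ drawn
from a counter-based random stream dedicated to that synapse.

**Wiring.**  Two distance-dependent rules per connection class
(ee, ei, ie, ii):

* **BSS** (bell-shaped strength): each cell contacts the nearest
  $\lfloor \text{fraction} \cdot N_{post} \rfloor$ targets (default 50%),
  with Gaussian weights $w(d) = w_{peak} e^{-d^2/2\sigma_w^2}$;
* **BSD** (bell-shaped density): uniform weights, connection probability
  $q(d) = q_0 e^{-d^2/2\sigma_d^2}$ normalised to a requested mean
  out-degree.

**Astrocytes.**  Each astrocyte integrates a Li–Rinzel-type Ca²⁺ oscillator
(IP₃-receptor release, SERCA uptake, leak) driven by an IP₃ pool that jumps
with every presynaptic spike in its territory, plus direct gap-junction Ca²⁺
exchange with neighbouring astrocytes:
$dCa/dt = -\sum_n J_n$.  Calcium maps onto release probability of the
covered excitatory synapses through a Hill sigmoid
$p(Ca) = p_0 + (p_{max}-p_0)\,Ca^{n_H}/(Ca^{n_H}+K_{Ca}^{n_H})$.

**Plasticity and memory.**  Spike-timing-dependent plasticity
($\Delta w = \pm A_\pm e^{-|\Delta t|/\tau_\pm}$, nearest-neighbour pairing)
or a frequency-threshold rule reshape the ee weight matrix while an
**external pattern** (a binary mask of driven e-cells) is memorized; recall
re-runs the network with plasticity off and weights frozen.  Readouts:
population frequency $F = \frac1N \sum_i f_i$, pairwise spike-train
coherence on 2-ms bins, and recall quality $C \in [0,1]$ — the cosine
similarity between the per-neuron spike-count vectors of the memorization
and recall phases.

**Reproducible parallel decomposition.**  Cells are partitioned into
contiguous index blocks ("workers") stepped block-by-block with global
per-step spike exchange.  Because every random draw is keyed to an entity
(synapse, seed, event index) rather than to a worker, results are
bit-identical for any worker count, and runs can be checkpointed and resumed
bit-exactly.  A Mode-I style `worker_scan()` probes candidate worker counts
and reports the performance curve (1/runtime).

## Worked example

Memorize a binary pattern in the default surrogate network
(100 e-cells, 25 i-cells, 9 astrocytes, BSD wiring), then recall it:

```r
library(gliasim)
cfg <- network_config(seed = 1, T_total = 400)
print(cfg)
#> Hybrid neuron-astrocyte network configuration
#>   populations: 100 e-neurons (R = 250 um), 25 i-neurons (R = 200 um), 9 astrocytes
#>   connectivity: ee=BSD, ei=BSD, ie=BSD, ii=BSD
#>   plasticity: NONE | glia modulation: ee+ei
#>   T = 400 ms, dt = 0.05 ms, seed = 1, workers = 1

ep1 <- ep_from_matrix(rep(c(TRUE, FALSE), 50), amplitude = 10,
                      onset = 50, offset = 350)
mem <- run_memorization(cfg, ep1, plasticity_rule("STDP"))
print(mem)
#> Simulation result [0, 400] ms (seed 1, 1 workers)
#>   spikes: 1032 (e), 127 (i)
#>   F_e = 25.8 Hz, F_i = 12.7 Hz, coherence = 0.417

rec <- run_recall(cfg, mem$connectivity, ep1)
recall_quality(mem$raster_e, rec$raster_e, window = c(50, 350))
#> Recall quality C = 0.9999 over windows [50, 350] / [50, 350] ms
```

The memorization stage drives the masked half of the e-population at
~26 Hz, STDP reshapes the ee weight matrix, and recalling the *same*
pattern with the memorized, frozen weights reproduces the spike pattern:
C = 1 (to four decimals).  A novel pattern recalls poorly
(C ≈ 0.5; try `exec/gliasim demo <dir>` for the four-stage protocol).
`plot(mem)` draws the spike raster; `plot(mem, "ca")` the astrocyte Ca map.

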