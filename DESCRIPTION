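Package: gliasim
Title: Hybrid Neuron-Astrocyte Spiking Network Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator for hybrid neuronal-astroglial networks:
    Hodgkin-Huxley excitatory and inhibitory neurons with conductance-based,
    probabilistic, delayed synapses are wired by distance-dependent Gaussian
    connectivity rules (bell-shaped strength or bell-shaped density), while a
    network of gap-junction-coupled astrocytes integrates IP3-driven calcium
    dynamics and maps calcium onto the release probability of the excitatory
    synapses inside each astrocyte's territory.  Includes spike-timing-dependent
    and frequency-dependent plasticity, an external-pattern memorization/recall
    protocol with a recall-quality readout, population-frequency and pairwise
    spike-coherence metrics, deterministic block-partitioned execution with a
    worker-count scan, and checkpoint/resume.  All random draws on synapses use
    counter-based streams keyed to the synapse, so simulations are bit-identical
    for any worker partition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
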