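# critsync

Simulation and analysis of **critical synchronization and 1/f dynamics in
rich-club spiking networks**.

Cortical networks combine a hierarchical, scale-free wiring with a *rich
club*: their most connected neurons (hubs) are densely connected to each
other. Whether those hubs act as inhibitory controllers or excitatory
amplifiers reshapes the collective dynamics — from long-range-correlated 1/f
activity with power-law-distributed synchronization events (the signature of
healthy cortical recordings) to Brownian, avalanche-dominated activity. This
package is an in-silico laboratory for that question, aimed at computational
neuroscientists studying criticality, excitation/inhibition balance and
network topology.

## What it implements

* **Network**: the deterministic Ravasz–Barabási clique hierarchy
  (25 → 125 → 625 nodes), rich-club wiring of every hub pair with
  probability κ, structural hub classification (5 global + 20 local hubs =
  4% of nodes), neuron typing (global hubs inhibitory in *case 1*, excitatory
  in *case 2*; local hubs inhibitory with probability η; non-hubs 80/20
  excitatory/inhibitory), the normalized rich-club coefficient
  Φ<sub>norm</sub> against a degree-preserving null, and the unidirectional /
  indegree-preserving-randomized control topologies.
* **Dynamics**: Izhikevich spiking neurons,
  `v' = 0.04v² + 5v + 140 − u + I + s`, `u' = a(bv − u)`, reset at 30 mV,
  integrated with midpoint RK-2 at h = 0.1 ms (compiled core), Gaussian
  thalamic drive (sd 5/2, redrawn per millisecond), Dale-law synapses
  delivering ±w for a single step, firing-rate measurement and
  weight-calibration curves.
* **Analyses**: detrended fluctuation analysis of the global state S(t)
  (exponent α; 0.5 white, 1 pink, 1.5 Brownian); the global lability of
  synchronization — Hilbert-phase differences of the 125 cluster signals,
  windowed synchronization index, synchronized-pair count M(t), lability
  ℓ(t) = |M(t+1) − M(t)|², and a bounded-support maximum-likelihood power-law
  fit for its exponent δ ∈ (0, 1].
* **Experiments**: per-cell pipeline runs, κ × η phase diagrams of α, pooled
  lability distributions, plus seed-deterministic surrogate generators
  (colored noise of prescribed spectral slope, sinusoid ensembles, bounded
  power-law samples) that make every analysis stage testable without the
  simulator.

## Worked example

One full pipeline pass in the 1/f regime (inhibitory global hubs, mixed
local hubs):

```r
library(critsync)
set.seed(7)
net <- build_study_network(case = 1, kappa = 0.75, eta = 0.75)
net
#> rcnet: 625 nodes, 4384 directed links (bidirectional)
#> hubs: 5 global, 20 local
#> types: 488 excitatory, 137 inhibitory

sim <- simulate_network(net, weight = 40, groups = net$cluster5)
sim
#> izhsim: 625 neurons, 10000 recorded steps (h = 0.1 ms), 3604 spikes, 6.17 spks/s (excitatory)

dfa(sim$S)
#> DFA: alpha = 0.999 over n in [10, 1000] (20 window sizes)

sync <- count_synchronized_pairs(sim$traces, nu = 50)
fit <- fit_powerlaw_delta(lability(sync$M))
fit$delta
#> [1] 0.9492
```

Reading the numbers: the excitatory population fires at ≈6 spks/s; the
global state shows α ≈ 1.0, i.e. long-range-correlated 1/f fluctuations; and
the distribution of jumps in the number of phase-locked cluster pairs
follows a power law with δ ≈ 0.95 — many local synchronization changes,
few global ones, the critical-synchronization signature expected when
inhibitory global hubs control a rich club of excitatory local hubs.

`sweep_phase_diagram()` maps α over a κ × η grid (means over independently
seeded runs) and `lability_grid()` pools ℓ across runs per configuration and
fits δ. The methods vignette (`vignettes/critsync-methods.Rmd`) documents the
model, the numerical conventions (noise discretization, DFA windowing, fit
supports) and the known limitations.

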