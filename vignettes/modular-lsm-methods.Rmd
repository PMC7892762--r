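---
title: "Modular liquid state machines: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modular liquid state machines: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modlsm)
```

## The model

A liquid state machine (LSM) classifies inputs by projecting them through a
fixed recurrent network of spiking neurons — the reservoir — and training
only a simple linear readout on the reservoir's firing-rate response. This
package implements an LSM whose reservoir is *modular*: it is partitioned
into internally recurrent modules wired to one another through a random
directed acyclic graph (DAG), with the two entry modules configured so that
their firing rates realize the line and circle Hough transforms of the input
image. The modular layout has two consequences that the package is built to
demonstrate:

1. **Computational cost.** Because the module graph is acyclic, each module
   can be simulated on its own, after its predecessors, using their recorded
   spike trains as input. Replacing one `N x N` coupling with per-module
   couplings turns the dominant per-step cost from `2N^2` into
   `sum_m 2 N_m^2` plus sparse inter-module terms.
2. **Robustness.** Structural damage (dead synapses) stays local to a
   module instead of perturbing every neuron's input, and the feed-forward
   Hough layers are unaffected by reservoir-internal damage entirely.

### Encoding

Images (28 x 28 by default, intensities in [0, 1]) are band-pass filtered
with a difference-of-Gaussians kernel — size 7, standard deviations 1 and 2,
each Gaussian normalized to unit sum so the kernel sums to zero — which
mimics the centre–surround receptive fields of retinal ganglion cells. The
filtered values are rate-coded: intensities map linearly to firing rates
with the image maximum at 160 spikes/s, and each pixel then spikes
independently in each of 1,600 steps of 0.4 ms with probability
`rate * dt` (at most 0.064). Negative filter responses are clipped to zero
by default; an optional two-channel mode encodes them as a separate OFF
population instead, since nothing in the rate-coding convention dictates one
choice (`encoder_config(rectify_negatives = FALSE)`).

### Hough input synapses

The input synapse map is *predefined*, not learned. A pixel `(x, y)`
connects to line-accumulator cell `(rho, theta)` when
`rho = x cos(theta) + y sin(theta)`, and to circle cell `(a, b, r)` when
`r^2 = (x - a)^2 + (y - b)^2`. On an integer pixel grid the exact equalities
are rarely satisfiable off-axis, so the default quantization is
*nearest-bin*, exactly as classical Hough accumulators vote: each
(pixel, theta) pair votes for the nearest rho bin, and each (pixel, centre)
pair for the nearest radius bin, within half a bin width. A *strict* mode
(exact equality) is retained because it admits enumeration oracles — a
vertical line hits one `theta = 0` cell 28 times; a radius-5 lattice circle
has exactly 12 pixels — and the tests compare both modes against
double-loop accumulators.

The grid ranges are not dictated by the accumulator sizes (16 x 12 line
cells, 6 x 6 x 6 circle cells), so the package fixes reasonable defaults
and leaves them configurable: theta evenly spaced on `[0, pi)`; rho bin
centres spanning `[-27*sqrt(2), 27*sqrt(2)]` (the attainable range for a
28 x 28 image under the parameterization above); circle centres evenly
spaced across the image; radii from 3 to 13 pixels. The assignment of 16
bins to rho and 12 to theta follows the usual convention of finer distance
than orientation resolution.

### Reservoir topologies

Four reference configurations are built by `assemble_reservoir()`:

| topology | neurons | structure |
|---|---|---|
| random | 1,500 | each ordered pair connected with probability 0.01 |
| small_world | 1,500 | 30 x 50 king lattice, 8 neighbours, rewiring 0.35 |
| metric | 1,500 | 15 x 10 x 10 lattice, `P = C exp(-D^2 / lambda^2)`, `lambda = 2` |
| modular | 1,488 | Hough modules (192, 216) + 8 small-world 9 x 15 modules in a DAG |

Small-world generation rewires each directed edge of the 8-neighbour
lattice with probability 0.35 to a uniform random target, resampling
collisions, so out-degrees are preserved exactly. Without wraparound the
9 x 15 module lattice has 940 directed edges (mean out-degree 6.96; with
rewiring the boundary effect keeps the average below the in-bulk value of
8). The metric network's `C` map is 0.3/0.2/0.4/0.1 for
ex-ex/ex-in/in-ex/in-in ordered type pairs; at an 80/20 excitatory split
the realized mean out-degree is about 9.3–9.4.

The module DAG is generated over topologically ordered labels: candidate
edges run from lower to higher labels, edges into the two input modules are
excluded, and each remaining candidate (44 of them for 10 modules) is
included with probability 0.25. "Non-input connections" is read as
*connections whose target is not an input module*; input modules may still
feed later modules, which is what makes them inputs. Each realized edge is
expanded by connecting every presynaptic neuron to 10 distinct random
neurons of the target module at a constant weight.

Unstated structural constants were fixed once, as follows, and are
configurable: the excitatory fraction is 0.8 (the convention of the
cortical-microcircuit models this family of reservoirs descends from); the
Hough modules are all-excitatory, feed-forward layers with no internal
recurrence (they are encoding layers whose rates should remain clean
accumulator images); the inter-module and input-synapse weight equals the
ex-ex weight, 20; the stand-alone small-world comparison reservoir uses a
30 x 50 lattice under the same rewiring rule; input synapses for
non-modular reservoirs connect each pixel to 10 random targets.

### Neuron and synapse model

Leaky integrate-and-fire dynamics
`tau dV/dt = -(V - V_rest) + R I(t)` with threshold 15 mV, reset and rest
at 13.5 mV (as printed in the source model family, although reset equal to
rest is unusual), membrane time constant 30 ms, and refractory periods of
5 ms (excitatory) / 2 ms (inhibitory). `R` is never given a value, so it
defaults to 1 — the synaptic weights (20 ex→ex, 45 ex→in, −17 from any
inhibitory neuron) absorb the physical scale. Delays are 1.5 ms for ex→ex
pairs and 0.8 ms otherwise.

Numerical choices:

* **Integration** is exponential Euler,
  `V <- V_rest + (V - V_rest) e^(-dt/tau) + R I (1 - e^(-dt/tau))`, which is
  exact for piecewise-constant current — the zero-input decay test can
  therefore demand agreement with the closed form at `1e-9`.
* **Discretization**: delays and refractory periods convert to steps by
  `ceiling(ms / dt)` with a 1-step minimum — at `dt = 0.4 ms`: 4 steps
  (ex→ex), 2 steps (otherwise), 13 steps (excitatory refractory), 5 steps
  (inhibitory).
* **Threshold** fires at `V >= V_th`; spiking neurons reset and skip their
  refractory steps entirely (no integration, voltage held at reset).
* Every simulation prepends a 50 ms (125-step) silent settle phase,
  excluded from feature extraction.

### Divide-and-conquer simulation

`simulate_network(..., mode = "modular")` simulates modules one at a time
in topological order (ascending label), feeding each module the recorded
rasters of its predecessors. Modules of equal DAG depth are conditionally
independent and could run in parallel; correctness is defined by the
sequential order, and the package treats parallelism as an optimization it
does not implement. The central correctness property is *exact* equality
with the monolithic whole-network run, not approximate: the compiled kernel
accumulates synaptic current column-by-column in ascending global
presynaptic index within each delay group, so the floating-point summation
order is identical whether the network is integrated jointly or per module.
The test suite asserts bit-identical rasters on a 3-module chain and on the
full 10-module, 1,488-neuron configuration.

### Readout

Per-neuron mean firing rates over the stimulus window feed a linear
support-vector readout with `C = 1`. The multiclass scheme is one-vs-rest
(one binary machine per class, argmax of decision values), the standard
choice for linear SVMs; one-vs-one is available. Features are used raw:
all are rates on one spikes/s scale, so standardization is off by default.
The binary machines come from libsvm via e1071; the scheme composition,
evaluation and confusion reporting are package code. Confusion matrices
are row-normalized percentages with true classes in rows.

### Perturbation analyses

Input noise adds zero-mean Gaussian pixel noise with standard deviation
`level x sd(image)` — the "20% white noise" phrasing read as a
noise-to-signal amplitude ratio — then clips to [0, 1]. System noise
disables exactly `round(fraction x E)` of the eligible synapses (uniform,
without replacement, exact count rather than per-synapse Bernoulli so
printed percentages are realized exactly). Eligible by default are the
reservoir-internal and inter-module synapses, not the input synapses:
ablation models damage inside the system, as opposed to input noise; the
scope is configurable because the original protocol does not say whether
input synapses were counted.

### Cost accounting

`count_flops()` makes its convention explicit — multiply-add = 2 ops,
6 ops per neuron update, dense mode `2 N_pre N_post` per matrix product —
because absolute published FLOP figures depend on unstated conventions.
The package therefore asserts only the relative claim: for the 10-module
configuration the dense modular count (`2(192^2 + 216^2 + 8*135^2)` intra
plus realized inter-module products) is less than half the monolithic
`2 * 1488^2`, matching the "more than twice as efficient" comparison.

## What the synthetic data emulates — and what it does not

`make_toy_dataset()` generates four classes of 28 x 28 stroke images —
vertical lines (random column), horizontal lines (random row), diagonals
(random offset), circles (random centre, radius 5) — with optional pixel
jitter. The classes are designed so the Hough layers are discriminative
(orientation separates the line classes; the radius signature separates
circles) while raw pixel space is deliberately hard for a linear readout,
since stroke position varies within each class.

Strokes default to 2 pixels wide, the approximate thickness of handwritten
digit strokes. This matters dynamically: 1-pixel strokes deliver so little
input current that the reservoir's recurrent pathway contributes almost
nothing (removing every recurrent synapse barely changes the spike counts),
which would make damage experiments vacuous. At 2-pixel width a substantial
share of reservoir spiking depends on recurrent input, so ablation measurably
perturbs the population code while the task stays solvable.

What passing tests on this fixture do **not** show: absolute accuracy
levels comparable to handwritten-digit benchmarks; robustness magnitudes
comparable to the full-scale experiments (the toy-scale accuracy drops are
far smaller); or anything about temporal structure in the
input, since the toy stimuli are statistically stationary over the
presentation window. Full-scale replication is supported through the IDX
loaders (`load_idx()`) but requires the external image files.

## Problem sizes used by the tests

Unit tests run on miniature hand-wired networks (up to 27 neurons) where
every expected number comes from an enumeration, a closed form, or a
brute-force oracle coded independently in the test file. The end-to-end
properties run at a deliberately reduced scale chosen to keep a complete
suite run in minutes on one core: 400 stimulus steps instead of 1,600
(settle phase unchanged at 125 steps), 12 training and 16 test images per
class, 10 replicate seeds for the ablation sweep and 5 for the topology
comparison. The structural checks (1,488-neuron composition, Hough module
sizes, DAG candidate counts, metric/random mean degrees) and the
modular-vs-monolithic equivalence run at full scale, where they are exact
or tightly banded.

## Known limitations

* Only clock-driven simulation with a global fixed `dt`; no event-driven
  path, conductance synapses, or plasticity.
* The modular scheduler requires the inter-module graph to be acyclic (by
  construction it is); arbitrary cyclic module graphs fall back to
  monolithic simulation only.
* One-channel rectified encoding discards the sign of the filter response
  by default; the OFF-channel mode doubles the input population and is not
  wired into the default Hough grids.
* Same-depth modules are simulated sequentially; the DAG parallelism is
  documented, not exploited.
* The audio workflow of the source model family (cochlear preprocessing of
  spoken digits) is out of scope.
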