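---
title: "Methods: behavior-based spiking network simulation and its optimized kernels"
author: "snnkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavior-based spiking network simulation and its optimized kernels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snnkit)
```

## The simulation model

snnkit simulates spiking neural networks in discrete time. The model
*structure* is held by three component types -- `NeuronGroup` (a homogeneous
population with per-neuron state arrays), `SynapseGroup` (a dense weight
matrix connecting a source to a destination population), and the `Network`
that owns everything -- while all *dynamics* live in small behavior modules
attached to components under integer priority keys. A behavior has a `setup`
hook, run exactly once before the first step, and a `step` hook, run exactly
once per iteration. Keys are global: each step executes every attached
behavior, anywhere in the network, in ascending key order. This separation
keeps each piece of dynamics (noise drive, membrane update, transmission,
plasticity, normalization, recording) a few lines long and independently
replaceable.

Two conventions are worth stating precisely because everything downstream
depends on them:

* **Iteration counter.** `net$iteration` is 0 after initialization and is
  incremented at the *start* of each step, so the first executed step
  observes iteration 1. Interval work gated on `iteration %% k == 0`
  therefore fires at steps k, 2k, ...; 300 steps at interval 100 normalize
  exactly three times (steps 100, 200, 300). Whether such counters are 0- or
  1-based is a genuine design choice; this package fixes 1-based and
  documents it here and in the raster files.
* **Key ties across components.** Keys must be unique per component but may
  collide across components; ties execute in component registration order,
  which is stable and reproducible across builds.

Initializing a network twice is an error rather than a no-op: a silent
re-initialization would silently reset learned weights.

### Reproducibility

One master seed is given per network. Every component derives its own
random stream from the master seed and its registration index, and all
random fills (`neuronVector`, `synapseMatrix`, the noise behaviors) draw
from the owning component's stream. Two consequences: identical seeds give
bit-identical runs, and attaching an extra component -- a recorder, say --
never perturbs the draws of the others. Random weight initialization draws
in a canonical source-major order before any physical transpose, so the
*semantic* weights depend only on the seed, never on the storage layout;
this is what lets the naive and optimized pipelines below produce
bit-identical spike rasters.

## The optimized kernels and their oracles

Synaptic work dominates the cost of dense SNN simulation, and all of it
factors through a handful of array operations. Each optimized kernel in
snnkit ships next to its naive counterpart, which serves as the oracle in
the test suite:

| operation | naive oracle | optimized form |
|---|---|---|
| transmission | full matrix-vector product | gather active source rows, sum |
| weight layout | destination-major (D x S) | source-major (S x D), contiguous gathers |
| STDP update | outer product of spike vectors | index-mesh update of touched entries |
| clipping | clamp full matrix | clamp mesh entries only |
| precision | f64 | f32/f16 storage grids |
| very sparse weights | dense matrix | row-compressed sparse gather |

The point of exploiting binary spike vectors is that transmission needs no
multiplications at all -- only the rows of the neurons that actually fired
(about 1% per step in the reference regime) need touching -- and that a
plasticity step touches only `|active pre| * |active post|` weights instead
of all S x D of them.

### The exactness contract

The optimized forms are claimed *exactly* equivalent to the naive ones in
f64, and the test suite asserts bitwise equality over thousands of random
instances. That claim is only provable if the implementation controls
summation order: floating-point addition is not associative, so a BLAS
matrix-vector product with blocked partial sums need not equal a
subset-sum, and R's built-in `rowSums`/`colSums` accumulate in extended
precision, which need not round like a double accumulator. All summation
kernels therefore accumulate in double precision, adding contributions in
ascending source-index order, through a small backend facade. Under that
contract the skipped terms of the indexed kernel are exact zeros, and
adding an exact zero never changes a double accumulator -- so indexed ==
product bitwise, and the sparse gather == the dense indexed kernel bitwise.
The mesh STDP update adds exactly the same `lr` to exactly the same
entries as the outer-product update, so those two are bitwise identical in
every dtype.

The facade (`getBackend("cpu")`) exposes allocation, random fill,
row/column accumulation, mesh add/clip and cast as swappable primitives;
an accelerated backend can be registered without touching kernel or model
code, at the price of re-validating the exactness contract for its
reductions.

### Reduced precision

R computes only in double. The `f32` and `f16` dtypes are therefore
*storage grids*: values are rounded to the nearest representable
float32/float16 after construction, casts, and each weight update, while
arithmetic between rounds runs in double. This matches the intended use of
lower precision here -- shrinking the memory footprint of large weight
matrices (`nominalBytes` reports 8/4/2 bytes per element) -- and keeps
every equivalence above intact. It does *not* emulate float32 accumulation
error; the 1e-5 relative tolerance the f32 transmission test asserts is an
upper bound that this scheme satisfies by a wide margin. f16 support is
storage-and-correctness only, with no performance claim. The float16
quantizer implements round-to-nearest-even including subnormals below
2^-14 and overflow to infinity above 65504, and is cross-checked against
numpy's float16 cast in the test suite.

### Multi-lag STDP

The one-step rule credits only the (pre at t-1, post at t) coincidence. A
wider discrete window is built by bundling recent spike vectors in a ring
buffer (`spikeHistory`) and applying the mesh update once per lag:
positive lags pair past pre spikes with current post spikes
(potentiation), negative lags the reverse (depression). The per-lag
amplitudes of the nine-step default window are not prescribed anywhere, so
the package fixes a symmetric discrete exponential,
`a(l) = sign(l) * A * exp(-|l|/3)` over lags -4..4 (lag 0 counted as
potentiation), fully overridable via `stdpMultiLag`'s `amplitudes`
argument.

### Normalization and clipping

`normalizeAfferent` divides each destination neuron's incoming weights by
their sum (target 1, configurable), leaving exactly-zero rows untouched --
dividing by zero would destroy the row, and a zero row carries no signal
to normalize. Clipping after a mesh update clamps only the touched
entries; out-of-range entries outside the mesh are deliberately left
alone, which the tests assert as a multiset-preservation property.

## In-place model updates

R's value semantics would copy the full weight matrix on every
subassignment through a function boundary, which at N = 10,000 means
copying 800 MB per plasticity step -- the opposite of what a sparse mesh
update is for. The reference-model behaviors therefore keep the weight
matrix bound directly in the synapse group's state environment and
evaluate block subassignments inside that environment, which R performs
in place while the matrix is unshared. Taking a snapshot
(`synapseWeights`) shares the matrix; the next in-place update then
copies once, transparently preserving the snapshot. The arithmetic of the
in-place path is identical to the value-semantic kernels, and a dedicated
test steps a model while replaying the same updates through
`stdpMesh`/`clipMesh`, asserting bitwise equality throughout.

## The reference models

Both shipped models are a single N-neuron population with a dense
recurrent all-to-all synapse group (self-connections kept) and the
behavior stack: noise input (key 1), neuron dynamics (key 2), Dirac
transmission (key 3), plasticity (key 4), optional interval normalization
(key 5), recorders (keys 1000+). Transmission reads the current step's
source spikes (the neuron behavior's key precedes the synapse's);
one-step plasticity pairs the *previous* step's pre spikes with the
current post spikes, with the previous-step buffer all-false at the first
iteration.

**LIF + one-step STDP.** Discrete leaky integrate-and-fire:
`v <- v + leak*(vRest - v) + I_syn + U(0, noiseHigh)`, spike when
`v >= vThreshold` (threshold inclusive), reset to `vReset`. Defaults:
`vRest = 0`, `vReset = 0`, `vThreshold = 1`, `leak = 0.1`. The exact
parameterization of this model is not prescribed, so the package fixes
dimensionless units and calibrates `noiseHigh = 0.165` so that an
*isolated* neuron fires in about 1% of steps -- the sparse-activity
regime all the kernel benchmarks assume. The closed-form subthreshold
decay `v(k) = vRest + (v0 - vRest)(1 - leak)^k` is asserted to 1e-10.

**Izhikevich + trace STDP.** One Euler step (dt = 1 model-time unit) of
`v' = 0.04 v^2 + 5 v + 140 - u + I`, `u' = a(bv - u)`, spike at
`v >= 30`, then `v <- c`, `u <- u + d`, with the regular-spiking defaults
a = 0.02, b = 0.2, c = -65, d = 8 and normal input noise calibrated the
same way (`noiseSd = 7` for ~1% isolated firing). The resting equilibrium
(v, u) = (-70, -14) is a root of the subthreshold system and is asserted
stationary; a 100-step trajectory under constant subthreshold input is
asserted within 0.5 model units of a 100-times-finer Euler reference.
The trace rule keeps per-neuron eligibility traces that decay by
`exp(-1/tau)` and gain +1 at spikes; a post spike potentiates by
`aPlus * xPre`, a pre spike depresses by `aMinus * xPost`, so an isolated
pre-post pair at lag D changes the weight by `aPlus * exp(-D/tauPre)` and
the reverse order by `-aMinus * exp(-D/tauPost)` -- the classic
exponential window, asserted directly by a pair protocol.

### Size-invariant parameterization

The models carry no homeostatic mechanism; activity must stay noise-driven
with weak recurrence, with comparable firing rates across population
sizes. With dense all-to-all connectivity the recurrent drive per neuron
scales with N unless weights do not, so initial weights are drawn uniform
on `[0, weightScale/N]` *and* the per-coincidence plasticity increments
(`learningRate`, `aPlus`/`aMinus`) are divided by N in
`buildReferenceModel`. Both the drive and its growth under learning are
then independent of N; without the increment scaling, potentiation per
destination spike grows linearly with N and the network runs away into
seizure-like activity at large sizes. Measured mean firing fractions at
N = 1,000 / 5,000 / 10,000 agree to three decimals (~1.29% per step). Clip
bounds are applied as configured (defaults [0, 1]).

## The benchmark harness

`timeOp` runs a configurable number of untimed warmup executions (default
10, to exclude allocation effects; no warmup count is prescribed anywhere,
so this is the package's choice) and then 1,000 timed repetitions by
default, reporting mean, median, sd and min recomputed from the raw
durations. `runGrid` runs whole models over a grid of kind x
implementation x size x dtype, 300 steps and 10 replicates per cell by
default; replicate r uses seed `masterSeed + r` in *every* cell, so the
naive and optimized implementations of the same replicate see identical
random conditions and their firing fractions must agree exactly -- a
strong cross-implementation check that the harness asserts. Cells that
fail (for example from memory exhaustion) are recorded as failed rows
rather than aborting the grid. `speedupTable` divides the slowest cell's
mean time by each cell's mean, so ratios are anchored at 1 and invariant
to rescaling. The *ordering* optimized < naive is asserted; the magnitude
of the speed-up is hardware-dependent and only reported.

## What the synthetic conditions do and do not show

All inputs are generated in code: Bernoulli spike vectors at a given rate
(1% in the reference regime), uniform random dense weight matrices, and
the two noise-driven models above. These reproduce the *computational*
conditions the kernels target -- binary sparse activity, dense weight
storage, Hebbian-style updates touching few entries per step -- and that
is exactly what passing tests certify: the optimized kernels compute the
same mathematics as their naive forms, deterministically, at realistic
sparsity. They do not make the models biologically calibrated: there are
no synaptic delays beyond the one-step STDP pairing, no refractoriness, no
homeostasis, no structured connectivity, and the noise drive stands in
for all unmodeled input. Conclusions about real neural data require none
of those, because the package's claims are about simulation mechanics,
not about the brain.

## Problem sizes in the tests

The test suite exercises the full 5,000 x 10,000 dense matrix (50 million
entries) for the construction, counting and memory checks, 1,000 random
kernel instances up to N = 200 at 1% spikes for the equivalence sweeps,
N = 1,000 x 300 steps for the naive/optimized raster identity, N = 2,000
x 300 steps x 10 replicates for the timing-ordering run, and
N in {1,000, 5,000, 10,000} for the rate-stability property. These sizes
were chosen so the whole suite runs in minutes on a single CPU while
still covering the reference geometry at full scale where it matters
(counts and memory) and at reduced scale where only ordering or identity
is at stake (wall-clock comparisons).

## Known limitations

* Only a CPU backend ships; the facade accepts accelerated backends but
  none is provided, so all performance statements are single-CPU.
* The naive pipeline is honest interpreted R and therefore slower than a
  BLAS-backed naive implementation would be; the reported speed-up ratio
  is a property of this implementation pair on this hardware, which is
  why the suite asserts ordering, never magnitude.
* f32/f16 are storage grids, not arithmetic emulation (see above).
* Weight snapshots and per-step array records export as headered CSV;
  there is no binary container format.
* `subgroup` views expose masked state access with write-through; they do
  not re-route synapse groups, which connect whole populations.
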