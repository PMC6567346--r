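---
title: "Breath VOC blood-glucose classification: models, solver, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breath VOC blood-glucose classification: models, solver, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Breath acetone and ethanol concentrations differ between low
(50–100 mg/dL) and high (180–240 mg/dL) blood-glucose states: acetone
1–3 ppm versus 5–7 ppm, ethanol 0–20 ppb versus 35–50 ppb. A two-sensor
metal-oxide (MOS) array sampling an artificial breath mixture through a
timed chamber protocol yields a pair of readings whose steady-state values
separate the two classes. `breathsvm` implements the entire chain — sample
simulation, feature extraction, SVM training and selection, and a
constrained-memory deployment path — so that the classification procedure
can be studied, tested, and reproduced without the physical apparatus.

Because no lab recordings are distributed with the package, the simulator
is the data source for every experiment here. The accuracies the test
suite and `scripts/acceptance.R` compute are therefore **synthetic-proxy**
results: they show that the pipeline recovers the class structure the
simulator encodes under realistic timing, response dynamics, and noise,
not that any particular hardware reaches those numbers.

## The gas-chamber simulator

### Transport model

The apparatus is three chambers in series: humidifier, VOC chamber, sensor
chamber, fed by clean air under a timed flow schedule (`default_protocol()`,
in seconds):

| phase     | window (s) | flow (L/min) |
|-----------|-----------|--------------|
| clean     | 0–300     | 1.5 |
| introduce | 300–360   | 0   |
| transport | 360–405   | 0.5 |
| steady    | 405–720   | 0   |
| clear     | 720–900   | 1.5 |

Gas transport is a linear two-compartment cascade, integrated with forward
Euler at the raw sampling interval `dt = 1` s. Writing `u` for the VOC-chamber
and `v` for the sensor-chamber concentration of one gas with drawn target
`c`:

- *Evaporation*: `du += k_evap (c − u) dt` once the lag (70 s, the delay
  observed when a sealed chamber is charged with the chemical) has elapsed
  after the start of the introduce phase, until the end of the last
  transport phase (the sample is depleted once flushing ends).
- *Advection*: with instantaneous flow `q`,
  `du −= k_adv q u dt` and `dv += k_adv q (u − v) dt`. Clean air enters the
  VOC chamber, so the clean and clear phases wash both chambers out; with
  `q = 0` (introduce, steady) the sensor chamber is frozen — this produces
  the steady-state plateau the features are sampled from.

Rates are `k_evap = 0.05 s⁻¹` and `k_adv = 0.08 (L/min)⁻¹ s⁻¹`, chosen once
so that the trace shape matches the published timing: response begins
~70 s after introduction, peaks at the end of transport, holds a flat
plateau through the steady phase, and clears within the 1.5 L/min purge.
Everything is linear in `c`, so the plateau level is exactly proportional
to the drawn concentration — disjoint class concentration ranges stay
disjoint at the sensor.

A protocol with no positive-flow phase is treated as a sealed
single-chamber experiment (sensor sits with the chemical), which is how
the lag observation is reproduced in the tests.

### Sensor model

Each sensor relaxes first-order toward a logarithmic saturation law, the
standard MOS idiom:

```
target(t) = baseline + s_a * log(1 + v_acetone) + s_e * log(1 + v_ethanol)
dy/dt = (target − y) / tau,   tau = tau_rise rising, tau_fall falling
```

with independent Gaussian noise of sd `noise_sd` added per raw sample. The
default array has two sensors with distinct gain pairs
(`s_a = 8, s_e = 1.5` and `s_a = 5, s_e = 3`; baselines 10 and 12 output
units; `tau_rise` 20/25 s, `tau_fall` 60/70 s), so the 2-D steady-state
feature vectors of the two classes are linearly well separated. Output
units are abstract — the hardware's units (resistance, voltage) are never
stated in the underlying experiments, and min–max scaling removes them
anyway.

`noise_sd = 0.05` output units by default. The worst-case noiseless class
gap on sensor 1 is ≈ 2.2 units (low acetone at its top of range versus
high at its bottom), so within-class scatter is small relative to the
between-class gap. This is a deliberate modeling choice: the published
steady-state cross-validation accuracies are at or near 100%, which is
only consistent with a low-noise, well-separated steady state. The
`residual_spike` sensor flag reproduces the ethanol carry-over bump at the
steady→clear boundary seen in the reference traces; it is off by default
and affects only the clear phase, outside every feature segment.

### What the simulator does *not* emulate

Sensor drift and aging, temperature/humidity sensitivity, cross-run
baseline wander, correlated (1/f) noise, adsorption hysteresis, and
chamber-volume physics are all absent. Consequently, passing tests
demonstrate correctness of the algorithms and the internal consistency of
the pipeline under the stated conditions — not robustness of the method to
real-sensor pathologies.

## Features

Five named segments, in seconds **relative to the start of chemical
introduction**: Baseline 0–50, Rise 65–85, SteadyState 150–400, Fall
450–500, LateFall 500–600. The reference origin is a design decision: with
it, the SteadyState window (absolute 450–700 s) lands inside the zero-flow
steady phase (405–720 s), which is the only consistent reading.

Readings are sampled at `start, start + period, …, end` inclusive
(default `period = 5` s → 51 steady-state readings per run). Raw samples
live at `0, 1, …, 899` s, so a window that ends exactly at the protocol
end has no raw sample under its final grid point; such grid points are
dropped, while windows genuinely outside the run are errors.

Labels are encoded +1 = high, −1 = low. Scaling is per-feature min–max
fit on training rows only — `(x − min)/(max − min)`, degenerate features
map to 0, out-of-range test values are *not* clipped — and is stored in
the model so deployment needs no separate preprocessing state.

## The SVM and its solver

`breath_svm()` solves the soft-margin dual

```
max  sum(a) − 0.5 * t(a*y) K (a*y)    s.t.  0 <= a_i <= C,  sum(a_i y_i) = 0
```

with an RBF kernel `K(x, xi) = exp(−(gamma/sigma) ||x − xi||²)`. `sigma`
is kept as an explicit divisor defaulting to 1: the single-parameter form
matches the common library convention behind the 2⁻³…2¹ gamma grid, while
a data-variance normalization can still be configured without rescaling
the grid.

The solver is sequential minimal optimization with maximal-violating-pair
working-set selection: each iteration picks `i = argmax_{I_up} −y∇` and
`j = argmin_{I_low} −y∇`, optimizes the pair in closed form, and updates
the dual gradient in O(n); convergence is declared when the KKT gap
`m(a) − M(a)` falls below `tol` (default 1e-3). Numerical details that
matter:

- *Zero curvature*: when `K_ii + K_jj − 2K_ij ≈ 0` (duplicated or
  collinear points) the dual is linear along the pair and the update moves
  to the better endpoint — required, e.g., for a duplicated point with
  conflicting labels, whose two coefficients must both pin at `C`.
- *Bound snapping*: alphas within `1e-12·C` of a bound are set exactly on
  it, so floating-point fuzz cannot strand a bounded point in the working
  set (this failure mode, detected against an independent QP oracle,
  leaves the solution visibly suboptimal otherwise).
- *Ties* in pair selection are broken uniformly at random through R's RNG;
  the training `seed` makes runs reproducible.
- *Bias*: the average of `y_i − f_nob(x_i)` over free support vectors
  (`tol < a_i < C − tol`); if every alpha is at a bound, the midpoint of
  the KKT interval `[m_up, m_low]`.
- *Support vectors*: points with `a_i > tol` are retained; everything else
  is dropped from the model, which is what keeps the packed model small.
- `max_passes` (default 100) caps the iteration count at
  `max_passes × n` pair updates; on these data the solver converges within
  the equivalent of one or two passes.

Ties at `f(x) = 0` classify as **high** — arbitrary but documented and
deterministic.

Correctness is contracted against an independent interior-point QP
solution (`kernlab::ipop`) on random small problems: dual objectives agree
within 1e-4 (trained at `tol = 1e-8`, so the bound is meaningful) and
predictions agree on every probe with a decision value away from zero.
The oracle is used only in tests, never by the implementation.

## Model selection

Cross-validation is leave-one-run-out over the full cross-product of
held-out (low, high) run pairs: 10 + 10 runs give 100 splits, each
training on 9 + 9 runs and testing every sampled reading of the held-out
pair. "Every permutation" of nine-plus-nine training samples is read as
exactly this cross-product; an index-paired variant is available via
`paired = TRUE`. Accuracy is pooled over readings across splits (correct
readings / total readings), matching reading-level reporting; the
default grid is C ∈ {2⁻³ … 2²} × γ ∈ {2⁻³ … 2¹} (30 cells). Ties for the
best cell break toward smaller C, then smaller γ — a regularization-first
rule consistent with the published example matrix, whose top-left cell is
the reported optimum. Scaling is refit inside every split on training
rows only, so no held-out reading influences its own preprocessing; the
tests assert the absence of leakage explicitly.

One subtlety: a *run-level* random-label permutation does **not** produce
50% cross-validation accuracy on strongly clustered data — with 8 + 8
runs the expected accuracy of cluster-majority labeling under a balanced
permutation is ≈ 60%, and we measure exactly that. The chance-level null
contract ("≈ 50% within a binomial band at ≥ 200 readings") is only
coherent when the label–feature association is fully destroyed, so the
null suite permutes labels at the *reading* level before a grouped
train/test split. That choice is deliberate and the run-level effect is
worth knowing about when interpreting permutation baselines on grouped
sensor data.

## Deployment

`pack_model()` flattens a fit into a fixed-layout container: `dim`,
`n_sv`, `gamma_eff = gamma/sigma`, `bias`, row-major `sv` array, `coefs`
(= `a_i y_i`), `scale_min`/`scale_max`, and a label map, under the format
tag `breathsvm-1`. The serialized form is JSON with full double precision
(lossless round trip; the tests require decision-value agreement to
1e-12 through the file). The memory footprint is exactly
`bytes_per_value × (n_sv·dim + n_sv + 2·dim + 2)` — no hidden overhead —
and `emit_source()` renders the same content as static C arrays at 9
significant digits (the single-precision deployment assumption) together
with a reference decision routine.

`stream_classify()` is the microcontroller-shaped loop: readings arrive
in time order, each on-grid reading inside the window is scaled,
evaluated, and labeled immediately with no lookahead and constant memory
beyond the model, and the running majority verdict is updated after every
reading. Per-reading labels are the primary output (matching reading-level
accuracy reporting); the majority verdict is a convenience. Stream labels
are asserted identical to batch classification of the same rows.

## Problem sizes and runtime choices

The study-scale experiments — 10 runs per class, 5 s sampling (51
steady-state readings per run), 100 leave-one-run-out splits, the 30-cell
grid, ~900-point training designs per split — run end to end in the test
suite and acceptance script; a full grid search takes on the order of
15 s on one CPU with the compiled solver. Unit tests use a 1/5-scale
protocol with the same phase structure where full-length runs add nothing.
Reported synthetic-proxy results (computed, not asserted from outside):
steady-state grid-search accuracy is 100% for both acetone-only and
mixture footprints under the default conditions, streaming accuracy on
fresh runs is 100%, and the reading-level null sits near chance within
the stated band.

## Known limitations

- Synthetic data only; see the simulator caveats above. Real-device
  accuracy claims require real recordings.
- Binary classification only; no probability calibration, no other
  kernels, no multiclass extension.
- The transient segments (Rise, Fall, LateFall) are simulated with the
  same linear dynamics as the plateau, so their synthetic CV accuracies
  are optimistic relative to hardware transients.
- Euler integration at `dt = 1 s` is adequate for time constants ≥ 8 s
  (the fastest washout here) but would need refinement for much faster
  protocols.
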