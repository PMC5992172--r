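---
title: "Estimating motor-team stopping forces: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating motor-team stopping forces: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slideforce)
```

This vignette is the package's own account of the science it implements:
the physical models behind each estimator, the parameters that matter, what
the synthetic-assay generator does and does not emulate, and the numerical
choices made where the underlying measurement procedure left the design
open.

## The physical setting

Kinesin-14 (Ncd) is a minus-end-directed, non-processive motor that
crosslinks two microtubules: its motor domains step on one filament while
its tail domains hold the other. How the tails are anchored governs how
much of the generated force reaches the cargo filament. The package
analyses four anchorage geometries: motor domains immobilised on a glass
surface transporting filaments (gliding); full-length motors whose
diffusive tails crosslink a transported filament to an immobilised one
(sliding); the same motors bridging non-aligned, crossing filaments, which
geometrically restricts tail diffusion; and motor domains statically
anchored on a microtubule. Forces are measured with optical tweezers: a
trapped microsphere bound to the transported filament experiences a
restoring force `k * x` (trap stiffness `k`, bead displacement `x`), and
either stalls the transport (gliding-scale forces, ~10 pN) or is used in
force-feedback scans (sliding-scale forces, below the ~0.5 pN thermal
noise floor of the trap).

## Bead-in-trap model and the trace simulator

A bead of drag `zeta_b` in a harmonic trap is an overdamped Langevin
system; its position is an Ornstein-Uhlenbeck (OU) process with relaxation
rate `k / zeta_b` and stationary variance `kB T / k` per axis
(equipartition). `simulate_trap_trace()` integrates this with the *exact*
discrete-time OU update

    x[t+dt] = mu + exp(-lambda dt) (x[t] - mu) + sqrt(var (1 - exp(-2 lambda dt))) eps

rather than an Euler step, so the stationary variance is unbiased at any
sample rate — tests of the equipartition diagnostic would otherwise
inherit an integration bias that scales with `dt`.

After the binding time the bead is rigidly coupled to a filament driven by
a motor team with the linear force-velocity relation `v(F) = v0 - F/gamma`
(`v0` unloaded velocity, `gamma` the team's friction coefficient, i.e.
the magnitude of the force-velocity slope). Writing the force balance on
the bead-filament compound with the motor drive `gamma (v0 - v)` gives
another OU process: relaxation rate `k / (zeta_b + gamma)`, mean force
rising exponentially to the plateau `gamma * v0` along the transport
direction, and — with fluctuation-dissipation noise on the combined drag —
the same equipartition force variance `k kB T`. No linkage compliance is
modelled (the bead-filament bond is treated as rigid; a compliant linker
would low-pass the transmitted force and is a possible extension), the two
trap axes are independent with equal stiffness, and instrument crosstalk
between lateral displacement and axial signal is not emulated. The
instrumental force offset is a constant added to the recorded channels,
which is exactly what the baseline-offset estimator removes.

Key parameters and defaults: trap stiffness 0.05 pN/nm (the calibrated
range of the instrument spans 0.05-0.1 pN/nm), bead drag 9.4e-6 pN s/nm
(Stokes drag of a 1 um silica sphere in water), temperature 298 K. The
tweezers objective is not actively temperature-controlled in these assays,
so ambient temperature is a choice, exposed in the config; all
`kB T` values use `kB = 0.0138065 pN nm/K`. Setting `temperature = 0`
gives noise-free traces, which the tests use as closed-form limits.

## Stopping force from a plateau

The plateau route mirrors a manual trace analysis: average each force axis
over a baseline window of several seconds before attachment (default 5 s)
to get the offsets; average each axis over the stalled plateau; combine
the offset-corrected means by Pythagoras. Because the signed per-axis
values are averaged *before* the magnitude is taken, fluctuations through
zero do not rectify into a bias; on a genuine plateau the force is far
from zero anyway.

Binding detection thresholds the derivative of the 0.1 s-smoothed force
magnitude (default 2 pN/s) and requires a subsequent rise of at least
1 pN above baseline — the event in a gliding trace rises at
`k * v0` ≈ 13 pN/s, an order of magnitude above the smoothed noise
derivative, so the defaults detect it within ~0.2 s. Plateau detection is
automated (the underlying procedure selects plateaus by eye, so a manual
window override exists): the post-binding force magnitude is binned (1 s
bins), local slopes are fitted over a 6 s rolling window, and the longest
contiguous run with |slope| <= 0.15 pN/s wins. The window sizes matter
physically: the bound bead's force fluctuations have correlation time
`(zeta_b + gamma)/k` (~0.7 s at gliding parameters), so slope estimates
must average over many correlation times or correlated noise masquerades
as slope. With these defaults the residual rise inside the detected
plateau contributes a bias well below 1%, and the plateau average over
100 seeded gliding traces recovers `gamma * v0` to within 2% (this is one
of the acceptance checks). All samples inside the window are averaged;
brief dips are not excluded.

## Stopping force from a force-velocity scan

For aligned sliding pairs the transmitted force is below the trap's noise
floor, so the estimator changes: scan segments hold a constant force (the
stage velocity is the response) or a constant velocity (the force is the
response), in both forward and backward directions. Both modes are pooled
as (velocity, force) points and fitted by weighted least squares of
**force on velocity** — the target quantity is a force difference, so
force is the response variable regardless of scan mode. The quality
weights act multiplicatively on squared residuals; their scale is a
by-eye steadiness rating with no defined units, so they are accepted as
given in (0, 1] (the synthetic generator draws them uniformly from
[0.5, 1]). The intercept is left free: constraining the line through the
independently measured `(v0, 0)` point would be an alternative, but the
unconstrained fit lets the intercept absorb any force offset of the scan
and keeps the slope an honest friction estimate. The stopping force is
`|slope| * v0`, with `v0` from the independent pre/post measurement
(averaged when both exist), and its standard error propagates the slope
SE and, when supplied, the `v0` uncertainty in quadrature.

Regressing force on a noisy velocity response inverts the
errors-in-variables direction; at realistic scan parameters (set-points
spanning ±5 pN, velocity responses spanning ~800 nm/s, velocity noise
~20 nm/s) the attenuation bias on the slope is below 1%, far inside the
10% recovery tolerance the acceptance tests demand over 200 seeded pairs.

## Passive corroborations

Two closed forms bound the sliding force independently.

*Entropic balance.* `N` diffusible crosslinkers confined in an overlap of
length `L` act as a 1-D ideal gas with expansion force `N kB T / L`
(valid in the dilute limit; no density cutoff is enforced). Motors slide
the overlap shut until this balances their force, so
`stall_overlap_inversion()` evaluates the gas law at the stalled state.
The simulated shortening follows `dL/dt = -rate (1 - L_stall/L)`, the
simplest relative-flux law with the right fixed point; it is integrated
via the exact separable-ODE time-of-flight, sampled until the recorded
length is within 0.5% of `L_stall`, so the round trip
simulate-then-invert recovers the motor force to better than 1% by
construction of the stall criterion, not by tuning.

*Buckling.* A constrained filament segment of length `L` (in um) with
flexural rigidity `EI` buckles at `prefactor * EI / L^2`. The default
`EI = 6e-24 N m^2` is the standard microtubule value, and the default
prefactor is `4 pi`, the form used in the analyses this package
reproduces — note the classical Euler clamped-clamped formula has
prefactor `4 pi^2`, exactly `pi` times larger, and is available via the
`prefactor` argument; the package defaults to the form whose printed
worked examples (1.1 pN at 8.3 um, 0.75 pN at 10 um) it reproduces, and
exposes the discrepancy rather than guessing intent.

## Velocity statistics

Per-filament velocities come in three modes matching how tracks are
produced: automated tracking (instantaneous frame-to-frame velocities,
averaged per filament), kymograph slopes (inherently averaged, passed
through unchanged), and hand-marked end-to-pivot distances for swivelling
filaments (treated as an ordinary track; no swivel correction beyond the
choice of coordinate). Population statistics weight each filament by its
observation duration; at uniform sampling the mean of instantaneous
velocities telescopes to net displacement over total time, which the
tests assert exactly. The weighted SD uses frequency-weight normalisation
(`sum(w) - mean(w)` in the denominator) so equal weights reduce exactly
to the ordinary sample SD; the weighted median is the value at half the
total weight. Whether reported population SDs should be weighted or raw
is ambiguous in practice, so both are emitted.

Boxplot statistics follow the 1.5 IQR fence definition; the quartile rule
is fixed to linear interpolation between order statistics at rank
`(n+1)p` so that tests can be exact against a brute-force reference
(the rule reproduces q1 = 2, q3 = 6 on the sample 1..7).

Motor counting divides background-subtracted integrated intensity by a
single-fluorophore calibration; synthetic intensities are sums of gamma
draws with the calibrated mean and coefficient of variation (a positive,
right-skewed model of fluorophore brightness). Surface-motor numbers are
`length x reach-band x density` with a 50 nm default reach band (motor
contour-length scale; no measured value exists, so it is exposed as a
parameter).

## What the generator does and does not emulate

The generator reproduces the statistical structure the estimators assume:
OU thermal noise with the right variance and correlation time, a rigid
bead-filament link, a strictly linear force-velocity relation, iid
Gaussian localisation noise, gamma-distributed fluorophore intensities,
deterministic overlap shortening. Real traces additionally contain
unspecific surface interactions, compliance and geometry changes of the
linkage, slow drift of the offsets, partial slips within plateaus, and
velocity fluctuations beyond trap noise. Passing the recovery tests
therefore shows the estimators are correct and unbiased *under the stated
model*, not that the model captures every artefact of a real experiment —
which is why the trace tools expose manual windows and quality weights,
the knobs an analyst uses when reality intrudes.

## Problem sizes and determinism

Every generator is deterministic given its seed (verified bit-for-bit in
the tests), and batch drivers derive per-trace seeds from the config seed
so whole directories reproduce byte-identically. The test suite sizes its
simulations to what the estimators need: 60 s at 1 kHz for the
equipartition check (variance SE ~0.6%), 100 seeded 40 s gliding traces
for plateau-estimator bias, 200 seeded scans for the sliding-regime
recovery, and 1000 random samples for the statistics oracles. The
analysis workflow under `analysis/` uses small per-geometry batches
(8 traces or 12 scans) as a narrative demonstration; the statistical
heavy lifting lives in the tests.

## Known limitations

- The bound-state model has a single friction coefficient; motor-number
  fluctuations, load-dependent detachment cascades and rebinding kinetics
  are reduced to an optional sharp detachment threshold with a fixed
  rebinding delay.
- `detect_plateau()` assumes one dominant plateau per binding event; a
  trace that detaches and rebinds is handled by re-running detection per
  event, not by segmenting automatically.
- The entropic-balance inversion trusts the supplied crosslinker count;
  in practice `N` comes from fluorescence counting with its own ~CV/sqrt(N)
  uncertainty, which propagates linearly into the force.
- The buckling formula treats the segment as ideal and the load as purely
  compressive; no elastica shape analysis is attempted.
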