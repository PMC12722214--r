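---
title: "Quantitative multi-metabolite CEST fingerprinting: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative multi-metabolite CEST fingerprinting: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cestmrf)
```

## The problem

Chemical exchange saturation transfer (CEST) MRI detects dilute labile
protons — amide protons of mobile proteins at +3.5 ppm, glutamate amine
protons at +3 ppm, aliphatic protons relayed through the nuclear
Overhauser effect (rNOE) at −3.5 ppm, and the broad semisolid
macromolecular (MT) pool — through their exchange with water. The
conventional CEST-weighted signal confounds concentration, exchange rate,
relaxation, and sequence parameters. Fingerprinting (MRF) resolves this:
a pseudo-random saturation schedule produces a tissue-specific signal
trajectory, and an inversion trained on simulated dictionaries maps each
pixel's trajectory to quantitative parameters — the proton volume
fractions \(f_{ss}, f_s\) and exchange rates \(k_{ssw}, k_{sw}\) of the
semisolid, rNOE, amide and glutamate pools.

`cestmrf` implements this workflow end to end: a multi-pool
Bloch–McConnell simulator, schedule/dictionary/phantom generators, a
sequential three-network quantification pipeline, the conventional
Z-spectrum metric suite used for comparison, and the recovery statistics.

## Spin physics

The simulator integrates the coupled Bloch–McConnell equations for a
water pool, any number of mobile solute pools (full transverse +
longitudinal dynamics), and an optional semisolid pool (longitudinal
only). Exchange is star-shaped — each solute exchanges with water at rate
\(k_{sw}\), the reverse rate following mass balance
\(k_{ws} = f_s\,k_{sw}\) so that equilibrium magnetization equals the
volume fraction. Continuous-wave saturation of amplitude \(\omega_1\) at
offset \(\Delta\omega\) saturates the semisolid pool at rate
\(\pi\omega_1^2\,g(\Delta\omega)\), with \(g\) a Lorentzian or (default)
super-Lorentzian absorption lineshape; the super-Lorentzian on-resonance
singularity is bridged by quadratic interpolation through anchors at 1,
1.5 and 2 ppm from the pool center — the standard workaround for its
divergence at the water resonance.

Within an acquisition entry all parameters are constant, so the system
\(\dot M = AM + c\) has the exact solution
\(M(t) = M_\infty + e^{At}(M_0 - M_\infty)\) with
\(M_\infty = -A^{-1}c\); the propagator is evaluated with the matrix
exponential (machine-precision accurate regardless of stiffness — the
glutamate amine rate reaches \(10^4\) s\(^{-1}\)). A fixed-step
Runge–Kutta route (`method = "rk4"`) provides an independent propagation
for cross-checks, and the test suite also verifies the engine against a
closed-form two-pool steady state obtained by solving \(AM+c=0\)
directly.

The readout is idealized: per entry the recorded signal is the water
longitudinal magnetization at the end of saturation weighted by
\(e^{-TE/T_2}\), after which transverse magnetization is spoiled, water
longitudinal magnetization is consumed by an ideal 90° excitation, and
the system relaxes for the rest of TR. The echo-train itself is not
simulated: trajectory shape is dominated by saturation and recovery, not
by the readout. MRF trajectories carry magnetization over between
entries (the acquisition is deliberately non-steady-state); conventional
Z-spectrum protocols, by contrast, are simulated as independent long-TR
measurements starting from equilibrium, which is the assumption
underlying all the standard Z-spectrum metrics (and makes direct
saturation exactly symmetric for an on-resonance water pool, a property
the tests rely on).

Static-field inhomogeneity is modeled by adding the tissue's `b0_shift`
to every pool's chemical shift, so a +0.1 ppm shift moves the spectrum
minimum to +0.1 ppm.

## Acquisition schedules

Each MRF protocol has 31 entries: an unsaturated M0 reference (TR 15 s,
TE 20 ms) followed by 30 saturated continuous-wave entries with TE 20 ms
and a TR (3.6–3.8 s) that keeps every protocol inside the 120–135 s
scan-time envelope of the acquisition this emulates. The exact per-entry
powers and offsets of that acquisition are not available, so `default_schedule()`
draws them reproducibly from target-appropriate ranges: the MT protocol
varies both offset (6–14 ppm, where no mobile metabolite is visible) and
power (0–6 µT) with 2.5 s saturation (the broad pool saturates slowly);
the rNOE protocol stays at −3.5 ppm with low powers (0.3–2 µT) and 2.5 s
saturation (slow exchange needs long low-power labeling); the amide
protocol at +3.5 ppm (0.3–4 µT, 1.5 s); the glutamate protocol at +3 ppm
with high powers (2–7 µT) and deliberately *short* 0.3 s saturation.
The short-saturation choice comes from a sensitivity analysis of the
forward model: for the fast-exchanging amine pool, whose steady-state
contribution is shadowed by direct water saturation and the semisolid
background (both of which also grow as \(\omega_1^2\)), the transient
regime after a long recovery carries three- to five-fold more
concentration contrast per entry than saturation to steady state.
Z-spectrum protocols sweep 7 → −7 ppm at fixed power (0.7/5.9/1.5 µT
presets); WASSR uses 0.3 µT, 3 s, ±1 ppm in 0.1 ppm steps.

## Dictionaries and the training distribution

A dictionary enumerates the Cartesian product of a parameter grid and
simulates one trajectory per combination (row order: first declared
parameter varies fastest; results are worker-count invariant). The
shipped grids bracket brain-like values at 7 T — water T1 1.2–2.4 s, T2
35–115 ms (deliberately excluding CSF; a wide-T2 variant is shipped
separately), \(f_{ss}\) 2–30 %, \(k_{ssw}\) 5–100 s\(^{-1}\), amide
\(f_s\) 0.05–0.95 %, \(k_{sw}\) 50–500 s\(^{-1}\), rNOE \(f_s\) 0.1–2 %,
\(k_{sw}\) 5–50 s\(^{-1}\), glutamate 2–30 mM with amine rate
4000–10000 s\(^{-1}\) (bracketing reported in vitro values around
7200–8300 s\(^{-1}\)). Glutamate is gridded in mM and converted to an
amine proton volume fraction via
\(f = 3c/111{,}000\) (three amine protons per molecule against the
110 M water-proton pool).

Grid sizes are a deliberate accuracy/runtime trade-off on a single CPU:
29,400 (MT), 46,080 (rNOE) and 84,672 (amide/glutamate) rows, with
resolution concentrated on the regressed parameters and on the semisolid
fraction (whose correction the joint network must interpolate); the
smaller dictionaries are oversampled during training with independent
noisy replicates, which is statistically equivalent to a larger noisy
dictionary over the same grid. Each stage's tissues contain only the
pools its protocol encodes — mobile pools parked many linewidths off
resonance contribute below \(10^{-3}\) of the signal (tested) and are
omitted, which keeps the generator matrices small. The one exception is
the aliphatic rNOE pool in the amide/glutamate stage: the glutamate
protocol's mirrored negative-offset entries sample its tail, so it is
kept (at its fixed base value) in that stage's tissue model. The
glutamate amine rate is gridded over the span of reported
physiological-condition measurements (5500–8500 s\(^{-1}\)) rather than
a wider hypothetical range: over-dispersing a near-degenerate parameter
(concentration and rate enter the amine saturation almost as a product)
inflates the estimator's shrinkage without adding realism.

## The sequential quantification pipeline

Because the semisolid pool affects the whole Z-spectrum, it is estimated
first: network 1 maps the L2-normalized MT trajectory (30 saturated
entries referenced to M0) plus water T1 and T2 (32 inputs) to
\(f_{ss}, k_{ssw}\). Those two estimates are shared downstream: network
2 (34 inputs) quantifies the rNOE pool, and network 3 (64 inputs: the
amide and glutamate trajectories plus the four scalars) jointly
quantifies amide and glutamate, accounting for their spectral proximity
(3.5 vs 3 ppm). All networks use 300-neuron ReLU hidden layers — two for
networks 1–2, four for the harder joint network — and sigmoid outputs
mapped to physical units by per-parameter min–max scaling over the
training grid (the bounded output is what the sigmoid implies; min–max
is our declared choice of affine map). Training uses Adam (learning rate
0.0002), minibatch 1024, MSE on scaled targets, fresh Gaussian noise
(1 % of M0) injected into the raw trajectories every epoch before
normalization, a 20 % validation split, and early stopping (patience 6
at the default experiment scale). Two standard conditioning devices make
the fixed learning rate workable on a CPU step budget: assembled inputs
are standardized per feature (the unit-norm trajectory entries carry
their information in \(\sim10^{-3}\)-scale variations around an
\(O(0.2)\) mean, which is numerically hostile raw), with center and
scale stored in the model; and each network gets a short clean warm-up —
a few epochs without noise injection — so the deterministic inverse map
(in particular the semisolid-background correction of the dilute-pool
outputs) is fitted with low-variance gradients before the noisy phase
instills robustness. Downstream networks are trained with the true upstream
parameters from the grid and receive the MT-stage *estimates* at
inference — exactly the error-propagation pathway the sequential design
trades for tractability.

Water T1/T2 are inputs, not outputs: they are taken from separately
provided maps, mirroring the acquisition this emulates. B0 is not a
network input (a shift hook exists in the tissue model); the emulated
acquisition's shimmed field made it unnecessary.

Design choices worth noting: models store the MD5 hash of their training
schedule and refuse inference on data from a different schedule;
training is bit-reproducible given the seed; divergent (non-finite)
loss aborts with a diagnostic.

## The digital phantom study

`make_digital_phantom()` synthesizes a 5×5 array of circular vials (64 ×
64 px, radius 4 px) varying amide volume fraction along one axis
(0.09–0.81 %) and glutamate concentration along the other (5–25 mM),
replicated over four semisolid MT backgrounds (6/12/18/24 %) — 100
parameter combinations. Non-varied parameters sit at the base tissue
values (water 1.8 s/55 ms; rNOE 1 %, 20 s\(^{-1}\); amide rate
200 s\(^{-1}\); amine rate 7000 s\(^{-1}\); \(k_{ssw}\) 40 s\(^{-1}\)).
Every pixel's four trajectories are simulated from its vial's tissue
model and perturbed with independent white Gaussian noise of standard
deviation 1 % of that pixel's M0 (the emulated study cites a reported
noise level without printing a number; 1 % is our declared default and is
recorded in every dataset). The truth values themselves are evenly
spaced choices within the in vivo dictionary ranges — the top amide
value 0.81 % and the 5/25 mM glutamate extremes are anchored by printed
values; the intermediate ticks are our evenly spaced choices.

What the phantom does *not* emulate: B0/B1 inhomogeneity fields (flat
field), partial-volume effects at vial edges, physiological motion, and
scanner-specific artifacts. Recovery statistics on this phantom
therefore demonstrate the pipeline's ability to invert its own forward
model under noise — the first-line validation — not robustness to
real-scanner confounds.

`run_fig2_experiment()` chains schedules → dictionaries → training →
phantom → quantification → statistics. At the default `"full"` scale it
completes in roughly 16 minutes on one CPU; `"reduced"` and
`"tiny"` presets thin the grids for testing. Recovery is summarized by
vial-mean statistics: Pearson r and ICC over all 100 vials for
\(f_{ss}\), and per-background (n = 25) minima for amide and glutamate.
The intraclass correlation is ICC(A,1) — two-way random effects,
absolute agreement, single measure — so additive bias lowers ICC but not
r; glutamate, the most dilute and noise-sensitive pool, shows this
first.

## Z-spectrum metrics

For comparison with conventional analysis the package implements, per
pixel or ROI: WASSR B0 mapping (cubic-spline interpolation to 0.001 ppm,
minimum location; boundary minima flagged), spline B0 correction and
smoothing, MTR \(=1-Z\), MTR asymmetry, \(\Delta ST = Z(7) - Z(\pm3.5)\),
GluCEST (%), AACID, and the Lorentzian-difference metrics: a bounded
five-pool Lorentzian decomposition (water, MT, amide, rNOE, amine at
0/−2.3/3.5/−3.5/3 ppm, fixed start values, Levenberg–Marquardt) yields
\(Z_{lab}\) (full fit) and \(Z_{ref}\) (fit minus the target pool), from
which \(MTR_{Rex} = 1/Z_{lab} - 1/Z_{ref}\) and
\(AREX = MTR_{Rex}/T_1\). The pool count, bounds and start values are
declared defaults (the source analyses do not state them); the default
processing order is WASSR → correction → smoothing → metrics.

## Numerical choices

- Propagation: exact matrix-exponential solution per piecewise-constant
  block; equilibrium state as initial condition; recovery propagators
  cached per duration.
- Super-Lorentzian integral: 256-point midpoint rule; singular gap
  bridged by quadratic interpolation (anchors 1/1.5/2 ppm), clamped
  non-negative.
- Interpolation of Z to arbitrary offsets: cubic splines, consistent with
  the spline smoothing convention.
- Degenerate inputs: zero-norm trajectories, constant correlation inputs,
  zero-variance paired differences, boundary WASSR minima and
  non-converged Lorentzian fits are flagged or rejected explicitly rather
  than returning silent NaNs.
- Seeds: every stochastic stage (schedule draws, noise injection,
  training shuffles/initialization) takes an explicit seed and restores
  the caller's RNG state.

## Known limitations

- The emulated acquisition's exact per-entry schedule parameters and
  production dictionary grids are unavailable; the shipped defaults are declared,
  configurable stand-ins, so absolute trajectory values are not
  comparable to scanner data acquired with the original schedules.
- The semisolid pool's chemical shift and lineshape are configurable
  defaults (0 ppm, super-Lorentzian); the source does not state them.
- Pulse shapes are continuous-wave blocks; shaped/adiabatic pulses and
  readout-train effects are out of scope.
- The quantification networks interpolate within their training grid;
  parameters outside the grid ranges are clipped by the sigmoid scaling
  (by design) and CSF-like T2 values require the wide-T2 grid.
- Glutamate recovery does not reach the accuracy of the semisolid and
  amide stages. Under the pixelwise unit-L2 normalization, the
  common-mode attenuation that carries most of the dilute amine signal is
  discarded, and the surviving trajectory shape is progressively masked
  by the semisolid response: on a *noiseless* phantom, the per-background
  regression slope of estimated versus true concentration falls from
  about 0.39 at a 6 % semisolid fraction to about 0.06 at 24 %, with the
  estimate regressing toward the grid mean. Longer training does not
  change this (a 150-epoch run with disabled early stopping performed no
  better than the default), so it is an identifiability ceiling of the
  normalized 30-entry trajectory with the shipped stand-in schedules, not
  an optimization artifact. Vial-mean glutamate statistics at the
  heaviest MT background should therefore be interpreted with caution.
- In vivo findings (animal cohorts, histology, MRS) are outside the
  package's scope; only the simulation-based validation is reproduced.
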