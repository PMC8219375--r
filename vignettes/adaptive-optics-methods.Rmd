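---
title: "Adaptive-optics set-up and correction on a simulated bench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive-optics set-up and correction on a simulated bench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aokit)
```

`aokit` implements the complete set-up and correction stack for adaptive
optics (AO) in microscopy — calibration of a deformable element to a
Zernike control matrix, characterisation of mode-recreation accuracy,
closed-loop wavefront flattening, sensorless correction and IsoSense
pattern generation — together with a simulated bench that stands in for
all hardware. This vignette explains the models behind each stage, the
parameters that matter, and the numerical and design choices made where
the problem left them open.

## The wavefront model

All wavefronts live on a circular pupil, sampled on a square grid with
pixel centres at `(grid_size - 1) / 2 ± k` and pupil radius
`(grid_size - 1) / 2` pixels. Phases are in radians. Zernike modes use
Noll indexing and Noll normalisation: a unit coefficient contributes unit
RMS phase over the pupil. The paperless alternative (peak-to-valley
normalisation) would make RMS bookkeeping awkward; with Noll
normalisation the RMS of a mode vector is simply the Euclidean norm of
its non-piston amplitudes, and `rms_error()` is directly interpretable.

`decompose()` fits modes by masked linear least squares rather than by
inner products. On a full disc the two coincide (the sampled basis is
orthogonal to ~1e-2 at grid 256), but least squares remains well-posed
when the pupil is partially clipped, e.g. after edge erosion in
interferometric reconstruction. Piston is always computed but excluded
from every correction — it has no optical effect.

"Central 95%" RMS follows the area convention: the sub-disc holding 95%
of the pupil *area*, i.e. radius `sqrt(0.95)` of the pupil radius. The
fraction is an explicit argument (`central_fraction`) so a radius
convention is one keystroke away.

## The simulated bench

### Deformable mirror

Two influence-function models:

* `linear_zernike` — each actuator drives a fixed, known mixture of
  Zernike modes; the exact modes-per-signal matrix is stored as
  `ground_truth_B`. This bench is *exactly* linear in the calibrated
  basis, so calibration, characterisation and flattening have analytic
  answers (recovery to 1e-8, identity assay, one-step convergence) and
  the correction machinery can be tested to machine precision.
* `gaussian_bumps` — each actuator deflects the surface by a Gaussian of
  width `influence_sigma`, emulating a continuous membrane whose shape at
  one point is coupled to its neighbours. This bench has truncation
  error, print-through ripple and saturation: the realistic case.

Defaults and why:

* `influence_sigma = 0.7 ×` actuator pitch, giving ~40% deflection at the
  neighbouring actuator. Commercial membrane mirrors quote inter-actuator
  coupling of roughly 30–45%; much wider coupling (e.g. 1.5 × pitch, ~80%)
  makes the mirror so smooth that mid-order Zernike modes become
  unreachable within any realistic stroke and closed-loop correction
  saturates and diverges.
* `alpao69_like` layout: a 9×9 lattice with three points removed per
  corner (69 actuators), pitch 0.28 pupil radii. The footprint slightly
  overfills the pupil — outermost centres sit at ~1.25 pupil radii — as
  on a real bench, where the beam underfills the mirror so that the pupil
  rim stays controllable. Squeezing all actuators inside the pupil leaves
  an uncorrectable edge ring and stalls flattening about 1 rad higher.
  The true Alpao geometry is proprietary; this layout is a stand-in with
  the right actuator count and symmetry.
* `stroke_scale = 40` rad of wavefront per unit control signal (~3.5 µm
  of mechanical stroke at 543 nm), with `stroke_limit = 1` and hard
  clamping plus a saturation flag. Membrane mirrors reach tens of
  microns; 40 rad lets the bench cancel several-radian aberrations
  without routine clamping while still allowing saturation to be studied.

### Wavefront sensors

* `direct_phase` — returns the phase itself (plus optional Gaussian
  noise). The noise-free limit isolates the correction mathematics from
  sensing physics.
* `interferogram` — `I = 0.5 + 0.5 cos(2π f x + φ)` inside the pupil,
  with an integer number `f` of carrier fringes across the grid so the
  carrier falls on an exact FFT bin (16 by default — enough to separate
  the sideband from DC at grid 256).
* `shack_hartmann` — the pupil is tiled by `lenslet_count²` cells (a cell
  is active when ≥ half its pixels are inside the pupil); each active
  cell renders a Gaussian spot displaced by `focal_scale` × the mean
  phase gradient over the cell.

Noise defaults to zero everywhere; tests that need noise switch it on
explicitly and pass a seed, so every stochastic path is reproducible.

### Image formation

`image_object()` computes the incoherent PSF as the squared modulus of
the Fourier transform of the pupil function `mask · exp(iφ)`, normalised
to unit sum, and convolves the object with it circularly. Exposure is
fixed by the *diffraction-limited* image: `photon_scale` counts at its
brightest pixel. Anchoring the scale to the flat-pupil image (rather than
each aberrated image) keeps total flux constant across aberrations, which
is what the `max_intensity` metric relies on.

## Calibration

Each actuator is stepped through p positions (default 5, evenly spaced
over ±0.8 of the stroke — the margin keeps the calibration clear of the
clamp), the wavefront is sensed and decomposed into M modes, and each
mode's amplitude is regressed against the control signal. The regression
includes an intercept: the rest wavefront need not be flat, and a static
system aberration then lands in the intercept rather than biasing the
slope. Only the slope enters B.

The control matrix is the SVD pseudo-inverse of B after two thresholds:

* `entry_threshold` (default 0.005, relative to the largest |entry|)
  zeroes entries of B that are mere noise. Its purpose is visible when a
  mode's entire row is noise — a mode the element cannot drive at all.
  Unthresholded inversion turns such rows into actuator demands of order
  1/noise; thresholding removes the mode from control entirely.
* `sv_cutoff` (default 0.01, relative to the largest singular value)
  discards near-null directions of the thresholded matrix. Singular
  values below machine precision are always dropped, regardless of the
  cutoff — the Moore–Penrose convention.

Both defaults are deliberately mild; they are configuration, not physics,
and experienced users are expected to tune them per device.

`set_phase()` is *absolute*: each call converts the requested mode vector
through the active control matrix and replaces the previous signals. Any
accumulation across iterations is done explicitly by the flattening loop,
which keeps loop semantics visible in one place. The device contract is
minimal — `n_actuators`, `send()`, `set_phase()`, `set_control_matrix()` —
so an externally calibrated matrix can be adopted directly.

## Characterisation and mode selection

`characterise()` applies each mode at a fixed amplitude (default 1 rad),
measures the wavefront, and stores the decomposed amplitudes normalised
by the applied amplitude: row = applied, column = measured. On the
`linear_zernike` bench with an exact control matrix the assay is the
identity to 1e-6; on the Gaussian bench the diagonal sags and
off-diagonal coupling appears, exactly the structure used to decide which
modes are safe to correct. `select_modes()` defaults — diagonal within
(0.75, 1.25), coupling ≤ 0.25 — are round numbers chosen as a starting
point, not calibrated constants.

## Closed-loop flattening

Each iteration: sense, decompose, record the RMS; if `stop_mode =
"either"` and the RMS is below δ, stop; otherwise add `-gain` × the
measured amplitudes of the selected modes to the running correction and
apply it. A final measurement after the last applied correction is
reported as `final_rms`. With this ordering the loop exits on the
*measured* residual, so a run that converges in one step still takes a
second iteration to observe it — matching how a hardware loop actually
behaves. `iterations_only` runs exactly N iterations regardless, the
photobleaching-conscious mode for sample correction.

The gain (default 1, i.e. plain opposite-amplitude correction) is a
robustness handle for miscalibrated systems; at 1 it reproduces the
textbook loop. On the noiseless linear bench with exact C the RMS is
non-increasing and reflattening from a converged state is a no-op.

At the package's reference scale (grid 128, 69 actuators, M = 69, p = 5)
a full calibrate–characterise–flatten pipeline runs in a few seconds; the
test suite and the acceptance script use that scale throughout.

## Sensorless correction

For each mode a set of probe amplitudes (default 7 points over ±1.5 rad)
is applied, an image acquired and scored, and `S(a) = offset + height ·
exp(-(a - centre)²/2w²)` fitted by Levenberg–Marquardt. The offset term
is there because real metrics decay to a sample-dependent floor, not to
zero. If the fit fails, the height is non-positive, or the centre lands
outside the scanned range, the best *sampled* amplitude is used instead
(`fit_ok = FALSE`) — a conservative fallback that can never extrapolate.

Three workflows differ only in orchestration: score each image as it
arrives and correct after each mode (`sequential_immediate`); acquire all
of a mode's images first (`sequential_deferred`); or acquire everything
with no intermediate correction and apply the summed correction once
(`simultaneous`). On a noiseless bench the two sequential workflows are
bit-identical. Image acquisition is delegated to a caller-supplied
`image_fn` receiving the absolute mode offset (accumulated correction +
probe): hardware orchestration stays outside the routine, and the
correction "application" in the sequential workflows is folded into the
subsequent probes, so `image_fn` runs exactly N × M times in every
workflow.

The four built-in metrics (spectral power in a mid-frequency annulus,
contrast, sharpness, peak intensity) span the frequency-, contrast- and
intensity-based families; they are registry entries like any
user-supplied metric, not privileged code paths.

## IsoSense patterns

Nine beams: the origin, four axial beams at (±γw, 0), (0, ±γw), and four
diagonal beams. The diagonal coordinate is ambiguous between γw/2 and
γw/√2; the default (`diagonal_convention = "radius"`) uses γw/√2, placing
every off-centre beam on a single ring of radius γw for isotropic
spectral fill, and the alternative is selectable. Beams are snapped to
the nearest discrete frequency bin (the snap distance is reported as an
attribute) rather than interpolated — the target device is a discrete
SLM. The emitted pattern is the squared modulus of the inverse transform,
normalised to [0, 1]: a real, non-negative intensity pattern.

## Numerical choices in the sensing suite

* **Fringe demodulation**: the DC term is suppressed by subtracting the
  mean pupil intensity, the positive sideband is located by peak search
  near the nominal carrier, windowed with a Gaussian (σ = 0.75 × carrier
  distance), shifted to the origin and inverse-transformed; the argument
  gives the wrapped phase. The window trades conjugate-sideband leakage
  against spatial smoothing; at the default the conjugate is attenuated
  below 3%.
* **Edge handling**: the hard pupil cutoff biases the demodulated phase
  in a rim of roughly `grid / (2π σ_window)` pixels. The registry method
  therefore erodes that rim, refits Zernike modes (36 by default) on the
  interior, and resynthesizes the full-pupil map. Piston and tip/tilt are
  zeroed afterwards — they are arbitrary under carrier demodulation, and
  documenting this spares users comparing against Shack–Hartmann output.
* **Carrier choice is physics, not preference**: demodulation fails once
  the local fringe frequency `f + ∂φ/∂x / 2π` goes negative, i.e. once
  the phase slope exceeds the carrier. A 16-fringe carrier at grid 256
  handles ~1 rad RMS in modes 2–20; 2–3 rad RMS needs 32–48 fringes. The
  round-trip tests scale the carrier with aberration strength for this
  reason.
* **Phase unwrapping** proceeds along the centre row, then down each
  column anchored on its centre-row pixel; for a centred disc every
  masked column crosses the centre row, so the result is continuous and
  differs from the input by exact multiples of 2π. This is adequate for
  the smooth phases a deformable mirror produces; it is not a
  residue-aware unwrapper and will fail on speckled or shot-noise-limited
  wrapped maps.
* **Shack–Hartmann centroids** use a cell-bounded first pass and then an
  iterated Gaussian-weighted window that tracks the estimate
  continuously. A hard, integer-placed window biases centroids of spots
  displaced toward a cell edge by several percent; the weighted iteration
  has the true centre as a fixed point and suppresses neighbouring spots
  smoothly. Reconstruction is modal: per-lenslet mean gradients of the
  Zernike basis are assembled into a least-squares system for the
  amplitudes. Lenslets below 5% of the brightest cell's flux are excluded;
  more than half excluded is an error.

## What the bench does and does not show

The generator reproduces the *structure* of a real AO set-up — coupled
influence functions, stroke limits and saturation, carrier-fringe and
spot-image sensing, photon-limited image formation — with exactly known
ground truth, so tests can assert recovery to tight tolerances. It does
not model hysteresis, temporal dynamics, membrane mechanics beyond the
Gaussian-coupling approximation, real Alpao geometry, non-common-path
error between sensor and camera, or detector artefacts. Passing tests
demonstrate that the correction mathematics and workflows are right; they
do not certify performance on any particular physical device, where those
unmodelled effects dominate the error budget.

## Known limitations

* The Zernike basis is evaluated by the explicit radial-polynomial sum,
  which loses accuracy beyond roughly Noll index 150; the intended range
  (≤ ~100 modes) is safe.
* The unwrapping algorithm assumes a centred-disc mask.
* `alpao69_like` is the only built-in non-square layout; arbitrary
  geometries can be had by overriding `actuator_centres` before use.
* The sensorless routines assume a metric with a single interior maximum
  per mode within the scanned range; multimodal metrics need a
  user-registered replacement for the Gaussian fit.
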