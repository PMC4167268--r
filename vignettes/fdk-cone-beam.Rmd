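---
title: "FDK cone-beam reconstruction: model, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FDK cone-beam reconstruction: model, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdkrecon)
```

## The reconstruction problem

Circular-orbit cone-beam CT measures line integrals of an attenuation
field f(x, y, z): a point source at distance `dso` from the rotation axis
and a flat detector at distance `dsd` from the source rotate rigidly
about z, recording K projections at uniformly spaced angles.  FDK
reconstructs f approximately by filtered backprojection of each 2D
projection along its own cone of rays.  It is exact in the orbit plane
(where it reduces to fan-beam filtered backprojection) and degrades
gracefully with cone angle; that approximation error, not implementation
error, is the dominant artifact away from the central slice.

The pipeline implemented here is

1. cosine pre-weight each projection: `P'(u,v) = P(u,v) · dsd / sqrt(dsd² + u² + v²)`;
2. ramp-filter every detector row of `P'` (FFT, zero-padded);
3. accumulate, for every voxel and every view,
   `Δθ/2 · (dsd/dso) · W₂ · Q(u, v)` with `W₂ = dso²/(dso − s)²` and
   bilinear interpolation of the filtered view Q at the voxel's projected
   detector coordinates.

## Coordinate convention (fixes image orientation)

All components share one convention, and it is worth stating loudly
because it decides left/right in every image:

* world origin = orbit center; rotation axis = z;
* at view angle θ the source is at **`dso · (−sin θ, cos θ, 0)`** (on the
  +y axis at θ = 0), looking through the origin along
  `(sin θ, −cos θ, 0)`;
* the detector u axis is `(cos θ, sin θ, 0)`, the v axis is +z, and
  (u, v) are physical lengths measured from the central ray;
* a voxel maps to `u = dsd·t/(dso − s)`, `v = dsd·z/(dso − s)` with
  `s = −x sin θ + y cos θ` (depth toward the source) and
  `t = x cos θ + y sin θ`;
* pixel-center alignment: fractional index = `(coord − offset)/pitch +
  (N − 1)/2`, so detector arrays are indexed `[v-row, u-column]`.

A consequence worth knowing: because the u axis co-rotates, the opposing
view of a point-symmetric object satisfies `P_{θ+π}(u, −v) = P_θ(u, v)`
(a v-flip, not a u-flip).  For divergent beams there is *no* exact
flip identity between opposing views of a general object — opposing rays
through mirrored detector positions are different lines — which is why the
test suite checks the point-reflection identity instead.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `dso`, `dsd` | length | 100, 150 (demo) | magnification 1.5, moderate divergence |
| `det_spacing_u/v` | length/px | 2.0 / 1.75 (demo) | keeps the demo phantom inside the field of view at all angles |
| `window` | – | `ramp` | no apodization: sharpest response; Hann/Hamming/Shepp–Logan available for noisy data |
| `cutoff` | ×Nyquist | 1.0 | full bandwidth |
| `pad_length` | samples | next power of two ≥ 2·det_cols | linear (not circular) convolution |
| `interp` | – | `bilinear` | the de-facto FDK standard; `nearest` kept for oracle cross-checks |
| `precision` | – | `double` | `single` emulates a float32 pipeline |

The demo configuration (64 × 60 px detector, 72 views, 64 × 60 × 50 voxel
grid at unit pitch) is the package's canonical small experiment; distances
and pitches are this package's own choice, selected so the bundled head
phantom projects entirely onto the detector at every angle.

## Normalization: why `Δθ/2 · dsd/dso`

The ramp response is sampled in physical detector frequencies,
`H(f_k) = |f_k|`, `f_k = k/(pad · Δu)` (units 1/length), so
`Q = real(IFFT(FFT(P'_padded) · H))` approximates the continuous
ramp-filtered projection with no stray factors of Δu.  Classical FDK is
stated on a *virtual* detector through the origin; rescaling its
coordinates to the physical detector (u = p·dsd/dso) turns the filtered
projection into `(dso/dsd)·Q_physical`, leaving the per-view weight
`Δθ/2 · (dsd/dso)` used here.  The constant is pinned empirically by the
density-recovery test: a uniform sphere of density 1 with radius 25% of
the field of view reconstructs to 0.990 at the center voxel (1.0% error)
with background below 0.033 — well inside the 5% / 0.05 tolerances the
package promises.

## Numerical choices

* **H(0) = 0 exactly.**  The frequency-sampled ramp has zero DC gain, so
  the kernel is exactly zero-mean.  The alternative construction (FFT of
  truncated spatial taps) has a small positive DC term; frequency
  sampling was chosen for its exact DC null, accepting a spectral-aliasing
  error of order `2n²/pad²` in the spatial taps (the
  Ramachandran–Lakshminarayanan closed form `h(0) = 1/(4Δu²)`,
  `h(odd n) = −1/(π²n²Δu²)`, `h(even n) = 0` is matched to better than
  1e-6 relative at lags ≤ 8 once pad ≥ 32768; even lags are exact).
* **Zero-padding** to ≥ 2 detector widths makes the row convolution
  linear; note that ramp-filtering a finite constant row still produces a
  rect edge response — zero DC gain annihilates only signals constant over
  the whole FFT period.
* **Out-of-detector voxels** contribute zero (no clamping); the per-view
  out-of-bounds fraction is recorded as an attribute.  Voxels at or
  behind the source are flagged and skipped.
* **Accumulation order** is fixed (ascending view index), so runs are
  bit-reproducible.
* **Single precision** is emulated by rounding to the nearest float32
  after loading, after filtering, and after every accumulated view
  (R has no native float type).  On the demo experiment the single- and
  double-precision volumes differ by ~3×10⁻⁷ max-abs, far inside the
  2.2×10⁻³ envelope expected of float pipelines on this problem.
* **Degenerate inputs**: empty stacks and NaN views are rejected with the
  offending view named; arcs short of 360° reconstruct but warn loudly
  that no short-scan (Parker) redundancy weighting is applied.

## What the synthetic generator does and does not emulate

The generator produces *exact* line integrals through additive ellipsoids
(closed-form ray/ellipsoid chords, one ray per pixel center), optional
i.i.d. Gaussian noise, and supersampled ground-truth voxelizations.  The
default object is a ten-ellipsoid 3D Shepp–Logan-style head (densities in
[0, 1] net), a stand-in fixture in the classic tradition — the package
makes no claim that it matches any particular scanner phantom.

Not emulated: polychromatic beam hardening, scatter, Poisson photon
statistics, detector blur and footprint integration, gantry wobble.
Passing tests therefore demonstrate geometric and numerical correctness
of the reconstruction chain, not robustness to physical effects in real
scans.

## Problem sizes used by the tests

Oracle-equivalence checks run on ≤ 16³ instances against literal scalar
reference loops; density recovery uses a 48³ grid with 90 views of a
64 × 64 detector; the end-to-end demo is the 64 × 60 × 50 / 72-view
experiment.  These sizes were chosen so the whole suite exercises every
path in seconds while keeping discretization fine enough for the stated
tolerances to be meaningful.

## Known limitations

* Circular orbits and flat detectors only; no helical scans, tilted or
  cylindrical detectors, or projection-matrix calibration input.
* No short-scan weighting: arcs < 360° give biased values (by design,
  with a warning).
* FDK's intrinsic cone-angle approximation: values away from the central
  plane are approximate even with perfect data.
* Voxels projecting off the detector simply receive fewer view
  contributions; truncated-projection (interior) correction is out of
  scope.
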