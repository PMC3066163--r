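---
title: "Forward 3D traction force microscopy with tfm3d: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forward 3D traction force microscopy with tfm3d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfm3d)
```

## The measurement problem

Adherent cells pull on their substrate. When the substrate is a compliant
polyacrylamide gel seeded with fluorescent microspheres (0.5 µm diameter,
nominally 0.3% by volume), a confocal microscope records the bead pattern as a
volumetric image stack before and during cell activity. The displacement of
the bead pattern between two stacks encodes the deformation the cell imposes;
with the gel's elastic constants known, deformation converts to stress, and
stress evaluated on a plane gives the traction vector field the cell exerts.
This "forward" route — image correlation, then differentiation, then a
constitutive law, then the Cauchy relation — avoids the ill-posed inverse
problem that classical 2D traction microscopy solves, at the cost of needing
accurate full-field 3D displacements.

`tfm3d` implements that forward chain, together with a synthetic scene
generator that stands in for the microscope so that every stage can be tested
against analytic ground truth.

## Displacement measurement: digital volume correlation

The reference and deformed stacks are divided into cubic subsets (default
$64^3$ voxels). For a subset pair $f$ (reference) and $g$ (deformed) the
circular cross-correlation

$$m(\mathbf{s}) = \sum_{\mathbf{x}} f(\mathbf{x})\, g(\mathbf{x} + \mathbf{s})$$

is evaluated through the FFT; the displacement of the subset is the lag that
maximizes $m$. Both subsets are mean-subtracted before transforming, which
suppresses the zero-lag pedestal that a constant intensity offset would
otherwise contribute. The two real transforms are obtained from a single
complex FFT of $f + i g$, and a compiled backend performs the transform and
extracts the relevant lag window; the R-level function
`cross_correlate_subsets()` computes the identical quantity and is itself
validated against a brute-force spatial-domain sum in the test suite.

The integer peak is refined to sub-voxel precision by least-squares fitting a
full 3D quadratic polynomial (10 coefficients) over the $3^3$ neighborhood of
the peak and returning the fitted stationary point. If the fitted Hessian is
not negative definite, or the refinement exceeds one voxel, the integer peak
is kept and the point is flagged; exact ties resolve to the lexicographically
smallest lag and are flagged too. Peak quality is tracked as the ratio of the
primary correlation peak to the strongest peak outside a 3-voxel exclusion
zone.

Parameters that matter:

* `subset_size` (voxels, default 64) — larger subsets average over more
  particles (hundreds at the default bead density) and are more robust, but
  low-pass the displacement field.
* `grid_spacing` (µm, default 2) — converted to an integer voxel stride per
  axis (rounded, minimum 1). Grid points whose subset would overhang the
  volume are simply not evaluated rather than padded.
* `max_lag` (default `subset_size/4`) — the peak search bound; with circular
  (un-padded) correlation this keeps wrap-around bias negligible. Zero
  padding is available (`pad = TRUE`) for cases where wrap-around matters
  more than speed.
* `fit_radius` (default 1, i.e. $3^3$) — the quadratic fit neighborhood,
  matched in scale to the strain stencil.

The displacement sign convention is reference → deformed: a feature that
moves toward larger coordinates has positive displacement, fixed by the
circular-shift oracle in the tests.

## From displacements to strain

Displacements are differentiated by a pointwise least-squares fit: around
each grid point the field is modeled as $u_i(\mathbf{x}) \approx c_i +
G_{ij}(x_j - x^0_j)$ and the twelve constants are fitted over the $3^3$
stencil of neighboring grid points in physical (micrometer) coordinates, so
anisotropic grids are handled transparently. On a full interior stencil the
fitted slope averages nine point-pairs per axis instead of the single pair a
central difference uses, cutting the noise variance of the gradient by a
factor of nine; the test suite demonstrates the advantage by Monte Carlo.
Boundary points fall back to the clipped, one-sided neighborhood when it
still has full rank (four independent positions); otherwise they are masked.

The small-strain tensor is the symmetric part, $\varepsilon = (G + G^T)/2$,
appropriate because measured gel strains stay within the linear range of the
material (components below 5%, which the package flags per point).

## Constitutive law and tractions

The polyacrylamide substrate is modeled as linearly elastic, isotropic and
incompressible: Young's modulus $E$ from unconfined compression (the
reference value used throughout is 9.64 kPa), Poisson's ratio $\nu = 0.5$,
shear modulus $\mu = E / (2(1+\nu))$. The stress is the deviatoric form

$$\sigma = 2\mu\,\varepsilon.$$

For a truly incompressible solid the hydrostatic pressure is statically
indeterminate from strain alone; it is set to zero, and $|\mathrm{tr}\,
\varepsilon|$ is carried along per point as a diagnostic (on incompressible
ground truth it stays at the strain noise floor). For $\nu < 0.5$ the
compressible Lamé form $\sigma = 2\mu\varepsilon + \lambda\,
\mathrm{tr}(\varepsilon) I$ is available, which makes the pressure ambiguity
itself testable. Tractions follow from the Cauchy relation $\mathbf{T} =
\sigma\,\mathbf{n}$ on any lattice plane; for the free surface $\mathbf{n} =
(0,0,1)$, $T_1, T_2$ are the in-plane shear tractions and $T_3$ the normal
traction, in Pa ($\equiv$ pN/µm²).

Poisson's ratio itself is calibrated by inverting the confined-compression
relation $M = E(1-\nu) / ((1+\nu)(1-2\nu))$ by bracketed root finding; the
map is strictly increasing on $[0, 0.5)$ so the inverse is unique, and the
divergence of $M$ as $\nu \to 0.5$ reproduces the experimental observation
that a laterally confined incompressible gel cannot be compressed further.

## The synthetic scene generator

The generator emulates what the pipeline consumes, not the microscope optics:

* bead centres uniformly random in a box at a chosen volume fraction
  (default 0.3%, radius 0.25 µm), reproducible from one integer seed;
* smooth analytic deformation maps (translation, affine, simple shear,
  Gaussian indentation, composites) supplying $u(\mathbf{x})$ and $\nabla u$
  in closed form;
* rendering as separable Gaussian spots with per-axis variance
  $r^2 + \sigma_{PSF}^2$ — the bead's Gaussian footprint convolved with a
  Gaussian PSF approximation, deposited directly at the sub-voxel bead
  position (mathematically identical to depositing and then blurring, without
  a volume-wide convolution);
* additive Gaussian noise at 5% of the peak single-bead intensity by default
  (Poisson shot noise available), then clamping to $[0,1]$ and quantization
  to 16-bit levels.

Defaults the data do not pin down, chosen once: voxel pitch (0.35, 0.35,
0.35) µm/voxel (in-plane pitch of a 512-pixel scan over a 150–200 µm field;
axial pitch taken equal for simplicity, with anisotropy supported
throughout); PSF sigmas (0.2, 0.2, 0.6) µm, the usual confocal elongation
along the optical axis; the 5% noise level. One internal tension in the
source material is worth recording: a 0.3% volume fraction of 0.25 µm beads
implies ~500 beads in a $64^3$ subset at 0.35 µm/voxel, while the
40–80-beads-per-subset figure implies a voxel pitch near 0.17 µm. The test
suite asserts the 40–80 count at the pitch where the two figures cohere; the
generator keeps 0.3% and 0.35 µm as independent defaults.

What the generator deliberately does not model: diffraction-limited (Airy)
optics, photobleaching, stage drift, refractive-index mismatch along depth,
or the cell itself. Passing tests on synthetic scenes therefore demonstrate
the correctness of the numerics under the stated imaging model, not
robustness to every artifact of a real microscope.

Periodic domains are a fixture device: rendering with wrap-around makes an
integer-voxel translation exactly a circular shift, which is the regime where
circular FFT correlation is exact. Tests that assert machine-precision
recovery use subsets that span the periodic cell; realistic (clipped,
windowed) scenes are held to the looser sub-voxel tolerances below.

## Numerical behavior and known limitations

* **Sub-voxel interpolation bias (peak locking).** Quadratic interpolation
  of a sampled, approximately Gaussian correlation peak carries a systematic
  S-shaped bias as a function of the fractional part of the true shift, with
  amplitude about ±0.06 voxel at the default spot size — reproducible across
  bead realizations, i.e. a property of the estimator, not noise. Rigid
  translations on windowed subsets are still recovered within 0.1 voxel RMS,
  but *gradients* of slowly varying fields sample the local slope of that
  S-curve, so strain components can be systematically off by up to ~10–15%
  when the displacement range spans only a fraction of a voxel. This is why
  the end-to-end simple-shear check is held to 10% rather than 1%, and why
  it is run on a fixed, stated scene; it is the dominant accuracy limit of
  single-pass DVC with quadratic peak refinement.
* **Window mismatch.** A subset sees content slide in from outside its
  window; for displacements up to `max_lag` this contributes edge bias of
  order (shift / subset size), which the default `max_lag = subset/4`
  keeps acceptable.
* **Degenerate inputs.** Constant-intensity subsets are flagged and masked,
  not fitted. Identical input volumes in the zero-load analysis are detected
  and flagged as measuring round-off, not noise.
* **Boundary stencils.** One-sided gradient stencils are unbiased only for
  fields that are linear across the stencil; near strong curvature the
  masked-interior values are the trustworthy ones.
* **Quadrature.** Control-volume balance integrates face tractions with a
  tensor-product trapezoid rule over lattice nodes (equivalent to a midpoint
  rule on bilinearly interpolated cell centres); it is exact for uniform and
  linearly varying stress, which is what the equilibrium tests exploit. The
  moment reference is the box centroid — immaterial when the net force
  vanishes.

## Sensitivity analysis and problem sizes

The zero-load experiment renders one undeformed bead field twice with
independent noise, runs the full pipeline on the pair, and summarizes every
resulting magnitude as noise. `scripts/acceptance.R` performs this at
256×256×128 voxels (≈16,000 beads, ≈12,000 subsets) and checks the
displacement / strain / traction noise floors against the published bounds
(0.12 µm, 0.5%, 80 Pa at E = 9.64 kPa); the test suite runs the same
analysis at 128×128×96 voxels, where the statistics are already stable, to
keep the default test run fast. RMS is the primary statistic, with the 95th
percentile reported alongside.

## Interfaces

All field results are tibbles (`x, y, z` in µm plus components), so they
compose with dplyr/tidyr directly; `tidy()`, `glance()` and `autoplot()`
methods cover the common reshaping and display needs. Volumes travel as
multi-page TIFF with a JSON sidecar holding the voxel size (the R `tiff`
package exposes no writable z-spacing tag), fields as CSV or legacy-ASCII
VTK structured points. A thin command-line wrapper (`inst/tfm3d`) exposes
the simulate / dvc / strain / traction / noise-floor / balance / calibrate /
run stages for shell use; `run_pipeline()` is the same orchestration in R,
emitting per-stage outputs and a JSON manifest so identical configurations
reproduce byte-identical results.
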