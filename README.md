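# tfm3d — forward three-dimensional traction force microscopy

`tfm3d` quantifies the forces adherent cells exert on compliant hydrogel
substrates, in all three dimensions. It is written for mechanobiology groups
who image fluorescent tracker beads in polyacrylamide gels with a confocal
microscope and want full-field 3D displacements, strains, stresses and
traction vectors out of those volume stacks — plus a synthetic-scene
generator so that every stage of the analysis can be validated against
analytic ground truth without any microscope data.

## The method

Given a reference volume `f` and a deformed volume `g` (multi-page TIFF
z-stacks of the bead pattern), the pipeline is forward — no inverse problem
is solved:

1. **Digital volume correlation (DVC).** For cubic subsets (default 64³
   voxels) on a regular grid (default 2 µm spacing), the circular
   cross-correlation

   m(**s**) = Σₓ f(**x**) g(**x** + **s**)

   is computed by FFT (mean-subtracted, compiled backend), and its peak is
   localized to sub-voxel precision by a least-squares 3D quadratic fit over
   the 3×3×3 neighborhood. The peak lag is the local displacement
   **u** = (u₁, u₂, u₃), with |**u**| = √(u₁² + u₂² + u₃²).

2. **Displacement gradients by pointwise least squares.** Around each grid
   point, u(**x**) ≈ **c** + G·(**x** − **x₀**) is fitted over a 3×3×3
   stencil of grid points, which is markedly less noise-sensitive than
   direct finite differences. The small-strain tensor is ε = (G + Gᵀ)/2.

3. **Constitutive law.** The gel is linearly elastic, isotropic and
   incompressible: σ = 2µε with µ = E/(2(1+ν)) and ν = 0.5. E comes from
   unconfined compression records (`young_modulus_unconfined()`; the
   reference value is 9.64 kPa) and ν from the confined compression modulus
   via M = E(1−ν)/((1+ν)(1−2ν)) (`poisson_from_confined_modulus()`).

4. **Cauchy tractions.** **T** = σ·**n** on any lattice plane; with the
   surface normal **n** = (0,0,1), T₁/T₂ are in-plane and T₃ is the normal
   traction, in Pa (≡ pN/µm²).

Quality control comes from two directions: zero-load sensitivity analysis
(`noise_floor()`: the whole pipeline run on two acquisitions of an
undeformed sample, so everything it reports is measurement noise) and
control-volume statics (`force_moment_balance()`: net force and moment from
integrating tractions over the faces of any sub-box, which must vanish in
equilibrium).

All field results are tibbles (`x, y, z` in µm + components) with
`tidy()` / `glance()` / `autoplot()` methods, so they drop straight into
dplyr/ggplot2 workflows. Fields export to CSV or legacy VTK; volumes to
multi-page TIFF with a JSON sidecar carrying the voxel size.

## Worked example: a sheared gel, end to end

Render a synthetic bead volume (0.3% volume fraction, 0.25 µm beads,
0.35 µm/voxel), apply a simple shear u₁ = γ·x₃ with γ = 0.01, and push the
pair through the full chain. For this deformation the closed-form surface
traction is T₁ = µγ = (9640/3)·0.01 ≈ 32.1 Pa.

```r
library(tfm3d)

voxel <- 0.35
dims  <- c(128, 128, 96)
beads <- generate_particle_field(domain = dims * voxel, volume_fraction = 0.003,
                                 radius = 0.25, seed = 11)
optics <- imaging_model(voxel_size = rep(voxel, 3), dims = dims,
                        noise = list(kind = "none"), bit_depth = 16)
gel <- material(E = 9640, nu = 0.5)

ref <- render_volume(beads, optics, seed = 1)
def <- render_volume(apply_deformation(beads,
                     deformation_map("simple_shear", gamma = 0.01)),
                     optics, seed = 1)

disp <- compute_displacement_field(ref, def,
                                   dvc_config(subset_size = 64, grid_spacing = 2))
glance(disp)
#> # A tibble: 1 × 6
#>   n_points n_valid masked_fraction rms_magnitude_um max_magnitude_um
#>      <int>   <int>           <dbl>            <dbl>            <dbl>
#> 1      726     726               0            0.159            0.221

surface <- disp |>
  estimate_displacement_gradient() |>
  strain_from_gradient() |>
  stress_from_strain(gel) |>
  surface_traction_map()
glance(surface)
#> # A tibble: 1 × 4
#>   n_points n_valid rms_magnitude_pa max_magnitude_pa
#>      <int>   <int>            <dbl>            <dbl>
#> 1      121     121             35.0             40.0

mean(surface$t1[surface$valid])
#> 34.9  # Pa, vs. 32.1 Pa closed form (+9%; see the methods vignette on
#>       # sub-voxel interpolation bias)

autoplot(surface)   # traction magnitude heat map with in-plane arrows
```

The displacement RMS of 0.159 µm is the imposed shear field itself (u₁ runs
from 0.11 to 0.22 µm across the imaged depth); with no imposed deformation
the same statistic drops to the ~0.001 µm noise floor.

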