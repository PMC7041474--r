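# patgv

Total-generalized-variation (TGV) reconstruction for photoacoustic
tomography (PAT) with optical phase-contrast detection.

## The problem

Camera-based phase-contrast PAT records, for each sample orientation
`φ`, a snapshot of the acoustic field at a fixed time `T` whose pixel values
are line integrals of the pressure — a scaled 2D Radon projection
`k_pc · R[p_T](s, φ, z)`. Recovering the initial pressure `p0` (the image of
the light-absorbing structures) takes two steps:

1. **Back propagation** in the frequency domain. The projection data obeys
   the 2D wave equation in `(s, z)` per angle, so
   `R[p0] ≈ F⁻¹[ F[2 R[p_T]] · cos(c_s |k| T) ]`.
2. **Radon inversion.** From `f ≈ R[p0]`, estimate `p0` slice-wise. Because
   few-angle data makes filtered back projection (FBP) break out in streak
   artifacts, the package solves the variational problem

       min_p  μ/2 ‖R p − f‖² + TGV²_α(p),
       TGV²_α(p) = min_q  α₁ ‖∇p − q‖_ℓ¹ + α₀ ‖E q‖_ℓ¹,

   (or TV in place of TGV) with a Chambolle–Pock primal-dual algorithm:
   exact-adjoint sparse Radon projector, forward-difference `∇` and
   symmetrized derivative `E` with exact negative-adjoint divergences,
   pointwise ball projections as dual proximal steps, projector rescaled to
   unit norm by power iteration, fixed iteration count. TGV avoids TV's
   staircase artifacts on smoothly varying pressure while both remain stable
   under angle reduction — the route to faster 3D PAT imaging.

The package also provides an FBP baseline (`pat_fbp()`), a seeded synthetic
phantom generator (vessel-like skeleton + ellipsoids + linear ramp, and a
hair-loop/microsphere phantom), spectral wave simulation of the whole
measurement (`simulate_measurement()`), quality metrics (PSNR, SSIM, maximum
amplitude projections, histogram statistics, the angular-sampling resolution
relation `Λ_min = Δφ · SL / 90°`), float-TIFF/YAML file interchange, an
end-to-end experiment runner (`run_experiment()`) and a CLI
(`inst/exec/pat`). Intended users: researchers in photoacoustic /
optoacoustic imaging and students of variational image reconstruction.

## Worked example

```r
library(patgv)

# synthetic pressure distribution: vessel skeleton (pressure 1),
# two ellipsoids (0.3, 0.6), linear ramp (0..0.8), embedded in zeros
sp  <- phantom_spec(inner_shape = c(40, 40, 8), outer_shape = c(64, 64, 8),
                    n_curves = 4, seed = 11)
p0  <- pat_phantom(sp)

# phase-contrast measurement at 96 angles, snapshot time T = 1.2
geo   <- pat_geometry(Nx = 64, Nz = 8, Nphi = 96, cs = 1, T = 1.2)
snaps <- simulate_measurement(p0, geo, k_pc = 1)
f     <- back_propagate(snaps, geo)

# few-angle setting: keep every 8th angle (12 angles)
geo12 <- subsample_angles(geo, 8)
f12   <- subsample_angles(f, 8)

fit <- pat_reconstruct(f12, geo12, method = "tgv", mu = 1000, iters = 2000)
fit
#> PAT reconstruction (TGV)
#>   volume: 64 x 64 x 8, data: 128 offsets x 12 angles x 8 slices
#>   mu = 1000, alpha1 = 1, alpha0 = 2.5, 2000 iterations
#>   projector norm 0.7159 (scaled by 1)
#>   value range: [-0.04261, 1.468]

ssim_index(coef(fit), p0)                      # 0.945: stable at 12 angles
ssim_index(pat_fbp(f12, geo12)$volume, p0)     # 0.390: FBP collapses
```

The fit is a classed object: `coef()` returns the volume, `fitted()` its
forward projection, `residuals()` the sinogram-domain misfit, `plot()` shows
a maximum amplitude projection or a slice, `summary()` reports voxel
statistics and the data residual. The SSIM contrast above (TGV barely
degrades from 96 to 12 angles while FBP drops from ≈0.93 to ≈0.39) is the
few-angle robustness the method exists for; the negative values in the TGV
range quantify residual background artifacts, which stay an order of
magnitude quieter than FBP's.

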