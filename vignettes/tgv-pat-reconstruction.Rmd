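---
title: "TGV-regularized Radon inversion for phase-contrast photoacoustic tomography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TGV-regularized Radon inversion for phase-contrast photoacoustic tomography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patgv)
```

## The imaging model

In photoacoustic tomography (PAT) a short laser pulse deposits energy in
absorbing structures (vasculature, chromophores) of a sample; thermoelastic
expansion launches an ultrasound field whose initial pressure $p_0$ is
proportional to the absorbed energy. In camera-based *phase-contrast*
detection, a probe beam crosses the water tank perpendicular to the sample's
rotation axis, and a CCD camera records, at a single time $T$ after
excitation and for each sample orientation $\varphi$, an image whose values
are proportional to the pressure integrated along the probe-beam path. Each
snapshot is therefore a scaled 2D Radon projection of the acoustic field at
time $T$:

$$ P_{I_T}(s, \varphi, z) \;=\; k_{pc}\, \mathcal{R}[p_T](s, \varphi, z),
\qquad
\mathcal{R}[p](s,\varphi,z) = \int_{-L}^{L} p\big(s\,\omega(\varphi) + r\,
\omega^{\perp}(\varphi) + (0,0,z)\big)\, dr ,$$

with $\omega(\varphi) = (\cos\varphi, \sin\varphi, 0)$ and a calibration
constant $k_{pc}$ (radians per pressure-length; physically
$2\pi/\lambda_{PB} \cdot dn/dp$). The package normalizes the integration
half-length to $L = 1$, so the reconstruction domain is
$[-\tfrac{\sqrt2}{2}, \tfrac{\sqrt2}{2}]^2 \times [0, h]$ and line offsets
span $s \in [-1, 1]$ — the offset range covers the square cross-section
including its corners, so parallel-beam data is complete for the whole
volume.

Reconstruction proceeds in the two steps the measurement suggests:

1. **Back propagation.** Because the Radon transform intertwines the 3D and
   2D Laplacians, the projection data itself obeys the 2D wave equation in
   $(s, z)$ per angle, with initial value $\mathcal{R}[p_0]$ and zero
   initial velocity. Time evolution is therefore the Fourier multiplier
   $\cos(c_s |k| T)$, and the initial projections are recovered as
   $$ f \;\approx\; \mathcal{R}[p_0] \;=\;
   \mathcal{F}^{-1}_{s,z}\big[\mathcal{F}_{s,z}[\,2\,\mathcal{R}[p_T]\,]
   \cos(c_s |k| T)\big]. $$
   Using $2\cos^2 = 1 + \cos(2\,c_s|k|T)$, the result is exactly
   $\mathcal{R}[p_0]$ plus an *echo*: the field evolved to time $2T$. Once
   $2 c_s T$ exceeds the sum of the data support radius and the region of
   interest radius, the echo's wavefront has left the region of interest and
   only the slowly decaying in-cone tail of the 2D wave remains
   (Huygens' principle fails in even dimensions), so the approximation error
   decays — but never vanishes — as $T$ grows. `forward_propagate()`,
   `back_propagate()` and `simulate_measurement()` implement both directions
   spectrally.

2. **Radon inversion.** Inverting $\mathcal{R}$ slice-wise from $f$ is
   ill-posed, and with few angles the classical filtered back projection
   (FBP) develops streak artifacts. The package's core is instead the
   variational estimate
   $$ \hat p \;=\; \arg\min_{p} \; \tfrac{\mu}{2}\, \lVert R\,p - f
   \rVert^2 \;+\; \mathrm{Reg}(p), $$
   with $\mathrm{Reg}$ either total variation
   $\mathrm{TV}(p) = \lVert \nabla p \rVert_{\ell^1}$ or second-order total
   generalized variation
   $$ \mathrm{TGV}^2_\alpha(p) \;=\; \min_{q}\;
   \alpha_1 \lVert \nabla p - q \rVert_{\ell^1} +
   \alpha_0 \lVert \mathcal{E} q \rVert_{\ell^1}, $$
   where $\mathcal{E} q = \tfrac12 (\nabla q + \nabla q^{\mathsf T})$ is the
   symmetrized derivative. TV is edge-preserving but biased toward
   piecewise-constant solutions (the *staircase* effect on smooth gradients);
   TGV balances first- and second-order penalties and reconstructs smooth
   ramps without staircasing while keeping sharp edges.

## Discretization

The volume lives on an $N_x \times N_x \times N_z$ voxel grid (space $P$),
the auxiliary field $q$ on the 3-vector grid $V$, and $\mathcal{E} q$ on the
symmetric-tensor grid $W$ whose six components are stored once with
off-diagonal slots double-counted in inner products, so pointwise magnitudes
are Frobenius norms. Derivatives are forward differences in voxel units with
a zero difference on the trailing plane of each axis; the divergences are
defined as the *exact* negative adjoints (backward differences with the
matching closure). Physical voxel spacing is deliberately absorbed into
$\mu$ and the $\alpha$ weights, the common convention in TGV imaging.

Two consequences of this boundary closure are worth knowing:

* the discrete gradient of an affine volume is constant only in the
  interior (zero on trailing planes), so the discrete TGV of a non-constant
  affine volume is a small positive boundary term rather than exactly zero —
  the suite verifies this value against an independent solver rather than
  asserting zero;
* the classical norm bounds $\lVert \nabla \rVert^2 \le 4d$ hold per
  dimension ($8$ for a single slice, $12$ in 3D).

The discrete projector `radon_forward()` deposits each square pixel's exact
footprint — the trapezoid obtained by convolving box profiles of widths
$\Delta x\,|\cos\varphi|$ and $\Delta x\,|\sin\varphi|$ — onto the $s$-bins,
integrated exactly over each bin. This makes per-pixel mass exact at every
angle and, because the adjoint shares the same sparse weights, the pair
$(R, R^{*})$ is adjoint to machine precision, which the convergence theory
of the solver requires. The default $N_s = 2 N_x$ matches the diagonal
sampling rate of the pixel grid and is configurable.

## The primal-dual solver

With $A(p, q) = (R\,p, \nabla p - q, \mathcal{E} q)$ and
$G(g, v, w) = \tfrac{\mu}{2}\lVert g - f\rVert^2 + \alpha_1 \lVert v
\rVert_{\ell^1} + \alpha_0 \lVert w \rVert_{\ell^1}$, the problem is the
saddle point of $\langle \xi, A u\rangle - G^{*}(\xi)$, solved by the
Chambolle–Pock iteration from zero initialization: dual step (discrepancy
prox $g \mapsto \tfrac{\mu}{\mu + \sigma}(g - \sigma f)$ and pointwise
projections of $v$ and $w$ onto the $\alpha_1$- and $\alpha_0$-balls), primal
gradient step through $A^{*}(g,v,w) = (R^{*}g - \operatorname{div} v,
-\operatorname{div} w - v)$, and an extragradient step. The projector is
first rescaled to unit norm (power iteration on $R^{*}R$; data rescaled by
the same factor), after which the single-slice bound
$\lVert A \rVert^2 < 12$ applies and the symmetric default steps
$\sigma = \tau = 1/\sqrt{12} - 10^{-6}$ are admissible.

For multi-slice volumes the measured $\lVert A \rVert^2$ rises toward
$\approx 14.8$ (the 3D gradient bound), mildly exceeding the classical
step-size condition at the default steps. The package keeps the
$\sigma\tau < 1/12$ default because it is the established choice for this
algorithm family; the suite checks on randomized 3D problems that iterates
remain bounded and objectives decrease, and users can pass tighter
`sigma`/`tau` when a certified guarantee matters. The only stopping rule is
the fixed iteration count `iters`, mirroring practice where intermediate
results are inspected on the fly; an objective trace is recorded when
`record_every > 0`, purely as a diagnostic. No positivity constraint is
imposed: reconstructions may go negative, which is informative about
artifact levels in true-zero background.

The TV variant drops $q$ and $w$ (dual pair $g$, $v$ only) and uses
$\sigma = \tau$ just inside $1/\sqrt{13}$, from
$\lVert (R; \nabla) \rVert^2 \le 1 + 12$.

### Parameters

* `mu` — discrepancy weight. Large values trust the data (appropriate for
  low noise: the residual term dominates), small values strengthen the
  regularization; quality degrades on both ends (over-smoothing versus
  surviving artifacts). There is no a-priori correct value; it should be
  chosen per dataset, with more regularization (smaller `mu`) for noisier or
  more undersampled data.
* `alpha1 = 1`, `alpha0 = 2.5` — TGV weights. $\alpha_1 = 1$ makes TGV
  directly comparable with TV ($\mathrm{TGV} \le \alpha_1 \mathrm{TV}$
  always, since $q = 0$ is feasible); $\alpha_0 = 2.5$ is a robust default
  for medical imaging that we keep throughout.
* `iters` — fixed iteration count; overestimate it rather than stopping
  early (the suite uses 20 000 on tiny oracle-checked problems, 2 000 on the
  64-voxel experiment below).

`tgv_value()` evaluates the TGV functional itself by running the same
primal-dual machinery on the inner minimization over $q$ (no data term); the
returned primal value is an upper bound that tightens with `inner_iters`.

## The synthetic phantom

`pat_phantom()` composes, additively, the three structure classes typical of
PAT pressure distributions: a vessel-like skeleton (random smooth
cubic-spline curves rasterized to one-voxel width, pressure exactly 1),
two ellipsoids of sub-unit pressure (defaults 0.3 and 0.6) emulating
tumor-like inclusions, and a linear ramp (default 0 to 0.8) emulating a
smooth tissue background; the structured inner block is embedded centered in
a larger zero volume, mirroring a $128 \times 128 \times 40$ structure
inside a $281 \times 281 \times 40$ reconstruction domain at default sizes.
All placements scale with the grid, so the same spec generates desk-scale
phantoms. The generator is seeded and bit-reproducible.

What it does *not* emulate: real vasculature topology (the curves are random
splines, not a measured vessel tree), optical fluence/scattering
heterogeneity, acoustic attenuation, heterogeneous sound speed, and the
camera's limited view. Passing tests therefore demonstrate correctness of
the operators and solver and the *relative* behavior of FBP/TV/TGV under
angle reduction — not absolute image quality on animal data.

## Numerical choices

* **Spectral padding.** Wave propagation pads each $(s, z)$ slice by
  `pad_margin` (default $c_s T$) so the periodic solution coincides with the
  free-space one; `simulate_measurement()` additionally extends the camera
  grid by `fov_margin` so the full wave pattern is retained, and
  `back_propagate()` crops back to the sinogram window recorded in the
  snapshot object. FFT lengths are rounded up to products of 2 and 3.
* **FBP conventions.** Ram-Lak filtering in the frequency domain (with
  optional Shepp–Logan or Hann apodization), linear interpolation during
  back projection, $\pi / N_\varphi$ angular weight. Since $s \in [-1,1]$
  covers the whole square domain, no validity cropping is needed.
* **SSIM convention.** Slice-wise 2D windows (7×7 uniform), population
  moments, standard constants $K_1 = 0.01$, $K_2 = 0.03$, data range taken
  from the reference volume; a 3D-window variant is available via
  `dims = 3`. PSNR uses `peak = max(ref)` by default.
* **Degenerate inputs.** Zero data reconstructs to exactly zero (zero is a
  fixed point of the iteration from zero initialization); `T = 0` makes
  forward propagation the identity and back propagation exactly twice the
  pressure sinogram; empty ramp regions warn and no-op.

## The scaled-down few-angle experiment

The suite reproduces the qualitative few-angle pattern on a desk-scale
version of the numerical experiment: a $64 \times 64 \times 8$ phantom
(structured $40^2 \times 8$ inner block), noiseless phase-contrast
simulation at $c_s T = 1.2$, back propagation, and reconstruction from 96
versus 12 uniform angles with $N = 2000$ iterations. Because the simulated
data is noiseless, the per-datum choice of `mu` lands at a large value
(`mu = 1000`) for the quality comparison; the staircase comparison between
TV and TGV is run at the moderate `mu = 2`, where the regularizer visibly
shapes the solution on the ramp. The expected pattern — SSIM collapsing for
FBP but stable for TGV, quieter true-zero background under TGV, and
value-clustering on the ramp under TV only — is asserted by
`tests/testthat/test-acceptance.R`; the tests themselves compute every
number they assert.

```{r, eval = FALSE}
sp  <- phantom_spec(inner_shape = c(40, 40, 8), outer_shape = c(64, 64, 8),
                    n_curves = 4, seed = 11)
p0  <- pat_phantom(sp)
geo <- pat_geometry(Nx = 64, Nz = 8, Nphi = 96, cs = 1, T = 1.2)
f   <- back_propagate(simulate_measurement(p0, geo), geo)
fit <- pat_reconstruct(subsample_angles(f, 8), subsample_angles(geo, 8),
                       method = "tgv", mu = 1000, iters = 2000)
ssim_index(coef(fit), p0)
```

## Known limitations

* Second-order TGV only; no higher orders and no anisotropic, voxel-aware
  derivative weights (physical spacing is absorbed into the weights).
* Parallel-beam geometry only, matching the physical projection setup; no
  fan/cone beam.
* The limited camera field of view (detection angles below 180°) is modeled
  only as optional cropping; the reconstruction error it induces in the
  back-propagation step is outside the package's scope.
* No acceleration (preconditioning, adaptive steps) of the primal-dual
  iteration and no GPU path; problem sizes beyond roughly
  $300^2 \times 40$ voxels with hundreds of angles become slow in plain R.
* The back-propagation echo error decays with $T$ but is never exactly zero
  on bounded windows (2D wave tails); choose $c_s T$ comfortably above the
  support separation.
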