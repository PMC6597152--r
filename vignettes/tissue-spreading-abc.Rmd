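---
title: "Inferring tissue-spreading mechanics from time-lapse kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring tissue-spreading mechanics from time-lapse kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

An embryonic ectoderm explant cultured on a fibronectin substrate spreads
radially over about ten hours. `epiboly` models the explant as a
two-dimensional compressible continuum observed in a fixed (Eulerian) frame.
The visible cell density rho(x, t) (cells/mm^2) obeys a diffusion equation
with a material-addition source,

    d rho / dt = (k/b) * Laplacian(rho) + q,    in the tissue domain,

where `k` is the residual stretching modulus of the tissue (stiffness after
fast cytoskeletal rearrangement), `b` the adhesion constant coupling the
tissue to the substrate, and `q` a source describing visible material added
by radial intercalation and active cell shape change. On the moving tissue
edge the density is pinned by the balance between the lamellipodia force `F`
per unit edge length and the stiffness,

    rho = rho_u * exp(-F/k),

and the edge itself advances at

    v . n = -(k/b) * exp(F/k) / rho_u * (grad rho . n),

which is exactly the speed at which the diffusive flux arriving at the edge
builds new tissue at the edge density. `rho_u` is the density of relaxed,
unstressed tissue. The source is a mass-limited logistic,

    q = alpha * rho * (1 - rho / (rho_u * exp(F/k)))   while m < m0 / 2,
    q = 0                                              once  m >= m0 / 2,

with `m(t)` the cumulative visible mass added so far and `m0` the initial
visible mass: at most 50% more cells can surface, reflecting that embryos add
no net volume. Because `F`, `k`, `b` enter only as ratios, the inferable
parameters are `F/k` (dimensionless), `k/b` (um^2/h), `alpha` (1/h) and
`rho_u` (cells/mm^2).

Two subtleties are worth stating plainly:

* **Density units.** The initial interior density is 0.0047 cells/um^2 =
  4700 cells/mm^2, while the prior for `rho_u` spans 1000-2000. Read
  literally in the same unit these would be inconsistent (no spreading). The
  package adopts cells/mm^2 as the canonical unit — interior density 4700,
  `rho_u` in 1000-2000 — which makes the interior denser than the edge and
  drives outward spreading. `model_config(density_unit_scale =)` lets a user
  restore any other scaling between the two conventions.
* **The growth law is applied literally.** Where rho exceeds the limiting
  density `rho_u * exp(F/k)` the logistic term is negative and is *not*
  clipped; under the default initial density the tissue starts compressed for
  most prior draws, so the cumulative added mass `m` can transiently decrease
  before the interior relaxes below the limiting density. The m0/2 cap is
  inclusive (`m >= m0/2` shuts growth off).

## The solver

The moving boundary is tracked with a level set phi on a fixed Cartesian
grid (default: a square domain comfortably larger than the explant,
spacing h = 10-20 um): phi is the signed distance to the edge, negative
inside. One time step comprises

1. explicit (FTCS) diffusion + growth of rho at interior nodes, with the
   edge Dirichlet value imposed through subcell ghost values: for an
   interior node whose neighbour lies outside, the interface crossing
   fraction theta = phi_c / (phi_c - phi_n) places the boundary value
   between them, and the ghost value is the linear extrapolation through
   that crossing. theta is clamped below at 0.5 and the diffusion step is
   bounded by `0.9 * theta_min * h^2 / (4 k/b)`, which keeps every stencil
   coefficient non-negative — the pure-diffusion substep then obeys a
   discrete maximum principle (tested);
2. edge speed at interior band nodes from one-sided differences of rho
   projected on the normal (normal from central differences of phi); in the
   outward direction the difference runs to the subcell interface point
   carrying the Dirichlet value, which proved markedly more accurate against
   the radial reference than interior-only differences;
3. extension of the speed across a narrow band (6 cells) by neighbour
   averaging, then Godunov upwind advection of phi as normal motion.

Advection is *chunked*: diffusion substeps accumulate time until the front
would have moved 0.15 cells at the current maximum speed, then phi is
advected once with the accumulated time and the speed field is refreshed.
This keeps the expensive speed/extension work amortized while front motion
stays first-order accurate; widening the chunk to ~0.5 cells biases a
spreading disk's radius low by a few tenths of a percent per 10 h, which is
why the default is small. Every fifth refresh the level set is rebuilt as an
exact signed distance to the marching-squares zero contour (band nodes get
exact polyline distances; the far field is refreshed against subsampled
contour vertices). Newly engulfed nodes take the edge density — constant
extrapolation of the Dirichlet value, consistent with the first-order front.

If the front comes within two cells of the domain edge the run stops and the
series is flagged `escaped` (a rejection condition during fitting, not an
error). `compute_dt()` documents the baseline stability bound
`0.9 * min(h^2/(4 k/b), h/(2 vmax), 1/(4 alpha))`; the solver's internal
step is never coarser.

**Validation.** An independent 1D radial finite-volume solver with
continuous front tracking (`radial_reference()`, cell size 1-2 um, the
Dirichlet value slaved onto the front cell by interpolation so all stencil
distances stay >= dr) serves as the oracle for circular explants. At
h = 10 um the 2D solver tracks the oracle's radius within ~1.2% at every
frame of a 10-h run across the tested parameter range, and the t_end contour
error against an h/4 reference drops by about a factor of 2 when h is
halved, as expected for first-order front tracking. Mass on a frozen domain
is conserved to well under 1%.

## From registration output to density ratios

Elastic registration of a frame pair (j, j + delta) yields a displacement
field u on the pixel grid. The deformation gradient is F = grad(u) + I
(central differences inside, one-sided at borders — exact for affine
motion), and under local mass conservation det F equals the ratio of the
earlier to the later density, the quantity the model can also predict:
`xi_comp = rho(., j) / rho(., j + delta)` at each grid node inside the
tissue at both frames. delta defaults to 5 frames (25 min), the smallest
increment at which changes are reliably detectable; larger gaps accumulate
inelastic events (rearrangement, division) that break the elastic
assumption. Off-tissue nodes carry an explicit 0 sentinel and a mask, so no
division by zero can occur downstream. Pixel-grid maps are bilinearly
interpolated onto the computational grid; a node is on-mask only when all
four surrounding pixels are (the conservative choice at mask edges).

A numerical caveat worth knowing: the ratio field has a kink at the tissue
edge (the last on-mask ring can carry ratios several times the interior
value), so the *pointwise* round-trip error of resampling through an
unaligned pixel grid is dominated by that ring and shrinks only linearly
with the pixel size. Consistency between measured and simulated ratio maps
is therefore assessed as the RMS relative mismatch over the shared mask
(below 1% for pixel grids at 6 um, between the camera resolution of
2.6 um/px and the default analysis grid of 20 um); maps resampled onto the
analysis grid itself — the default preprocessing — agree exactly.

## The error function and ABC rejection

A candidate parameter set theta is scored against a dataset by simulating
from the dataset's initial contour and summing two terms. For each
post-initial frame j, every computational edge point's minimum distance to
the experimental edge polyline is computed and D_j is their root mean
square; z_d = sum_j D_j (um). For each pair (j, j + delta), P_j is the RMS
node-wise difference between the computational and experimental density
ratios over the *full* grid, with 0 sentinels in both maps — nodes covered
by tissue in exactly one of the two maps contribute their full squared
ratio, deliberately penalizing shape mismatch; z_p = sum_j P_j. The total is

    z = z_d + w * z_p,  w = 1000,

the weight bringing both terms to the same order. z is the NaN sentinel —
never accepted — if the simulation escapes the domain, if the density at the
explant centre (the grid node nearest the initial centroid) rises
frame-to-frame by more than a relative 1e-6, or if the solver fails
numerically. The t = 0 contour is the candidate's initial condition, so
frame 1 of the distance sum is the first post-initial frame; the frame-j
density pairs start at j = 1 (t = 0).

ABC rejection draws theta from independent uniform priors — F/k in (0, 1.5),
k/b in (500, 5000) um^2/h, alpha in (0, 1) 1/h, rho_u in (1000, 2000)
cells/mm^2 — and accepts candidates with z at or below a tolerance
(default 1500). The accepted sets approximate the posterior. Summaries
follow the usual corner-plot conventions: per-parameter histograms smoothed
with a Gaussian kernel at Silverman's bandwidth (the mode is the smoothed
argmax), all-pairs 2D histograms, central 95% percentile intervals, and
Pearson correlations over the best 20% (by z) of accepted sets. Mean and
mode are both reported; they answer different questions for ridge-shaped
posteriors.

## The synthetic-data generator

Real spreading datasets are image-derived; the generator emulates their
derived kinematic products, not the micrographs. A protocol fixes the
ground-truth parameters, the initial shape (circle, 2:1 ellipse, or a
Fourier-perturbed blob; areas 0.14-2.23 mm^2 are the observed range, default
0.28 mm^2), the 5-min/10-h schedule, and the noise model: experimental
contours are the simulated contours resampled at 3x the computational point
density with i.i.d. Gaussian jitter of sd 13 um per coordinate (about 5
pixels at 2.6 um/px, the stated upper bound on edge-segmentation error of
roughly 2 cell widths), and ratio maps are multiplied on-mask by log-normal
noise with sdlog 0.02. Ratio maps are emitted on the computational grid by
default (as a preprocessing pipeline that resamples registration output onto
the analysis grid would); set `ratio_map_spacing` to emit them on an offset
pixel grid and exercise the interpolation path. These noise magnitudes are
protocol fields, never hidden constants.

What passing recovery tests on such data does *not* show: robustness to
spatially correlated segmentation error, to registration failure near the
edge, to non-circular asymmetric spreading, or to model misspecification —
the synthetic tissue obeys the fitted model exactly.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script runs use a coarse fitting grid
(1.5 x 1.5 mm, h = 20 um) and a few hundred candidate simulations
(threshold calibrated to accept ~12% of candidates), which recovers alpha
and rho_u within their 95% intervals and reproduces the strong negative
F/k-k/b correlation; the solver-accuracy checks run at h = 10 um (radial
oracle) and h = 20/10/5 um over shorter horizons (grid convergence). These
sizes are the package's chosen desk-scale study; the full-scale design
(10,000 acceptances per explant) uses identical code paths.

## Known limitations

* First-order front tracking: contour positions carry O(h) error; h = 10 um
  is a good cost/accuracy point for ~mm-sized explants.
* The two error terms weight shape mismatch twice (z_d directly, z_p through
  the sentinel convention); w = 1000 keeps the printed convention rather
  than re-balancing.
* Uniform thickness, isotropic stiffness, homogeneous substrate; none of
  the heterogeneous or viscous extensions are modelled.
* The centre-density rejection rule is applied literally; parameter sets
  whose limiting density exceeds the initial density grow at the centre and
  are rejected by construction, which carves a known region out of the
  prior.
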