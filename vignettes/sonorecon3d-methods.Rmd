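---
title: "Surface and volume reconstruction with quality assessment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface and volume reconstruction with quality assessment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SonoRecon3D)
```

SonoRecon3D implements the computational chain used when ultrasound
imagery is reconstructed into 3D models and the reconstructions are
scored: local polynomial surface models over depth images, robust and
regularized surface regression, trilinear volume interpolation with
isosurface extraction, and full-reference image-quality metrics. This
vignette explains each model, the assumptions behind it, the numerical
choices made where the mathematics leaves freedom, and what the built-in
phantoms do and do not establish about real data.

## Depth images and the surface-patch family

A depth image stores one depth sample per pixel of an n-row × m-column
grid. Pixel indices `(a, b)` are 0-based, `a` over rows and `b` over
columns, and map to centered image-plane coordinates

$$x_b = b - \tfrac{m-1}{2}, \qquad y_a = -a + \tfrac{n-1}{2},$$

so the image center becomes the origin with y pointing up. The mapping is
affine and exactly invertible (`planeToImageCoords()`); real-valued
indices are allowed so sub-pixel queries use the same convention.

Local surfaces are drawn from a nested polynomial family indexed by
*tier*: tier 1 is the plane $a_0 + a_1 x + a_2 y$ (3 coefficients), tier
2 adds the bilinear $a_3 xy$ term, tier 3 the pure quadratics
$a_4 x^2 + a_5 y^2$, tier 4 the cubics and tier 5 the quartics, up to 15
coefficients $a_0\ldots a_{14}$. We order the family cumulatively so
that zero-padding a tier-$(t{-}1)$ patch into tier $t$ changes no
evaluated value; this nesting is asserted property-style in the tests.
The tiers trade bias for variance: a plane needs only 3 well-placed
samples but cannot bend, the quartic follows curved anatomy but needs
≥ 15 samples and is far more noise-sensitive. Tier 1–3 are the practical
defaults for small patches.

Two local operations complete the module. The plane through three stored
depth-image points is solved exactly (a 3 × 3 system), refusing triples
whose (x, y) projections are collinear — the determinant test uses a
relative threshold of $10^{-12}$ times the squared coordinate scale, so
the error is about degenerate geometry, not units. Sub-pixel depth
lookup splits the enclosing unit pixel quad into two triangles and
returns the planar interpolant of the enclosing triangle. The split
diagonal is fixed at $(a_0,b_0)$–$(a_1,b_1)$ in every quad: any fixed
choice reproduces vertices and planar fields exactly (both are tested),
and fixing it makes results reproducible across machines; nothing in the
underlying geometry prefers one diagonal.

## Surface regression: least squares, LMedS, thin-plate regularization

Given scattered points $(x_a, y_a, z_a)$, the fit objective is

$$\chi^2 = \sum_{a} \left(z_a - f(x_a, y_a; a_0,\ldots,a_{m-1})\right)^2 .$$

`leastSquaresFit()` minimizes it by QR decomposition of the monomial
design matrix; it refuses under-determined problems (n below the
coefficient count) and rank-deficient designs (e.g. all points on a
line) rather than returning one of infinitely many minimizers.

Ultrasound-derived point sets contain gross outliers (shadowing,
specular dropouts), and a single bad point can move the least-squares
plane arbitrarily far. `lmedsFit()` therefore implements the least
median of squares rule

$$\hat{c} = \arg\min_c \; \operatorname{med}_a \left(z_a - f(x_a, y_a; c)\right)^2 ,$$

whose breakdown point approaches 50 %. The median has no closed-form
minimizer, so the classical resampling strategy is used: draw `nSubsets`
random minimal subsets (subset size = the tier's coefficient count, the
smallest exactly solvable problem), fit each exactly, score every
candidate by the median of its squared residuals over *all* points, and
keep the best. Specific choices, none of which are forced by the
estimator's definition:

* **Median convention.** For even n the *lower* median (the smaller
  middle order statistic) is used, consistently in the fitter and all
  oracles.
* **Number of draws.** Default `nSubsets = 500`. The chance that a draw
  is outlier-free is $(1-\varepsilon)^p$; at 30 % contamination and
  subset size 3 that is ≈ 0.34, so 500 draws miss an all-inlier subset
  with probability ≈ $10^{-90}$ — deterministic success in practice
  while keeping the default fit under a second.
* **Seeding.** All draws come from a caller-supplied seed through an
  internal RNG scope that restores the caller's random stream; identical
  seeds give bit-identical `FitResult`s (a tested contract).
* **Inlier refinement.** With `refine = TRUE` (default) the winning
  patch is polished by least squares on its inliers, where a point is an
  inlier if its squared residual is at most $(2.5 s)^2$ with the
  classical finite-sample robust scale
  $s = 1.4826\,(1 + 5/(n-m))\sqrt{\operatorname{med} r^2}$. The 1.4826
  factor converts a median absolute deviation to a Gaussian sigma; the
  $(1+5/(n-m))$ term inflates it for small samples. If fewer than a
  minimal subset of inliers survive (e.g. on exactly-fitting data where
  the median residual is 0), the unrefined patch is returned.
* **Reported statistics.** The stored `chiSquare` and
  `medianSqResidual` are always those of the *returned* patch over all
  points, so they are recomputable from the result — the suite asserts
  this for every fitter.

When data are too sparse or too irregular to pin down a higher-tier
patch, `regularizedFit()` minimizes

$$\chi^2 + \alpha^2 \iint f_{xx}^2 + 2 f_{xy}^2 + f_{yy}^2 \, dx\,dy ,$$

the thin-plate bending energy over the data's bounding rectangle (or a
caller-supplied one). For polynomial patches the integral is a quadratic
form in the coefficients with exactly computable monomial integrals, so
no quadrature is involved. The penalty's null space is the affine
surfaces; with three non-collinear points and $\alpha > 0$ the penalized
problem has a unique solution even when $\chi^2$ alone is
under-determined, and as $\alpha \to \infty$ the fit tends to the best
least-squares plane (both behaviours are tested). Numerically the
solution is computed from the augmented least-squares system
$\bigl[\,D;\ \alpha B\,\bigr]$ with $B^{\top}B = P$ (eigenvalue square
root of the penalty matrix) by LAPACK QR: the augmented formulation has
condition number of order $\alpha$, where the penalized normal equations
would square it and fail near machine precision for large $\alpha$. The
weight enters squared ($\alpha^2$), matching the form of the objective
above; $\alpha$ has units of length$^{2}$ (residuals are lengths, the
bending integrand length$^{-2}$·area).

## Trilinear cells and marching-tetrahedra isosurfaces

A voxel grid samples a scalar field on a regular lattice
(`origin + index · spacing`). Each cell carries the unique trilinear
interpolant

$$f(x,y,z) = a_0 + a_1 x + a_2 y + a_3 z + a_4 xy + a_5 yz + a_6 zx + a_7 xyz ,$$

whose coefficients are finite differences of the 8 corner values (the
closed-form solution of the 8 × 8 interpolation system; the test suite
checks it against a dense solve). The reduced bilinear form without the
$zx$ and $xyz$ terms is exposed as a separate operation
(`evalLinearPatch3D()`): both six- and eight-term local models appear in
the surface-reconstruction literature, and keeping them distinct lets
either be used deliberately rather than silently conflating them.

The isosurface $\{f = c\}$ is extracted by **marching tetrahedra**: each
cell is split into the 6 tetrahedra of the Kuhn subdivision around the
main diagonal, the same split in every cell so that neighbouring cells
triangulate shared faces identically. Per tetrahedron the sign pattern
of $f - c$ at the 4 corners has no ambiguous configurations (unlike
classic marching cubes), yielding 0, 1 or 2 triangles. Design details:

* **Vertex placement.** A cut tetrahedron edge contributes one vertex at
  the root of the cell's *trilinear* restriction along that edge. On
  axis-aligned edges the restriction is linear and the root is the plain
  linear-interpolation root in closed form; on face and interior
  diagonals it is quadratic/cubic and is bracketed and solved to
  $10^{-13}$. This keeps every emitted vertex on the interpolated level
  set (the suite audits $|f(v) - c| \le 10^{-6}\cdot$range at every
  vertex), which plain linear placement on diagonal edges would not
  achieve. Face-diagonal restrictions are the face's bilinear form and
  therefore identical from both incident cells.
* **Welding and watertightness.** Vertices are keyed by the unordered
  pair of lattice ids of their edge, so each cut edge yields exactly one
  shared vertex and the mesh is watertight wherever the level set stays
  interior to the volume (edge-incidence audit: every edge borders
  exactly 2 triangles on the sphere phantom).
* **Degeneracy handling.** Samples exactly equal to $c$ are perturbed by
  $+10^{-9}\cdot$(field range) before extraction (configurable), so no
  zero-area triangles or on-sample vertices arise. Iso values outside
  the sampled range return an empty mesh, not an error; grids with fewer
  than 2 samples on an axis are refused.
* **Orientation.** Triangles are oriented so normals point from the
  $f > c$ side toward the $f < c$ side, consistently across the mesh.

## Image-quality metrics

For two m × n monochrome images $I, K$ with peak intensity
$\mathrm{MAX}_I$:

$$\mathrm{MSE} = \frac{1}{mn}\sum_{i,j}(I_{ij}-K_{ij})^2, \qquad
  \mathrm{PSNR} = 10\log_{10}\frac{\mathrm{MAX}_I^2}{\mathrm{MSE}} .$$

$\mathrm{MAX}_I$ defaults to 255 (8-bit) and is part of the pair's
contract — it is never inferred from data, since an image that happens
not to reach its nominal peak would otherwise silently change its own
scale. PSNR of identical images is undefined by the formula; the package
returns the sentinel `Inf` (band "excellent") rather than failing. PSNR
bands follow the conventional thresholds — above 40 dB excellent, 30–40
good, 20–30 poor, below 20 unacceptable — with ties resolved so that
"excellent" requires *strictly* more than 40 dB (40 and 30 are "good",
20 is "poor"); the band boundaries are recovered by bisection in the
acceptance tests.

SSIM is the mean over local window positions of
$l^\alpha c^\beta s^\gamma$ with the standard stabilized luminance,
contrast and structure terms. Internals follow the de-facto standard
configuration — 11 × 11 window, Gaussian weighting with σ = 1.5 pixels,
$C_1 = (0.01\,\mathrm{MAX}_I)^2$, $C_2 = (0.03\,\mathrm{MAX}_I)^2$,
$C_3 = C_2/2$, unit exponents — because the defining product fixes none
of them; all are arguments. Only full (valid) window positions enter the
mean, so no padding policy can distort border behaviour. Two numerical
choices matter:

* With the default $\beta = \gamma$, $C_3 = C_2/2$ the contrast and
  structure terms are combined algebraically into
  $(2\sigma_{xy}+C_2)/(\sigma_x^2+\sigma_y^2+C_2)$, avoiding square
  roots; together with exact doubling in floating point this makes
  `ssim(I, I)` return *exactly* 1, which the acceptance suite asserts
  over 50 seeded images.
* The structure term of the stabilized form can be negative for
  anti-correlated windows, so SSIM is not confined to [0, 1] in general.
  The raw value is reported and merely flagged (`ssim_negative` in
  reports); clamping would hide exactly the distortions the flag marks.
  For non-unit exponents a sign-preserving power is used so fractional
  exponents of negative terms stay real.

`vasBand()` bands a 0–10 visual analogue scale score into the standard
discomfort categories (0–2 comfortable, then mild, moderate, severe,
extreme in steps of 2). The printed scale labels only integer scores;
for continuous scores the implementation treats each band as
left-open/right-closed above 2, which agrees with the printed labels at
every integer. `compareAlgorithms()` assembles PSNR, band and SSIM into
a per-algorithm table in input order, serializable to CSV/JSON; rows are
recomputable from the stored inputs to $10^{-9}$ (tested).

## What the phantoms emulate — and what they do not

Every pipeline stage is exercised by seeded generators returning their
ground truth, so parameter-recovery tests need no external data:

* `makeDepthPhantom()` samples a known patch on the pixel grid, adds
  Gaussian depth noise, and corrupts `round(outlierFrac · N)` pixels
  (seeded draw) by a fixed additive offset. Fixed-magnitude outliers
  keep the exhaustive LMedS oracle deterministic; the fraction is capped
  below 0.5, the LMedS breakdown bound.
* `makeVolumePhantom()` samples $f = x^2+y^2+z^2$ about the grid center
  (so iso level $c = r^2$ is an exact sphere — vertex radii are
  auditable in closed form) or the ramp $f = x$ (planar iso levels).
  Default lattice 17³ at spacing 0.25, covering [−2, 2]³: fine enough
  that the sphere audit is meaningful, small enough that extraction runs
  in well under a second.
* `makeSpecklePair()` applies multiplicative Gaussian speckle
  $K = \mathrm{clip}(I(1+\eta), 0, \mathrm{MAX}_I)$, a standard
  first-order surrogate for ultrasound speckle; its Monte-Carlo MSE is
  checked against the closed-form second moment.
* `makeHoneycombImage()` draws the Voronoi boundary of a hexagonal
  lattice as bright walls over darker interiors plus speckle, emulating
  the hyperechoic honeycomb appearance of the sciatic nerve in
  cross-section.

These phantoms validate the *mathematics*: recovery of generating
parameters, robustness at stated contamination levels, mesh geometry
against analytic surfaces, metric behaviour under controlled distortion.
They do not reproduce B-mode physics — no attenuation, no
depth-dependent point-spread, no Rayleigh/Gamma speckle statistics, no
probe geometry — so passing tests demonstrate correctness of the
algorithms, not clinical performance on real sweeps. Quality metrics on
real reconstructions depend on acquisition details that synthetic
phantoms cannot stand in for.

## Problem sizes and runtime

The shipped test-bed sizes are chosen so the whole suite runs in seconds
on one core while keeping every check statistically meaningful: 64 × 64
images for metric properties (50 replicates for the self-identity
check), 10–80-point regressions (with a 14-point instance small enough
for exhaustive $\binom{14}{3}$ enumeration as an oracle), 500 LMedS
draws, and 9³–17³ voxel lattices. All sizes are arguments, and the
algorithms scale in the obvious way (LMedS linearly in draws × points;
extraction linearly in crossed cells).

## Known limitations

* Polynomial patches are global over their fitting domain; no piecewise
  stitching or continuity constraints across patches is provided.
* `regularizedFit()` integrates the penalty over an axis-aligned
  rectangle; strongly non-rectangular point domains over-penalize empty
  corners.
* The isosurface extractor is single-resolution marching tetrahedra: no
  adaptive refinement, mesh simplification or normal smoothing, and
  tetrahedral splits produce more (thinner) triangles than marching
  cubes on the same lattice.
* SSIM is the single-scale index; multi-scale variants are out of scope.
* File formats are deliberately minimal (PGM/PNG/TIFF, CSV, raw+JSON
  volumes, OBJ/ascii-PLY); there is no DICOM ingestion.
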