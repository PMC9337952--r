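# SonoRecon3D

SonoRecon3D is an R toolkit for the computational core of intelligent 3D
reconstruction of ultrasound imagery, as used when a B-mode sweep of a
structure such as the sciatic nerve (the bright "honeycomb" cross-section
seen during ultrasound-guided nerve block) is turned into a 3D model and
the reconstructed images are scored for quality. It is aimed at
researchers prototyping reconstruction pipelines and at anyone who needs
robust surface fitting, isosurface extraction or full-reference image
quality metrics with a fully synthetic, seeded test bed.

The package covers four stages:

1. **Depth-image surface modeling.** Pixels `(a, b)` of an n × m depth
   image map to centered image-plane coordinates
   `x_b = b − (m−1)/2`, `y_a = −a + (n−1)/2`. Local surfaces are drawn
   from the nested polynomial patch family
   `z₁ = a₀ + a₁x + a₂y` (plane), `z₂ = z₁ + a₃xy`,
   `z₃ = z₂ + a₄x² + a₅y²`, up to the full quartic `z₅` with coefficients
   `a₀ … a₁₄`. Planes through three stored points and triangular
   (barycentric) sub-pixel depth interpolation complete the local toolkit.
2. **Robust surface regression.** Patches are fitted to scattered
   `(x, y, z)` points by ordinary least squares
   (`χ² = Σₐ (zₐ − f(xₐ, yₐ))²`), by **least median of squares**
   (`argmin med (zₐ − f(xₐ, yₐ; c))²` with random minimal-subset
   resampling, robust to up to half the points being gross outliers), and
   by thin-plate **regularized** regression
   (`χ² + α² ∬ f²ₓₓ + 2f²ₓᵧ + f²ᵧᵧ dx dy`, evaluated in closed form for
   polynomial patches).
3. **Volume interpolation and isosurfaces.** Voxel cells carry the
   trilinear interpolant
   `f = a₀ + a₁x + a₂y + a₃z + a₄xy + a₅yz + a₆zx + a₇xyz` (and the
   reduced bilinear form without the `zx`/`xyz` terms as a separate
   operation); the isosurface `{f = c}` is extracted as a watertight
   triangle mesh by marching tetrahedra.
4. **Image-quality assessment.** MSE, PSNR
   (`10·log₁₀(MAX_I²/MSE)`) with the conventional decibel quality bands
   (> 40 dB excellent, 30–40 good, 20–30 poor, < 20 unacceptable), SSIM
   (`l·c·s` over Gaussian windows), VAS discomfort banding, and
   comparison-table reports over any set of algorithm outputs.

Everything is testable without external data through seeded phantom
generators: polynomial depth surfaces with noise and outliers, analytic
sphere/ramp volumes, multiplicative-speckle image pairs, and a
hyperechoic honeycomb texture.

## Worked example

Fit a plane to a depth phantom in which 30 % of the pixels are corrupted
by +60 depth-unit outliers, then extract a sphere isosurface and score a
speckled honeycomb image:

```r
library(SonoRecon3D)

truth <- SurfacePatch(1, c(5, 1.5, -2))        # z = 5 + 1.5 x − 2 y
ph  <- makeDepthPhantom(20, 20, truth, noiseSigma = 0.1,
                        outlierFrac = 0.3, outlierMagnitude = 60, seed = 11)
pts <- depthImageToPoints(ph$image)

round(patchCoeffs(fittedPatch(leastSquaresFit(pts, tier = 1))), 3)
#> [1] 22.998  1.275 -1.856        # least squares is dragged off by outliers

rob <- lmedsFit(pts, tier = 1, nSubsets = 500, seed = 1)
round(patchCoeffs(fittedPatch(rob)), 3)
#> [1]  4.995  1.501 -2.001        # LMedS recovers the generating plane
rob
#> FitResult: tier-1 patch, chi^2 = 432172, median r^2 = 0.010237, 280/400 inliers

vol  <- makeVolumePhantom("sphere_volume", dims = c(17, 17, 17), spacing = 0.25)
mesh <- extractIsosurface(vol$grid, c = 1)     # radius-1 sphere: c = r²
mesh
#> TriMesh: 830 vertices, 1656 triangles, iso value 1
range(sqrt(rowSums(meshVertices(mesh)^2)))     # vertex radii hug r = 1
#> [1] 0.9764233 1.0000000

clean <- makeHoneycombImage(128, 128, seed = 2)
pair  <- makeSpecklePair(clean, noiseSigma = 0.15, seed = 3)
compareAlgorithms(clean, list(identity = clean, speckled = testImage(pair)))
#> QualityReport (reference: reference)
#>  algorithm  psnr_db psnr_band     ssim
#>   identity      Inf excellent 1.000000
#>   speckled 22.96551      poor 0.920461
```

The least-squares intercept is biased by ≈ +18 (30 % of the +60 outliers),
while the LMedS fit agrees with the generating plane to ~3 decimals; its
`chi^2` is large only because it is summed over the corrupted pixels too.
The `identity` row shows the identical-image sentinel (infinite PSNR,
SSIM exactly 1); the speckled copy lands in the "poor" PSNR band.

## Command line

A thin CLI over the same functions is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "sonorecon3d.R", package = "SonoRecon3D"))')
Rscript "$CLI" phantom --kind sphere_volume --dims 17,17,17 --spacing 0.25 --out sphere
Rscript "$CLI" isosurface --volume sphere.raw --iso 1 --out mesh   # mesh.obj + mesh.ply
Rscript "$CLI" metrics --reference ref.pgm --test denoised=out.pgm --out report
```

Subcommands: `phantom`, `fit`, `isosurface`, `metrics`; exit codes are 0
(success), 2 (usage error), 3 (data error); logs go to stderr, data only
to files.

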