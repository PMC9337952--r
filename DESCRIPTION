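Package: SonoRecon3D
Title: Surface and Volume Reconstruction with Image-Quality Assessment for
    3D Ultrasound
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Toolkit for intelligent three-dimensional reconstruction of
    ultrasound imagery: polynomial surface-patch models fitted to depth
    images by least squares, least-median-of-squares robust regression and
    thin-plate regularized regression; trilinear interpolation on voxel
    grids with watertight isosurface extraction by marching tetrahedra;
    and full-reference image-quality metrics (MSE, PSNR with decibel
    quality bands, SSIM) together with seeded synthetic phantoms (planes,
    polynomial patches, sphere and ramp volumes, speckle image pairs, and
    hyperechoic honeycomb textures) so every stage of the pipeline can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'depth-surface.R'
    'io.R'
    'phantoms.R'
    'quality-metrics.R'
    'robust-fit.R'
    'volume-recon.R'
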