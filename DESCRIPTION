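Package: craniofuse
Title: Region-Fusion Craniofacial Reconstruction from Corresponded Skull and Face Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical craniofacial reconstruction with a region-fusion strategy.
    Corresponded skull and face triangle meshes are segmented into five facial
    regions (left eye, right eye, nose, mouth, frame) by fuzzy c-means clustering
    on robust-PCA vertex features; each region of each modality is embedded in a
    low-dimensional latent space with a Gaussian process latent variable model
    (GP-LVM); least-squares support vector regression (LSSVR) with an RBF kernel
    maps skull latents (optionally augmented with age and BMI) to face latents;
    regional face predictions are fused into one smooth mesh by rigid positioning,
    contour-shrinking blend bands and thin-plate-spline splicing. Includes mesh
    I/O (OBJ, ascii PLY), a reconstruction-error metric, an end-to-end pipeline
    with a global (non-regional) baseline, and a synthetic generator of paired
    skull/face populations with known region-wise latent structure for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
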