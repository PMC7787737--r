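# craniofuse

Region-fusion craniofacial reconstruction: estimating a face surface from a
skull surface using skull–face shape relations learned from a database of
corresponded triangle meshes. It is aimed at researchers in forensic facial
reconstruction and statistical shape modelling who have (or can simulate)
skull/face pairs in dense point correspondence — every skull shares one mesh
topology, every face another, and vertex *i* means the same anatomical
location in each sample of a modality.

Because the skull–face relation differs between facial regions, the method
is regional end to end:

1. **Segmentation.** Fuzzy c-means (fuzzifier *m* = 2, *C* = 5 clusters) on
   per-vertex features built from robust-PCA-denoised, across-sample
   displacement covariation partitions skull and face into left eye, right
   eye, nose, mouth and frame.
2. **Latent embedding.** Per region and modality, a Gaussian process latent
   variable model (GP-LVM) with ARD squared-exponential kernel
   *k*(x, x′) = σ²_f exp(−½ Σ_d (x_d − x′_d)²/M_d) embeds the flattened
   region shapes in a low-dimensional latent space by maximizing
   L = −(D/2) log det(K + σ²_n I) − ½ tr((K + σ²_n I)⁻¹ Y Yᵀ) − (MD/2) log 2π.
3. **Regression.** Multi-output least-squares support vector regression
   (LSSVR, RBF kernel) maps skull latents — optionally augmented with
   z-scored age and BMI — to face latents; training reduces to the linear
   KKT system [[0, 1ᵀ], [1, Ω + I/C]]·[b; α] = [0; y], with (C, σ²) tuned
   by cross-validation from the customary initial values (1000, 100).
4. **Reconstruction and fusion.** An unknown skull's regions are projected
   into the skull latent spaces, mapped to face latents, decoded to
   regional face meshes, and spliced into one smooth face: each region
   boundary shrinks *k* rings to blend bands on both sides, and a pair of
   thin-plate splines moves the two boundaries to their midpoints
   P₂ = (P₀ + P₁)/2 while fixing the inner contours.

Accuracy is measured as the mean Euclidean vertex distance (mm) between
reconstruction and ground truth (`average_error`). A global
(non-regional) baseline — the identical pipeline with one region covering
the whole mesh — is included for comparison, as is a synthetic generator of
corresponded skull/face populations with known region-wise latent
structure, attribute effects and noise, so the whole chain is testable
without access to a private CT database.

## Worked example

Simulate a population, train the regional reconstructor, and score it on
held-out pairs:

```r
library(craniofuse)

cfg <- generator_config(seed = 42)           # 40x40 head grid, 72 pairs
pop <- sample_population(cfg)
sp  <- split_samples(pop$samples, n_test = 12, seed = 1)

conf   <- cfr_config(attributes = TRUE, tune = TRUE, seed = 1)
bundle <- train_cfr(sp$train, conf)
bundle
#> cfr_bundle: 5 region(s) [frame, nose, mouth, right_eye, left_eye], 60 training samples, S0 = 17.88 mm

report <- evaluate_cfr(bundle, sp$test)
report
#> Reconstruction error (mm):
#>     region    min    max   mean     sd
#>    overall 0.3983 1.6316 0.6938 0.3754
#>      frame 0.3650 1.7517 0.6969 0.4219
#>       nose 0.4880 2.3362 1.2475 0.5488
#>      mouth 0.3708 1.0097 0.6206 0.1762
#>  right_eye 0.3451 0.9629 0.5596 0.1807
#>   left_eye 0.3488 0.6758 0.4741 0.1001
```

The table is the per-region and fused-face reconstruction error over the 12
test pairs: with 0.2 mm vertex noise planted by the generator, the fused
face lands at 0.69 mm mean error. A single reconstruction against its
ground truth and against the mean-face predictor (predicting the training
mean face for everyone):

```r
p     <- sp$test$pairs[[1]]
recon <- reconstruct_face(bundle, p$skull, age = p$age, bmi = p$bmi)
average_error(recon, p$face)          # 1.154285  (mm)
average_error(bundle$mean_face, p$face)  # 2.918137  (mm)
```

Meshes are read and written as OBJ or ascii PLY (`read_mesh`,
`write_mesh`); populations as directories of OBJ files plus an
`attributes.csv` (`write_sample_set`, `read_sample_set`); trained bundles
as a JSON directory (`save_bundle`, `load_bundle`). A thin command-line
front end with `simulate`, `train`, `reconstruct` and `evaluate`
subcommands ships in `inst/cli/craniofuse.R`.

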