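#' Pipeline configuration
#'
#' Collects the tunable parameters of the full reconstructor with the
#' method's customary defaults: fuzzifier `m = 2` and `clusters = 5` for the
#' segmentation, LSSVR regularization `C_reg = 1000` and RBF width
#' `sigma2 = 100`, and a latent dimension of at most 8 (further capped at
#' the number of PCA modes above the noise floor, and at `M - 2`).
#'
#' @param q maximum latent dimension per region and modality.
#' @param m FCM fuzzifier.
#' @param clusters number of regions.
#' @param feature_dim PCA dimension of the clustered vertex features.
#' @param C_reg,sigma2 LSSVR hyperparameters (initial values when `tune`).
#' @param tune if `TRUE`, grid-search `(C_reg, sigma2)` by 5-fold CV.
#' @param S0 fusion shrink step in mm; `NULL` = 2 x mean edge length of the
#'   face template (two blend rings, matched to feature-region scale).
#' @param attributes if `TRUE`, augment the regression inputs with z-scored
#'   age and BMI.
#' @param gplvm_maxit,encode_maxit optimizer caps.
#' @param seed master seed for segmentation and any randomized step.
#' @export
cfr_config <- function(q = 8L, m = 2, clusters = 5L, feature_dim = 8L,
                       C_reg = 1000, sigma2 = 100, tune = FALSE, S0 = NULL,
                       attributes = FALSE, gplvm_maxit = 200L,
                       encode_maxit = 200L, seed = 1L) {
  structure(list(q = as.integer(q), m = m, clusters = as.integer(clusters),
                 feature_dim = as.integer(feature_dim), C_reg = C_reg,
                 sigma2 = sigma2, tune = tune, S0 = S0,
                 attributes = attributes,
                 gplvm_maxit = as.integer(gplvm_maxit),
                 encode_maxit = as.integer(encode_maxit),
                 seed = as.integer(seed)),
            class = "cfr_config")
}

# latent dimension actually used for a data matrix: PCA dimensions standing
# clearly above the noise floor (eigenvalue share > max(0.5%, 5x the median
# share) — shape spectra here are a few strong modes over a flat noise
# tail), capped at q_max and M - 2
choose_q <- function(Y, q_max) {
  M <- nrow(Y)
  Yc <- sweep(Y, 2L, colMeans(Y))
  ev <- svd(Yc, nu = 0L, nv = 0L)$d^2
  if (sum(ev) == 0) return(1L)
  frac <- ev / sum(ev)
  qn <- sum(frac > max(0.005, 5 * stats::median(frac)))
  max(1L, min(q_max, qn, M - 2L))
}

#' Train the region-fusion craniofacial reconstructor
#'
#' Segments the training meshes into regions (fuzzy c-means on spectral
#' features of the robust-PCA-denoised displacement trajectories, computed
#' once on the training set and transferred to any corresponded mesh by
#' vertex index), then per region fits a skull GP-LVM
#' and a face GP-LVM and trains a multi-output LSSVR from skull latents
#' (optionally attribute-augmented) to face latents.
#'
#' @param samples training [sample_set] (at least `q + 2` pairs).
#' @param config a [cfr_config()].
#' @param skull_labeling,face_labeling optional precomputed
#'   `region_labeling`s (e.g. planted or previously saved); segmentation is
#'   run only for the missing ones.
#' @return Object of class `cfr_bundle`.
#' @export
train_cfr <- function(samples, config = cfr_config(),
                      skull_labeling = NULL, face_labeling = NULL) {
  M <- n_samples(samples)
  if (M < 4L) stop("need at least 4 training samples")
  if (is.null(skull_labeling))
    skull_labeling <- segment_modality(samples, "skull", C = config$clusters,
                                       m = config$m,
                                       feature_dim = config$feature_dim,
                                       seed = config$seed)
  if (is.null(face_labeling))
    face_labeling <- segment_modality(samples, "face", C = config$clusters,
                                      m = config$m,
                                      feature_dim = config$feature_dim,
                                      seed = config$seed)
  regions <- face_labeling$names
  if (!setequal(regions, skull_labeling$names))
    stop("skull and face labelings disagree on region names")
  attrs <- attribute_table(samples)[, c("age", "bmi"), drop = FALSE]
  if (config$attributes && anyNA(attrs))
    stop("attribute augmentation requested but age/bmi missing")
  mean_face <- tri_mesh(Reduce(`+`, lapply(samples$pairs,
                                           function(p) p$face$vertices)) / M,
                        samples$face_faces)
  S0 <- if (is.null(config$S0)) 2 * mean_edge_length(mean_face) else config$S0
  models <- list()
  for (rn in regions) {
    sk_idx <- region_vertices(skull_labeling, rn)
    fa_idx <- region_vertices(face_labeling, rn)
    if (length(sk_idx) < 4L || length(fa_idx) < 4L)
      stop("region '", rn, "' has fewer than 4 vertices")
    Ys <- shape_matrix(samples, "skull", sk_idx)
    Yf <- shape_matrix(samples, "face", fa_idx)
    qs <- choose_q(Ys, config$q)
    qf <- choose_q(Yf, config$q)
    gs <- fit_gplvm(Ys, qs, maxit = config$gplvm_maxit, seed = config$seed,
                    modality = "skull", region = rn)
    gf <- fit_gplvm(Yf, qf, maxit = config$gplvm_maxit, seed = config$seed,
                    modality = "face", region = rn)
    Xin <- gs$X
    astats <- NULL
    if (config$attributes) {
      Xin <- augment_with_attributes(Xin, attrs)
      astats <- attr(Xin, "stats")
    }
    hp <- list(C_reg = config$C_reg, sigma2 = config$sigma2)
    if (config$tune)
      hp <- tune_hyperparams(Xin, gf$X, folds = 5L, seed = config$seed)
    reg <- train_multi(Xin, gf$X, C_reg = hp$C_reg, sigma2 = hp$sigma2)
    models[[rn]] <- list(skull = gs, face = gf, lssvr = reg,
                         attr_stats = astats,
                         C_reg = hp$C_reg, sigma2 = hp$sigma2)
  }
  structure(list(skull_labeling = skull_labeling,
                 face_labeling = face_labeling,
                 models = models, regions = regions,
                 mean_face = mean_face,
                 skull_faces = samples$skull_faces,
                 face_faces = samples$face_faces,
                 S0 = S0, config = config,
                 training_ids = sample_ids(samples)),
            class = "cfr_bundle")
}

#' @export
print.cfr_bundle <- function(x, ...) {
  cat(sprintf("cfr_bundle: %d region(s) [%s], %d training samples, S0 = %.2f mm\n",
              length(x$regions), paste(x$regions, collapse = ", "),
              length(x$training_ids), x$S0))
  invisible(x)
}

# encode a skull region, regress, decode the face region; returns the face
# region vertex matrix on the global face topology subset
reconstruct_region <- function(bundle, rn, skull, attrs) {
  m <- bundle$models[[rn]]
  sk_idx <- region_vertices(bundle$skull_labeling, rn)
  fa_idx <- region_vertices(bundle$face_labeling, rn)
  y <- flatten(skull, sk_idx)
  x_sk <- gplvm_encode(m$skull, y, maxit = bundle$config$encode_maxit)
  xin <- matrix(x_sk, nrow = 1L)
  if (bundle$config$attributes) {
    xin <- augment_with_attributes(xin, attrs, stats = m$attr_stats)
  }
  x_fa <- predict_multi(m$lssvr, xin)
  dec <- gplvm_decode(m$face, as.numeric(x_fa))
  list(vertices = unflatten(dec$mean), index = fa_idx)
}

#' Reconstruct a face from an unknown skull
#'
#' Per region: the skull region is projected into its latent space, the
#' LSSVR maps the skull latent (plus optional z-scored attributes) to the
#' face latent, and the face GP-LVM decodes a regional face. The frame
#' reconstruction plus the regional reconstructions assemble the initial
#' fused face, and [fuse_regions()] splices the four feature regions onto
#' the frame base with thin-plate-spline blend bands.
#'
#' @param bundle a [train_cfr()] bundle.
#' @param skull a [tri_mesh] in correspondence with the training skull
#'   topology.
#' @param age,bmi attributes of the target individual; required when the
#'   bundle was trained with `attributes = TRUE`.
#' @param fuse if `FALSE`, return the unspliced initial fusion.
#' @return Reconstructed face [tri_mesh] on the global face topology.
#' @export
reconstruct_face <- function(bundle, skull, age = NA_real_, bmi = NA_real_,
                             fuse = TRUE) {
  if (n_vertices(skull) != length(bundle$skull_labeling$label))
    stop("skull does not match the training skull topology")
  attrs <- data.frame(age = age, bmi = bmi)
  if (bundle$config$attributes && anyNA(attrs))
    stop("bundle was trained with attributes; supply age and bmi")
  parts <- lapply(stats::setNames(bundle$regions, bundle$regions),
                  function(rn) reconstruct_region(bundle, rn, skull, attrs))
  # initial fusion: every region contributes its own vertices
  base_v <- bundle$mean_face$vertices
  for (p in parts) base_v[p$index, ] <- p$vertices
  base <- tri_mesh(base_v, bundle$face_faces)
  if (length(bundle$regions) == 1L || !fuse) return(base)
  # if the learned segmentation makes splicing geometrically infeasible
  # (overlapping blend bands, regions without interior), fall back to the
  # initial fusion, which is already a complete face
  tryCatch({
    feature_parts <- lapply(
      stats::setNames(setdiff(bundle$regions, "frame"),
                      setdiff(bundle$regions, "frame")),
      function(rn) {
        sub <- region_submesh(base, bundle$face_labeling, rn)
        list(mesh = sub$mesh, index_map = sub$index_map)
      })
    fuse_regions(base, feature_parts, bundle$face_labeling, S0 = bundle$S0,
                 align = FALSE)
  }, error = function(e) {
    warning("region splicing infeasible (", conditionMessage(e),
            "); returning the initial fusion")
    base
  })
}

#' Train / reconstruct with the global (non-regional) baseline
#'
#' The identical pipeline with a single region covering the whole mesh:
#' one skull GP-LVM, one face GP-LVM, one LSSVR, no fusion step.
#'
#' @inheritParams train_cfr
#' @export
train_cfr_global <- function(samples, config = cfr_config()) {
  nsk <- n_vertices(samples$pairs[[1L]]$skull)
  nfa <- n_vertices(samples$pairs[[1L]]$face)
  train_cfr(samples, config,
            skull_labeling = region_labeling(rep(1L, nsk), "global", "skull"),
            face_labeling = region_labeling(rep(1L, nfa), "global", "face"))
}

#' @rdname train_cfr_global
#' @inheritParams reconstruct_face
#' @export
reconstruct_global <- function(bundle, skull, age = NA_real_, bmi = NA_real_) {
  reconstruct_face(bundle, skull, age = age, bmi = bmi, fuse = FALSE)
}

#' Evaluate a reconstructor on a held-out test set
#'
#' Reconstructs every test skull, scores it against the true face with
#' [average_error()], and tabulates per-region statistics (min, max, mean,
#' s.d. over samples; regional errors are computed on the region vertex
#' subsets of the fused face).
#'
#' @param bundle a trained `cfr_bundle`.
#' @param test a [sample_set] sharing the training topologies.
#' @param baseline optional second bundle (e.g. the global one) evaluated on
#'   the same pairs for comparison.
#' @return Object of class `cfr_evaluation`: `per_sample` (data frame of
#'   per-sample, per-region errors in mm), `stats` (the summary table),
#'   and optionally `baseline_per_sample`.
#' @export
evaluate_cfr <- function(bundle, test, baseline = NULL) {
  if (n_samples(test) < 1L) stop("empty test set")
  regions <- bundle$regions
  rows <- lapply(test$pairs, function(p) {
    recon <- reconstruct_face(bundle, p$skull, age = p$age, bmi = p$bmi)
    err <- c(overall = average_error(recon, p$face),
             vapply(stats::setNames(regions, regions), function(rn) {
               idx <- region_vertices(bundle$face_labeling, rn)
               average_error(recon$vertices[idx, , drop = FALSE],
                             p$face$vertices[idx, , drop = FALSE])
             }, numeric(1L)))
    c(list(id = p$id), as.list(err))
  })
  per_sample <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  stat_cols <- setdiff(names(per_sample), "id")
  stats_tab <- do.call(rbind, lapply(stat_cols, function(cn) {
    x <- per_sample[[cn]]
    data.frame(region = cn, min = min(x), max = max(x), mean = mean(x),
               sd = if (length(x) > 1L) stats::sd(x) else 0,
               stringsAsFactors = FALSE)
  }))
  out <- list(per_sample = per_sample, stats = stats_tab)
  if (!is.null(baseline)) {
    base_err <- vapply(test$pairs, function(p) {
      recon <- reconstruct_face(baseline, p$skull, age = p$age, bmi = p$bmi)
      average_error(recon, p$face)
    }, numeric(1L))
    out$baseline_per_sample <- data.frame(id = sample_ids(test),
                                          overall = base_err,
                                          stringsAsFactors = FALSE)
  }
  structure(out, class = "cfr_evaluation")
}

#' @export
print.cfr_evaluation <- function(x, ...) {
  cat("Reconstruction error (mm):\n")
  print(x$stats, row.names = FALSE, digits = 4)
  if (!is.null(x$baseline_per_sample))
    cat(sprintf("baseline mean overall error: %.4f mm\n",
                mean(x$baseline_per_sample$overall)))
  invisible(x)
}

#' Write an evaluation report to CSV
#'
#' Writes `per_sample.csv` and `summary.csv` (and `baseline_per_sample.csv`
#' when present) into `dir`; numeric formatting is fixed so repeated runs
#' under the same seeds are byte-identical.
#'
#' @param report a `cfr_evaluation`.
#' @param dir output directory.
#' @export
write_evaluation <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(d) {
    for (cn in names(d)) if (is.numeric(d[[cn]])) d[[cn]] <- sprintf("%.9g", d[[cn]])
    d
  }
  utils::write.csv(fmt(report$per_sample), file.path(dir, "per_sample.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(fmt(report$stats), file.path(dir, "summary.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(report$baseline_per_sample))
    utils::write.csv(fmt(report$baseline_per_sample),
                     file.path(dir, "baseline_per_sample.csv"),
                     row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Mean signed offset along outward vertex normals
#'
#' Average of `(a_i - b_i) . n_i` over vertices, with normals taken from
#' `b`; positive when `a` lies outside `b`. Used to quantify the attribute
#' response (e.g. BMI 30 vs BMI 20 reconstructions of one skull).
#'
#' @param a,b corresponded [tri_mesh]es.
#' @export
mean_normal_offset <- function(a, b) {
  nrm <- vertex_normals(b)
  mean(rowSums((a$vertices - b$vertices) * nrm))
}
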