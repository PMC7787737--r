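# Bundle persistence: everything numeric goes into one JSON document (full
# double precision via digits = NA); Cholesky caches are rebuilt on load.

gplvm_to_list <- function(g) {
  list(X = g$X, Yc = g$Yc, mean = g$mean,
       lengthscales = g$params$lengthscales, sf2 = g$params$sf2,
       sn2 = g$params$sn2, q = g$q, objective = g$objective,
       objective_init = g$objective_init, modality = g$modality,
       region = g$region, seed = g$seed)
}

gplvm_from_list <- function(l) {
  X <- as.matrix(l$X); Yc <- as.matrix(l$Yc)
  params <- list(lengthscales = as.numeric(l$lengthscales),
                 sf2 = l$sf2, sn2 = l$sn2)
  ch <- chol_with_jitter(se_kernel_matrix(X, X, params) +
                           diag(params$sn2, nrow(X)))
  alpha <- backsolve(ch$chol, forwardsolve(t(ch$chol), Yc))
  structure(list(X = X, Yc = Yc, mean = as.numeric(l$mean), params = params,
                 chol = ch$chol, jitter = ch$jitter, alpha = alpha,
                 q = as.integer(l$q), objective_init = l$objective_init,
                 objective = l$objective, modality = l$modality,
                 region = l$region, seed = l$seed),
            class = "gplvm")
}

#' Save / load a trained reconstructor bundle
#'
#' The bundle is persisted as a directory holding one JSON document
#' (`bundle.json`, full-precision numbers) plus the two labeling CSVs for
#' human inspection.
#'
#' @param bundle a `cfr_bundle`.
#' @param dir target directory (created if missing).
#' @export
save_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  doc <- list(
    regions = bundle$regions,
    skull_label = bundle$skull_labeling$label,
    skull_names = bundle$skull_labeling$names,
    face_label = bundle$face_labeling$label,
    face_names = bundle$face_labeling$names,
    mean_face_vertices = bundle$mean_face$vertices,
    skull_faces = bundle$skull_faces,
    face_faces = bundle$face_faces,
    S0 = bundle$S0,
    config = unclass(bundle$config),
    training_ids = bundle$training_ids,
    models = lapply(bundle$models, function(m) {
      list(skull = gplvm_to_list(m$skull), face = gplvm_to_list(m$face),
           lssvr = list(X = m$lssvr$X, alpha = m$lssvr$alpha, b = m$lssvr$b,
                        sigma2 = m$lssvr$sigma2, C_reg = m$lssvr$C_reg,
                        center = m$lssvr$center, scale = m$lssvr$scale),
           attr_stats = m$attr_stats, C_reg = m$C_reg, sigma2 = m$sigma2)
    }))
  jsonlite::write_json(doc, file.path(dir, "bundle.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_labeling(bundle$skull_labeling, file.path(dir, "skull_labels.csv"))
  write_labeling(bundle$face_labeling, file.path(dir, "face_labels.csv"))
  invisible(NULL)
}

#' @rdname save_bundle
#' @param dir directory written by [save_bundle()].
#' @export
load_bundle <- function(dir) {
  doc <- jsonlite::read_json(file.path(dir, "bundle.json"),
                             simplifyVector = TRUE)
  cfg <- doc$config
  config <- cfr_config(q = cfg$q, m = cfg$m, clusters = cfg$clusters,
                       feature_dim = cfg$feature_dim, C_reg = cfg$C_reg,
                       sigma2 = cfg$sigma2, tune = cfg$tune,
                       S0 = if (is.null(cfg$S0)) NULL else cfg$S0,
                       attributes = cfg$attributes,
                       gplvm_maxit = cfg$gplvm_maxit,
                       encode_maxit = cfg$encode_maxit, seed = cfg$seed)
  models <- lapply(doc$models, function(m) {
    ls <- m$lssvr
    reg <- structure(list(X = as.matrix(ls$X), alpha = as.matrix(ls$alpha),
                          b = as.numeric(ls$b), sigma2 = ls$sigma2,
                          C_reg = ls$C_reg, center = as.numeric(ls$center),
                          scale = as.numeric(ls$scale)),
                     class = "multi_lssvr")
    ast <- m$attr_stats
    if (!is.null(ast)) ast <- list(center = as.numeric(ast$center),
                                   scale = as.numeric(ast$scale))
    list(skull = gplvm_from_list(m$skull), face = gplvm_from_list(m$face),
         lssvr = reg, attr_stats = ast, C_reg = m$C_reg, sigma2 = m$sigma2)
  })
  structure(list(
    skull_labeling = region_labeling(doc$skull_label, doc$skull_names, "skull"),
    face_labeling = region_labeling(doc$face_label, doc$face_names, "face"),
    models = models, regions = doc$regions,
    mean_face = tri_mesh(as.matrix(doc$mean_face_vertices),
                         as.matrix(doc$face_faces)),
    skull_faces = matrix(as.integer(as.matrix(doc$skull_faces)),
                         ncol = 3L),
    face_faces = matrix(as.integer(as.matrix(doc$face_faces)), ncol = 3L),
    S0 = doc$S0, config = config, training_ids = doc$training_ids),
    class = "cfr_bundle")
}
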