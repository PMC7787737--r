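#' Corresponded skull/face sample pair
#'
#' @param skull,face [tri_mesh] objects in dense correspondence with the
#'   reference topologies of their sample set.
#' @param id unique sample identifier.
#' @param age age in years; `bmi` body mass index in kg/m^2.
#' @param sex optional sex flag (character), not used by the default models.
#' @export
corresponded_pair <- function(skull, face, id, age = NA_real_, bmi = NA_real_,
                              sex = NA_character_) {
  validate_tri_mesh(skull); validate_tri_mesh(face)
  structure(list(skull = skull, face = face, id = as.character(id),
                 age = as.numeric(age), bmi = as.numeric(bmi), sex = sex),
            class = "corresponded_pair")
}

#' Corresponded sample set
#'
#' The training unit: a list of [corresponded_pair]s sharing one skull
#' topology and one face topology (dense point correspondence — vertex `i`
#' is the same anatomical location in every sample of a modality).
#'
#' @param pairs list of [corresponded_pair].
#' @return Object of class `sample_set` with `pairs`, `skull_faces`,
#'   `face_faces`.
#' @export
sample_set <- function(pairs) {
  if (length(pairs) == 0L) stop("sample_set: no pairs")
  ids <- vapply(pairs, function(p) p$id, character(1L))
  if (anyDuplicated(ids)) stop("sample_set: duplicate sample ids")
  sf <- pairs[[1L]]$skull$faces; ff <- pairs[[1L]]$face$faces
  nsk <- n_vertices(pairs[[1L]]$skull); nfa <- n_vertices(pairs[[1L]]$face)
  for (p in pairs) {
    if (n_vertices(p$skull) != nsk || !identical(p$skull$faces, sf))
      stop("sample_set: skull topology mismatch for sample ", p$id)
    if (n_vertices(p$face) != nfa || !identical(p$face$faces, ff))
      stop("sample_set: face topology mismatch for sample ", p$id)
  }
  structure(list(pairs = pairs, skull_faces = sf, face_faces = ff),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("sample_set: %d pairs, skull %d vertices, face %d vertices\n",
              length(x$pairs), n_vertices(x$pairs[[1L]]$skull),
              n_vertices(x$pairs[[1L]]$face)))
  invisible(x)
}

n_samples <- function(samples) length(samples$pairs)

sample_ids <- function(samples)
  vapply(samples$pairs, function(p) p$id, character(1L))

# M x 3n matrix of flattened shape vectors for one modality
shape_matrix <- function(samples, modality = c("skull", "face"),
                         vertex_subset = NULL) {
  modality <- match.arg(modality)
  do.call(rbind, lapply(samples$pairs, function(p)
    flatten(p[[modality]], vertex_subset)))
}

attribute_table <- function(samples) {
  data.frame(id = sample_ids(samples),
             age = vapply(samples$pairs, function(p) p$age, numeric(1L)),
             bmi = vapply(samples$pairs, function(p) p$bmi, numeric(1L)),
             stringsAsFactors = FALSE)
}

#' Write a sample set to a directory
#'
#' Writes `<id>_skull.obj` and `<id>_face.obj` per pair plus an
#' `attributes.csv` with columns `id,age,bmi`.
#' @param samples a [sample_set].
#' @param dir output directory (created if missing).
#' @export
write_sample_set <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in samples$pairs) {
    write_mesh(p$skull, file.path(dir, paste0(p$id, "_skull.obj")))
    write_mesh(p$face, file.path(dir, paste0(p$id, "_face.obj")))
  }
  utils::write.csv(attribute_table(samples),
                   file.path(dir, "attributes.csv"), row.names = FALSE)
  invisible(NULL)
}

#' Read a sample set written by [write_sample_set()]
#' @param dir directory containing `attributes.csv` and per-sample OBJ files.
#' @export
read_sample_set <- function(dir) {
  at <- utils::read.csv(file.path(dir, "attributes.csv"),
                        stringsAsFactors = FALSE)
  if (!all(c("id", "age", "bmi") %in% names(at)))
    stop("attributes.csv must have columns id,age,bmi")
  pairs <- lapply(seq_len(nrow(at)), function(i) {
    id <- as.character(at$id[[i]])
    corresponded_pair(
      skull = read_mesh(file.path(dir, paste0(id, "_skull.obj"))),
      face = read_mesh(file.path(dir, paste0(id, "_face.obj"))),
      id = id, age = at$age[[i]], bmi = at$bmi[[i]])
  })
  sample_set(pairs)
}

#' Seeded train/test split of a sample set
#'
#' Mirrors the study design of holding out a random test set from the
#' corresponded database.
#'
#' @param samples a [sample_set].
#' @param n_test number of held-out pairs.
#' @param seed integer seed; the split is deterministic given the seed.
#' @return List with `train` and `test` sample sets.
#' @export
split_samples <- function(samples, n_test, seed = 1L) {
  M <- n_samples(samples)
  if (n_test < 1L || n_test >= M) stop("n_test must be in [1, n_samples)")
  idx <- local({ set.seed(as.integer(seed)); sample.int(M, n_test) })
  list(train = sample_set(samples$pairs[-idx]),
       test = sample_set(samples$pairs[idx]))
}
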