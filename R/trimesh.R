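#' Triangle mesh
#'
#' The universal shape carrier of the package: an `n x 3` vertex matrix in
#' millimetres and an `m x 3` integer face matrix of vertex indices (1-based,
#' triangles only). All meshes of one modality in a corresponded sample set
#' share one face matrix, so vertex `i` means the same anatomical location in
#' every sample.
#'
#' @param vertices numeric matrix, `n x 3`, finite coordinates in mm.
#' @param faces integer matrix, `m x 3`, vertex indices in `1..n`; may have
#'   zero rows (a point cloud).
#' @return An object of class `tri_mesh` with elements `vertices` and `faces`.
#' @export
tri_mesh <- function(vertices, faces = matrix(integer(), 0L, 3L)) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  faces <- as.matrix(faces)
  if (length(faces) == 0L) faces <- matrix(integer(), 0L, 3L)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix of vertex indices")
  m <- structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
  validate_tri_mesh(m)
  m
}

validate_tri_mesh <- function(m) {
  if (!all(is.finite(m$vertices))) stop("tri_mesh: non-finite vertex coordinate")
  n <- nrow(m$vertices)
  if (nrow(m$faces) > 0L) {
    if (any(m$faces < 1L) || any(m$faces > n))
      stop("tri_mesh: face index out of range [1, ", n, "]")
    dup <- m$faces[, 1L] == m$faces[, 2L] | m$faces[, 2L] == m$faces[, 3L] |
      m$faces[, 1L] == m$faces[, 3L]
    if (any(dup)) stop("tri_mesh: face with a repeated vertex index")
  }
  invisible(m)
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d faces\n", nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)

#' Read a triangle mesh from OBJ or ascii PLY
#'
#' OBJ `f` records are 1-based on disk and kept 1-based internally; vertex
#' order is preserved exactly as in the file. Non-triangular faces are
#' rejected rather than triangulated, so that dense-correspondence semantics
#' stay unambiguous.
#'
#' @param path file path.
#' @param format `"obj"` or `"ply"`; default guessed from the extension.
#' @return A [tri_mesh].
#' @export
read_mesh <- function(path, format = c("auto", "obj", "ply")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("obj", "ply")) stop("cannot guess mesh format from extension: ", path)
    format <- ext
  }
  if (!file.exists(path)) stop("mesh file does not exist: ", path)
  if (format == "obj") read_obj(path) else read_ply(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- list(); fl <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "#")) next
    tok <- strsplit(ln, "[[:space:]]+")[[1L]]
    if (tok[1L] == "v") {
      xyz <- suppressWarnings(as.numeric(tok[2:4]))
      if (length(tok) < 4L || anyNA(xyz))
        stop("malformed OBJ vertex at line ", i, " of ", path)
      vl[[length(vl) + 1L]] <- xyz
    } else if (tok[1L] == "f") {
      idx <- tok[-1L]
      if (length(idx) != 3L)
        stop("non-triangle face (", length(idx), " vertices) at line ", i, " of ", path)
      ii <- suppressWarnings(as.integer(sub("/.*$", "", idx)))
      if (anyNA(ii)) stop("malformed OBJ face at line ", i, " of ", path)
      fl[[length(fl) + 1L]] <- ii
    }
  }
  v <- if (length(vl)) do.call(rbind, vl) else matrix(numeric(), 0L, 3L)
  f <- if (length(fl)) do.call(rbind, fl) else matrix(integer(), 0L, 3L)
  tri_mesh(v, f)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || trimws(lines[1L]) != "ply")
    stop("not a PLY file: ", path)
  nv <- nf <- NA_integer_; hdr_end <- NA_integer_
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1L]]
    if (length(tok) >= 1L && tok[1L] == "format" && tok[2L] != "ascii")
      stop("only ascii PLY is supported: ", path)
    if (length(tok) >= 3L && tok[1L] == "element") {
      if (tok[2L] == "vertex") nv <- as.integer(tok[3L])
      if (tok[2L] == "face") nf <- as.integer(tok[3L])
    }
    if (length(tok) >= 1L && tok[1L] == "end_header") { hdr_end <- i; break }
  }
  if (is.na(hdr_end) || is.na(nv)) stop("malformed PLY header in ", path)
  if (is.na(nf)) nf <- 0L
  body <- lines[(hdr_end + 1L):length(lines)]
  body <- body[trimws(body) != ""]
  if (length(body) < nv + nf) stop("truncated PLY body in ", path)
  v <- matrix(NA_real_, nv, 3L)
  for (i in seq_len(nv)) {
    xyz <- suppressWarnings(as.numeric(strsplit(trimws(body[[i]]), "[[:space:]]+")[[1L]][1:3]))
    if (anyNA(xyz)) stop("malformed PLY vertex at body line ", i, " of ", path)
    v[i, ] <- xyz
  }
  f <- matrix(integer(), nf, 3L)
  for (i in seq_len(nf)) {
    tok <- suppressWarnings(as.integer(strsplit(trimws(body[[nv + i]]), "[[:space:]]+")[[1L]]))
    if (anyNA(tok[1L]) || tok[1L] != 3L)
      stop("non-triangle PLY face at body line ", nv + i, " of ", path)
    f[i, ] <- tok[2:4] + 1L  # PLY indices are 0-based on disk
  }
  tri_mesh(v, f)
}

#' Write a triangle mesh as OBJ or ascii PLY
#'
#' @param mesh a [tri_mesh]; meshes with non-finite vertices are refused.
#' @param path output file path.
#' @param format `"obj"` or `"ply"`; default guessed from the extension.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "obj", "ply")) {
  format <- match.arg(format)
  validate_tri_mesh(mesh)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("obj", "ply")) stop("cannot guess mesh format from extension: ", path)
    format <- ext
  }
  v <- mesh$vertices; f <- mesh$faces
  if (format == "obj") {
    out <- c(
      sprintf("v %.9g %.9g %.9g", v[, 1L], v[, 2L], v[, 3L]),
      if (nrow(f)) sprintf("f %d %d %d", f[, 1L], f[, 2L], f[, 3L])
    )
  } else {
    out <- c(
      "ply", "format ascii 1.0",
      sprintf("element vertex %d", nrow(v)),
      "property double x", "property double y", "property double z",
      sprintf("element face %d", nrow(f)),
      "property list uchar int vertex_indices",
      "end_header",
      sprintf("%.9g %.9g %.9g", v[, 1L], v[, 2L], v[, 3L]),
      if (nrow(f)) sprintf("3 %d %d %d", f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L)
    )
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(out, con)
  invisible(NULL)
}

#' Flatten mesh vertices to a shape vector
#'
#' Shape vectors are the flat `(x1, y1, z1, ..., xN, yN, zN)` representation
#' (mm) used by the latent-variable models; under a fixed topology they
#' round-trip losslessly with the vertex matrix via [unflatten()].
#'
#' @param mesh a [tri_mesh].
#' @param vertex_subset optional integer vector of vertex indices to keep
#'   (e.g. one region), in the given order.
#' @return Numeric vector of length `3 * length(subset)`.
#' @export
flatten <- function(mesh, vertex_subset = NULL) {
  v <- mesh$vertices
  if (!is.null(vertex_subset)) {
    if (any(vertex_subset < 1L) || any(vertex_subset > nrow(v)))
      stop("vertex_subset index out of range")
    v <- v[vertex_subset, , drop = FALSE]
  }
  as.vector(t(v))
}

#' Rebuild a vertex matrix (or mesh) from a shape vector
#'
#' @param values numeric vector of length divisible by 3.
#' @param faces optional face matrix; if supplied a [tri_mesh] is returned,
#'   otherwise the bare vertex matrix.
#' @export
unflatten <- function(values, faces = NULL) {
  if (length(values) %% 3L != 0L) stop("shape vector length must be divisible by 3")
  v <- matrix(values, ncol = 3L, byrow = TRUE)
  if (is.null(faces)) v else tri_mesh(v, faces)
}

#' Canonical pose normalization from anchor vertices
#'
#' Stand-in for anatomical (Frankfurt-plane) alignment: the anchor centroid is
#' moved to the origin, the mean anchor distance is scaled to 1, and the
#' rotation is fixed by the orthonormal frame spanned by the first anchor
#' differences. The output is invariant to any similarity transform (proper
#' rotation + translation + uniform scale) of the input.
#'
#' @param mesh a [tri_mesh].
#' @param anchor_indices at least 3 non-collinear vertex indices.
#' @return List with `mesh` (normalized) and `transform`
#'   (`rotation`, `scale`, `center`): normalized = R (v - center) / scale.
#' @export
normalize_pose <- function(mesh, anchor_indices) {
  if (length(anchor_indices) < 3L) stop("need at least 3 anchor indices")
  a <- mesh$vertices[anchor_indices, , drop = FALSE]
  ctr <- colMeans(a)
  ac <- sweep(a, 2L, ctr)
  s <- mean(sqrt(rowSums(ac^2)))
  if (s <= 0) stop("anchors are coincident")
  u <- ac[2L, ] - ac[1L, ]
  w <- ac[3L, ] - ac[1L, ]
  e3 <- c(u[2L] * w[3L] - u[3L] * w[2L],
          u[3L] * w[1L] - u[1L] * w[3L],
          u[1L] * w[2L] - u[2L] * w[1L])
  n3 <- sqrt(sum(e3^2))
  if (n3 < 1e-12 * sqrt(sum(u^2)) * sqrt(sum(w^2)) || sum(u^2) == 0)
    stop("anchor vertices are collinear")
  e1 <- u / sqrt(sum(u^2))
  e3 <- e3 / n3
  e2 <- c(e3[2L] * e1[3L] - e3[3L] * e1[2L],
          e3[3L] * e1[1L] - e3[1L] * e1[3L],
          e3[1L] * e1[2L] - e3[2L] * e1[1L])
  R <- rbind(e1, e2, e3, deparse.level = 0L)
  vn <- sweep(mesh$vertices, 2L, ctr) %*% t(R) / s
  list(mesh = tri_mesh(vn, mesh$faces),
       transform = list(rotation = R, scale = s, center = ctr))
}

#' Average reconstruction error between corresponded meshes
#'
#' The evaluation metric of the method: the mean Euclidean distance (mm)
#' between corresponding vertices of a reconstructed and a ground-truth face,
#' `averageError = (1/n) * sum_i ||recon_i - truth_i||`.
#'
#' @param recon,truth [tri_mesh] objects (or vertex matrices) with identical
#'   vertex counts in dense correspondence.
#' @return Non-negative scalar, mm.
#' @export
average_error <- function(recon, truth) {
  vr <- if (inherits(recon, "tri_mesh")) recon$vertices else as.matrix(recon)
  vt <- if (inherits(truth, "tri_mesh")) truth$vertices else as.matrix(truth)
  if (nrow(vr) != nrow(vt)) stop("vertex counts differ: ", nrow(vr), " vs ", nrow(vt))
  mean(sqrt(rowSums((vr - vt)^2)))
}

## ---- mesh topology helpers ----

# unique undirected edges as a 2-column matrix
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  unique(e)
}

mean_edge_length <- function(mesh) {
  e <- mesh_edges(mesh)
  if (nrow(e) == 0L) stop("mesh has no edges")
  mean(sqrt(rowSums((mesh$vertices[e[, 1L], , drop = FALSE] -
                       mesh$vertices[e[, 2L], , drop = FALSE])^2)))
}

# adjacency list over unique edges
vertex_adjacency <- function(mesh) {
  e <- mesh_edges(mesh)
  n <- n_vertices(mesh)
  adj <- vector("list", n)
  if (nrow(e)) {
    sp1 <- split(e[, 2L], e[, 1L])
    sp2 <- split(e[, 1L], e[, 2L])
    for (k in names(sp1)) adj[[as.integer(k)]] <- c(adj[[as.integer(k)]], sp1[[k]])
    for (k in names(sp2)) adj[[as.integer(k)]] <- c(adj[[as.integer(k)]], sp2[[k]])
  }
  adj
}

# area-weighted outward vertex normals (unit length); orientation follows faces
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  n <- matrix(0, nrow(v), 3L)
  p1 <- v[f[, 1L], , drop = FALSE]
  p2 <- v[f[, 2L], , drop = FALSE]
  p3 <- v[f[, 3L], , drop = FALSE]
  u <- p2 - p1; w <- p3 - p1
  fn <- cbind(u[, 2L] * w[, 3L] - u[, 3L] * w[, 2L],
              u[, 3L] * w[, 1L] - u[, 1L] * w[, 3L],
              u[, 1L] * w[, 2L] - u[, 2L] * w[, 1L])
  for (k in 1:3) {
    n[, 1L] <- n[, 1L] + unname(tapply_add(fn[, 1L], f[, k], nrow(v)))
    n[, 2L] <- n[, 2L] + unname(tapply_add(fn[, 2L], f[, k], nrow(v)))
    n[, 3L] <- n[, 3L] + unname(tapply_add(fn[, 3L], f[, k], nrow(v)))
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

tapply_add <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

# BFS graph distance (in edge hops) from a seed set, restricted to `allowed`
# vertices (seeds themselves need not be in `allowed`); unreached = Inf
graph_distance <- function(adj, seeds, allowed) {
  n <- length(adj)
  ok <- logical(n); ok[allowed] <- TRUE
  d <- rep(Inf, n)
  d[seeds] <- 0
  frontier <- seeds
  k <- 0L
  while (length(frontier)) {
    k <- k + 1L
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[ok[nxt] & d[nxt] == Inf]
    d[nxt] <- k
    frontier <- nxt
  }
  d
}
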