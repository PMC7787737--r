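#' Per-vertex displacement trajectories for craniofacial segmentation
#'
#' Row `j` is the across-sample trajectory of vertex `j`'s displacement from
#' the population mean, projected on the mean-mesh outward normal (the
#' soft-tissue displacement scalar, in mm): an `N x M` matrix. Vertices that
#' move together across the population — the behaviour the regional models
#' exploit — have correlated rows.
#'
#' @param samples a [sample_set] with at least 2 pairs.
#' @param modality `"skull"` or `"face"`.
#' @return Numeric matrix, one row per vertex, one column per sample;
#'   attribute `mean_mesh` holds the population mean [tri_mesh].
#' @export
build_vertex_features <- function(samples, modality = c("skull", "face")) {
  modality <- match.arg(modality)
  if (n_samples(samples) < 2L) stop("need at least 2 samples for features")
  Vs <- lapply(samples$pairs, function(p) p[[modality]]$vertices)
  mu <- Reduce(`+`, Vs) / length(Vs)
  mean_mesh <- tri_mesh(mu, samples[[paste0(modality, "_faces")]])
  nrm <- vertex_normals(mean_mesh)
  traj <- vapply(Vs, function(V) rowSums((V - mu) * nrm), numeric(nrow(mu)))
  traj <- traj - rowMeans(traj)
  # covariate adjustment: attribute effects (age, BMI) are global soft-tissue
  # modes, uninformative for a partition into local regions — residualize
  # them out when the attributes are known
  at <- attribute_table(samples)
  A <- as.matrix(at[, c("age", "bmi")])
  A <- A[, apply(A, 2L, function(x) !anyNA(x) && stats::sd(x) > 0), drop = FALSE]
  if (ncol(A)) {
    A <- scale(A)
    traj <- traj - traj %*% A %*% solve(crossprod(A), t(A))
  }
  structure(traj, mean_mesh = mean_mesh)
}

#' Spectral shape features from displacement trajectories
#'
#' Turns per-vertex displacement trajectories into clusterable features in
#' three steps. (1) The trajectory matrix is denoised with robust PCA and
#' *global* deformation modes — singular vectors whose energy spreads over a
#' large fraction of vertices, such as overall size and attribute effects —
#' are projected out, since they carry no information about a partition into
#' local regions. (2) The remaining localized covariation defines an
#' affinity `|cor|` between vertices (small entries thresholded to zero, the
#' threshold scaled to the sampling noise `~2.5/sqrt(M)`), whose normalized
#' spectral embedding separates groups of co-moving vertices. (3) Each
#' vertex's embedding direction is weighted by its residual energy share, so
#' vertices without localized variation (the frame) collapse into one tight
#' cluster near the origin.
#'
#' @param traj `N x M` trajectory matrix from [build_vertex_features()].
#' @param n_eigen embedding dimensions (default 6).
#' @param pr_threshold participation-ratio fraction above which a mode
#'   counts as global (default 0.2; a single removal pass, so that weaker
#'   modes mixing a local region with frame leftovers are not eaten).
#' @param affinity_threshold absolute-correlation floor; default
#'   `max(0.35, 2.5/sqrt(M))`.
#' @return `N x (n_eigen + 1)` feature matrix for [fcm_cluster()].
#' @export
spectral_shape_features <- function(traj, n_eigen = 6L, pr_threshold = 0.2,
                                    affinity_threshold = NULL) {
  traj <- as.matrix(traj)
  M <- ncol(traj)
  if (is.null(affinity_threshold))
    affinity_threshold <- max(0.35, 2.5 / sqrt(M))
  # conservative sparsity weight: S should catch gross outliers only —
  # at the standard lambda, spatially localized region modes themselves
  # look "sparse" and would be stripped from L
  dec <- rpca_decompose(traj, lambda = 4 / sqrt(max(dim(traj))),
                        max_iter = 100L, tol = 1e-6)
  L <- dec$L
  tot <- sqrt(rowSums(traj^2))
  k <- min(10L, dim(L) - 1L)
  sv <- svd(L, nu = k, nv = k)
  pr <- apply(sv$u, 2L, function(u) (sum(u^2)^2 / sum(u^4)) / length(u))
  glob <- pr > pr_threshold
  if (any(glob)) {
    L <- L - sv$u[, glob, drop = FALSE] %*%
      (sv$d[seq_len(k)][glob] * t(sv$v[, glob, drop = FALSE]))
  }
  res <- sqrt(rowSums(L^2))
  rho <- res / pmax(tot, 1e-12)
  rho <- rho / max(rho, 1e-12)
  Ln <- L / pmax(res, 1e-12)
  A <- abs(tcrossprod(Ln))
  A[A < affinity_threshold] <- 0
  diag(A) <- 0
  dg <- rowSums(A)
  dg[dg == 0] <- 1e-12
  W <- A / sqrt(dg) / rep(sqrt(dg), each = nrow(A))
  ev <- eigen(W, symmetric = TRUE)
  E <- ev$vectors[, seq_len(min(n_eigen, ncol(ev$vectors))), drop = FALSE]
  rn <- sqrt(rowSums(E^2))
  rn[rn == 0] <- 1
  cbind(rho, (E / rn) * rho)
}

#' Project feature rows to their top principal directions
#'
#' PCA of the (RPCA-denoised) feature rows with a deterministic sign
#' convention: the largest-magnitude loading of each component is positive.
#'
#' @param L numeric matrix (rows = vertices).
#' @param d target dimensionality, `d <= min(dim(L))`.
#' @return `nrow(L) x d` score matrix.
#' @export
reduce_features <- function(L, d) {
  L <- as.matrix(L)
  if (d > min(dim(L))) stop("d exceeds min(dim(L))")
  Lc <- sweep(L, 2L, colMeans(L))
  dec <- svd(Lc, nu = 0L, nv = d)
  V <- dec$v
  for (k in seq_len(d)) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  Lc %*% V
}

#' Fuzzy c-means clustering
#'
#' Minimizes `J = sum_j sum_i u_ij^m ||v_i - x_j||^2` subject to
#' `sum_i u_ij = 1` by alternating the closed-form center update
#' `v_i = sum_j u_ij^m x_j / sum_j u_ij^m` and the membership update
#' `u_ij = 1 / sum_k (||v_i - x_j|| / ||v_k - x_j||)^{2/(m-1)}`, stopping
#' when `max|U_t - U_{t+1}| < epsilon`. A point coincident with a center
#' receives membership 1 to that center (and ties split equally).
#'
#' @param features vertex feature matrix (rows = points).
#' @param C number of clusters (>= 2).
#' @param m fuzzifier (> 1); default 2.
#' @param epsilon stop tolerance on the membership matrix; default 1e-5.
#' @param max_iter iteration cap; default 300.
#' @param seed seed for the k-means++ center initialization.
#' @return Object of class `fcm_membership`: `u` (C x N memberships),
#'   `centers` (C x d), `m`, `objective` (J per iteration), `iterations`.
#' @export
fcm_cluster <- function(features, C = 5L, m = 2, epsilon = 1e-5,
                        max_iter = 300L, seed = 1L) {
  X <- as.matrix(features)
  if (C < 2L) stop("C must be >= 2")
  if (m <= 1) stop("fuzzifier m must be > 1")
  N <- nrow(X)
  if (N < C) stop("fewer points than clusters")
  for (attempt in 0:1) {
    centers <- kmeanspp_init(X, C, seed = as.integer(seed) + attempt)
    U <- fcm_memberships(X, centers, m)
    Jtrace <- numeric(0L)
    it <- 0L
    repeat {
      it <- it + 1L
      centers <- fcm_centers(X, U, m)
      Unew <- fcm_memberships(X, centers, m)
      Jtrace <- c(Jtrace, fcm_objective(X, centers, Unew, m))
      delta <- max(abs(Unew - U))
      U <- Unew
      if (delta < epsilon || it >= max_iter) break
    }
    lab <- apply(U, 2L, which.max)
    if (length(unique(lab)) == C) {
      return(structure(list(u = U, centers = centers, m = m,
                            objective = Jtrace, iterations = it),
                       class = "fcm_membership"))
    }
  }
  stop("fcm_cluster: empty cluster at convergence after re-seeding")
}

# k-means++ seeding, self-contained and deterministic given the seed
kmeanspp_init <- function(X, C, seed) {
  set.seed(seed)
  N <- nrow(X)
  idx <- sample.int(N, 1L)
  centers <- X[idx, , drop = FALSE]
  d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
  while (nrow(centers) < C) {
    if (sum(d2) == 0) {
      nxt <- sample.int(N, 1L)
    } else {
      nxt <- sample.int(N, 1L, prob = d2 / sum(d2))
    }
    centers <- rbind(centers, X[nxt, , drop = FALSE])
    d2 <- pmin(d2, rowSums(sweep(X, 2L, X[nxt, ])^2))
  }
  centers
}

# squared distances C x N between centers and points
fcm_dist2 <- function(X, centers) {
  cn <- rowSums(centers^2)
  xn <- rowSums(X^2)
  d2 <- outer(cn, xn, `+`) - 2 * centers %*% t(X)
  pmax(d2, 0)
}

fcm_memberships <- function(X, centers, m) {
  d2 <- fcm_dist2(X, centers)
  p <- 1 / (m - 1)
  U <- matrix(0, nrow(d2), ncol(d2))
  zero <- d2 < .Machine$double.eps
  anyzero <- colSums(zero) > 0L
  w <- (1 / d2[, !anyzero, drop = FALSE])^p
  U[, !anyzero] <- sweep(w, 2L, colSums(w), "/")
  if (any(anyzero)) {
    zz <- zero[, anyzero, drop = FALSE]
    U[, anyzero] <- sweep(zz, 2L, colSums(zz), "/")
  }
  U
}

fcm_centers <- function(X, U, m) {
  Um <- U^m
  sweep(Um %*% X, 1L, rowSums(Um), "/")
}

fcm_objective <- function(X, centers, U, m) {
  sum(U^m * fcm_dist2(X, centers))
}

#' Crisp labels from a fuzzy membership matrix
#'
#' Vertex `j` is assigned the cluster with the largest membership `u_ij`;
#' ties break to the lowest cluster index.
#'
#' @param U a `fcm_membership` or a bare C x N membership matrix.
#' @param modality optional modality tag carried along.
#' @return Object of class `region_labeling`: integer `label` per vertex in
#'   `1..C`, `names` (per-cluster region names, initially `region_1..C`),
#'   `modality`.
#' @export
assign_labels <- function(U, modality = NA_character_) {
  um <- if (inherits(U, "fcm_membership")) U$u else as.matrix(U)
  lab <- apply(um, 2L, which.max)
  region_labeling(lab, paste0("region_", seq_len(nrow(um))), modality)
}

region_labeling <- function(label, names, modality = NA_character_) {
  label <- as.integer(label)
  if (any(label < 1L) || any(label > length(names)))
    stop("region label out of range")
  structure(list(label = label, names = as.character(names),
                 modality = modality),
            class = "region_labeling")
}

#' @export
print.region_labeling <- function(x, ...) {
  tab <- table(factor(x$label, levels = seq_along(x$names)))
  cat("region_labeling (", x$modality, "): ",
      paste(sprintf("%s=%d", x$names, as.integer(tab)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

region_vertices <- function(labeling, region) {
  r <- if (is.character(region)) match(region, labeling$names) else as.integer(region)
  if (is.na(r) || r < 1L || r > length(labeling$names)) stop("unknown region: ", region)
  which(labeling$label == r)
}

#' Greedily merge similar clusters
#'
#' Repeatedly merges the pair of clusters whose centers are closest, summing
#' their memberships, until `target_count` clusters remain or the smallest
#' center distance exceeds `tau`.
#'
#' @param U a `fcm_membership`.
#' @param tau center-distance threshold; pairs farther than `tau` are never
#'   merged (`tau = 0` merges only coincident centers... i.e. nothing, unless
#'   centers coincide exactly).
#' @param target_count desired number of clusters.
#' @return A new `fcm_membership` with merged memberships and recomputed
#'   centers.
#' @export
merge_similar_regions <- function(U, tau, target_count) {
  if (!inherits(U, "fcm_membership")) stop("U must be a fcm_membership")
  um <- U$u; centers <- U$centers
  if (target_count > nrow(um)) stop("target_count exceeds current cluster count")
  mass <- rowSums(um)
  while (nrow(um) > target_count) {
    D <- as.matrix(stats::dist(centers))
    diag(D) <- Inf
    dmin <- min(D)
    if (dmin > tau) {
      stop("cannot reach target_count under tau; remaining center distances: ",
           paste(sprintf("%.4g", sort(unique(D[upper.tri(D)]))), collapse = ", "))
    }
    ij <- which(D == dmin, arr.ind = TRUE)[1L, ]
    i <- min(ij); j <- max(ij)
    # merged center: membership-mass weighted mean of the two old centers
    centers[i, ] <- (mass[i] * centers[i, ] + mass[j] * centers[j, ]) /
      (mass[i] + mass[j])
    mass[i] <- mass[i] + mass[j]
    um[i, ] <- um[i, ] + um[j, ]
    um <- um[-j, , drop = FALSE]
    centers <- centers[-j, , drop = FALSE]
    mass <- mass[-j]
  }
  structure(list(u = um, centers = centers, m = U$m,
                 objective = U$objective, iterations = U$iterations),
            class = "fcm_membership")
}

#' Extract the submesh of one region
#'
#' Keeps all vertices carrying the region label and the faces whose three
#' vertices all carry it.
#'
#' @param mesh the global [tri_mesh].
#' @param labeling a `region_labeling` for that mesh.
#' @param region region name or index.
#' @return List with `mesh` (the region [tri_mesh]) and `index_map`
#'   (region-vertex row -> global vertex index).
#' @export
region_submesh <- function(mesh, labeling, region) {
  verts <- region_vertices(labeling, region)
  if (length(verts) == 0L) stop("region is empty: ", region)
  inreg <- logical(n_vertices(mesh))
  inreg[verts] <- TRUE
  keep <- inreg[mesh$faces[, 1L]] & inreg[mesh$faces[, 2L]] & inreg[mesh$faces[, 3L]]
  if (!any(keep)) stop("region has no complete face: ", region)
  new_id <- integer(n_vertices(mesh))
  new_id[verts] <- seq_along(verts)
  f <- mesh$faces[keep, , drop = FALSE]
  f[] <- new_id[f]
  list(mesh = tri_mesh(mesh$vertices[verts, , drop = FALSE], f),
       index_map = verts)
}

#' Ordered boundary loops of a region
#'
#' Boundary edges are the edges incident to exactly one region face (a face
#' whose three vertices carry the region label). Loops are returned closed
#' (first vertex implicitly follows the last) and consistently ordered.
#'
#' @inheritParams region_submesh
#' @return List of integer vectors of global vertex indices, one per loop;
#'   empty list if the region covers a closed mesh.
#' @export
region_boundary <- function(mesh, labeling, region) {
  verts <- region_vertices(labeling, region)
  inreg <- logical(n_vertices(mesh))
  inreg[verts] <- TRUE
  keep <- inreg[mesh$faces[, 1L]] & inreg[mesh$faces[, 2L]] & inreg[mesh$faces[, 3L]]
  f <- mesh$faces[keep, , drop = FALSE]
  if (nrow(f) == 0L) stop("region has no complete face: ", region)
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  cnt <- table(key)
  bkey <- names(cnt)[cnt == 1L]
  if (length(bkey) == 0L) return(list())
  be <- do.call(rbind, lapply(strsplit(bkey, " "), as.integer))
  # walk loops
  nb <- list()
  for (k in seq_len(nrow(be))) {
    for (v in be[k, ]) nb[[as.character(v)]] <- c(nb[[as.character(v)]], be[k, be[k, ] != v])
  }
  if (any(vapply(nb, length, integer(1L)) != 2L))
    stop("non-manifold region boundary (vertex on != 2 boundary edges)")
  loops <- list()
  visited <- character(0L)
  for (start in sort(unique(as.vector(be)))) {
    s <- as.character(start)
    if (s %in% visited) next
    loop <- start
    prev <- NA_integer_
    cur <- start
    repeat {
      nbrs <- nb[[as.character(cur)]]
      nxt <- if (is.na(prev)) min(nbrs) else nbrs[nbrs != prev][1L]
      if (nxt == start) break
      loop <- c(loop, nxt)
      prev <- cur
      cur <- nxt
    }
    visited <- c(visited, as.character(loop))
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Spatially clean a vertex labeling
#'
#' Two standard post-processing passes over the mesh graph: (1) majority
#' smoothing — a vertex whose neighbours mostly agree on another label
#' switches to it (repeated up to `iterations` times); (2) for every region
#' except the reference (largest) one, only the largest connected component
#' is kept and stray components are relabelled to the reference region, so
#' feature regions are single islands with clean (manifold) boundaries.
#'
#' @param labeling a `region_labeling`.
#' @param mesh the mesh carrying the labels.
#' @param iterations majority-smoothing passes (default 3).
#' @return The cleaned `region_labeling`.
#' @export
smooth_labels <- function(labeling, mesh, iterations = 3L) {
  adj <- vertex_adjacency(mesh)
  lab <- labeling$label
  C <- length(labeling$names)
  for (it in seq_len(iterations)) {
    changed <- FALSE
    for (v in seq_along(lab)) {
      nb <- adj[[v]]
      if (length(nb) == 0L) next
      tab <- tabulate(lab[nb], nbins = C)
      best <- which.max(tab)
      if (best != lab[[v]] && tab[[best]] > length(nb) / 2) {
        lab[[v]] <- best
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # keep only the largest connected component of each non-reference region
  ref <- which.max(tabulate(lab, nbins = C))
  for (r in setdiff(seq_len(C), ref)) {
    verts <- which(lab == r)
    if (length(verts) == 0L) next
    comp <- integer(length(lab))
    cid <- 0L
    for (v in verts) {
      if (comp[[v]] != 0L) next
      cid <- cid + 1L
      queue <- v
      comp[[v]] <- cid
      while (length(queue)) {
        cur <- queue[[1L]]; queue <- queue[-1L]
        nb <- adj[[cur]]
        nb <- nb[lab[nb] == r & comp[nb] == 0L]
        comp[nb] <- cid
        queue <- c(queue, nb)
      }
    }
    sizes <- tabulate(comp[verts], nbins = cid)
    keep <- which.max(sizes)
    lab[verts[comp[verts] != keep]] <- ref
  }
  region_labeling(lab, labeling$names, labeling$modality)
}

#' Name clusters as craniofacial regions by centroid position
#'
#' Assigns the conventional five region names to arbitrary cluster indices
#' using the canonical head frame (x lateral, y forward out of the face,
#' z up): the largest cluster is the frame; of the rest, the two with the
#' most lateral centroids are the left (x < 0) and right eyes; of the
#' remaining two, the higher centroid is the nose and the lower the mouth.
#'
#' @param labeling a `region_labeling` with exactly 5 clusters.
#' @param mesh the mesh the labels live on (the population mean mesh).
#' @return The labeling with `names` set to
#'   `left_eye`, `right_eye`, `nose`, `mouth`, `frame`.
#' @export
name_regions <- function(labeling, mesh) {
  C <- length(labeling$names)
  if (C != 5L) stop("name_regions expects exactly 5 clusters, got ", C)
  sizes <- tabulate(labeling$label, nbins = 5L)
  if (any(sizes == 0L)) stop("name_regions: empty cluster")
  cent <- t(vapply(1:5, function(r)
    colMeans(mesh$vertices[labeling$label == r, , drop = FALSE]), numeric(3L)))
  nm <- rep(NA_character_, 5L)
  frame <- which.max(sizes)
  nm[frame] <- "frame"
  rest <- setdiff(1:5, frame)
  lat <- rest[order(abs(cent[rest, 1L]), decreasing = TRUE)]
  eyes <- lat[1:2]
  nm[eyes[which.min(cent[eyes, 1L])]] <- "left_eye"
  nm[eyes[which.max(cent[eyes, 1L])]] <- "right_eye"
  mid <- setdiff(rest, eyes)
  nm[mid[which.max(cent[mid, 3L])]] <- "nose"
  nm[mid[which.min(cent[mid, 3L])]] <- "mouth"
  region_labeling(labeling$label, nm, labeling$modality)
}

#' Write / read a region labeling as CSV
#'
#' Columns: `vertex_index` (1-based), `label`, `region_name`.
#' @param labeling a `region_labeling`.
#' @param path CSV path.
#' @export
write_labeling <- function(labeling, path) {
  utils::write.csv(data.frame(vertex_index = seq_along(labeling$label),
                              label = labeling$label,
                              region_name = labeling$names[labeling$label]),
                   path, row.names = FALSE)
  invisible(NULL)
}

#' @rdname write_labeling
#' @param modality modality tag for the read labeling.
#' @export
read_labeling <- function(path, modality = NA_character_) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d <- d[order(d$vertex_index), ]
  nms <- character(max(d$label))
  for (i in seq_len(nrow(d))) nms[d$label[[i]]] <- d$region_name[[i]]
  region_labeling(d$label, nms, modality)
}

#' Segment one modality of a corresponded sample set
#'
#' The full segmentation chain: per-vertex displacement trajectories,
#' robust-PCA denoising and spectral shape features
#' ([spectral_shape_features()]), fuzzy c-means with `C` clusters (best of
#' `n_init` deterministic initializations by the FCM objective), crisp
#' labels, and anatomical naming (when `C == 5`).
#'
#' @inheritParams build_vertex_features
#' @param C number of regions (default 5).
#' @param m fuzzifier (default 2).
#' @param feature_dim spectral embedding dimensionality.
#' @param seed clustering seed.
#' @param epsilon,max_iter FCM stopping controls.
#' @param n_init number of FCM initializations (seeds `seed .. seed+n_init-1`).
#' @return A named `region_labeling`.
#' @export
segment_modality <- function(samples, modality = c("skull", "face"), C = 5L,
                             m = 2, feature_dim = 6L, seed = 1L,
                             epsilon = 1e-5, max_iter = 300L, n_init = 3L) {
  modality <- match.arg(modality)
  traj <- build_vertex_features(samples, modality)
  mean_mesh <- attr(traj, "mean_mesh")
  feat <- spectral_shape_features(traj, n_eigen = feature_dim)
  best <- NULL
  for (s in seq_len(n_init)) {
    U <- tryCatch(fcm_cluster(feat, C = C, m = m, epsilon = epsilon,
                              max_iter = max_iter, seed = seed + s - 1L),
                  error = function(e) NULL)
    if (is.null(U)) next
    if (is.null(best) || utils::tail(U$objective, 1L) <
        utils::tail(best$objective, 1L)) best <- U
  }
  if (is.null(best)) stop("fcm_cluster failed for every initialization")
  lab <- assign_labels(best, modality)
  lab <- smooth_labels(lab, mean_mesh)
  if (C == 5L) lab <- name_regions(lab, mean_mesh)
  lab
}
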