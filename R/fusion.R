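#' Rigid alignment of corresponding point sets (orthogonal Procrustes)
#'
#' Finds the proper rotation `R` and translation `T` minimizing
#' `sum_i ||R p0_i + T - p1_i||^2` (Kabsch algorithm; reflections are
#' disallowed, `det(R) = +1`).
#'
#' @param P0 `n x 3` source points (n >= 3, non-degenerate).
#' @param P1 `n x 3` corresponding target points.
#' @return List with `R` (3x3 rotation) and `T` (length-3 translation).
#' @export
rigid_align <- function(P0, P1) {
  P0 <- as.matrix(P0); P1 <- as.matrix(P1)
  if (nrow(P0) != nrow(P1)) stop("point counts differ")
  if (nrow(P0) < 3L) stop("need at least 3 points")
  c0 <- colMeans(P0); c1 <- colMeans(P1)
  H <- crossprod(sweep(P0, 2L, c0), sweep(P1, 2L, c1))
  dec <- svd(H)
  if (dec$d[2L] < 1e-12 * max(dec$d[1L], 1))
    stop("degenerate (rank-deficient) point configuration")
  S <- diag(c(1, 1, sign(det(dec$v %*% t(dec$u)))))
  R <- dec$v %*% S %*% t(dec$u)
  list(R = R, T = drop(c1 - R %*% c0))
}

apply_rigid <- function(transform, points) {
  sweep(as.matrix(points) %*% t(transform$R), 2L, transform$T, `+`)
}

#' Shrink a region boundary inward over the mesh graph
#'
#' Realizes boundary shrinking "with step S0" as k-ring graph erosion:
#' `k = max(1, round(S0 / mean edge length))`; the inner contour consists of
#' the vertices at graph distance exactly `k` from the boundary (restricted
#' to the `within` side), and the blend band is the boundary plus the
#' vertices at distances `1..k-1`.
#'
#' @param mesh the global [tri_mesh] (supplies connectivity and the edge
#'   length scale).
#' @param boundary integer vector of boundary vertex indices (one or more
#'   closed loops).
#' @param S0 shrink step in mm.
#' @param within integer vector of vertex indices defining the side to
#'   shrink into (the region's vertices, or their complement for the
#'   reverse shrink on the base mesh).
#' @return List with `inner` (contour vertex indices), `band` (boundary and
#'   strictly-between vertices), `k` (rings actually used).
#' @export
shrink_contour <- function(mesh, boundary, S0, within) {
  if (S0 <= 0) stop("S0 must be positive")
  mel <- mean_edge_length(mesh)
  k <- max(1L, as.integer(round(S0 / mel)))
  adj <- vertex_adjacency(mesh)
  side <- setdiff(within, boundary)
  if (length(side) == 0L)
    stop("no interior on the requested side (region has no vertices beyond its boundary)")
  d <- graph_distance(adj, boundary, side)
  dmax <- max(d[side][is.finite(d[side])], 0)
  if (dmax < k) {
    if (dmax < 1) stop("side too thin to shrink even one ring")
    warning("side thinner than ", k, " rings; reducing to k = ", dmax)
    k <- as.integer(dmax)
  }
  inner <- side[d[side] == k]
  band <- c(boundary, side[d[side] >= 1 & d[side] <= k - 1L])
  list(inner = inner, band = band, k = k)
}

#' Midpoints of corresponding boundary points
#'
#' The interpolation targets of the splicing step: `P2 = (P0 + P1) / 2`.
#'
#' @param B0_points,B1_points `n x 3` matrices in corresponding order.
#' @export
midpoint_targets <- function(B0_points, B1_points) {
  B0_points <- as.matrix(B0_points); B1_points <- as.matrix(B1_points)
  if (!all(dim(B0_points) == dim(B1_points))) stop("point counts differ")
  (B0_points + B1_points) / 2
}

#' Fit a 3-D thin-plate-spline interpolant
#'
#' Radial basis `U(r) = r^3` plus an affine part, solving
#' `[[K, P], [P^T, 0]] [w; a] = [targets; 0]` with the standard side
#' conditions `P^T w = 0`; the map is exact at every control point and
#' reproduces affine maps with zero warp.
#'
#' @param control `n x 3` control points (>= 4, not all coplanar).
#' @param target `n x 3` target points (anchors simply have
#'   `target = control`).
#' @return Object of class `tps_map`: `control`, `W` (warp coefficients,
#'   `n x 3`), `A` (affine, `4 x 3` with the constant row first).
#' @export
fit_tps <- function(control, target) {
  control <- as.matrix(control); target <- as.matrix(target)
  n <- nrow(control)
  if (n < 4L) stop("need at least 4 control points")
  if (nrow(target) != n) stop("control/target counts differ")
  K <- tps_basis(control, control)
  P <- cbind(1, control)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4L, 4L)))
  rhs <- rbind(target, matrix(0, 4L, 3L))
  sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
  if (is.null(sol)) {
    A[seq_len(n), seq_len(n)] <- K + diag(1e-9, n)
    sol <- tryCatch(solve(A, rhs), error = function(e)
      stop("singular TPS system (coplanar controls?) even after jitter"))
  }
  structure(list(control = control, W = sol[seq_len(n), , drop = FALSE],
                 A = sol[n + 1:4, , drop = FALSE]),
            class = "tps_map")
}

tps_basis <- function(X, C) {
  d2 <- outer(rowSums(X^2), rowSums(C^2), `+`) - 2 * X %*% t(C)
  pmax(d2, 0)^1.5
}

#' Evaluate a thin-plate-spline map
#'
#' @param map a [fit_tps()] map.
#' @param points `m x 3` query points.
#' @return `m x 3` warped points.
#' @export
apply_tps <- function(map, points) {
  pts <- as.matrix(points)
  tps_basis(pts, map$control) %*% map$W + cbind(1, pts) %*% map$A
}

#' Fuse regional reconstructions into one smooth face mesh
#'
#' For each feature-region part, optionally rigidly positions it onto the
#' base (Procrustes over the corresponding — same-index — vertices), then
#' splices it in smoothly: the region boundary `B0` shrinks `k` rings into
#' the part to a fixed contour `B0'`, and reversely shrinks `k` rings into
#' the base side to `B1'`; a pair of thin-plate splines `f0` (fixes `B0'`,
#' sends the part boundary `P0` to the midpoints `P2 = (P0 + P1)/2`) and
#' `f1` (fixes `B1'`, sends the base boundary positions `P1` to `P2`) warps
#' the band vertices on each side. The output takes part vertices inside
#' `B0'` unchanged, base vertices outside `B1'` unchanged, and both sides
#' meet exactly at `P2` on the seam.
#'
#' @param base full-topology [tri_mesh] serving as the global model (the
#'   frame-side reconstruction).
#' @param parts named list (region name -> list(`mesh`, `index_map`)) of
#'   regional reconstructions, as produced by [region_submesh()] topology
#'   plus predicted vertices.
#' @param labeling the `region_labeling` of the shared global topology.
#' @param S0 shrink step in mm; default 3 x mean edge length.
#' @param align if `TRUE`, rigidly align each part to the base first. The
#'   pipeline passes `FALSE` because its parts are decoded in the global
#'   frame already (and alignment would cancel predicted positional
#'   offsets).
#' @return Fused [tri_mesh] on the base topology; attribute `provenance` is
#'   a per-vertex factor (`base`, `part:<region>`, `band0:<region>`,
#'   `band1:<region>`, `seam:<region>`).
#' @export
fuse_regions <- function(base, parts, labeling, S0 = NULL, align = TRUE) {
  validate_tri_mesh(base)
  if (length(labeling$label) != n_vertices(base))
    stop("labeling does not match base topology")
  if (is.null(S0)) S0 <- 3 * mean_edge_length(base)
  out <- base$vertices
  prov <- rep("base", n_vertices(base))
  adj <- vertex_adjacency(base)
  all_verts <- seq_len(n_vertices(base))
  claimed <- logical(n_vertices(base))  # band/region ownership for overlap checks
  # process parts largest boundary first
  ord <- names(parts)
  bsize <- vapply(ord, function(rn) {
    length(unlist(region_boundary(base, labeling, rn)))
  }, numeric(1L))
  for (rn in ord[order(bsize, decreasing = TRUE)]) {
    part <- parts[[rn]]
    if (is.null(part)) { warning("missing region part: ", rn); next }
    gi <- part$index_map
    rverts <- region_vertices(labeling, rn)
    if (!setequal(gi, rverts))
      stop("index_map of part '", rn, "' does not cover its region")
    pv <- part$mesh$vertices
    if (align) {
      tr <- rigid_align(pv, base$vertices[gi, , drop = FALSE])
      pv <- apply_rigid(tr, pv)
    }
    pos <- integer(n_vertices(base))      # global index -> part row
    pos[gi] <- seq_along(gi)
    loops <- region_boundary(base, labeling, rn)
    B0 <- unlist(loops)
    mel_k <- shrink_contour(base, B0, S0, within = rverts)
    outer_side <- setdiff(all_verts, rverts)
    out_k <- shrink_contour(base, B0, S0, within = c(outer_side, B0))
    band1 <- setdiff(out_k$band, B0)      # strictly outside the region
    # overlap check between parts: outer bands and inner contours must be free
    touched <- c(rverts, band1, out_k$inner)
    if (any(claimed[touched]))
      stop("blend band of region '", rn, "' overlaps a previously fused region")
    claimed[touched] <- TRUE
    P0 <- pv[pos[B0], , drop = FALSE]
    P1 <- base$vertices[B0, , drop = FALSE]
    P2 <- midpoint_targets(P0, P1)
    # part side: interior (distance >= k) kept; band warped; boundary -> P2
    inner_keep <- setdiff(rverts, c(B0, mel_k$band))
    out[inner_keep, ] <- pv[pos[inner_keep], , drop = FALSE]
    out[mel_k$inner, ] <- pv[pos[mel_k$inner], , drop = FALSE]
    band0 <- setdiff(mel_k$band, B0)
    Q0 <- pv[pos[mel_k$inner], , drop = FALSE]
    f0 <- fit_tps(rbind(Q0, P0), rbind(Q0, P2))
    if (length(band0))
      out[band0, ] <- apply_tps(f0, pv[pos[band0], , drop = FALSE])
    out[B0, ] <- P2
    # base side: band warped toward P2, fixed at B1'
    Q1 <- base$vertices[out_k$inner, , drop = FALSE]
    f1 <- fit_tps(rbind(Q1, P1), rbind(Q1, P2))
    if (length(band1))
      out[band1, ] <- apply_tps(f1, base$vertices[band1, , drop = FALSE])
    prov[setdiff(rverts, c(B0, band0))] <- paste0("part:", rn)
    prov[band0] <- paste0("band0:", rn)
    prov[band1] <- paste0("band1:", rn)
    prov[B0] <- paste0("seam:", rn)
  }
  fused <- tri_mesh(out, base$faces)
  attr(fused, "provenance") <- prov
  fused
}
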