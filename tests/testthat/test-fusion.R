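test_that("rigid_align recovers planted rotations and translations", {
  set.seed(41)
  P0 <- matrix(rnorm(30), 10L, 3L)
  expect_identity <- rigid_align(P0, P0)
  expect_lt(max(abs(expect_identity$R - diag(3))), 1e-10)
  expect_lt(max(abs(expect_identity$T)), 1e-10)
  R <- rot_z(30)
  P1 <- P0 %*% t(R) + rep(c(1, 2, 3), each = 10L)
  tr <- rigid_align(P0, P1)
  expect_lt(max(abs(tr$R - R)), 1e-8)
  expect_lt(max(abs(tr$T - c(1, 2, 3))), 1e-8)
  expect_lt(max(abs(craniofuse:::apply_rigid(tr, P0) - P1)), 1e-8)
  # mirrored targets: reflection disallowed, det stays +1
  Pm <- P0 %*% diag(c(-1, 1, 1))
  trm <- rigid_align(P0, Pm)
  expect_equal(det(trm$R), 1, tolerance = 1e-10)
  # optimality sanity: residual no worse than the identity transform
  res_fit <- sum((craniofuse:::apply_rigid(trm, P0) - Pm)^2)
  expect_lte(res_fit, sum((P0 - Pm)^2) + 1e-12)
  expect_error(rigid_align(cbind(1:5, 0, 0), cbind(1:5, 1, 0)), "degenerate")
  expect_error(rigid_align(P0[1:2, ], P1[1:2, ]), "at least 3")
})

test_that("contour shrinking equals a brute-force BFS on the mesh graph", {
  m <- random_grid_mesh(10L, 5L, seed = 42L, jitter = 0)  # strip, 5 rows
  boundary <- which(m$vertices[, 2L] == 1)  # first row
  mel <- craniofuse:::mean_edge_length(m)
  sh <- shrink_contour(m, boundary, S0 = 2.05 * mel, within = seq_len(50L))
  expect_equal(sh$k, 2L)
  expect_equal(sort(sh$inner), which(m$vertices[, 2L] == 3))
  expect_setequal(sh$band, c(boundary, which(m$vertices[, 2L] == 2)))
  # BFS oracle over the edge list
  e <- craniofuse:::mesh_edges(m)
  d <- rep(Inf, 50L); d[boundary] <- 0
  repeat {
    d2 <- d
    for (k in seq_len(nrow(e))) {
      d2[e[k, 1L]] <- min(d2[e[k, 1L]], d[e[k, 2L]] + 1)
      d2[e[k, 2L]] <- min(d2[e[k, 2L]], d[e[k, 1L]] + 1)
    }
    if (identical(d2, d)) break
    d <- d2
  }
  expect_equal(sort(sh$inner), sort(which(d == 2)))
  # S0 below one edge length: k = 1 and the band is the boundary alone
  sh1 <- shrink_contour(m, boundary, S0 = 0.5 * mel, within = seq_len(50L))
  expect_equal(sh1$k, 1L)
  expect_setequal(sh1$band, boundary)
  # a side too thin to shrink the requested number of rings
  expect_warning(shrink_contour(m, boundary, S0 = 10 * mel,
                                within = seq_len(50L)), "thinner")
  expect_error(shrink_contour(m, seq_len(50L), S0 = mel,
                              within = seq_len(50L)), "no interior")
})

test_that("midpoint targets are element-wise and symmetric", {
  a <- rbind(c(0, 0, 0), c(2, 4, 6))
  b <- rbind(c(0, 0, 0), c(0, 0, 0))
  expect_equal(midpoint_targets(a, b), rbind(c(0, 0, 0), c(1, 2, 3)))
  expect_equal(midpoint_targets(a, b), midpoint_targets(b, a))
  expect_equal(midpoint_targets(a, a), a)
  expect_error(midpoint_targets(a, b[1L, , drop = FALSE]), "differ")
})

test_that("thin-plate splines interpolate exactly and reproduce affine maps", {
  set.seed(43)
  ctrl <- matrix(rnorm(18), 6L, 3L)
  # identity: targets equal controls, warp vanishes, affine part is identity
  id <- fit_tps(ctrl, ctrl)
  expect_lt(max(abs(id$W)), 1e-9)
  expect_lt(max(abs(id$A - rbind(0, diag(3)))), 1e-9)
  q <- matrix(rnorm(30), 10L, 3L)
  expect_lt(max(abs(apply_tps(id, q) - q)), 1e-8)
  # affine reproduction at arbitrary query points
  Aff <- matrix(rnorm(9), 3L); b <- c(1, -2, 0.5)
  tmap <- fit_tps(ctrl, ctrl %*% t(Aff) + rep(b, each = 6L))
  expect_lt(max(abs(apply_tps(tmap, q) - (q %*% t(Aff) + rep(b, each = 10L)))),
            1e-7)
  # random targets: exact at controls, coefficients match a dense solve
  targ <- ctrl + matrix(rnorm(18, 0, 0.5), 6L)
  w <- fit_tps(ctrl, targ)
  expect_lt(max(abs(apply_tps(w, ctrl) - targ)), 1e-8)
  K <- craniofuse:::tps_basis(ctrl, ctrl)
  P <- cbind(1, ctrl)
  Afull <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4L, 4L)))
  sol <- solve(Afull, rbind(targ, matrix(0, 4L, 3L)))
  expect_equal(w$W, sol[1:6, ], tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(w$A, sol[7:10, ], tolerance = 1e-8, ignore_attr = TRUE)
  # naive evaluation oracle at one query point
  naive <- colSums(sol[1:6, ] * sqrt(rowSums(sweep(ctrl, 2L, q[1L, ])^2))^3) +
    drop(c(1, q[1L, ]) %*% sol[7:10, ])
  expect_equal(apply_tps(w, q[1L, , drop = FALSE])[1L, ], naive,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(fit_tps(ctrl[1:3, ], targ[1:3, ]), "at least 4")
})

test_that("self-fusion of parts cut from one face is the identity", {
  tpl <- make_template(generator_config(seed = 5L))
  base <- tpl$face
  lab <- tpl$labeling
  parts <- lapply(stats::setNames(
    setdiff(lab$names, "frame"), setdiff(lab$names, "frame")),
    function(rn) region_submesh(base, lab, rn))
  S0 <- 2.05 * craniofuse:::mean_edge_length(base)
  fused <- fuse_regions(base, parts, lab, S0 = S0, align = TRUE)
  expect_lt(max(abs(fused$vertices - base$vertices)), 1e-6)
  expect_identical(fused$faces, base$faces)
})

test_that("a translated part blends midway at the seam and decays inward", {
  tpl <- make_template(generator_config(seed = 5L))
  base <- tpl$face
  lab <- tpl$labeling
  sub <- region_submesh(base, lab, "left_eye")
  part <- sub
  part$mesh <- tri_mesh(sweep(sub$mesh$vertices, 2L, c(1, 0, 0), `+`),
                        sub$mesh$faces)
  S0 <- 2.05 * craniofuse:::mean_edge_length(base)
  fused <- fuse_regions(base, list(left_eye = part), lab, S0 = S0,
                        align = FALSE)
  dx <- fused$vertices[, 1L] - base$vertices[, 1L]
  B0 <- unlist(region_boundary(base, lab, "left_eye"))
  rverts <- which(lab$label == match("left_eye", lab$names))
  inner <- craniofuse:::shrink_contour(base, B0, S0, within = rverts)
  outer <- craniofuse:::shrink_contour(
    base, B0, S0, within = setdiff(seq_len(nrow(base$vertices)), rverts))
  # midpoint rule at the seam
  expect_equal(dx[B0], rep(0.5, length(B0)), tolerance = 1e-9)
  # part interior beyond the inner contour: bit-identical to the part
  deep <- setdiff(rverts, c(B0, setdiff(inner$band, B0)))
  expect_identical(fused$vertices[deep, ], part$mesh$vertices[
    match(deep, sub$index_map), ])
  # blend bands lie between the two sides
  band0 <- setdiff(inner$band, B0)
  band1 <- setdiff(outer$band, B0)
  expect_true(all(dx[band0] > 0.3 & dx[band0] < 1 + 1e-9))
  expect_true(all(dx[band1] > -1e-9 & dx[band1] < 0.7))
  # vertices beyond both bands on the base side: bit-identical to the base
  untouched <- setdiff(seq_len(nrow(base$vertices)),
                       c(rverts, band1, outer$inner))
  expect_identical(fused$vertices[untouched, ], base$vertices[untouched, ])
})

test_that("rigid positioning undoes a planted similarity placement", {
  tpl <- make_template(generator_config(seed = 5L))
  base <- tpl$face
  lab <- tpl$labeling
  sub <- region_submesh(base, lab, "nose")
  moved <- sub
  moved$mesh <- tri_mesh(sub$mesh$vertices %*% t(rot_z(10)) +
                           rep(c(4, -2, 1), each = nrow(sub$mesh$vertices)),
                         sub$mesh$faces)
  fused <- fuse_regions(base, list(nose = moved), lab,
                        S0 = 2.05 * craniofuse:::mean_edge_length(base),
                        align = TRUE)
  expect_lt(max(abs(fused$vertices - base$vertices)), 1e-6)
})

test_that("a missing region part is skipped with a warning", {
  tpl <- make_template(generator_config(seed = 5L))
  lab <- tpl$labeling
  parts <- list(left_eye = region_submesh(tpl$face, lab, "left_eye"),
                nose = NULL)
  expect_warning(fuse_regions(tpl$face, parts, lab,
                              S0 = 2.05 * craniofuse:::mean_edge_length(tpl$face),
                              align = FALSE),
                 "missing region")
})
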