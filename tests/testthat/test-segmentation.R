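test_that("FCM membership update matches the closed form", {
  # fixed centers 0 and 1, point at 0.25, m = 2: exponent 2/(m-1) = 2 gives
  # memberships (0.9, 0.1)
  U <- craniofuse:::fcm_memberships(matrix(0.25, 1L, 1L),
                                    matrix(c(0, 1), 2L, 1L), m = 2)
  expect_equal(as.numeric(U), c(0.9, 0.1), tolerance = 1e-12)
  # zero-distance convention: a point coincident with a center gets 1
  U0 <- craniofuse:::fcm_memberships(matrix(0, 1L, 1L),
                                     matrix(c(0, 1), 2L, 1L), m = 2)
  expect_equal(as.numeric(U0), c(1, 0))
})

test_that("FCM satisfies its constraint and objective invariants", {
  set.seed(4)
  X <- rbind(matrix(rnorm(100, 0, 0.05), 50L), matrix(rnorm(100, 5, 0.05), 50L))
  f <- fcm_cluster(X, C = 2L, m = 2, seed = 1L)
  expect_lt(max(abs(colSums(f$u) - 1)), 1e-12)
  expect_true(all(f$u >= 0 & f$u <= 1))
  expect_true(all(diff(f$objective) <= 1e-9))
  # tight well-separated blobs: near-crisp memberships, planted partition
  expect_gt(min(apply(f$u, 2L, max)), 0.99)
  lab <- apply(f$u, 2L, which.max)
  expect_equal(length(unique(lab[1:50])), 1L)
  expect_equal(length(unique(lab[51:100])), 1L)
  expect_false(lab[1L] == lab[51L])
  expect_error(fcm_cluster(X, C = 1L), "C must be")
  expect_error(fcm_cluster(X, C = 2L, m = 1), "m must be")
})

test_that("duplicating a feature row yields the duplicate's label", {
  set.seed(5)
  X <- rbind(matrix(rnorm(60, 0, 0.1), 30L, 2L), matrix(rnorm(60, 4, 0.1), 30L, 2L))
  X2 <- rbind(X, X[7L, ])
  f <- fcm_cluster(X2, C = 2L, seed = 1L)
  lab <- assign_labels(f)
  expect_equal(lab$label[61L], lab$label[7L])
})

test_that("assign_labels takes the argmax with ties to the lowest index", {
  U <- cbind(c(0.2, 0.5, 0.3), c(0.5, 0.5, 0), c(1, 0, 0))
  lab <- assign_labels(U)
  expect_equal(lab$label, c(2L, 1L, 1L))
  one_hot <- diag(3)
  expect_equal(assign_labels(one_hot)$label, 1:3)
})

test_that("merge_similar_regions greedily merges closest centers", {
  set.seed(6)
  # 7 planted clusters where two pairs share (nearly) identical centers
  centers <- rbind(c(0, 0), c(0, 0.001), c(5, 0), c(5, 0.001),
                   c(0, 5), c(5, 5), c(10, 10))
  X <- centers[rep(1:7, each = 20L), ] + matrix(rnorm(280, 0, 0.05), 140L)
  f <- fcm_cluster(X, C = 7L, seed = 2L)
  merged <- merge_similar_regions(f, tau = 1, target_count = 5L)
  expect_equal(nrow(merged$u), 5L)
  expect_lt(max(abs(colSums(merged$u) - 1)), 1e-9)
  # tau = 0 forbids any merge
  expect_error(merge_similar_regions(f, tau = 0, target_count = 5L),
               "cannot reach")
  expect_error(merge_similar_regions(f, tau = 1, target_count = 9L),
               "exceeds")
})

test_that("region_submesh extracts complete-face submeshes with index maps", {
  m <- random_grid_mesh(5L, 5L, seed = 8L)
  whole <- region_labeling_for_test(rep(1L, 25L), "all")
  sub <- region_submesh(m, whole, "all")
  expect_identical(sub$mesh$vertices, m$vertices)
  expect_identical(sub$mesh$faces, m$faces)
  # a single labeled triangle
  lab1 <- rep(2L, 25L)
  lab1[m$faces[1L, ]] <- 1L
  lab <- region_labeling_for_test(lab1, c("tri", "rest"))
  sub1 <- region_submesh(m, lab, "tri")
  expect_equal(nrow(sub1$mesh$vertices), 3L)
  expect_equal(nrow(sub1$mesh$faces), 1L)
  # every submesh vertex maps back to a vertex with that label
  set.seed(9)
  rl <- region_labeling_for_test(sample(1:2, 25L, TRUE), c("a", "b"))
  for (rn in c("a", "b")) {
    s <- tryCatch(region_submesh(m, rl, rn), error = function(e) NULL)
    if (!is.null(s)) expect_true(all(rl$label[s$index_map] == match(rn, rl$names)))
  }
})

test_that("region boundaries are closed ordered loops matching an edge census", {
  # disc-shaped region on a grid: boundary edge count by brute force
  m <- random_grid_mesh(7L, 7L, seed = 10L, jitter = 0)
  ctr <- c(4, 4)
  inside <- sqrt((m$vertices[, 1L] - ctr[1L])^2 +
                   (m$vertices[, 2L] - ctr[2L])^2) < 2.5
  lab <- region_labeling_for_test(ifelse(inside, 1L, 2L), c("disc", "rest"))
  loops <- region_boundary(m, lab, "disc")
  expect_equal(length(loops), 1L)
  # brute-force census of one-sided edges
  inreg <- lab$label == 1L
  keep <- inreg[m$faces[, 1L]] & inreg[m$faces[, 2L]] & inreg[m$faces[, 3L]]
  f <- m$faces[keep, , drop = FALSE]
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  n_boundary_edges <- sum(table(key) == 1L)
  expect_equal(length(loops[[1L]]), n_boundary_edges)
  # region = one triangle: its 3 vertices form the loop
  lab1 <- rep(2L, 25L)
  m2 <- random_grid_mesh(5L, 5L, seed = 1L)
  lab1[m2$faces[1L, ]] <- 1L
  l1 <- region_boundary(m2, region_labeling_for_test(lab1, c("t", "r")), "t")
  expect_equal(sort(l1[[1L]]), sort(m2$faces[1L, ]))
  # whole closed mesh: empty boundary
  tpl <- make_template(generator_config(n_theta = 16L, n_phi = 16L, n = 2L,
                                        seed = 1L))
  whole <- region_labeling_for_test(rep(1L, 258L), "all")
  expect_equal(length(region_boundary(tpl$skull, whole, "all")), 0L)
})

test_that("reduce_features preserves in-subspace geometry and separations", {
  set.seed(11)
  B <- qr.Q(qr(matrix(rnorm(15), 5L, 3L)))
  Z <- matrix(rnorm(120), 40L, 3L)
  X <- Z %*% t(B)  # rows live in a 3-dim subspace
  S <- reduce_features(X, 3L)
  d_orig <- dist(X)
  expect_lt(max(abs(dist(S) - d_orig)), 1e-9)
  expect_error(reduce_features(X, 9L), "exceeds")
  # planted 2-cluster rows stay separated after projection to 2 dims
  X2 <- rbind(matrix(rnorm(60, 0, 0.2), 30L, 2L),
              matrix(rnorm(60, 6, 0.2), 30L, 2L)) %*% t(B[, 1:2])
  S2 <- reduce_features(X2, 2L)
  between <- sqrt(sum((colMeans(S2[1:30, ]) - colMeans(S2[31:60, ]))^2))
  within <- mean(c(apply(S2[1:30, ], 2L, sd), apply(S2[31:60, ], 2L, sd)))
  expect_gt(between, 5 * within)
  # deterministic sign: repeated runs identical
  expect_identical(reduce_features(X, 2L), reduce_features(X, 2L))
})

test_that("vertex trajectories localize displacement and center to zero", {
  pop <- small_pop()
  s2 <- sample_set(pop$samples$pairs[1:2])
  # two identical samples would give all-zero trajectories; here: same
  # sample twice
  dup <- sample_set(list(pop$samples$pairs[[1L]],
                         local({p <- pop$samples$pairs[[1L]]; p$id <- "dup"; p})))
  traj <- build_vertex_features(dup, "face")
  expect_lt(max(abs(traj)), 1e-9)
  # displacing one vertex in one sample shows up only in that row
  p1 <- pop$samples$pairs[[1L]]
  p2 <- pop$samples$pairs[[1L]]
  p2$id <- "shifted"
  nrm <- craniofuse:::vertex_normals(p1$face)
  p2$face$vertices[5L, ] <- p2$face$vertices[5L, ] + 2 * nrm[5L, ]
  tr2 <- build_vertex_features(sample_set(list(p1, p2)), "face")
  expect_gt(abs(tr2[5L, 2L]), 0.5)
  expect_lt(max(abs(tr2[-5L, ])), 0.2)
})

test_that("segmentation is invariant to sample order", {
  pop <- small_pop()
  lab1 <- segment_modality(pop$samples, "face", seed = 1L)
  perm <- sample_set(pop$samples$pairs[c(7:14, 1:6)])
  lab2 <- segment_modality(perm, "face", seed = 1L)
  expect_identical(lab1$names[lab1$label], lab2$names[lab2$label])
})

test_that("smooth_labels removes stray islands and keeps majorities", {
  m <- random_grid_mesh(8L, 8L, seed = 12L, jitter = 0)
  lab <- rep(1L, 64L)
  lab[m$vertices[, 1L] >= 6] <- 2L  # right band
  lab[19L] <- 2L                    # stray vertex deep in region 1
  sm <- smooth_labels(region_labeling_for_test(lab, c("a", "b")), m)
  expect_equal(sm$label[19L], 1L)
  expect_true(all(sm$label[m$vertices[, 1L] >= 7] == 2L))
})

test_that("labeling CSV round-trips", {
  lab <- region_labeling_for_test(c(1L, 2L, 2L, 1L, 3L),
                                  c("left_eye", "nose", "frame"))
  tf <- withr::local_tempfile(fileext = ".csv")
  write_labeling(lab, tf)
  lab2 <- read_labeling(tf)
  expect_identical(lab2$label, lab$label)
  expect_identical(lab2$names, lab$names)
})
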