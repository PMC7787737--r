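# shared fixtures, generated in code and cached per test run

# a small synthetic population (20x20 head, 14 pairs) with planted labels
small_pop <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- generator_config(n_theta = 20L, n_phi = 20L, n = 14L, seed = 9L)
      cache <<- sample_population(cfg)
    }
    cache
  }
})

# a trained tiny bundle on planted labels (shared across pipeline tests)
tiny_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pop <- small_pop()
      sp <- split_samples(pop$samples, 2L, seed = 1L)
      pl <- pop$truth$labeling
      skl <- craniofuse:::region_labeling(pl$label, pl$names, "skull")
      mel <- craniofuse:::mean_edge_length(pop$samples$pairs[[1L]]$face)
      conf <- cfr_config(seed = 1L, attributes = TRUE, S0 = 0.9 * mel)
      cache <<- list(
        bundle = train_cfr(sp$train, conf, skull_labeling = skl,
                           face_labeling = pl),
        train = sp$train, test = sp$test, pop = pop)
    }
    cache
  }
})

# random valid triangle mesh (a jittered grid patch)
random_grid_mesh <- function(nx = 6L, ny = 6L, seed = 1L, jitter = 0.1) {
  set.seed(seed)
  g <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  v <- cbind(g$x, g$y, 0) + matrix(rnorm(3L * nx * ny, 0, jitter), ncol = 3L)
  id <- function(i, j) (j - 1L) * nx + i
  f <- NULL
  for (j in seq_len(ny - 1L)) {
    for (i in seq_len(nx - 1L)) {
      f <- rbind(f, c(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L)),
                 c(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L)))
    }
  }
  tri_mesh(v, f)
}

# rotation matrix about z by angle (degrees)
rot_z <- function(deg) {
  a <- deg * pi / 180
  rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
}

# fraction of variance of the planted latents unexplained by an affine map
# of the recovered ones (independent oracle for latent-recovery checks)
affine_residual <- function(recovered, planted) {
  fit <- stats::lm(planted ~ recovered)
  sum(stats::residuals(fit)^2) / sum(scale(planted, scale = FALSE)^2)
}

# public-ish handle on the internal labeling constructor for test scaffolding
region_labeling_for_test <- function(label, names, modality = "face") {
  craniofuse:::region_labeling(label, names, modality)
}

# the full-scale study bundle (default generator, 60/12 split), shared by
# the end-to-end acceptance checks
full_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- generator_config(seed = 42L)
      pop <- sample_population(cfg)
      sp <- split_samples(pop$samples, 12L, seed = 1L)
      conf <- cfr_config(attributes = TRUE, tune = TRUE, seed = 1L)
      cache <<- list(
        bundle = suppressWarnings(train_cfr(sp$train, conf)),
        train = sp$train, test = sp$test, pop = pop, conf = conf)
    }
    cache
  }
})
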