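#' Configuration of the synthetic paired-mesh population generator
#'
#' The generator emulates the statistical role of a corresponded skull/face
#' CT database: paired shape families driven by shared region-wise
#' low-dimensional latent factors (linear on the skull side, nonlinear on
#' the face side, and different in every region), attribute effects of age
#' and BMI on the facial soft-tissue offset, and additive vertex noise.
#'
#' @param n_theta,n_phi grid resolution of the head parameterization
#'   (>= 8 each); the template has `n_theta * n_phi + 2` vertices.
#' @param n number of sample pairs (>= 2).
#' @param q_r latent dimensions per region (single value or named vector
#'   over `left_eye`, `right_eye`, `nose`, `mouth`, `frame`).
#' @param amplitudes displacement amplitude per region, mm.
#' @param base_depth soft-tissue base depth (face offset from skull), mm.
#' @param beta_age age effect on facial offset, mm per decade from age 45.
#' @param beta_bmi BMI effect on facial offset, mm per kg/m^2 from BMI 24.
#' @param sigma_noise additive Gaussian vertex noise s.d., mm.
#' @param seed integer seed; the whole population is deterministic given it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_theta = 40L, n_phi = 40L, n = 72L, q_r = 3L,
                             amplitudes = c(left_eye = 3.5, right_eye = 3.5,
                                            nose = 3.5, mouth = 3.5, frame = 3.0),
                             base_depth = 6, beta_age = 0.3, beta_bmi = 0.25,
                             sigma_noise = 0.2, seed = 1L) {
  if (n_theta < 8L || n_phi < 8L) stop("grid resolution must be at least 8 x 8")
  if (n < 2L) stop("need n >= 2 samples")
  if (any(amplitudes < 0) || base_depth <= 0 || sigma_noise < 0)
    stop("amplitudes must be >= 0, base_depth > 0, sigma_noise >= 0")
  regions <- c("left_eye", "right_eye", "nose", "mouth", "frame")
  if (length(q_r) == 1L) q_r <- stats::setNames(rep(as.integer(q_r), 5L), regions)
  if (!all(regions %in% names(q_r))) stop("q_r must name all five regions")
  if (!all(regions %in% names(amplitudes))) stop("amplitudes must name all five regions")
  structure(list(n_theta = as.integer(n_theta), n_phi = as.integer(n_phi),
                 n = as.integer(n), q_r = q_r[regions],
                 amplitudes = amplitudes[regions], base_depth = base_depth,
                 beta_age = beta_age, beta_bmi = beta_bmi,
                 sigma_noise = sigma_noise, seed = as.integer(seed)),
            class = "generator_config")
}

# region boxes in normalized (theta/pi, phi/pi) coordinates; the gaps between
# boxes keep the blend bands of neighbouring regions disjoint at default S0
synth_region_boxes <- function() {
  list(right_eye = list(th = c(0.12, 0.40), ph = c(0.06, 0.42)),
       left_eye  = list(th = c(0.12, 0.40), ph = c(0.63, 0.97)),
       nose      = list(th = c(0.505, 0.68), ph = c(0.30, 0.70)),
       mouth     = list(th = c(0.78, 0.95), ph = c(0.28, 0.72)))
}

#' Build the template skull/face pair with planted regions
#'
#' A deformed-ellipsoid grid head (half-axes 70 x 85 x 90 mm; x lateral,
#' y forward out of the face, z up) closed with two pole vertices; the face
#' template is the skull offset outward along its vertex normals by the
#' soft-tissue base depth. Five contiguous regions (two lateral eyes, a
#' central nose, a lower mouth, remainder frame) are planted from the grid
#' parameterization.
#'
#' @param config a [generator_config()].
#' @return List with `skull`, `face` ([tri_mesh], shared topology),
#'   `labeling` (planted `region_labeling`), `theta`/`phi` per vertex, and
#'   the per-vertex region window functions used by the displacement fields.
#' @export
make_template <- function(config) {
  nt <- config$n_theta; np <- config$n_phi
  i <- rep(seq_len(nt), each = np)
  j <- rep(seq_len(np), times = nt)
  theta <- pi * i / (nt + 1)
  phi <- 2 * pi * (j - 1) / np
  ax <- c(70, 85, 90)
  V <- cbind(ax[1L] * sin(theta) * cos(phi),
             ax[2L] * sin(theta) * sin(phi),
             ax[3L] * cos(theta))
  top <- c(0, 0, ax[3L]); bottom <- c(0, 0, -ax[3L])
  V <- rbind(V, top, bottom)
  ntv <- nt * np
  id <- function(ii, jj) (ii - 1L) * np + ((jj - 1L) %% np) + 1L
  quads <- NULL
  for (ii in seq_len(nt - 1L)) {
    jj <- seq_len(np)
    a <- id(ii, jj); b <- id(ii, jj + 1L); cc <- id(ii + 1L, jj + 1L); d <- id(ii + 1L, jj)
    quads <- rbind(quads, cbind(a, d, cc), cbind(a, cc, b))
  }
  jj <- seq_len(np)
  f_top <- cbind(ntv + 1L, id(1L, jj), id(1L, jj + 1L))
  f_bot <- cbind(ntv + 2L, id(nt, jj + 1L), id(nt, jj))
  F <- rbind(quads, f_top, f_bot)
  # enforce outward orientation via the signed volume
  vol <- sum(vapply(seq_len(nrow(F)), function(k) {
    p <- V[F[k, ], , drop = FALSE]
    det(p) / 6
  }, numeric(1L)))
  if (vol < 0) F <- F[, c(1L, 3L, 2L)]
  skull <- tri_mesh(V, F)
  theta_all <- c(theta, 0, pi)
  phi_all <- c(phi, 0, 0)
  boxes <- synth_region_boxes()
  lab <- rep(5L, nrow(V))  # frame
  names5 <- c("left_eye", "right_eye", "nose", "mouth", "frame")
  for (rn in names(boxes)) {
    b <- boxes[[rn]]
    inb <- theta_all / pi >= b$th[1L] & theta_all / pi <= b$th[2L] &
      phi_all / pi >= b$ph[1L] & phi_all / pi <= b$ph[2L]
    lab[inb] <- match(rn, names5)
  }
  counts <- tabulate(lab, 5L)
  if (any(counts[1:4] < 4L))
    stop("degenerate resolution: a planted region has fewer than 4 vertices")
  labeling <- region_labeling(lab, names5, "face")
  nrm <- vertex_normals(skull)
  face <- tri_mesh(V + config$base_depth * nrm, F)
  windows <- synth_windows(theta_all, phi_all, lab)
  list(skull = skull, face = face, labeling = labeling,
       theta = theta_all, phi = phi_all, normals = nrm, windows = windows)
}

# plateau window per region: 1 over the box interior, raised-cosine ramp to
# 0 over a narrow rim (width ~0.035 in theta/pi units, i.e. one or two mesh
# rings at typical resolutions), so region displacements stay region-local;
# the frame window is the leftover mass so displacements stay smooth
synth_windows <- function(theta, phi, lab) {
  boxes <- synth_region_boxes()
  names5 <- c("left_eye", "right_eye", "nose", "mouth", "frame")
  W <- matrix(0, length(theta), 5L, dimnames = list(NULL, names5))
  plateau <- function(x, lo, hi, w0 = 0.035) {
    t <- x - lo
    span <- hi - lo
    w <- min(w0, span / 3)
    ifelse(t <= 0 | t >= span, 0,
           ifelse(t < w, sin(pi / 2 * t / w)^2,
                  ifelse(t > span - w, sin(pi / 2 * (span - t) / w)^2, 1)))
  }
  for (rn in names(boxes)) {
    b <- boxes[[rn]]
    W[, rn] <- plateau(theta / pi, b$th[1L], b$th[2L]) *
      plateau(phi / pi, b$ph[1L], b$ph[2L])
  }
  W[, "frame"] <- pmax(1 - rowSums(W[, 1:4, drop = FALSE]), 0)
  W
}

# fixed low-order harmonics in box-local coordinates (u, v in [0, 1] across
# the region box), so the fields of one region vary within it and stay
# mutually independent even over a small box
synth_field <- function(theta, phi, k, box, shift = 0) {
  u <- (theta / pi - box$th[1L]) / (box$th[2L] - box$th[1L])
  v <- (phi / pi - box$ph[1L]) / (box$ph[2L] - box$ph[1L])
  tab <- rbind(c(1, 0), c(0, 1), c(1, 1), c(2, 0), c(0, 2), c(2, 1),
               c(1, 2), c(3, 0), c(2, 2), c(0, 3))
  a <- tab[((k - 1L) %% nrow(tab)) + 1L, ]
  cos(pi * a[1L] * u + 0.7 * shift) * cos(pi * a[2L] * v + 1.1 * shift + 0.3 * k)
}

# frame fields are global low-order modes (overall size and large-scale head
# shape), the realistic regime for the non-feature remainder
synth_frame_field <- function(theta, phi, k, shift = 0) {
  if (k == 1L) rep(1, length(theta))
  else if (k == 2L) cos(theta)
  else sin(theta) * cos(phi + shift + 0.4 * (k - 3L))
}

#' Sample a corresponded synthetic population
#'
#' Per sample: region latents `z_r ~ N(0, I)`; the skull region displacement
#' is a linear map of `z_r` through smooth windowed angular basis fields and
#' the face region displacement a distinct nonlinear map
#' (`0.6 linear + 0.35 tanh + 0.25 centered-quadratic` of mixed latents) of
#' the *same* `z_r`, so the skull-to-face relation differs between regions
#' and is nonlinear. Age ~ U(19, 75) and BMI ~ N(24, 3) add outward
#' soft-tissue offsets through fixed positive weight fields; iid Gaussian
#' vertex noise is added to both meshes.
#'
#' @param config a [generator_config()].
#' @return List with `samples` (a [sample_set]), `truth` (template, planted
#'   labeling, per-sample latents, attributes, noise-free face vertex
#'   matrices, and the generator maps' coefficients).
#' @export
sample_population <- function(config) {
  tpl <- make_template(config)
  set.seed(config$seed)
  regions <- c("left_eye", "right_eye", "nose", "mouth", "frame")
  # fixed per-region mixing matrices (drawn once, part of the ground truth)
  mix <- lapply(stats::setNames(regions, regions), function(rn) {
    q <- config$q_r[[rn]]
    list(A = rand_rot(q), B = rand_rot(q), C = rand_rot(q), D = rand_rot(q))
  })
  nrm <- tpl$normals
  nv <- n_vertices(tpl$skull)
  # basis fields per region: windowed harmonics along the template normal
  boxes <- synth_region_boxes()
  basis <- lapply(stats::setNames(regions, regions), function(rn) {
    q <- config$q_r[[rn]]
    fieldfun <- if (rn == "frame") {
      function(k, shift) synth_frame_field(tpl$theta, tpl$phi, k, shift)
    } else {
      function(k, shift) synth_field(tpl$theta, tpl$phi, k, boxes[[rn]], shift)
    }
    sk <- vapply(seq_len(q), function(k)
      tpl$windows[, rn] * fieldfun(k, 0), numeric(nv))
    fa <- vapply(seq_len(q), function(k)
      tpl$windows[, rn] * fieldfun(k, 2), numeric(nv))
    list(skull = sk, face = fa)
  })
  w_bmi <- sin(tpl$theta)
  w_age <- sin(tpl$theta) * (0.5 + 0.5 * cos(2 * tpl$phi))
  age <- stats::runif(config$n, 19, 75)
  bmi <- stats::rnorm(config$n, 24, 3)
  latents <- vector("list", config$n)
  pairs <- vector("list", config$n)
  faces_clean <- vector("list", config$n)
  for (s in seq_len(config$n)) {
    z <- lapply(stats::setNames(regions, regions), function(rn)
      stats::rnorm(config$q_r[[rn]]))
    ds <- numeric(nv); df <- numeric(nv)
    for (rn in regions) {
      amp <- config$amplitudes[[rn]]
      zr <- z[[rn]]
      ds <- ds + amp * drop(basis[[rn]]$skull %*% (mix[[rn]]$A %*% zr))
      h <- 0.6 * (mix[[rn]]$B %*% zr) +
        0.35 * tanh(1.5 * (mix[[rn]]$C %*% zr)) +
        0.25 * ((mix[[rn]]$D %*% zr)^2 - 1)
      df <- df + amp * drop(basis[[rn]]$face %*% h)
    }
    df <- df + config$beta_bmi * (bmi[[s]] - 24) * w_bmi +
      config$beta_age * (age[[s]] - 45) / 10 * w_age
    skull_v <- tpl$skull$vertices + ds * nrm
    face_v <- tpl$face$vertices + df * nrm
    faces_clean[[s]] <- face_v
    noise_s <- matrix(stats::rnorm(3 * nv, 0, config$sigma_noise), nv, 3L)
    noise_f <- matrix(stats::rnorm(3 * nv, 0, config$sigma_noise), nv, 3L)
    id <- sprintf("synth_%03d", s)
    pairs[[s]] <- corresponded_pair(
      tri_mesh(skull_v + noise_s, tpl$skull$faces),
      tri_mesh(face_v + noise_f, tpl$face$faces),
      id = id, age = age[[s]], bmi = bmi[[s]])
    latents[[s]] <- z
  }
  ids <- vapply(pairs, function(p) p$id, character(1L))
  names(latents) <- names(faces_clean) <- ids
  list(samples = sample_set(pairs),
       truth = list(template = tpl, labeling = tpl$labeling,
                    latents = latents, faces_clean = faces_clean,
                    attributes = data.frame(id = ids, age = age, bmi = bmi,
                                            stringsAsFactors = FALSE),
                    mix = mix, config = config))
}

# uniformly random rotation (QR of a Gaussian matrix, sign-fixed)
rand_rot <- function(q) {
  if (q == 1L) return(matrix(1, 1L, 1L))
  M <- matrix(stats::rnorm(q * q), q, q)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  Q * rep(sign(diag(qr.R(qr_))), each = q)
}

#' Noise-free ground-truth face of one synthetic sample
#'
#' @param truth the `truth` record from [sample_population()].
#' @param id sample id.
#' @return The noise-free face [tri_mesh]; the error floor for tests.
#' @export
oracle_best_face <- function(truth, id) {
  v <- truth$faces_clean[[id]]
  if (is.null(v)) stop("unknown sample id: ", id)
  tri_mesh(v, truth$template$face$faces)
}
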