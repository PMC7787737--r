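test_that("the squared-exponential kernel matches its closed form", {
  p <- list(lengthscales = 1, sf2 = 1, sn2 = 0.1)
  expect_equal(se_kernel(0.3, 0.3, p), 1)  # k(x, x) = sf2
  expect_equal(se_kernel(0, 1, p), exp(-0.5), tolerance = 1e-9)
  p2 <- list(lengthscales = c(0.5, 2), sf2 = 1.7, sn2 = 0.1)
  x <- c(0.2, -1); y <- c(1, 0.5)
  expect_equal(se_kernel(x, y, p2),
               1.7 * exp(-0.5 * sum((x - y)^2 / c(0.5, 2))))
  expect_equal(se_kernel(x, y, p2), se_kernel(y, x, p2))
  # monotone decay to zero with distance
  vals <- sapply(seq(0, 20, by = 1), function(d) se_kernel(0, d, p))
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[21L], 1e-10)
  expect_error(se_kernel(0, 0, list(lengthscales = -1, sf2 = 1, sn2 = 1)),
               "positive")
})

test_that("log marginal likelihood equals the dense Gaussian log-pdf oracle", {
  set.seed(21)
  X <- matrix(rnorm(15), 5L, 3L)
  Y <- matrix(rnorm(15), 5L, 3L)
  p <- list(lengthscales = c(0.5, 1, 2), sf2 = 1.3, sn2 = 0.1)
  v <- log_marginal_likelihood(X, Y, p)
  K <- craniofuse:::se_kernel_matrix(X, X, p) + diag(p$sn2, 5L)
  oracle <- sum(apply(Y, 2L, function(y)
    -0.5 * drop(t(y) %*% solve(K, y)) -
      0.5 * as.numeric(determinant(K)$modulus) - 2.5 * log(2 * pi)))
  expect_equal(v, oracle, tolerance = 1e-8)
  # closed form for M = 1, D = 1, y = 0
  v1 <- log_marginal_likelihood(matrix(0), matrix(0), p = list(
    lengthscales = 1, sf2 = 2, sn2 = 0.5))
  expect_equal(v1, -0.5 * log(2 * pi * 2.5), tolerance = 1e-12)
  # isotropic lengthscales: invariant under orthogonal rotation of X
  piso <- list(lengthscales = c(1.3, 1.3, 1.3), sf2 = 1, sn2 = 0.2)
  Q <- qr.Q(qr(matrix(rnorm(9), 3L)))
  expect_equal(log_marginal_likelihood(X, Y, piso),
               log_marginal_likelihood(X %*% Q, Y, piso), tolerance = 1e-9)
})

test_that("likelihood gradients match central finite differences", {
  set.seed(22)
  X <- matrix(rnorm(12), 4L, 3L)
  Y <- matrix(rnorm(20), 4L, 5L)
  p <- list(lengthscales = c(0.7, 1.2, 2), sf2 = 0.9, sn2 = 0.3)
  g <- log_marginal_likelihood(X, Y, p, gradients = TRUE)
  eps <- 1e-6
  for (idx in list(c(1L, 1L), c(3L, 2L), c(4L, 3L))) {
    Xp <- X; Xp[idx[1L], idx[2L]] <- Xp[idx[1L], idx[2L]] + eps
    Xm <- X; Xm[idx[1L], idx[2L]] <- Xm[idx[1L], idx[2L]] - eps
    fd <- (log_marginal_likelihood(Xp, Y, p) -
             log_marginal_likelihood(Xm, Y, p)) / (2 * eps)
    expect_equal(g$grad_X[idx[1L], idx[2L]], fd, tolerance = 1e-5)
  }
  th <- c(log(p$lengthscales), log(p$sf2), log(p$sn2))
  for (i in seq_along(th)) {
    thp <- th; thp[i] <- thp[i] + eps
    thm <- th; thm[i] <- thm[i] - eps
    mk <- function(t) list(lengthscales = exp(t[1:3]), sf2 = exp(t[4L]),
                           sn2 = exp(t[5L]))
    fd <- (log_marginal_likelihood(X, Y, mk(thp)) -
             log_marginal_likelihood(X, Y, mk(thm))) / (2 * eps)
    expect_equal(g$grad_log_params[i], fd, tolerance = 1e-5)
  }
})

test_that("fit_gplvm recovers planted latents up to an affine map", {
  set.seed(23)
  Z <- matrix(rnorm(40), 20L, 2L)
  Y <- Z %*% matrix(rnorm(60), 2L, 30L) + 0.01 * matrix(rnorm(600), 20L)
  fit <- fit_gplvm(Y, 2L)
  expect_gte(fit$objective, fit$objective_init)
  expect_lt(affine_residual(fit$X, Z), 0.05)
  # same seed and data: bit-identical result
  fit2 <- fit_gplvm(Y, 2L)
  expect_identical(fit$X, fit2$X)
  expect_identical(fit$params, fit2$params)
  expect_error(fit_gplvm(Y[1:3, ], 2L), "q \\+ 2")
})

test_that("decoding interpolates training data and reverts to the prior", {
  set.seed(24)
  Z <- matrix(rnorm(24), 12L, 2L)
  Y <- Z %*% matrix(rnorm(16), 2L, 8L) + 0.005 * matrix(rnorm(96), 12L)
  fit <- fit_gplvm(Y, 2L)
  # near-noiseless: decoding a training latent returns that training row
  i <- 5L
  dec <- gplvm_decode(fit, fit$X[i, ])
  expect_lt(max(abs(dec$mean - Y[i, ])), 50 * sqrt(fit$params$sn2))
  expect_gte(dec$var, 0)
  expect_lte(dec$var, fit$params$sf2 + 1e-6)
  # far from all training latents: mean reverts to the data mean, variance
  # to the prior
  far <- gplvm_decode(fit, c(1e3, 1e3))
  expect_lt(max(abs(far$mean - fit$mean)), 1e-8)
  expect_equal(far$var, fit$params$sf2, tolerance = 1e-8)
  expect_error(gplvm_decode(fit, c(1, 2, 3)), "mismatch")
})

test_that("2-point decode agrees with an independent linear-solve oracle", {
  X <- matrix(c(-0.5, 0.7), 2L, 1L)
  Yc <- matrix(c(1.2, -0.4, 0.3, 0.9), 2L, 2L)
  p <- list(lengthscales = 0.8, sf2 = 1.5, sn2 = 0.05)
  model <- structure(list(
    X = X, Yc = Yc, mean = c(10, 20), params = p,
    chol = chol(craniofuse:::se_kernel_matrix(X, X, p) + diag(p$sn2, 2L)),
    alpha = solve(craniofuse:::se_kernel_matrix(X, X, p) + diag(p$sn2, 2L), Yc),
    q = 1L), class = "gplvm")
  xs <- 0.2
  out <- gplvm_decode(model, xs)
  K <- craniofuse:::se_kernel_matrix(X, X, p) + diag(p$sn2, 2L)
  k <- p$sf2 * exp(-0.5 * (xs - X[, 1L])^2 / p$lengthscales)
  mu_o <- drop(t(k) %*% solve(K) %*% Yc) + c(10, 20)
  v_o <- p$sf2 - drop(t(k) %*% solve(K) %*% k)
  expect_equal(out$mean, mu_o, tolerance = 1e-10)
  expect_equal(out$var, v_o, tolerance = 1e-10)
})

test_that("encoding recovers the latent of a training shape", {
  set.seed(25)
  Z <- matrix(rnorm(30), 15L, 2L)
  Y <- Z %*% matrix(rnorm(40), 2L, 20L) + 0.005 * matrix(rnorm(300), 15L)
  fit <- fit_gplvm(Y, 2L)
  spread <- stats::sd(fit$X)
  for (i in c(3L, 11L)) {
    x <- gplvm_encode(fit, Y[i, ])
    expect_lt(sqrt(sum((x - fit$X[i, ])^2)) / spread, 1e-2)
  }
  # two inits in the same basin agree
  xa <- gplvm_encode(fit, Y[3L, ], init = "nn")
  xb <- gplvm_encode(fit, Y[3L, ], init = fit$X[3L, ] + 0.05)
  expect_lt(max(abs(xa - xb)), 1e-4)
  # encoding the data mean returns something finite
  xm <- gplvm_encode(fit, fit$mean)
  expect_true(all(is.finite(xm)))
  expect_error(gplvm_encode(fit, 1:3), "mismatch")
})

test_that("encode/decode round-trips latents drawn in the training hull", {
  set.seed(26)
  Z <- matrix(rnorm(36), 18L, 2L)
  Y <- cbind(Z, Z^2 / 2) %*% matrix(rnorm(4 * 12), 4L, 12L) +
    0.01 * matrix(rnorm(216), 18L)
  fit <- fit_gplvm(Y, 2L)
  spread <- stats::sd(fit$X)
  set.seed(27)
  for (rep in 1:3) {
    w <- runif(nrow(fit$X)); w <- w / sum(w)
    x0 <- drop(w %*% fit$X)  # inside the convex hull
    y0 <- gplvm_decode(fit, x0)$mean
    x1 <- gplvm_encode(fit, y0, init = x0 + 0.2 * rnorm(2L))
    expect_lt(sqrt(sum((x1 - x0)^2)) / spread, 0.15)
  }
})
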