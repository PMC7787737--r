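#' Squared-exponential (ARD) kernel value
#'
#' `k(x, x') = sigma_f^2 * exp(-1/2 * sum_d (x_d - x'_d)^2 / M_d)` with one
#' lengthscale `M_d` per latent dimension (automatic relevance
#' determination).
#'
#' @param x,x2 latent vectors of equal length.
#' @param params list with `lengthscales` (positive vector), `sf2` (signal
#'   variance), `sn2` (noise variance; not added here).
#' @return Scalar covariance, in `(0, sf2]`.
#' @export
se_kernel <- function(x, x2, params) {
  check_kernel_params(params, length(x))
  if (length(x) != length(x2)) stop("latent dimension mismatch")
  params$sf2 * exp(-0.5 * sum((x - x2)^2 / params$lengthscales))
}

check_kernel_params <- function(params, q) {
  if (any(params$lengthscales <= 0) || params$sf2 <= 0 || params$sn2 <= 0)
    stop("kernel parameters must be strictly positive")
  if (length(params$lengthscales) != q)
    stop("lengthscale count must equal latent dimension")
  invisible(params)
}

# kernel matrix between latent row-sets (no noise term)
se_kernel_matrix <- function(X, X2, params) {
  Xs <- sweep(X, 2L, sqrt(params$lengthscales), "/")
  X2s <- sweep(X2, 2L, sqrt(params$lengthscales), "/")
  d2 <- outer(rowSums(Xs^2), rowSums(X2s^2), `+`) - 2 * Xs %*% t(X2s)
  params$sf2 * exp(-0.5 * pmax(d2, 0))
}

# Cholesky of K + sn2 I with an escalating jitter ladder
chol_with_jitter <- function(Ksn) {
  jit <- 0
  for (j in c(0, 10^seq(-10, -6))) {
    ch <- tryCatch(chol(Ksn + diag(j, nrow(Ksn))), error = function(e) NULL)
    if (!is.null(ch)) return(list(chol = ch, jitter = j))
  }
  stop("Cholesky factorization failed even with jitter up to 1e-6")
}

#' GP-LVM log marginal likelihood and gradients
#'
#' The standard multi-output GP-LVM objective: all `D` output dimensions
#' share one latent configuration `X` and one kernel, so
#' `L = -(D/2) log det(K + sn2 I) - (1/2) tr((K + sn2 I)^{-1} Y Y^T)
#'    - (M D / 2) log 2 pi`,
#' i.e. the sum over output dimensions of the log-density of each centered
#' data column under `N(0, K + sn2 I)`.
#'
#' @param X `M x q` latent coordinates.
#' @param Y_centered `M x D` centered data.
#' @param params kernel parameters (see [se_kernel()]).
#' @param gradients if `TRUE`, attach gradients with respect to `X` and the
#'   log-parameters `(log lengthscales, log sf2, log sn2)`.
#' @return Scalar log likelihood; with `gradients`, a list
#'   `(value, grad_X, grad_log_params)`.
#' @export
log_marginal_likelihood <- function(X, Y_centered, params, gradients = FALSE) {
  X <- as.matrix(X); Y <- as.matrix(Y_centered)
  q <- ncol(X); M <- nrow(X); D <- ncol(Y)
  check_kernel_params(params, q)
  K <- se_kernel_matrix(X, X, params)
  Ksn <- K + diag(params$sn2, M)
  ch <- chol_with_jitter(Ksn)$chol
  logdet <- 2 * sum(log(diag(ch)))
  Ainv_Y <- backsolve(ch, forwardsolve(t(ch), Y))
  val <- -0.5 * D * logdet - 0.5 * sum(Y * Ainv_Y) - 0.5 * M * D * log(2 * pi)
  if (!gradients) return(val)
  Kinv <- chol2inv(ch)
  # dL/dKsn = 1/2 (Kinv Y Y^T Kinv - D Kinv)
  G <- 0.5 * (Ainv_Y %*% t(Ainv_Y) - D * Kinv)
  H <- G * K
  grad_X <- matrix(0, M, q)
  for (d in seq_len(q)) {
    xd <- X[, d]
    grad_X[, d] <- (2 / params$lengthscales[[d]]) *
      (H %*% xd - xd * rowSums(H))
  }
  grad_lls <- vapply(seq_len(q), function(d) {
    D2 <- outer(X[, d], X[, d], `-`)^2 / params$lengthscales[[d]]
    sum(G * (K * D2 / 2))
  }, numeric(1L))
  grad_lsf2 <- sum(G * K)
  grad_lsn2 <- params$sn2 * sum(diag(G))
  list(value = val, grad_X = grad_X,
       grad_log_params = c(grad_lls, grad_lsf2, grad_lsn2))
}

#' Fit a Gaussian process latent variable model
#'
#' Centers the data, initializes the latent coordinates from PCA scores, and
#' jointly optimizes latents and log kernel hyperparameters by L-BFGS on the
#' log marginal likelihood. The returned objective is never below its value
#' at initialization.
#'
#' @param Y `M x D` shape matrix (rows = samples, e.g. flattened region
#'   vertices in mm).
#' @param q latent dimension, `q <= M - 2`.
#' @param maxit optimizer iteration cap.
#' @param seed seed (kept for provenance; the fit itself is deterministic).
#' @param modality,region tags carried in the model.
#' @return Object of class `gplvm`: latents `X`, centered data `Yc`, data
#'   mean `mean`, kernel `params`, cached `chol`, `alpha = (K+sn2 I)^{-1} Yc`,
#'   objective values at init and optimum.
#' @export
fit_gplvm <- function(Y, q, maxit = 200L, seed = 1L,
                      modality = NA_character_, region = NA_character_) {
  Y <- as.matrix(Y)
  M <- nrow(Y); D <- ncol(Y)
  if (M < q + 2L) stop("need at least q + 2 samples (got M = ", M, ", q = ", q, ")")
  mu <- colMeans(Y)
  Yc <- sweep(Y, 2L, mu)
  # PCA init, unit-variance latent columns
  dec <- svd(Yc, nu = q, nv = 0L)
  X0 <- dec$u * rep(dec$d[seq_len(q)], each = M) / sqrt(M)
  csd <- apply(X0, 2L, stats::sd)
  csd[csd == 0] <- 1
  X0 <- sweep(X0, 2L, csd, "/")
  tot_var <- mean(apply(Yc, 2L, stats::var)) + 1e-12
  theta0 <- c(as.vector(X0), rep(0, q), log(tot_var), log(tot_var * 0.01 + 1e-10))
  unpack <- function(theta) {
    X <- matrix(theta[seq_len(M * q)], M, q)
    lp <- theta[-seq_len(M * q)]
    list(X = X, params = list(lengthscales = exp(lp[seq_len(q)]),
                              sf2 = exp(lp[q + 1L]), sn2 = exp(lp[q + 2L])))
  }
  fn <- function(theta) {
    p <- unpack(theta)
    -log_marginal_likelihood(p$X, Yc, p$params)
  }
  gr <- function(theta) {
    p <- unpack(theta)
    g <- log_marginal_likelihood(p$X, Yc, p$params, gradients = TRUE)
    -c(as.vector(g$grad_X), g$grad_log_params)
  }
  # bound log-params to keep the kernel numerically sane
  lower <- c(rep(-Inf, M * q), rep(log(1e-6), q), log(tot_var * 1e-8 + 1e-300),
             log(tot_var * 1e-10 + 1e-300))
  upper <- c(rep(Inf, M * q), rep(log(1e6), q), log(tot_var * 1e4 + 1e300),
             log(tot_var * 1e2 + 1e-6))
  opt <- stats::optim(theta0, fn, gr, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = maxit, factr = 1e7))
  L0 <- -fn(theta0)
  Lopt <- -opt$value
  theta <- if (Lopt >= L0) opt$par else theta0
  p <- unpack(theta)
  K <- se_kernel_matrix(p$X, p$X, p$params)
  ch <- chol_with_jitter(K + diag(p$params$sn2, M))
  alpha <- backsolve(ch$chol, forwardsolve(t(ch$chol), Yc))
  structure(list(X = p$X, Yc = Yc, mean = mu, params = p$params,
                 chol = ch$chol, jitter = ch$jitter, alpha = alpha,
                 q = q, objective_init = L0, objective = max(Lopt, L0),
                 modality = modality, region = region, seed = seed),
            class = "gplvm")
}

#' @export
print.gplvm <- function(x, ...) {
  cat(sprintf("gplvm [%s/%s]: M=%d, D=%d, q=%d, logL=%.2f\n",
              x$modality, x$region, nrow(x$X), ncol(x$Yc), x$q, x$objective))
  invisible(x)
}

#' Decode a latent point to a shape vector
#'
#' GP posterior prediction at `x_star`: mean
#' `mu* = k(x*, X) (K + sn2 I)^{-1} Y` per output dimension plus the stored
#' data mean, and shared predictive variance
#' `Sigma* = k(x*, x*) - k(x*, X) (K + sn2 I)^{-1} k(X, x*)`.
#'
#' @param model a [fit_gplvm()] model.
#' @param x_star latent vector of length `q`.
#' @return List with `mean` (length-D shape vector, mm) and `var`
#'   (non-negative scalar, bounded by `sf2` plus jitter).
#' @export
gplvm_decode <- function(model, x_star) {
  if (length(x_star) != model$q) stop("latent dimension mismatch")
  k <- se_kernel_matrix(matrix(x_star, 1L), model$X, model$params)
  mu <- drop(k %*% model$alpha) + model$mean
  kk <- backsolve(model$chol, forwardsolve(t(model$chol), drop(k)))
  v <- model$params$sf2 - sum(drop(k) * kk)
  list(mean = mu, var = max(v, 0))
}

#' Project a new shape into the latent space
#'
#' The inverse mapping the reconstruction step needs: finds the latent point
#' whose predictive density best explains `y_new`, i.e. minimizes
#' `D/2 log v(x) + ||y - mu(x)||^2 / (2 v(x))` with
#' `v(x) = Sigma*(x) + sn2`, by BFGS with analytic gradients from an
#' initial point (`"nn"` = latent of the nearest training shape in data
#' space).
#'
#' @param model a [fit_gplvm()] model.
#' @param y_new length-D shape vector (same vertex subset and order as the
#'   training shapes).
#' @param init `"nn"` or a numeric length-q starting point.
#' @param maxit optimizer cap.
#' @return Latent vector of length `q`; attribute `converged` is `FALSE`
#'   (with a warning) if the optimizer failed, in which case the best
#'   iterate is returned.
#' @export
gplvm_encode <- function(model, y_new, init = "nn", maxit = 200L) {
  D <- ncol(model$Yc)
  if (length(y_new) != D) stop("shape vector length mismatch")
  yc <- y_new - model$mean
  # multi-start: the requested init plus the latents of the nearest
  # training shapes in data space (the likelihood surface is sharp when
  # sn2 is small, and a single start can be caught by the wrong basin)
  d2 <- rowSums(sweep(model$Yc, 2L, yc)^2)
  nn_idx <- order(d2)[seq_len(min(3L, nrow(model$X)))]
  starts <- lapply(nn_idx, function(i) model$X[i, ])
  if (!identical(init, "nn")) {
    if (length(init) != model$q) stop("init must be 'nn' or a length-q vector")
    starts <- c(list(as.numeric(init)), starts)
  }
  ls <- model$params$lengthscales
  obj <- function(x) {
    k <- drop(se_kernel_matrix(matrix(x, 1L), model$X, model$params))
    mu <- drop(crossprod(model$alpha, k))
    Kik <- backsolve(model$chol, forwardsolve(t(model$chol), k))
    v <- max(model$params$sf2 - sum(k * Kik), 0) + model$params$sn2
    r <- yc - mu
    0.5 * D * log(v) + sum(r^2) / (2 * v)
  }
  grd <- function(x) {
    k <- drop(se_kernel_matrix(matrix(x, 1L), model$X, model$params))
    mu <- drop(crossprod(model$alpha, k))
    Kik <- backsolve(model$chol, forwardsolve(t(model$chol), k))
    v <- max(model$params$sf2 - sum(k * Kik), 0) + model$params$sn2
    r <- yc - mu
    rr <- sum(r^2)
    g <- numeric(model$q)
    Ar <- model$alpha %*% r           # M-vector: d(mu . r)/dk
    for (d in seq_len(model$q)) {
      dk <- k * (model$X[, d] - x[[d]]) / ls[[d]]
      dv <- -2 * sum(Kik * dk)
      dmu_r <- sum(Ar * dk)
      g[[d]] <- 0.5 * D * dv / v - dmu_r / v - rr * dv / (2 * v^2)
    }
    g
  }
  # constrain the search to the training latent hull (with margin): outside
  # it the posterior reverts to the prior, the objective flattens and an
  # unconstrained step can strand the optimizer on the plateau
  margin <- apply(model$X, 2L, stats::sd)
  lower <- apply(model$X, 2L, min) - 1.5 * margin
  upper <- apply(model$X, 2L, max) + 1.5 * margin
  best <- starts[[1L]]
  best_val <- obj(best)
  ok <- FALSE
  for (x0 in starts) {
    if (obj(x0) < best_val) { best <- x0; best_val <- obj(x0) }
    # quasi-Newton run, then a simplex refinement: when sn2 is small the
    # basin around the optimum is narrow and a long line-search step can
    # jump across it, which the step-limited simplex does not
    res <- tryCatch(
      stats::optim(x0, obj, grd, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = maxit, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(res) && res$convergence == 0L &&
        res$value <= best_val + 1e-10 * (1 + abs(best_val))) ok <- TRUE
    if (!is.null(res) && res$value < best_val) {
      best <- as.numeric(res$par)
      best_val <- res$value
    }
    nm <- tryCatch(
      stats::optim(x0, obj, method = "Nelder-Mead",
                   control = list(maxit = 50L * model$q, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(nm) && nm$value < best_val) {
      best <- as.numeric(nm$par)
      best_val <- nm$value
      ok <- TRUE
    }
  }
  # final polish from the overall best point
  fin <- tryCatch(
    stats::optim(best, obj, grd, method = "L-BFGS-B", lower = pmin(lower, best),
                 upper = pmax(upper, best),
                 control = list(maxit = maxit, factr = 1e4)),
    error = function(e) NULL)
  if (!is.null(fin) && fin$value <= best_val) {
    best <- as.numeric(fin$par)
    best_val <- fin$value
    ok <- ok || fin$convergence == 0L
  }
  if (!ok) warning("gplvm_encode: optimizer did not improve on its starts; ",
                   "returning the best candidate")
  structure(best, converged = ok)
}
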