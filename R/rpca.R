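#' Robust principal component analysis (principal component pursuit)
#'
#' Decomposes `X = L + S` with `L` low-rank and `S` sparse by minimizing
#' `||L||_* + lambda ||S||_1`, solved with the inexact augmented Lagrangian
#' method (singular-value thresholding on `L`, soft thresholding on `S`).
#' Used to denoise per-vertex feature matrices before clustering.
#'
#' @param X numeric matrix with finite entries.
#' @param lambda sparsity weight; default `1/sqrt(max(dim(X)))`.
#' @param tol relative Frobenius tolerance on `||X - L - S||`.
#' @param max_iter maximum iterations; on non-convergence the best iterate is
#'   returned with a warning.
#' @return List with `L`, `S`, `iterations`, `converged`.
#' @export
rpca_decompose <- function(X, lambda = NULL, tol = 1e-7, max_iter = 200) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("rpca_decompose: X must be finite")
  if (is.null(lambda)) lambda <- 1 / sqrt(max(dim(X)))
  normX <- sqrt(sum(X^2))
  if (normX == 0) {
    return(list(L = X, S = X, iterations = 0L, converged = TRUE))
  }
  sv <- svd(X, nu = 0L, nv = 0L)$d
  norm2 <- sv[1L]
  norm_inf <- max(abs(X)) / lambda
  Y <- X / max(norm2, norm_inf)
  mu <- 1.25 / norm2
  mu_bar <- mu * 1e7
  rho <- 1.5
  S <- matrix(0, nrow(X), ncol(X))
  L <- S
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # L-step: singular value thresholding
    dec <- svd(X - S + Y / mu)
    dth <- pmax(dec$d - 1 / mu, 0)
    r <- sum(dth > 0)
    L <- if (r > 0) {
      dec$u[, seq_len(r), drop = FALSE] %*% (dth[seq_len(r)] *
        t(dec$v[, seq_len(r), drop = FALSE]))
    } else matrix(0, nrow(X), ncol(X))
    # S-step: soft thresholding
    Tm <- X - L + Y / mu
    S <- sign(Tm) * pmax(abs(Tm) - lambda / mu, 0)
    Z <- X - L - S
    Y <- Y + mu * Z
    mu <- min(mu * rho, mu_bar)
    if (sqrt(sum(Z^2)) / normX < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("rpca_decompose: no convergence in ", max_iter,
            " iterations; returning best iterate")
  list(L = L, S = S, iterations = it, converged = converged)
}
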