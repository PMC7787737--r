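rbf_kernel_matrix <- function(X, X2, sigma2) {
  d2 <- outer(rowSums(X^2), rowSums(X2^2), `+`) - 2 * X %*% t(X2)
  exp(-pmax(d2, 0) / (2 * sigma2))
}

#' Train a least-squares support vector regressor (RBF kernel)
#'
#' LSSVR replaces the inequality constraints of classic SVR with equality
#' constraints and squared slacks, so training reduces to one linear KKT
#' system:
#' `[[0, 1^T], [1, Omega + I/C_reg]] [b; alpha] = [0; y]` with
#' `Omega_ij = exp(-||x_i - x_j||^2 / (2 sigma2))`. The first KKT row forces
#' `sum(alpha) = 0`.
#'
#' @param X `n x p` input matrix (n >= 2).
#' @param y length-n target vector.
#' @param C_reg regularization parameter (> 0); larger values interpolate
#'   the training data more tightly.
#' @param sigma2 RBF kernel width (> 0).
#' @return Object of class `lssvr`: `X` (support inputs), `alpha`, `b`,
#'   `sigma2`, `C_reg`.
#' @export
train_lssvr <- function(X, y, C_reg = 1000, sigma2 = 100) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 training points")
  if (C_reg <= 0 || sigma2 <= 0) stop("C_reg and sigma2 must be positive")
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  sol <- lssvr_solve(X, matrix(y, ncol = 1L), C_reg, sigma2)
  structure(list(X = X, alpha = sol$alpha[, 1L], b = sol$b[[1L]],
                 sigma2 = sigma2, C_reg = C_reg),
            class = "lssvr")
}

# shared KKT solve; Y may have several columns (one system, many RHS)
lssvr_solve <- function(X, Y, C_reg, sigma2) {
  n <- nrow(X)
  Omega <- rbf_kernel_matrix(X, X, sigma2)
  A <- rbind(c(0, rep(1, n)), cbind(1, Omega + diag(1 / C_reg, n)))
  rhs <- rbind(0, Y)
  sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
  if (is.null(sol)) {
    A[-1L, -1L] <- A[-1L, -1L] + diag(1e-10, n)
    sol <- tryCatch(solve(A, rhs), error = function(e)
      stop("singular LSSVR KKT system even after jitter"))
  }
  list(b = sol[1L, ], alpha = sol[-1L, , drop = FALSE])
}

#' Predict from an LSSVR model
#'
#' `f(x) = sum_i alpha_i exp(-||x - x_i||^2 / (2 sigma2)) + b`.
#'
#' @param model a [train_lssvr()] model.
#' @param x a length-p vector or an `m x p` matrix of query points.
#' @return Numeric vector of predictions.
#' @export
predict_lssvr <- function(model, x) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(x) != ncol(model$X)) stop("input dimension mismatch")
  drop(rbf_kernel_matrix(x, model$X, model$sigma2) %*% model$alpha + model$b)
}

#' Train a multi-output LSSVR
#'
#' One independent LSSVR per output column, all sharing the same support
#' inputs, hyperparameters and (standardized) input scaling, so only one KKT
#' factorization is needed.
#'
#' @param X `n x p` inputs; standardized internally (zero-variance columns
#'   are centered only), the statistics stored for prediction.
#' @param Y `n x k` targets.
#' @inheritParams train_lssvr
#' @return Object of class `multi_lssvr`: `X` (standardized supports),
#'   `alpha` (`n x k`), `b` (length k), `sigma2`, `C_reg`, `center`, `scale`.
#' @export
train_multi <- function(X, Y, C_reg = 1000, sigma2 = 100) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y row counts differ")
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  sol <- lssvr_solve(Xs, Y, C_reg, sigma2)
  structure(list(X = Xs, alpha = sol$alpha, b = sol$b,
                 sigma2 = sigma2, C_reg = C_reg, center = ctr, scale = scl),
            class = "multi_lssvr")
}

#' @rdname train_multi
#' @param model a `multi_lssvr`.
#' @param x length-p vector or `m x p` matrix.
#' @return `predict_multi`: an `m x k` matrix (dropped to a vector for a
#'   single query).
#' @export
predict_multi <- function(model, x) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(x) != ncol(model$X)) stop("input dimension mismatch")
  xs <- sweep(sweep(x, 2L, model$center), 2L, model$scale, "/")
  K <- rbf_kernel_matrix(xs, model$X, model$sigma2)
  out <- K %*% model$alpha + rep(model$b, each = nrow(xs))
  if (nrow(out) == 1L) drop(out) else out
}

#' Grid-search hyperparameter tuning by k-fold cross-validation
#'
#' Realizes iterative feedback adjustment of `(C, sigma2)` as a seeded
#' k-fold CV over log-spaced grids centered on the customary initial values
#' `C = 1000`, `sigma2 = 100`.
#'
#' @param X,Y training inputs and (possibly multi-column) targets.
#' @param C_grid,sigma2_grid candidate values.
#' @param folds number of CV folds (>= 2).
#' @param seed fold-assignment seed.
#' @return List with `C_reg`, `sigma2`, and `cv` (the full mean-squared
#'   error table).
#' @export
tune_hyperparams <- function(X, Y, C_grid = 10^(2:5), sigma2_grid = 10^(0:3),
                             folds = 5L, seed = 1L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (folds < 2L) stop("folds must be >= 2")
  if (n < folds) stop("need at least `folds` samples")
  fold_id <- local({
    set.seed(as.integer(seed))
    sample(rep_len(seq_len(folds), n))
  })
  grid <- expand.grid(C_reg = C_grid, sigma2 = sigma2_grid)
  grid$mse <- vapply(seq_len(nrow(grid)), function(g) {
    errs <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      if (sum(tr) < 2L) return(NA_real_)
      m <- train_multi(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                       C_reg = grid$C_reg[[g]], sigma2 = grid$sigma2[[g]])
      pred <- predict_multi(m, X[!tr, , drop = FALSE])
      mean((as.matrix(pred) - Y[!tr, , drop = FALSE])^2)
    }, numeric(1L))
    mean(errs, na.rm = TRUE)
  }, numeric(1L))
  best <- which.min(grid$mse)
  list(C_reg = grid$C_reg[[best]], sigma2 = grid$sigma2[[best]], cv = grid)
}

#' Append z-scored attributes to latent inputs
#'
#' Attributes (age in years, BMI in kg/m^2) are z-scored with training
#' statistics — recorded so that reconstruction-time queries reuse the same
#' scaling — and concatenated after the latent dimensions.
#'
#' @param latents `n x q` latent inputs.
#' @param attrs `n x a` data frame or matrix of attributes (0 columns allowed).
#' @param stats optional list(`center`, `scale`) from a previous call; if
#'   `NULL`, computed from `attrs`.
#' @return The augmented `n x (q + a)` matrix with attribute `stats`
#'   attached.
#' @export
augment_with_attributes <- function(latents, attrs, stats = NULL) {
  latents <- as.matrix(latents)
  A <- as.matrix(attrs)
  if (ncol(A) == 0L) return(structure(latents, stats = list(center = numeric(0L),
                                                            scale = numeric(0L))))
  if (nrow(A) != nrow(latents)) stop("attribute rows must align with latent rows")
  if (anyNA(A)) stop("missing attribute value")
  if (is.null(stats)) {
    ctr <- colMeans(A)
    scl <- apply(A, 2L, stats::sd)
    if (any(scl == 0)) stop("zero-variance attribute column: ",
                            paste(colnames(A)[scl == 0], collapse = ", "))
    stats <- list(center = ctr, scale = scl)
  }
  As <- sweep(sweep(A, 2L, stats$center), 2L, stats$scale, "/")
  structure(cbind(latents, As), stats = stats)
}
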