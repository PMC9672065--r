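#' Gaussian kernel value
#'
#' `kappa(d) = exp(-d^2 / sigma^2)`.  Note the convention: there is no
#' factor 2 in the denominator, matching the kernel used throughout the
#' potential-to-density and density-to-energy maps.  Many KRR libraries
#' default to `exp(-d^2 / (2 sigma^2))`; this package does not.
#'
#' @param distance non-negative distance(s) in the input metric.
#' @param sigma positive kernel width (same units).
#' @return kernel value(s) in (0, 1].
#' @export
gaussian_kernel <- function(distance, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a positive scalar")
  if (any(distance < 0)) stop("distance must be non-negative")
  exp(-(distance / sigma)^2)
}

## Squared Euclidean cross-distances between rows of x and rows of y.
row_dist2 <- function(x, y = x) {
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  d2
}

#' Gaussian kernel matrix of a descriptor set
#'
#' Rows of `x` are descriptors whose Euclidean distance realizes the
#' model metric (potential rows from [potential_matrix()] are pre-scaled
#' so this equals the L2 potential metric).
#'
#' @param x n x d descriptor matrix.
#' @param sigma kernel width.
#' @param y optional m x d matrix for a rectangular cross-kernel.
#' @return n x n symmetric (or n x m) kernel matrix; unit diagonal in the
#'   symmetric case.
#' @export
kernel_matrix <- function(x, sigma, y = NULL) {
  x <- as.matrix(x)
  if (is.null(y)) {
    k <- exp(-row_dist2(x) / sigma^2)
    diag(k) <- 1
    (k + t(k)) / 2
  } else {
    y <- as.matrix(y)
    if (ncol(y) != ncol(x)) stop("descriptor dimensions differ")
    exp(-row_dist2(x, y) / sigma^2)
  }
}

#' Solve the kernel ridge regression normal equations
#'
#' Computes `W = (K + lambda I)^(-1) Y` by Cholesky factorization; one
#' solve is shared across all target columns.  A small floor
#' (`1e-12 * mean(diag(K))`) guards conditioning when `lambda = 0`.
#'
#' @param k square symmetric kernel matrix.
#' @param targets numeric vector or M x T matrix of regression targets.
#' @param ridge_lambda non-negative ridge strength.
#' @return a list of class `"krr_weights"` with elements `weights`
#'   (M x T matrix) and `ridge_lambda`.
#' @export
fit_ridge <- function(k, targets, ridge_lambda = 1e-12) {
  k <- as.matrix(k)
  y <- as.matrix(targets)
  if (nrow(k) != ncol(k)) stop("kernel matrix must be square")
  if (nrow(y) != nrow(k)) stop("targets row count must equal the kernel size")
  if (ridge_lambda < 0) stop("ridge_lambda must be non-negative")
  lam <- max(ridge_lambda, 1e-12 * mean(diag(k)))
  kr <- k
  diag(kr) <- diag(kr) + lam
  ch <- tryCatch(chol(kr), error = function(e)
    stop("kernel system is singular or indefinite; increase ridge_lambda ",
         "(chol: ", conditionMessage(e), ")"))
  solve2 <- function(b) backsolve(ch, backsolve(ch, b, transpose = TRUE))
  w <- solve2(y)
  ## two rounds of iterative refinement: at tiny lambda the system is
  ## ill-conditioned and the raw factorization solve loses ~6 digits;
  ## refinement restores near-machine-precision training interpolation
  for (it in 1:2) w <- w + solve2(y - kr %*% w)
  structure(list(weights = w, ridge_lambda = lam), class = "krr_weights")
}

#' Fit a Gaussian-kernel ridge regression model
#'
#' Convenience wrapper: builds the kernel matrix from descriptor rows,
#' solves the ridge system, and retains the training descriptors needed
#' for prediction.
#'
#' @param x n x d training descriptor matrix (metric-scaled).
#' @param y targets (vector or n x T matrix).
#' @param sigma Gaussian kernel width.
#' @param lambda ridge strength.
#' @return an object of class `"krr"`.
#' @export
krr_fit <- function(x, y, sigma, lambda = 1e-12) {
  x <- as.matrix(x)
  fit <- fit_ridge(kernel_matrix(x, sigma), y, lambda)
  structure(list(x = x, weights = fit$weights, sigma = sigma,
                 lambda = fit$ridge_lambda), class = "krr")
}

#' Predict from a fitted KRR model
#'
#' Evaluates `sum_i w_i kappa(d(x_i, query))` per target column.
#'
#' @param object a fitted [krr_fit()] model.
#' @param newdata m x d matrix of query descriptors (or a single vector).
#' @param ... unused.
#' @return m x T matrix of predictions.
#' @export
predict.krr <- function(object, newdata, ...) {
  q <- if (is.null(dim(newdata))) matrix(newdata, 1) else as.matrix(newdata)
  kernel_matrix(q, object$sigma, object$x) %*% object$weights
}

#' Cross-validated kernel hyperparameter selection
#'
#' K-fold grid search minimizing the mean out-of-fold MAE (averaged over
#' all target columns).  Fold assignment is shuffled with the given seed,
#' so the selection is deterministic.
#'
#' @param x descriptor matrix; rows are samples.
#' @param y targets (vector or matrix).
#' @param sigma_grid,lambda_grid candidate values (non-empty).
#' @param folds number of folds (>= 2).
#' @param seed RNG seed for the fold shuffle.
#' @return list with `sigma`, `lambda`, and the full `cv` results
#'   data.frame (columns sigma, lambda, mae).
#' @export
cross_validate <- function(x, y, sigma_grid, lambda_grid = 1e-10,
                           folds = 5L, seed = 1L) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  if (length(sigma_grid) < 1L || length(lambda_grid) < 1L)
    stop("hyperparameter grids must be non-empty")
  if (folds < 2L) stop("at least 2 folds required")
  if (n < folds) stop("fewer samples than folds")
  fold_id <- with_local_seed(seed, sample(rep_len(seq_len(folds), n)))
  grid <- expand.grid(sigma = sigma_grid, lambda = lambda_grid,
                      KEEP.OUT.ATTRS = FALSE)
  d2 <- row_dist2(x)
  grid$mae <- vapply(seq_len(nrow(grid)), function(gi) {
    sg <- grid$sigma[gi]; lm <- grid$lambda[gi]
    kfull <- exp(-d2 / sg^2)
    errs <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      fit <- fit_ridge(kfull[tr, tr, drop = FALSE], y[tr, , drop = FALSE], lm)
      pred <- kfull[!tr, tr, drop = FALSE] %*% fit$weights
      mean(abs(pred - y[!tr, , drop = FALSE]))
    }, 0)
    mean(errs)
  }, 0)
  best <- which.min(grid$mae)
  list(sigma = grid$sigma[best], lambda = grid$lambda[best], cv = grid)
}

#' Median-heuristic kernel width
#'
#' Median pairwise distance of (a subsample of) the descriptor rows; the
#' customary starting point for the Gaussian kernel width.
#'
#' @param x descriptor matrix.
#' @param n_max subsample size cap.
#' @param seed RNG seed for the subsample.
#' @return positive scalar.
#' @export
median_heuristic <- function(x, n_max = 500L, seed = 1L) {
  x <- as.matrix(x)
  if (nrow(x) > n_max)
    x <- x[with_local_seed(seed, sample(nrow(x), n_max)), , drop = FALSE]
  d2 <- row_dist2(x)
  d <- sqrt(d2[upper.tri(d2)])
  stats::median(d[d > 0])
}
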