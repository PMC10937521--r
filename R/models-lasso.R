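# Parallel-lambda LASSO bank: L independent LASSO models, one per penalty,
# stored as a p x L coefficient matrix and updated in a single pass by
# proximal stochastic gradient descent. The "parallelism" is purely an
# efficiency device -- each column follows exactly the trajectory it would
# follow trained alone with the same batch order.
#
# Objective per model: mean((y - X b - b0)^2) + lambda * sum(|b|), intercept
# unpenalized. The proximal step soft-thresholds by eta * lambda, producing
# exact zeros (subgradient descent would not).

#' Smallest all-zero penalty
#'
#' With the objective `mean((y - X b - b0)^2) + lambda * ||b||_1` and an
#' unpenalized intercept, the zero solution is optimal exactly when
#' `lambda >= 2 * max|X^T (y - mean(y))| / n`.
#'
#' @param X Feature matrix (standardized).
#' @param y Response.
#' @return `lambda_max`.
#' @export
lasso_lambda_max <- function(X, y) {
  2 * max(abs(crossprod(X, y - mean(y)))) / length(y)
}

#' Log-spaced penalty grid
#'
#' @param lambda_max Largest penalty (from [lasso_lambda_max()]).
#' @param L Grid length (default 32).
#' @param ratio Smallest/largest penalty ratio (default 1e-3).
#' @return Strictly decreasing penalty vector of length `L`.
#' @export
lasso_lambda_grid <- function(lambda_max, L = 32L, ratio = 1e-3) {
  L <- check_count(L, "L")
  if (L == 1L) return(lambda_max)
  exp(seq(log(lambda_max), log(lambda_max * ratio), length.out = L))
}

#' Initialize a LASSO bank
#'
#' All coefficients and intercepts start at zero.
#'
#' @param p Number of features.
#' @param lambda Strictly decreasing penalty grid.
#' @param feature_names Optional feature names.
#' @return A `lasso_bank`: `params` ([model_params()] with `W` `p x L` and
#'   intercept vector `b`), `lambda`, `feature_names`.
#' @export
lasso_bank <- function(p, lambda, feature_names = NULL) {
  if (any(diff(lambda) >= 0)) {
    if (length(lambda) > 1) abort("lambda grid must be strictly decreasing")
  }
  if (any(lambda < 0)) abort("penalties must be nonnegative")
  L <- length(lambda)
  params <- model_params(list(W = matrix(0, p, L), b = numeric(L)),
                         kind = "lasso_bank")
  structure(list(params = params, lambda = lambda,
                 feature_names = feature_names),
            class = "lasso_bank")
}

#' Per-penalty LASSO objective
#'
#' @param bank A `lasso_bank` (or its `params`).
#' @param X Standardized feature matrix.
#' @param y Response vector.
#' @param lambda Penalty grid (taken from `bank` if absent).
#' @return Length-L vector: MSE + `lambda * ||W_l||_1` per model.
#' @export
lasso_loss <- function(bank, X, y, lambda = NULL) {
  params <- if (inherits(bank, "lasso_bank")) bank$params else bank
  lambda <- lambda %||% bank$lambda
  W <- params$tensors$W
  if (nrow(W) != ncol(X)) abort("feature dimension mismatch")
  resid <- y - (X %*% W + rep(params$tensors$b, each = length(y)))
  colMeans(resid^2) + lambda * colSums(abs(W))
}

soft_threshold <- function(x, t) {
  s <- abs(x) - t
  s[s < 0] <- 0
  sign(x) * s
}

#' One proximal-SGD epoch over a LASSO bank
#'
#' Shuffles the data into mini-batches (seeded), then for each batch takes a
#' gradient step on the MSE term for every penalty at once and
#' soft-thresholds each column by `eta * lambda_l`; the intercept takes a
#' plain gradient step. Batch order depends only on the seed and the data,
#' never on the grid length, so each column's trajectory is identical to
#' training that penalty alone.
#'
#' @param params Bank [model_params()].
#' @param data List with `X` (standardized) and `y`.
#' @param lambda Penalty grid.
#' @param eta Learning rate for this epoch.
#' @param batch_size Mini-batch size.
#' @param seed Epoch shuffling seed.
#' @return Updated [model_params()].
#' @export
lasso_epoch <- function(params, data, lambda, eta, batch_size, seed) {
  X <- data$X; y <- data$y
  dimnames(X) <- NULL
  n <- length(y)
  W <- params$tensors$W
  b <- params$tensors$b
  order <- with_seed(seed, sample.int(n))
  starts <- seq(1L, n, by = batch_size)
  L <- length(lambda)
  for (s in starts) {
    idx <- order[s:min(s + batch_size - 1L, n)]
    Xb <- X[idx, , drop = FALSE]
    yb <- y[idx]
    nb <- length(idx)
    # one column at a time, so every penalty sees exactly the floating-point
    # operations a standalone single-penalty model would see
    for (l in seq_len(L)) {
      resid <- Xb %*% W[, l] + (b[l] - yb)
      grad_W <- crossprod(Xb, resid) * (2 / nb)
      W[, l] <- soft_threshold(W[, l] - eta * grad_W, eta * lambda[l])
      b[l] <- b[l] - eta * (2 / nb) * sum(resid)
    }
    if (!all(is.finite(b))) abort("non-finite LASSO loss; reduce the learning rate")
  }
  model_params(list(W = W, b = b), kind = "lasso_bank")
}

#' Predict from one bank member
#'
#' @param bank A `lasso_bank`.
#' @param X Standardized feature matrix.
#' @param which_lambda Column index of the penalty to use (default all).
#' @return Prediction vector (or matrix over the grid).
#' @export
lasso_predict <- function(bank, X, which_lambda = NULL) {
  W <- bank$params$tensors$W
  b <- bank$params$tensors$b
  pred <- X %*% W + rep(b, each = nrow(X))
  if (is.null(which_lambda)) pred else pred[, which_lambda]
}

#' Feature standardization parameters from training data
#'
#' Per-feature mean and SD; in the federated setting these come from one
#' (sum, sum of squares, count) aggregation round, which this function
#' reproduces exactly when given the pooled matrix. Constant features get
#' unit scale.
#'
#' @param X Raw feature matrix (training rows only).
#' @return List with `center` and `scale`.
#' @export
standardizer_fit <- function(X) {
  n <- nrow(X)
  s <- colSums(X)
  ss <- colSums(X^2)
  center <- s / n
  v <- ss / n - center^2
  scale <- sqrt(pmax(v, 0))
  scale[scale < 1e-12] <- 1
  list(center = center, scale = scale)
}

# Federated variant: aggregate (sum, sumsq, count) across client matrices.
standardizer_fit_federated <- function(X_list) {
  n <- sum(vapply(X_list, nrow, numeric(1)))
  s <- Reduce(`+`, lapply(X_list, colSums))
  ss <- Reduce(`+`, lapply(X_list, function(x) colSums(x^2)))
  center <- s / n
  scale <- sqrt(pmax(ss / n - center^2, 0))
  scale[scale < 1e-12] <- 1
  list(center = center, scale = scale)
}

standardizer_apply <- function(std, X) {
  sweep(sweep(X, 2, std$center), 2, std$scale, "/")
}

#' @method tidy lasso_bank
#' @export
tidy.lasso_bank <- function(x, ...) {
  W <- x$params$tensors$W
  nm <- x$feature_names %||% sprintf("x%d", seq_len(nrow(W)))
  tibble::tibble(
    lambda = rep(x$lambda, each = nrow(W)),
    term = rep(nm, times = length(x$lambda)),
    estimate = as.numeric(W)
  )
}

#' @method glance lasso_bank
#' @export
glance.lasso_bank <- function(x, ...) {
  tibble::tibble(
    n_lambda = length(x$lambda),
    lambda_max = max(x$lambda),
    lambda_min = min(x$lambda),
    n_features = nrow(x$params$tensors$W),
    nonzero_min = min(colSums(x$params$tensors$W != 0)),
    nonzero_max = max(colSums(x$params$tensors$W != 0))
  )
}
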