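# Fully-connected ancestry classifier: input PCs -> hidden layers with selu
# activations -> raw class scores. Written directly over model_params tensors
# so the federated engine can average, inject and perturb weights at will,
# with hand-rolled backpropagation and seeded mini-batch SGD.

SELU_SCALE <- 1.0507009873554805
SELU_ALPHA <- 1.6732632423543772

#' Scaled exponential linear unit
#' @param x Numeric input.
#' @return `scale * x` for positive input, `scale * alpha * (exp(x) - 1)`
#'   otherwise; `selu(0) = 0` exactly.
#' @export
selu <- function(x) {
  neg <- x <= 0
  out <- x
  out[neg] <- SELU_ALPHA * (exp(x[neg]) - 1)
  SELU_SCALE * out
}

selu_grad <- function(x) {
  out <- x
  pos <- x > 0
  out[pos] <- 1
  out[!pos] <- SELU_ALPHA * exp(x[!pos])
  SELU_SCALE * out
}

#' Parameter count of a fully-connected network
#'
#' @param d_in Input width.
#' @param hidden Hidden layer sizes.
#' @param d_out Output width.
#' @return Total number of weights and biases.
#' @export
mlp_count_params <- function(d_in = 20L, hidden = c(800L, 200L), d_out = 26L) {
  sizes <- c(d_in, hidden, d_out)
  sum(sizes[-length(sizes)] * sizes[-1]) + sum(sizes[-1])
}

#' Initialize an MLP
#'
#' Weights are drawn `N(0, 1/fan_in)` (the variance-scaling scheme paired
#' with selu activations); biases start at zero. The default architecture is
#' 20 inputs, hidden layers 800 and 200, 26 outputs.
#'
#' @param d_in,hidden,d_out Layer widths.
#' @param seed Integer seed.
#' @return A [model_params()] of kind `"mlp"` with a `sizes` attribute.
#' @export
mlp_init <- function(d_in = 20L, hidden = c(800L, 200L), d_out = 26L, seed = 1) {
  sizes <- as.integer(c(d_in, hidden, d_out))
  tensors <- with_seed(mix_seed(seed, 808L), {
    out <- list()
    for (l in seq_len(length(sizes) - 1L)) {
      out[[paste0("W", l)]] <- matrix(rnorm(sizes[l] * sizes[l + 1L],
                                            sd = 1 / sqrt(sizes[l])),
                                      sizes[l], sizes[l + 1L])
      out[[paste0("b", l)]] <- numeric(sizes[l + 1L])
    }
    out
  })
  params <- model_params(tensors, kind = "mlp")
  attr(params, "sizes") <- sizes
  params
}

#' Forward pass
#'
#' Affine, selu, repeated through the hidden layers; the output layer is
#' affine only and returns raw (unnormalized) class scores.
#'
#' @param params An MLP [model_params()].
#' @param X `n x d_in` input matrix (PC scores).
#' @return `n x d_out` raw score matrix.
#' @export
mlp_forward <- function(params, X) {
  t <- params$tensors
  n_layers <- length(t) / 2L
  a <- as.matrix(X)
  if (ncol(a) != nrow(t$W1)) abort("input width does not match the network")
  for (l in seq_len(n_layers)) {
    z <- a %*% t[[paste0("W", l)]] +
      rep(t[[paste0("b", l)]], each = nrow(a))
    a <- if (l < n_layers) selu(z) else z
  }
  a
}

#' Mean cross-entropy of raw scores
#'
#' `mean(-log softmax(scores)[label])`, computed with the log-sum-exp trick.
#'
#' @param scores `n x C` raw score matrix.
#' @param labels Integer class labels in `1..C`.
#' @return Mean loss.
#' @export
cross_entropy <- function(scores, labels) {
  if (any(labels < 1) || any(labels > ncol(scores))) {
    abort("labels must index score columns")
  }
  n <- nrow(scores)
  mx <- scores[cbind(seq_len(n), max.col(scores, ties.method = "first"))]
  lse <- mx + log(rowSums(exp(scores - mx)))
  picked <- scores[cbind(seq_len(n), labels)]
  mean(lse - picked)
}

# softmax with the same stabilization
softmax_rows <- function(scores) {
  n <- nrow(scores)
  mx <- scores[cbind(seq_len(n), max.col(scores, ties.method = "first"))]
  e <- exp(scores - mx)
  e / rowSums(e)
}

# Full backprop: returns gradients with the same tensor structure.
mlp_grad <- function(params, X, labels) {
  th <- params$tensors
  n_layers <- length(th) / 2L
  n <- nrow(X)
  acts <- vector("list", n_layers + 1L)
  zs <- vector("list", n_layers)
  acts[[1]] <- as.matrix(X)
  for (l in seq_len(n_layers)) {
    zs[[l]] <- acts[[l]] %*% th[[paste0("W", l)]] +
      rep(th[[paste0("b", l)]], each = n)
    acts[[l + 1L]] <- if (l < n_layers) selu(zs[[l]]) else zs[[l]]
  }
  probs <- softmax_rows(acts[[n_layers + 1L]])
  delta <- probs
  delta[cbind(seq_len(n), labels)] <- delta[cbind(seq_len(n), labels)] - 1
  delta <- delta / n
  grads <- list()
  for (l in rev(seq_len(n_layers))) {
    grads[[paste0("W", l)]] <- crossprod(acts[[l]], delta)
    grads[[paste0("b", l)]] <- colSums(delta)
    if (l > 1) {
      delta <- tcrossprod(delta, th[[paste0("W", l)]]) * selu_grad(zs[[l - 1L]])
    }
  }
  grads[names(th)]
}

#' One SGD epoch over an MLP
#'
#' Seeded shuffle into mini-batches, then plain gradient steps on the mean
#' cross-entropy.
#'
#' @param params An MLP [model_params()].
#' @param data List with `X` (inputs) and `y` (integer labels `1..C`).
#' @param eta Learning rate for this epoch.
#' @param batch_size Mini-batch size.
#' @param seed Epoch shuffling seed.
#' @return Updated [model_params()].
#' @export
mlp_epoch <- function(params, data, eta, batch_size, seed) {
  X <- data$X; y <- data$y
  n <- nrow(X)
  t <- params$tensors
  order <- with_seed(seed, sample.int(n))
  for (s in seq(1L, n, by = batch_size)) {
    idx <- order[s:min(s + batch_size - 1L, n)]
    grads <- mlp_grad(model_params(t, "mlp"), X[idx, , drop = FALSE], y[idx])
    for (nm in names(t)) t[[nm]] <- t[[nm]] - eta * grads[[nm]]
  }
  out <- model_params(t, kind = "mlp")
  attr(out, "sizes") <- attr(params, "sizes")
  out
}

#' Predicted class labels
#'
#' @param params An MLP [model_params()].
#' @param X Input matrix.
#' @return Integer labels (argmax of the raw scores; ties to the first).
#' @export
mlp_predict <- function(params, X) {
  max.col(mlp_forward(params, X), ties.method = "first")
}
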