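# Exact federated PCA by eigenvector stacking: each client sends its local
# eigenvalues and eigenvectors (up to n_k - 1 of them), the server stacks the
# sqrt-eigenvalue-scaled rows and takes one SVD. With full local rank and a
# common center the stacked Gram matrix equals the pooled Gram matrix, so the
# federated loadings span the centralized ones exactly.

#' Global variant means by one aggregation round
#'
#' Each client contributes (sum, count) per variant over its non-missing
#' calls; the server returns the pooled mean. This is the common center that
#' makes stacked federated PCA exact.
#'
#' @param blocks List of [geno_block()]s on the shared variant set.
#' @return Numeric vector of per-variant global means.
#' @export
global_center <- function(blocks) {
  sums <- Reduce(`+`, lapply(blocks, function(b) {
    colSums(b$geno, na.rm = TRUE)
  }))
  counts <- Reduce(`+`, lapply(blocks, function(b) {
    colSums(!is.na(b$geno))
  }))
  out <- unname(sums / pmax(counts, 1))
  out[counts == 0] <- 0
  out
}

#' Local PCA packet
#'
#' Computes the top `d` eigenpairs of one client's covariance of locally
#' centered dosages, for upload to the server. Missing calls are imputed
#' with the global center first, after which the locally centered matrix has
#' rank at most `n_k - 1` — the maximum available number of components. The
#' packet also records the client's mean vector, which the server already
#' observes during the (sum, count) centering round.
#'
#' @param block A [geno_block()] restricted to the shared variant union.
#' @param center Global mean vector from [global_center()].
#' @param d Number of components, at most `n_k - 1`.
#' @return A `pca_packet`: `node_id`, `evals` (covariance eigenvalues,
#'   nonincreasing), `evecs` (`d x m`, orthonormal rows), `mean` (local
#'   column means after imputation), `n`.
#' @export
local_pca <- function(block, center, d = NULL) {
  n <- nrow(block$geno)
  d <- d %||% (n - 1L)
  if (d > n - 1L) abort("d must not exceed the client sample count minus one")
  if (d < 1L) abort("d must be >= 1")
  d <- min(d, ncol(block$geno)) # a wide client's rank is capped by variants
  x <- impute_dosages(block$geno, center = center)
  mu <- colMeans(x)
  x <- sweep(x, 2, mu)
  sv <- svd(x, nu = 0, nv = d)
  evals <- sv$d[seq_len(d)]^2 / (n - 1)
  structure(list(node_id = block$samples$sample_id[1] %||% "node",
                 evals = evals, evecs = t(sv$v), mean = mu, n = n),
            class = "pca_packet")
}

#' Server-side stacked aggregation
#'
#' Stacks every client's rows `sqrt((n_k - 1) * eval) * evec`, plus one
#' mean-correction row `sqrt(n_k) * (mean_k - center)` per client, into one
#' joint matrix and takes its SVD; the top `n_pcs` right singular vectors
#' become the shared loadings. The stacked Gram matrix then equals the
#' pooled globally-centered scatter exactly whenever every client sends its
#' full local rank `n_k - 1`. The sign of each loading row is fixed so its
#' largest-magnitude entry is positive.
#'
#' @param packets List of [local_pca()] packets on the same variant order.
#' @param n_pcs Number of shared components (default 20).
#' @param center Global mean vector, stored for projection; defaults to the
#'   sample-size-weighted mean of the packet means (identical to
#'   [global_center()] under the imputation used here).
#' @return A `pca_model`: `loadings` (`n_pcs x m`, orthonormal rows),
#'   `center`, `explained` (pooled singular values), `n_pcs`.
#' @export
pstack_aggregate <- function(packets, n_pcs = 20L, center = NULL) {
  if (length(packets) == 0) abort("at least one packet required")
  ms <- vapply(packets, function(p) ncol(p$evecs), integer(1))
  if (length(unique(ms)) != 1) abort("packets disagree on the variant count")
  n_k <- vapply(packets, function(p) p$n, numeric(1))
  center <- center %||%
    drop(crossprod(vapply(packets, function(p) p$mean, numeric(ms[1])),
                   n_k / sum(n_k)))
  stacked <- do.call(rbind, lapply(packets, function(p) {
    rbind(sqrt(pmax(p$evals, 0) * (p$n - 1)) * p$evecs,
          sqrt(p$n) * (p$mean - center))
  }))
  n_pcs <- min(n_pcs, ncol(stacked), nrow(stacked))
  sv <- svd(stacked, nu = 0, nv = n_pcs)
  loadings <- t(sv$v)
  loadings <- fix_signs(loadings)
  structure(list(loadings = loadings, center = center,
                 explained = sv$d[seq_len(n_pcs)], n_pcs = n_pcs),
            class = "pca_model")
}

# Deterministic sign convention: each component's largest-|.| entry positive.
fix_signs <- function(loadings) {
  for (i in seq_len(nrow(loadings))) {
    j <- which.max(abs(loadings[i, ]))
    if (loadings[i, j] < 0) loadings[i, ] <- -loadings[i, ]
  }
  loadings
}

#' Project samples onto a PC space
#'
#' `scores = (dosages - center) %*% t(loadings)` with missing calls imputed
#' at the model's center (so they contribute exactly zero).
#'
#' @param model A `pca_model`.
#' @param block A [geno_block()] in the model's variant order.
#' @return `n x n_pcs` score matrix.
#' @export
pca_project <- function(model, block) {
  if (ncol(block$geno) != ncol(model$loadings)) {
    abort("variant count does not match the PCA model")
  }
  x <- impute_dosages(block$geno, center = model$center)
  x <- sweep(x, 2, model$center)
  x %*% t(model$loadings)
}

#' Centralized PCA reference path
#'
#' Pools all clients' rows, centers with the same global means, and takes a
#' single SVD. Used as the non-federated arm of the PCA comparisons.
#'
#' @param blocks List of [geno_block()]s on the shared variant set.
#' @param n_pcs Number of components.
#' @return A `pca_model`.
#' @export
centralized_pca <- function(blocks, n_pcs = 20L) {
  center <- global_center(blocks)
  x <- do.call(rbind, lapply(blocks, function(b) {
    impute_dosages(b$geno, center = center)
  }))
  x <- sweep(x, 2, center)
  n_pcs <- min(n_pcs, dim(x) - c(1L, 0L))
  sv <- svd(x, nu = 0, nv = n_pcs)
  structure(list(loadings = fix_signs(t(sv$v)), center = center,
                 explained = sv$d[seq_len(n_pcs)], n_pcs = n_pcs),
            class = "pca_model")
}

#' Federated PCA end-to-end
#'
#' One centering aggregation round, one local eigendecomposition per client
#' (full rank `n_k - 1` by default, the exact-PCA choice), and one stacked
#' SVD on the server.
#'
#' @param blocks List of [geno_block()]s on the shared variant set.
#' @param n_pcs Number of shared components.
#' @param d Per-client component count; default full local rank.
#' @return A `pca_model`.
#' @export
federated_pca <- function(blocks, n_pcs = 20L, d = NULL) {
  center <- global_center(blocks)
  packets <- lapply(blocks, function(b) local_pca(b, center, d = d))
  pstack_aggregate(packets, n_pcs = n_pcs, center = center)
}

#' Communication cost of federated PCA
#'
#' Upload: each client sends `d_k * m + d_k` values (eigenvector matrix plus
#' eigenvalue vector). Broadcast: the server returns `n_pcs * m` values to
#' each client. Linear in the number of variants.
#'
#' @param m_variants Number of shared variants.
#' @param packets List of packets (for the `d_k` and client count).
#' @param bytes_per_value Bytes per transmitted value (default 8).
#' @param n_pcs Broadcast width (default 20).
#' @return Total byte count.
#' @export
pca_comm_cost <- function(m_variants, packets, bytes_per_value = 8L,
                          n_pcs = 20L) {
  upload <- sum(vapply(packets, function(p) {
    length(p$evals) * m_variants + length(p$evals)
  }, numeric(1)))
  broadcast <- length(packets) * n_pcs * m_variants
  (upload + broadcast) * bytes_per_value
}

#' Principal angles between two loading spans
#'
#' Canonical angles (radians) between the row spans of two loading matrices;
#' all zero means identical subspaces. Used for every subspace comparison in
#' the package (per-vector equality is meaningless under rotation).
#'
#' @param a,b Loading matrices (components in rows, same variant order).
#' @return Numeric vector of principal angles.
#' @export
principal_angles <- function(a, b) {
  qa <- qr.Q(qr(t(a)))
  qb <- qr.Q(qr(t(b)))
  s <- svd(crossprod(qa, qb), nu = 0, nv = 0)$d
  acos(pmin(pmax(s, -1), 1))
}
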