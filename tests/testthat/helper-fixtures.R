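# Shared fixtures and independent oracles used across the suite.

# Hudson FST estimator (ratio of averages) on two populations' true allele
# frequencies; independent of the generator under test.
hudson_fst <- function(p1, p2) {
  num <- (p1 - p2)^2
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  mean(num) / mean(den)
}

# Small two-population node pair used by several QC/assoc tests.
make_two_pop_nodes <- function(n_per_node = 100, n_variants = 300, fst = 0.1,
                               missing_rate = 0, seed = 42) {
  pm <- population_model(2, fst, n_variants)
  fr <- draw_population_frequencies(pm, seed)
  specs <- list(node_spec("A", n_per_node, c(1, 0)),
                node_spec("B", n_per_node, c(0, 1)))
  simulate_genotypes(fr, specs, missing_rate, seed)
}

# One homogeneous node with a simulated additive trait.
make_trait_node <- function(n = 200, m = 100, n_causal = 10, h2 = 0.5,
                            seed = 42) {
  pm <- population_model(1, 0, m)
  fr <- draw_population_frequencies(pm, seed)
  nodes <- simulate_genotypes(fr, list(node_spec("A", n, 1)), 0, seed)
  eff <- draw_causal_effects(m, n_causal, seed)
  tm <- trait_model(n_causal, h2)
  tm$noise_sd <- calibrate_noise_sd(nodes, tm, eff)
  list(node = simulate_phenotype(nodes[[1]], tm, eff, seed), effects = eff)
}

# Coordinate-descent LASSO oracle for our objective
# mean((y - X b - b0)^2) + lambda * sum(|b|), intercept unpenalized.
# Independent of the package's proximal-SGD training path.
cd_lasso <- function(X, y, lambda, iters = 5000, tol = 1e-12) {
  p <- ncol(X)
  n <- nrow(X)
  beta <- numeric(p)
  b0 <- mean(y)
  xs <- colSums(X^2) / n
  for (it in seq_len(iters)) {
    old <- c(beta, b0)
    r <- y - X %*% beta - b0
    for (j in seq_len(p)) {
      r <- r + X[, j] * beta[j]
      rho <- sum(X[, j] * r) / n
      beta[j] <- sign(rho) * max(abs(rho) - lambda / 2, 0) / xs[j]
      r <- r - X[, j] * beta[j]
    }
    b0 <- b0 + mean(r)
    r <- y - X %*% beta - b0
    if (max(abs(c(beta, b0) - old)) < tol) break
  }
  list(beta = beta, b0 = b0)
}

# Train a lasso bank to (near) convergence with full-batch proximal steps.
train_bank_fullbatch <- function(X, y, lambda, eta, epochs, seed = 1) {
  params <- lasso_bank(ncol(X), lambda)$params
  for (g in seq_len(epochs) - 1L) {
    params <- lasso_epoch(params, list(X = X, y = y), lambda, eta,
                          batch_size = nrow(X), seed = seed)
  }
  params
}

expect_tibble <- function(x) expect_s3_class(x, "tbl_df")
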