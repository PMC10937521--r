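test_that("flatten/unflatten is the identity for both model kinds", {
  mlp <- mlp_init(4, c(6, 5), 3, seed = 1)
  back <- unflatten_params(flatten_params(mlp), mlp)
  expect_equal(back$tensors, mlp$tensors)
  expect_equal(back$kind, "mlp")

  bank <- lasso_bank(7, lasso_lambda_grid(1, L = 5))$params
  bank$tensors$W[] <- rnorm(length(bank$tensors$W))
  bank$tensors$b[] <- rnorm(5)
  back2 <- unflatten_params(flatten_params(bank), bank)
  expect_equal(back2$tensors, bank$tensors)
  expect_equal(n_params(bank), 7 * 5 + 5)
})

test_that("the bank objective matches hand arithmetic", {
  set.seed(1)
  X <- matrix(rnorm(30), 10, 3)
  y <- rnorm(10)
  yc <- y - mean(y)
  lambda <- c(0.5, 0.1, 0)
  bank <- lasso_bank(3, lambda)
  # zero weights, zero intercept, centered response: loss = mean(y^2)
  expect_equal(lasso_loss(bank, X, yc), rep(mean(yc^2), 3))
  # hand-set two-feature check
  W <- matrix(0, 3, 3); W[1, ] <- 1; W[2, ] <- -2
  bank$params$tensors$W <- W
  bank$params$tensors$b <- c(0.5, 0.5, 0.5)
  pred <- X[, 1] - 2 * X[, 2] + 0.5
  mse <- mean((y - pred)^2)
  expect_equal(lasso_loss(bank, X, y),
               mse + lambda * 3) # sum|W_l| = 1 + 2 = 3 per column
  # lambda = 0 column is plain MSE
  expect_equal(lasso_loss(bank, X, y)[3], mse)
})

test_that("penalties at or above lambda_max keep the solution at zero", {
  set.seed(2)
  X <- scale(matrix(rnorm(200), 50, 4))[, ]
  y <- drop(X %*% c(1, -1, 0.5, 0)) + rnorm(50, 0, 0.3)
  lmax <- lasso_lambda_max(X, y)
  lambda <- c(lmax * 2, lmax)
  params <- train_bank_fullbatch(X, y, lambda, eta = 0.05, epochs = 300)
  expect_lt(max(abs(params$tensors$W)), 1e-12)
  expect_lt(abs(params$tensors$b[1] - mean(y)), 1e-6)
})

test_that("the unpenalized column converges to least squares", {
  set.seed(3)
  X <- scale(matrix(rnorm(40 * 3), 40, 3))[, ]
  y <- drop(X %*% c(2, 0, -1)) + rnorm(40, 0, 0.2)
  params <- train_bank_fullbatch(X, y, lambda = 1e-9, eta = 0.1,
                                 epochs = 4000)
  ols <- coef(lm(y ~ X))
  expect_lt(max(abs(params$tensors$W[, 1] - ols[-1])), 1e-6)
  expect_lt(abs(params$tensors$b[1] - ols[1]), 1e-6)
})

test_that("an orthonormal design converges to the soft-threshold closed form", {
  set.seed(4)
  raw <- matrix(rnorm(50 * 4), 50, 4)
  X <- qr.Q(qr(cbind(1, raw)))[, 2:5] # orthonormal, orthogonal to intercept
  y <- rnorm(50)
  lambda <- 0.002
  params <- train_bank_fullbatch(X, y, lambda, eta = 0.9, epochs = 3000)
  # minimizer of mean((y - Xb - b0)^2) + lambda |b|_1 with X^T X = I,
  # X^T 1 = 0: b_j = soft((X^T y)_j, n lambda / 2)
  target <- drop(crossprod(X, y))
  n <- length(y)
  closed <- sign(target) * pmax(abs(target) - n * lambda / 2, 0)
  expect_lt(max(abs(params$tensors$W[, 1] - closed)), 1e-6)
})

test_that("gradient training agrees with coordinate descent and glmnet", {
  set.seed(5)
  X <- scale(matrix(rnorm(80 * 5), 80, 5))[, ]
  y <- drop(X %*% c(1.5, -0.8, 0, 0, 0.4)) + rnorm(80, 0, 0.5)
  lambda <- 0.3
  params <- train_bank_fullbatch(X, y, lambda, eta = 0.1, epochs = 6000)
  oracle <- cd_lasso(X, y, lambda)
  expect_lt(max(abs(params$tensors$W[, 1] - oracle$beta)), 1e-5)
  # glmnet minimizes (1/2n)RSS + lam|b|; ours is (1/n)RSS + lam|b|
  gl <- glmnet::glmnet(X, y, lambda = lambda / 2, standardize = FALSE,
                       thresh = 1e-14)
  expect_lt(max(abs(params$tensors$W[, 1] - as.numeric(gl$beta))), 1e-4)
})

test_that("the bank trains every penalty exactly as a standalone model would", {
  set.seed(6)
  X <- scale(matrix(rnorm(60 * 4), 60, 4))[, ]
  y <- drop(X %*% c(1, -1, 0, 0.5)) + rnorm(60, 0, 0.4)
  lambda <- lasso_lambda_grid(lasso_lambda_max(X, y), L = 6)
  sched <- fed_schedule(1, 10, 0.02, 0.99, 8L)
  bank_fit <- client_update(lasso_bank(4, lambda)$params,
                            list(X = X, y = y), 10, sched, seed = 77,
                            lambda = lambda)
  for (l in c(1, 3, 6)) {
    solo <- client_update(lasso_bank(4, lambda[l])$params,
                          list(X = X, y = y), 10, sched, seed = 77,
                          lambda = lambda[l])
    expect_identical(bank_fit$tensors$W[, l], drop(solo$tensors$W))
    expect_identical(bank_fit$tensors$b[l], solo$tensors$b)
  }
})

test_that("converged sparsity is nonincreasing in the penalty", {
  set.seed(7)
  X <- scale(matrix(rnorm(100 * 8), 100, 8))[, ]
  y <- drop(X %*% c(2, -1.5, 1, 0.5, 0, 0, 0, 0)) + rnorm(100, 0, 0.5)
  lambda <- lasso_lambda_grid(lasso_lambda_max(X, y), L = 10)
  params <- train_bank_fullbatch(X, y, lambda, eta = 0.1, epochs = 2000)
  # exactly at lambda_max the proximal step can leave a last-ulp residue
  nnz <- colSums(abs(params$tensors$W) > 1e-10)
  expect_true(all(diff(nnz) >= 0)) # grid is decreasing, so nnz grows
  expect_equal(unname(nnz[1]), 0)
})

test_that("the MLP architecture count matches the printed total", {
  expect_equal(mlp_count_params(20, c(800, 200), 26), 182226)
  expect_equal(mlp_count_params(20, c(800, 200), 26),
               20 * 800 + 800 + 800 * 200 + 200 + 200 * 26 + 26)
  mp <- mlp_init(4, c(6, 5), 3, seed = 1)
  expect_equal(n_params(mp), mlp_count_params(4, c(6, 5), 3))
})

test_that("selu and cross-entropy behave at their anchor points", {
  expect_identical(selu(0), 0)
  expect_equal(selu(1), 1.0507009873554805)
  expect_equal(selu(-1e9), -1.0507009873554805 * 1.6732632423543772)

  mp <- mlp_init(5, c(4), 3, seed = 2)
  for (nm in names(mp$tensors)) mp$tensors[[nm]][] <- 0
  X <- matrix(rnorm(20 * 5), 20, 5)
  scores <- mlp_forward(mp, X)
  expect_true(all(scores == 0))
  expect_equal(cross_entropy(scores, rep(1L, 20)), log(3))
  expect_equal(cross_entropy(matrix(0, 4, 26), rep(2L, 4)), log(26))

  # saturated scores drive the loss to zero
  hot <- matrix(0, 10, 4)
  lab <- sample(1:4, 10, replace = TRUE)
  hot[cbind(1:10, lab)] <- 100
  expect_lt(cross_entropy(hot, lab), 1e-6)

  # hand two-class example: scores (1, 0), label 1
  expect_equal(cross_entropy(matrix(c(1, 0), 1, 2), 1L),
               -log(exp(1) / (exp(1) + 1)))
})

test_that("backpropagation matches numerical gradients", {
  set.seed(8)
  mp <- mlp_init(3, c(4, 3), 2, seed = 8)
  X <- matrix(rnorm(6 * 3), 6, 3)
  y <- sample(1:2, 6, replace = TRUE)
  grads <- fedgeno:::mlp_grad(mp, X, y)
  flat <- flatten_params(mp)
  num <- numeric(length(flat))
  eps <- 1e-6
  for (i in seq_along(flat)) {
    up <- flat; up[i] <- up[i] + eps
    dn <- flat; dn[i] <- dn[i] - eps
    num[i] <- (cross_entropy(mlp_forward(unflatten_params(up, mp), X), y) -
               cross_entropy(mlp_forward(unflatten_params(dn, mp), X), y)) /
      (2 * eps)
  }
  analytic <- unlist(lapply(grads, as.numeric), use.names = FALSE)
  expect_lt(max(abs(analytic - num)), 1e-6)
})

test_that("the MLP can memorize a small random sample", {
  set.seed(9)
  X <- matrix(rnorm(64 * 20), 64, 20)
  y <- sample(1:26, 64, replace = TRUE)
  mp <- mlp_init(20, c(800, 200), 26, seed = 9)
  acc <- 0
  for (epoch in 1:2000) {
    mp <- mlp_epoch(mp, list(X = X, y = y), 0.1, 64L, epoch)
    if (epoch %% 25 == 0) {
      acc <- accuracy(y, mlp_predict(mp, X))
      if (acc == 1) break
    }
  }
  expect_equal(acc, 1)
})

test_that("regression and classification metrics follow their formulas", {
  y <- c(1, 2, 3, 4)
  expect_equal(r2_score(y, y), 1)
  expect_equal(r2_score(y, rep(mean(y), 4)), 0)
  expect_lt(r2_score(y, c(4, 3, 2, 1)), 0)
  expect_error(r2_score(rep(1, 4), y), "variance")

  expect_equal(accuracy(1:4, 1:4), 1)
  expect_equal(accuracy(1:4, 5:8), 0)
  expect_equal(accuracy(1:4, c(1, 2, 3, 9)), 0.75)
})

test_that("bank and fit summaries expose tidy interfaces", {
  bank <- lasso_bank(3, c(0.2, 0.1), feature_names = c("a", "b", "c"))
  td <- tidy(bank)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 6)
  gl <- glance(bank)
  expect_equal(gl$n_lambda, 2)
})

test_that("checkpoints round-trip through their text archive", {
  dir <- withr::local_tempdir()
  mp <- mlp_init(4, c(5), 3, seed = 11)
  write_checkpoint(mp, file.path(dir, "mlp"))
  back <- read_checkpoint(file.path(dir, "mlp"))
  expect_equal(back$params$tensors, mp$tensors)
  expect_equal(back$params$kind, "mlp")

  lam <- c(0.3, 0.1)
  bank <- lasso_bank(3, lam)$params
  bank$tensors$W[] <- rnorm(6)
  write_checkpoint(bank, file.path(dir, "bank"), lambda = lam)
  back2 <- read_checkpoint(file.path(dir, "bank"))
  expect_equal(back2$params$tensors$W, bank$tensors$W)
  expect_equal(back2$lambda, lam)
})
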