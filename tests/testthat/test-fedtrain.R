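scalar_params <- function(x) model_params(list(w = matrix(x, 1, 1)), "mlp")

make_client <- function(n, d_in = 4, classes = 3, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * d_in), n, d_in)
  y <- sample(seq_len(classes), n, replace = TRUE)
  list(train = list(X = X, y = y),
       val = list(X = X[seq_len(min(10, n)), , drop = FALSE],
                  y = y[seq_len(min(10, n))]))
}

test_that("aggregation is the exact sample-size-weighted mean", {
  one <- fedavg_aggregate(list(scalar_params(5)), 7)
  expect_equal(one$tensors$w[1, 1], 5)

  two <- fedavg_aggregate(list(scalar_params(0), scalar_params(2)), c(10, 10))
  expect_equal(two$tensors$w[1, 1], 1)

  three <- fedavg_aggregate(list(scalar_params(8), scalar_params(4),
                                 scalar_params(0)), c(1, 2, 5))
  expect_equal(three$tensors$w[1, 1], (8 + 8 + 0) / 8)

  # identical clients return their parameters within 1e-12
  mp <- mlp_init(3, c(4), 2, seed = 2)
  agg <- fedavg_aggregate(list(mp, mp, mp), c(3, 4, 5))
  expect_lt(max(abs(flatten_params(agg) - flatten_params(mp))), 1e-12)

  bad <- model_params(list(w = matrix(0, 2, 2)), "mlp")
  expect_error(fedavg_aggregate(list(mp, bad), c(1, 1)), "shapes")
  expect_error(fedavg_aggregate(list(mp), 0), "positive")
})

test_that("zero local epochs or a zero learning rate leave parameters unchanged", {
  cl <- make_client(20)
  mp <- mlp_init(4, c(5), 3, seed = 3)
  sched <- fed_schedule(1, 1, 0.1, 1, 8L)
  expect_identical(client_update(mp, cl$train, 0, sched, seed = 1)$tensors,
                   mp$tensors)
  sched0 <- fed_schedule(1, 3, 0, 1, 8L)
  out <- client_update(mp, cl$train, 3, sched0, seed = 1)
  expect_equal(out$tensors, mp$tensors)
})

test_that("a one-client federation reproduces plain training bit-exactly", {
  cl <- make_client(30, seed = 4)
  sched <- fed_schedule(5, 3, 0.05, 0.99, 8L)
  init <- mlp_init(4, c(6), 3, seed = 4)
  fed <- run_fedavg(init, list(cl), sched, seed = 11)
  solo <- train_single(init, cl, sched, seed = 11)
  expect_identical(flatten_params(fed$final_params),
                   flatten_params(solo$final_params))
  expect_identical(flatten_params(fed$params), flatten_params(solo$params))
  expect_equal(fed$best_round, solo$best_round)

  # and for the bank model
  set.seed(5)
  Xb <- matrix(rnorm(40 * 6), 40, 6)
  yb <- rnorm(40)
  lam <- lasso_lambda_grid(lasso_lambda_max(Xb, yb), L = 5)
  clb <- list(train = list(X = Xb, y = yb),
              val = list(X = Xb[1:10, ], y = yb[1:10]))
  initb <- lasso_bank(6, lam)$params
  fedb <- run_fedavg(initb, list(clb), sched, seed = 12, lambda = lam)
  solob <- train_single(initb, clb, sched, seed = 12, lambda = lam)
  expect_identical(flatten_params(fedb$final_params),
                   flatten_params(solob$final_params))
})

test_that("homogeneous clients with full-batch single-epoch rounds match centralized descent", {
  cl1 <- make_client(25, seed = 6)
  clients <- list(cl1, cl1, cl1)
  pooled <- list(train = list(X = do.call(rbind, lapply(clients, function(c) c$train$X)),
                              y = unlist(lapply(clients, function(c) c$train$y))),
                 val = cl1$val)
  init <- mlp_init(4, c(6), 3, seed = 6)
  R <- 8
  sched_fed <- fed_schedule(R, 1, 0.05, 1, batch_size = 25L)
  sched_cen <- fed_schedule(R, 1, 0.05, 1, batch_size = 75L)
  fed <- run_fedavg(init, clients, sched_fed, seed = 13)
  cen <- train_single(init, pooled, sched_cen, seed = 13)
  expect_lt(max(abs(flatten_params(fed$final_params) -
                    flatten_params(cen$final_params))), 1e-10)
})

test_that("schedules splitting a fixed epoch budget consume identical local epochs", {
  a <- fed_schedule(32, 1, 0.1)
  b <- fed_schedule(1, 32, 0.1)
  expect_equal(a$total_epochs, b$total_epochs)
})

test_that("round logs account communication linearly and monotonically", {
  cl <- make_client(20, seed = 7)
  init <- mlp_init(4, c(5), 3, seed = 7)
  sched <- fed_schedule(6, 1, 0.05, 1, 8L)
  fit <- run_fedavg(init, list(cl, cl), sched, seed = 14)
  per_round <- 2 * 2 * n_params(init) * 8
  expect_equal(unique(diff(unique(fit$log$cum_bytes))), per_round)
  expect_true(all(diff(fit$log$cum_bytes) >= 0))

  curve <- model_comm_cost(init, sched, K = 2)
  expect_equal(max(curve), per_round * 6)
  expect_equal(model_comm_cost(182226, fed_schedule(512, 1, 0.1), K = 5,
                               bytes_per_value = 4)[512],
               2 * 5 * 182226 * 4 * 512)
  expect_equal(model_comm_cost(init, sched, K = 0), rep(0, 6))
  # doubling rounds doubles the total
  expect_equal(max(model_comm_cost(init, fed_schedule(12, 1, 0.05), K = 2)),
               2 * per_round * 6)
})

test_that("validation aggregation weights clients by validation size", {
  set.seed(8)
  mk <- function(n_val) {
    X <- matrix(rnorm(12 * 2), 12, 2)
    y <- sample(1:2, 12, replace = TRUE)
    list(train = list(X = X, y = y),
         val = list(X = matrix(rnorm(n_val * 2), n_val, 2),
                    y = sample(1:2, n_val, replace = TRUE)))
  }
  clients <- list(mk(10), mk(90))
  init <- mlp_init(2, c(3), 2, seed = 8)
  sched <- fed_schedule(1, 1, 0, 1, 4L) # eta 0: params stay at init
  fit <- run_fedavg(init, clients, sched, seed = 15)
  expected <- 0.1 * cross_entropy(mlp_forward(init, clients[[1]]$val$X),
                                  clients[[1]]$val$y) +
              0.9 * cross_entropy(mlp_forward(init, clients[[2]]$val$X),
                                  clients[[2]]$val$y)
  expect_equal(fit$val_loss_by_round[1, 1], expected)
})

test_that("penalty selection follows argmin with its documented tie-breaks", {
  fit <- list(val_loss_by_round = rbind(c(0.5, 0.2, 0.9)))
  expect_equal(federated_lambda_select(fit)$lambda_index, 2)
  # tie across penalties: larger penalty (earlier column) wins
  tie <- list(val_loss_by_round = rbind(c(0.4, 0.3, 0.3, 0.5)))
  expect_equal(federated_lambda_select(tie)$lambda_index, 3 - 1)
  # value tie across (round, penalty): the larger penalty wins first,
  # then the earlier round
  rounds <- list(val_loss_by_round = rbind(c(0.5, 0.2), c(0.2, 0.4)))
  sel <- federated_lambda_select(rounds)
  expect_equal(sel$round, 2)
  expect_equal(sel$lambda_index, 1)
  same_col <- list(val_loss_by_round = rbind(c(0.9, 0.2), c(0.9, 0.2)))
  expect_equal(federated_lambda_select(same_col)$round, 1)
  expect_error(federated_lambda_select(list(val_loss_by_round = NULL)),
               "rounds")
})

test_that("client updates never mutate the received parameters", {
  cl <- make_client(16, seed = 9)
  mp <- mlp_init(4, c(5), 3, seed = 9)
  before <- flatten_params(mp)
  sched <- fed_schedule(1, 2, 0.1, 1, 8L)
  invisible(client_update(mp, cl$train, 2, sched, seed = 1))
  expect_identical(flatten_params(mp), before)
})
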