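# The federated-averaging engine: R rounds of broadcast -> local training ->
# sample-size-weighted aggregation, simulated sequentially in one process
# with strictly isolated client state. Learning-rate decay follows a global
# epoch counter that continues across rounds, so the (R, E) split of a fixed
# total epoch budget changes only the communication pattern, never the
# amount of local computation.

#' Federated training schedule
#'
#' @param rounds Communication rounds `R` (>= 1).
#' @param epochs_per_round Local epochs `E` per round (>= 1).
#' @param eta Initial local learning rate.
#' @param decay Per-local-epoch multiplicative learning-rate decay.
#' @param batch_size Mini-batch size.
#' @return An object of class `fed_schedule`; `R * E` is the total local
#'   epoch budget.
#' @export
fed_schedule <- function(rounds, epochs_per_round, eta, decay = 1,
                         batch_size = 16L) {
  rounds <- check_count(rounds, "rounds")
  epochs_per_round <- check_count(epochs_per_round, "epochs_per_round")
  check_number(eta, "eta", lower = 0)
  check_number(decay, "decay", lower = 0, upper = 1)
  batch_size <- check_count(batch_size, "batch_size")
  structure(list(rounds = rounds, epochs_per_round = epochs_per_round,
                 eta = eta, decay = decay, batch_size = batch_size,
                 total_epochs = rounds * epochs_per_round),
            class = "fed_schedule")
}

#' Sample-size-weighted parameter average
#'
#' `omega <- sum_k (n_k / n) * omega_k`, elementwise over every tensor.
#'
#' @param client_params List of conformable [model_params()].
#' @param n_k Positive per-client sample counts.
#' @return The aggregated [model_params()].
#' @export
fedavg_aggregate <- function(client_params, n_k) {
  if (length(client_params) != length(n_k)) abort("one weight per client required")
  if (any(n_k <= 0)) abort("client sizes must be positive")
  out <- params_combine(client_params, n_k / sum(n_k))
  attr(out, "sizes") <- attr(client_params[[1]], "sizes")
  out
}

# Dispatch one local epoch by model kind.
run_epoch <- function(params, data, eta, batch_size, seed, lambda = NULL) {
  switch(params$kind,
    lasso_bank = lasso_epoch(params, data, lambda, eta, batch_size, seed),
    mlp = mlp_epoch(params, data, eta, batch_size, seed),
    abort(sprintf("unknown model kind '%s'", params$kind))
  )
}

# Loss vector by kind (length L for banks, length 1 for the MLP).
eval_loss <- function(params, data, lambda = NULL) {
  switch(params$kind,
    lasso_bank = lasso_loss(params, data$X, data$y, lambda = lambda),
    mlp = cross_entropy(mlp_forward(params, data$X), data$y),
    abort(sprintf("unknown model kind '%s'", params$kind))
  )
}

#' Client-side local update
#'
#' Runs `E` epochs of seeded mini-batch gradient descent from the received
#' parameters and returns the updated copy; the input is never mutated. The
#' learning rate of local epoch `i` (with `epoch_offset` epochs already
#' consumed globally) is `eta * decay^(epoch_offset + i - 1)`. Each epoch's
#' batch shuffle is seeded by `mix_seed(seed, client_id, global_epoch)`, so
#' trajectories are reproducible and identical wherever the same global
#' epoch sequence is consumed.
#'
#' @param params Received [model_params()].
#' @param data Client training data (`X`, `y`).
#' @param E Number of local epochs; 0 returns the parameters unchanged.
#' @param schedule A [fed_schedule()] (for `eta`, `decay`, `batch_size`).
#' @param seed Global seed.
#' @param client_id Integer client index (seed stream).
#' @param epoch_offset Global epochs consumed before this call.
#' @param lambda Penalty grid for bank models.
#' @return Updated [model_params()].
#' @export
client_update <- function(params, data, E, schedule, seed, client_id = 1L,
                          epoch_offset = 0L, lambda = NULL) {
  if (is.null(data$y) || length(data$y) == 0) abort("client has no training data")
  for (i in seq_len(E)) {
    g_epoch <- epoch_offset + i - 1L
    eta_i <- schedule$eta * schedule$decay^g_epoch
    params <- run_epoch(params, data, eta_i, schedule$batch_size,
                        seed = mix_seed(seed, 9001L, client_id, g_epoch),
                        lambda = lambda)
  }
  params
}

#' Run federated averaging
#'
#' `R` rounds of broadcast, parallel-contract client updates (simulated
#' sequentially, no cross-client state), and weighted aggregation. After
#' each aggregation the validation loss is computed per client on its own
#' validation split and aggregated with validation-count weights; the
#' returned model is the aggregated checkpoint with the best (minimum over
#' the penalty grid, for banks) validation loss over rounds.
#'
#' @param init Initial [model_params()].
#' @param clients List of client datasets, each
#'   `list(train = list(X, y), val = list(X, y))`.
#' @param schedule A [fed_schedule()].
#' @param seed Global seed.
#' @param lambda Penalty grid for bank models.
#' @param bytes_per_value Communication accounting unit (default 8).
#' @return List with `params` (best checkpoint), `final_params` (last
#'   round), `log` (tibble: one row per round with aggregated validation
#'   loss, per-client pre/post losses, cumulative bytes), `val_loss_by_round`
#'   (matrix, rounds x penalties for banks), `best_round`.
#' @export
run_fedavg <- function(init, clients, schedule, seed = 1, lambda = NULL,
                       bytes_per_value = 8L) {
  K <- length(clients)
  if (K < 1) abort("at least one client required")
  n_k <- vapply(clients, function(cl) length(cl$train$y) %||% nrow(cl$train$X),
                numeric(1))
  v_k <- vapply(clients, function(cl) length(cl$val$y) %||% 0, numeric(1))
  params <- init
  size <- n_params(init)
  best <- list(loss = Inf, params = init, round = 0L)
  logs <- vector("list", schedule$rounds)
  val_by_round <- NULL
  cum_bytes <- 0
  for (r in seq_len(schedule$rounds)) {
    epoch_offset <- (r - 1L) * schedule$epochs_per_round
    pre_loss <- vapply(clients, function(cl) {
      mean(eval_loss(params, cl$train, lambda = lambda))
    }, numeric(1))
    updated <- lapply(seq_len(K), function(k) {
      client_update(params, clients[[k]]$train, schedule$epochs_per_round,
                    schedule, seed, client_id = k,
                    epoch_offset = epoch_offset, lambda = lambda)
    })
    post_loss <- vapply(seq_len(K), function(k) {
      mean(eval_loss(updated[[k]], clients[[k]]$train, lambda = lambda))
    }, numeric(1))
    params <- fedavg_aggregate(updated, n_k)
    # round-trip: broadcast down at round start, client uploads back
    cum_bytes <- cum_bytes + 2 * K * size * bytes_per_value
    val_mat <- vapply(clients, function(cl) {
      eval_loss(params, cl$val, lambda = lambda)
    }, numeric(length(lambda %||% 1)))
    val_mat <- matrix(val_mat, ncol = K)
    agg_val <- drop(val_mat %*% (v_k / sum(v_k)))
    val_by_round <- rbind(val_by_round, agg_val)
    crit <- min(agg_val)
    if (crit < best$loss) {
      best <- list(loss = crit, params = params, round = r)
    }
    logs[[r]] <- tibble::tibble(
      round = r,
      client = seq_len(K),
      pre_loss = pre_loss,
      post_loss = post_loss,
      val_loss = crit,
      cum_bytes = cum_bytes
    )
  }
  structure(list(params = best$params, final_params = params,
                 log = dplyr::bind_rows(logs),
                 val_loss_by_round = unname(val_by_round),
                 best_round = best$round, best_loss = best$loss,
                 schedule = schedule, n_k = n_k),
            class = "fedavg_fit")
}

#' @export
print.fedavg_fit <- function(x, ...) {
  cat(sprintf("<fedavg_fit> %d clients, R=%d E=%d; best val loss %.4g at round %d\n",
              length(x$n_k), x$schedule$rounds, x$schedule$epochs_per_round,
              x$best_loss, x$best_round))
  invisible(x)
}

#' @method glance fedavg_fit
#' @export
glance.fedavg_fit <- function(x, ...) {
  tibble::tibble(
    n_clients = length(x$n_k),
    rounds = x$schedule$rounds,
    epochs_per_round = x$schedule$epochs_per_round,
    total_epochs = x$schedule$total_epochs,
    best_round = x$best_round,
    best_val_loss = x$best_loss,
    total_bytes = max(x$log$cum_bytes)
  )
}

#' @method tidy fedavg_fit
#' @export
tidy.fedavg_fit <- function(x, ...) x$log

#' Penalty selection from aggregated validation losses
#'
#' Argmin over (round, penalty) of the aggregated validation loss; ties go
#' to the larger penalty (smaller column index of a decreasing grid), then
#' the earlier round.
#'
#' @param fit A [run_fedavg()] result trained on a bank model.
#' @return List with `round`, `lambda_index`, `loss`.
#' @export
federated_lambda_select <- function(fit) {
  v <- fit$val_loss_by_round
  if (is.null(v) || nrow(v) == 0) abort("no completed rounds")
  best <- which(v == min(v), arr.ind = TRUE)
  # earlier round then larger lambda (lower column index) among ties
  best <- best[order(best[, 2], best[, 1]), , drop = FALSE]
  best <- best[order(best[, 2])[1], ]
  list(round = unname(best[1]), lambda_index = unname(best[2]),
       loss = min(v))
}

#' Non-federated training loop
#'
#' The local/centralized arm: a plain epoch loop over one dataset with the
#' same decay accounting and seed-stream semantics as a federated client,
#' and the same best-checkpoint rule evaluated every `epochs_per_round`
#' epochs. Written independently of [run_fedavg()] so that the degenerate
#' one-client federation can be checked against it.
#'
#' @param init Initial [model_params()].
#' @param data `list(train = list(X, y), val = list(X, y))`.
#' @param schedule A [fed_schedule()]; `rounds * epochs_per_round` epochs run.
#' @param seed Global seed.
#' @param client_id Seed stream identifier (default 1).
#' @param lambda Penalty grid for banks.
#' @return List with `params` (best checkpoint), `final_params`,
#'   `val_loss_by_round`, `best_round`, `best_loss`.
#' @export
train_single <- function(init, data, schedule, seed = 1, client_id = 1L,
                         lambda = NULL) {
  params <- init
  best <- list(loss = Inf, params = init, round = 0L)
  val_by_round <- NULL
  for (g in seq_len(schedule$total_epochs) - 1L) {
    eta_g <- schedule$eta * schedule$decay^g
    params <- run_epoch(params, data$train, eta_g, schedule$batch_size,
                        seed = mix_seed(seed, 9001L, client_id, g),
                        lambda = lambda)
    if ((g + 1L) %% schedule$epochs_per_round == 0L) {
      v <- eval_loss(params, data$val, lambda = lambda)
      val_by_round <- rbind(val_by_round, v)
      if (min(v) < best$loss) {
        best <- list(loss = min(v), params = params,
                     round = (g + 1L) %/% schedule$epochs_per_round)
      }
    }
  }
  list(params = best$params, final_params = params,
       val_loss_by_round = unname(val_by_round),
       best_round = best$round, best_loss = best$loss, schedule = schedule)
}

#' Communication cost of federated model training
#'
#' Each round every client downloads and uploads the full parameter set:
#' `2 * K * size(params) * bytes_per_value` per round.
#'
#' @param params A [model_params()] (or a parameter count).
#' @param schedule A [fed_schedule()].
#' @param K Client count.
#' @param bytes_per_value Bytes per value (default 8).
#' @return Cumulative byte curve of length `rounds`.
#' @export
model_comm_cost <- function(params, schedule, K, bytes_per_value = 8L) {
  size <- if (inherits(params, "model_params")) n_params(params) else params
  if (K == 0) return(rep(0, schedule$rounds))
  cumsum(rep(2 * K * size * bytes_per_value, schedule$rounds))
}
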