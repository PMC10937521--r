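# Cross-validation harness and the three study designs:
#   * local vs federated vs centralized phenotype prediction,
#   * the communication sweep for the ancestry classifier,
#   * the federated-vs-centralized PCA input-size sweep.
# All three share the fold rotation: for CV iteration t, test = fold t,
# validation = fold (t + 1) mod n_folds, train = the rest; every compared
# model is evaluated on the identical merged test set.

#' Assign cross-validation folds per node
#'
#' Random per-node partition into `n_folds` folds whose sizes differ by at
#' most one; deterministic given the seed.
#'
#' @param nodes List of [node_data()] objects.
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed.
#' @return The nodes with 0-based `folds` filled in.
#' @export
assign_folds <- function(nodes, n_folds = 10L, seed = 1) {
  n_folds <- check_count(n_folds, "n_folds", min = 2L)
  purrr::imap(nodes, function(nd, k) {
    n <- nrow(nd$block$geno)
    if (n < n_folds) {
      abort(sprintf("node %d has %d samples; need >= %d", k, n, n_folds))
    }
    nd$folds <- with_seed(mix_seed(seed, 1212L, k), {
      sample(rep(seq_len(n_folds) - 1L, length.out = n))
    })
    nd
  })
}

#' Train/validation/test split for one CV iteration
#'
#' @param folds 0-based fold vector from [assign_folds()].
#' @param t CV iteration in `0..n_folds-1`: test = fold `t`, validation =
#'   fold `(t + 1) mod n_folds`, train = the remaining folds.
#' @param n_folds Number of folds.
#' @return List of integer indices `train`, `val`, `test`.
#' @export
fold_split <- function(folds, t, n_folds = 10L) {
  test_f <- t %% n_folds
  val_f <- (t + 1L) %% n_folds
  list(train = which(folds != test_f & folds != val_f),
       val = which(folds == val_f),
       test = which(folds == test_f))
}

# Feature matrix for the polygenic model: dosages of the selected variants
# (mean-imputed within the given rows) plus age and sex.
pheno_features <- function(node, ids, rows) {
  j <- match(ids, node$block$variants$id)
  g <- impute_dosages(node$block$geno[rows, j, drop = FALSE])
  cbind(g, age = node$pheno$age[rows], sex = node$pheno$sex[rows])
}

# Covariates-only least-squares baseline (age + sex + intercept).
covariate_baseline <- function(train_X, train_y, test_X) {
  fit <- stats::lm.fit(cbind(1, train_X), train_y)
  drop(cbind(1, test_X) %*% fit$coefficients)
}

# Fit a lasso bank on one dataset and return test predictions at the
# validation-selected penalty.
fit_bank_single <- function(train, val, test_X, schedule, L, ratio, seed,
                            client_id = 1L) {
  std <- standardizer_fit(train$X)
  Xtr <- standardizer_apply(std, train$X)
  lambda <- lasso_lambda_grid(lasso_lambda_max(Xtr, train$y), L = L, ratio = ratio)
  init <- lasso_bank(ncol(Xtr), lambda)$params
  fit <- train_single(init, list(train = list(X = Xtr, y = train$y),
                                 val = list(X = standardizer_apply(std, val$X),
                                            y = val$y)),
                      schedule, seed = seed, client_id = client_id,
                      lambda = lambda)
  li <- best_lambda_index(fit$val_loss_by_round)
  W <- fit$params$tensors$W[, li$lambda_index]
  b <- fit$params$tensors$b[li$lambda_index]
  # the checkpoint rule tracks the row optimum; re-pick the column at the
  # best round for the reported model
  drop(standardizer_apply(std, test_X) %*% W + b)
}

# Argmin over (round, lambda); ties -> larger lambda then earlier round.
best_lambda_index <- function(val_by_round) {
  hits <- which(val_by_round == min(val_by_round), arr.ind = TRUE)
  hits <- hits[order(hits[, 2], hits[, 1]), , drop = FALSE]
  list(round = unname(hits[1, 1]), lambda_index = unname(hits[1, 2]))
}

#' Phenotype-prediction study
#'
#' The many-node, low-heterogeneity design: per-node variant QC and GWAS on
#' the training folds, random-effects meta-analysis for the shared feature
#' set, then per-node local banks (on local-GWAS and on meta-GWAS
#' variants), a federated bank (meta variants), a centralized bank
#' (centralized-GWAS variants) and covariates-only baselines, all evaluated
#' by R-squared on the identical merged test set of each fold.
#'
#' @param nodes Simulated nodes (e.g. `simulate_regime("biobank")$nodes`);
#'   folds are assigned if absent.
#' @param n_folds Folds (default 10); all are run.
#' @param cv_iterations Optional subset of CV iterations (0-based).
#' @param top_m Number of selected variants.
#' @param n_pcs GWAS covariate PCs per node.
#' @param schedule A [fed_schedule()] for the bank training.
#' @param L,ratio Penalty-grid shape.
#' @param qc Logical: run per-node variant QC on training folds first.
#' @param seed Integer seed.
#' @return Tibble of class `pheno_experiment`: `fold`, `model`, `node`,
#'   `r2`.
#' @export
run_phenotype_experiment <- function(nodes, n_folds = 10L,
                                     cv_iterations = NULL,
                                     top_m = 100L, n_pcs = 20L,
                                     schedule = fed_schedule(8L, 8L, 5e-3,
                                                             0.99, 16L),
                                     L = 16L, ratio = 1e-3, qc = TRUE,
                                     seed = 1) {
  if (is.null(nodes[[1]]$folds)) nodes <- assign_folds(nodes, n_folds, seed)
  cv_iterations <- cv_iterations %||% (seq_len(n_folds) - 1L)
  thresholds <- qc_thresholds()
  res <- purrr::map(cv_iterations, function(t) {
    splits <- lapply(nodes, function(nd) fold_split(nd$folds, t, n_folds))
    # per-node variant QC + GWAS on training folds only
    stats <- purrr::map2(nodes, splits, function(nd, sp) {
      keep_ids <- nd$block$variants$id
      if (qc) {
        vq <- variant_qc(block_subset(nd$block, samples = sp$train), thresholds)
        keep_ids <- vq$report$id[vq$report$kept]
      }
      sub <- node_data(block_subset(nd$block,
                                    variants = match(keep_ids, nd$block$variants$id)),
                       nd$pheno)
      gwas_node(sub, rows = sp$train, n_pcs = n_pcs)
    })
    meta <- meta_random_effects(stats)
    meta_ids <- select_top_snps(meta, top_m)
    local_ids <- lapply(stats, select_top_snps, m = top_m)
    # centralized GWAS: pooled training rows as one node
    pooled_train <- block_rbind(purrr::map2(nodes, splits, function(nd, sp) {
      block_subset(nd$block, samples = sp$train)
    }))
    pooled_pheno <- dplyr::bind_rows(purrr::map2(nodes, splits, function(nd, sp) {
      nd$pheno[sp$train, ]
    }))
    central_stats <- gwas_node(node_data(pooled_train, pooled_pheno),
                               n_pcs = n_pcs)
    central_ids <- select_top_snps(central_stats, top_m)

    test_y <- unlist(purrr::map2(nodes, splits, function(nd, sp) {
      nd$pheno$phenotype[sp$test]
    }))
    gather <- function(ids, part) {
      purrr::map2(nodes, splits, function(nd, sp) {
        pheno_features(nd, ids, sp[[part]])
      })
    }
    ys <- function(part) purrr::map2(nodes, splits,
                                     function(nd, sp) nd$pheno$phenotype[sp[[part]]])

    rows <- list()
    # --- local models (own-GWAS and meta features) ---
    for (k in seq_along(nodes)) {
      sp <- splits[[k]]; nd <- nodes[[k]]
      for (feat in c("local", "meta")) {
        ids <- if (feat == "local") local_ids[[k]] else meta_ids
        pred <- fit_bank_single(
          list(X = pheno_features(nd, ids, sp$train),
               y = nd$pheno$phenotype[sp$train]),
          list(X = pheno_features(nd, ids, sp$val),
               y = nd$pheno$phenotype[sp$val]),
          do.call(rbind, gather(ids, "test")),
          schedule, L, ratio, seed = mix_seed(seed, 13L, t), client_id = k)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          fold = t, model = if (feat == "local") "local" else "local_meta",
          node = nd$pheno$node_id[1], r2 = r2_score(test_y, pred))
      }
      base_pred <- covariate_baseline(
        cbind(nd$pheno$age[sp$train], nd$pheno$sex[sp$train]),
        nd$pheno$phenotype[sp$train],
        do.call(rbind, purrr::map2(nodes, splits, function(nd2, sp2) {
          cbind(nd2$pheno$age[sp2$test], nd2$pheno$sex[sp2$test])
        })))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        fold = t, model = "covariates_local", node = nd$pheno$node_id[1],
        r2 = r2_score(test_y, base_pred))
    }
    # --- federated bank on meta features ---
    Xtr_list <- gather(meta_ids, "train")
    std_fed <- standardizer_fit_federated(Xtr_list)
    ytr_list <- ys("train")
    lam_max_fed <- {
      # aggregated X^T (y - ybar) sums across clients
      n_tot <- sum(lengths(ytr_list))
      ybar <- sum(unlist(ytr_list)) / n_tot
      xy <- Reduce(`+`, purrr::map2(Xtr_list, ytr_list, function(x, y) {
        drop(crossprod(standardizer_apply(std_fed, x), y - ybar))
      }))
      2 * max(abs(xy)) / n_tot
    }
    lambda_fed <- lasso_lambda_grid(lam_max_fed, L = L, ratio = ratio)
    clients <- purrr::pmap(list(Xtr_list, ytr_list, gather(meta_ids, "val"),
                                ys("val")), function(xt, yt, xv, yv) {
      list(train = list(X = standardizer_apply(std_fed, xt), y = yt),
           val = list(X = standardizer_apply(std_fed, xv), y = yv))
    })
    fed <- run_fedavg(lasso_bank(ncol(Xtr_list[[1]]), lambda_fed)$params,
                      clients, schedule, seed = mix_seed(seed, 13L, t),
                      lambda = lambda_fed)
    sel <- federated_lambda_select(fed)
    Xte_fed <- standardizer_apply(std_fed, do.call(rbind, gather(meta_ids, "test")))
    pred_fed <- drop(Xte_fed %*% fed$params$tensors$W[, sel$lambda_index] +
                       fed$params$tensors$b[sel$lambda_index])
    rows[[length(rows) + 1L]] <- tibble::tibble(
      fold = t, model = "federated", node = "all",
      r2 = r2_score(test_y, pred_fed))
    # --- centralized bank on centralized-GWAS features ---
    pred_cen <- fit_bank_single(
      list(X = do.call(rbind, gather(central_ids, "train")),
           y = unlist(ytr_list)),
      list(X = do.call(rbind, gather(central_ids, "val")),
           y = unlist(ys("val"))),
      do.call(rbind, gather(central_ids, "test")),
      schedule, L, ratio, seed = mix_seed(seed, 13L, t), client_id = 0L)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      fold = t, model = "centralized", node = "all",
      r2 = r2_score(test_y, pred_cen))
    # --- centralized covariates-only baseline ---
    base_cen <- covariate_baseline(
      cbind(pooled_pheno$age, pooled_pheno$sex),
      pooled_pheno$phenotype,
      do.call(rbind, purrr::map2(nodes, splits, function(nd, sp) {
        cbind(nd$pheno$age[sp$test], nd$pheno$sex[sp$test])
      })))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      fold = t, model = "covariates_centralized", node = "all",
      r2 = r2_score(test_y, base_cen))
    dplyr::bind_rows(rows)
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("pheno_experiment", class(out))
  out
}

# Shared-feature preparation for the ancestry designs: per-node variant QC,
# LD pruning on training rows, cross-node id union, restriction to the union.
ancestry_feature_union <- function(nodes, splits, prune_window = 50L,
                                   prune_step = 5L, prune_r2 = 0.1,
                                   qc = TRUE) {
  thresholds <- qc_thresholds()
  kept <- purrr::map2(nodes, splits, function(nd, sp) {
    tr <- block_subset(nd$block, samples = sp$train)
    if (qc) {
      tr <- variant_qc(tr, thresholds)$block
    }
    ld_prune(tr, window = prune_window, step = prune_step, r2_max = prune_r2)
  })
  variant_union(kept, catalog = nodes[[1]]$block$variants$id)
}

# Project every node's splits onto a PC model fitted on training rows.
ancestry_client_data <- function(nodes, splits, ids, n_pcs, mode = "federated",
                                 d = NULL) {
  train_blocks <- purrr::map2(nodes, splits, function(nd, sp) {
    block_subset(nd$block, samples = sp$train,
                 variants = match(ids, nd$block$variants$id))
  })
  model <- if (mode == "federated") {
    federated_pca(train_blocks, n_pcs = n_pcs, d = d)
  } else {
    centralized_pca(train_blocks, n_pcs = n_pcs)
  }
  levels_pop <- sort(unique(unlist(lapply(nodes, function(nd) nd$pheno$population))))
  clients <- purrr::map2(nodes, splits, function(nd, sp) {
    sub <- function(part) {
      b <- block_subset(nd$block, samples = sp[[part]],
                        variants = match(ids, nd$block$variants$id))
      list(X = pca_project(model, b),
           y = match(nd$pheno$population[sp[[part]]], levels_pop))
    }
    list(train = sub("train"), val = sub("val"), test = sub("test"))
  })
  list(clients = clients, pca = model, levels = levels_pop,
       packets = attr(model, "packets"))
}

#' Ancestry-prediction communication sweep
#'
#' The few-node, high-heterogeneity design: shared variants from per-node
#' pruning + union, federated PCA on the training folds, then FedAvg MLPs
#' at every epochs-per-round setting with the total local epoch budget held
#' fixed, plus a centralized MLP, recording per-round losses, accuracies and
#' cumulative communication (model traffic plus the one-off federated-PCA
#' cost).
#'
#' @param nodes Simulated continental-regime nodes; folds assigned if
#'   absent.
#' @param n_folds Folds (default 10).
#' @param cv_iterations Optional subset of CV iterations (0-based).
#' @param epochs_per_round Settings to sweep (default `c(1,2,4,8,16,32)`).
#' @param total_epochs Fixed local-epoch budget (default 512).
#' @param n_pcs Shared PCs (default 20).
#' @param hidden MLP hidden sizes for the sweep.
#' @param eta,decay,batch_size MLP optimizer settings.
#' @param seed Integer seed.
#' @return List of class `ancestry_experiment`: `summary` (tibble: fold,
#'   `epochs_per_round`, final/best losses and accuracies, bytes),
#'   `round_logs` (per-round tibble), `n_snps`.
#' @export
run_ancestry_experiment <- function(nodes, n_folds = 10L,
                                    cv_iterations = NULL,
                                    epochs_per_round = c(1L, 2L, 4L, 8L, 16L, 32L),
                                    total_epochs = 512L, n_pcs = 20L,
                                    hidden = c(64L, 32L), eta = 0.1,
                                    decay = 0.9999, batch_size = 64L,
                                    seed = 1) {
  if (is.null(nodes[[1]]$folds)) nodes <- assign_folds(nodes, n_folds, seed)
  cv_iterations <- cv_iterations %||% (seq_len(n_folds) - 1L)
  n_classes <- length(unique(unlist(lapply(nodes, function(nd) nd$pheno$population))))
  summaries <- list()
  logs <- list()
  n_snps <- NA_integer_
  for (t in cv_iterations) {
    splits <- lapply(nodes, function(nd) fold_split(nd$folds, t, n_folds))
    ids <- ancestry_feature_union(nodes, splits)
    n_snps <- length(ids)
    prep <- ancestry_client_data(nodes, splits, ids, n_pcs, mode = "federated")
    pca_bytes <- pca_comm_cost(length(ids),
                               lapply(prep$clients, function(cl) {
                                 list(evals = numeric(nrow(cl$train$X) - 1L))
                               }), n_pcs = n_pcs)
    for (E in epochs_per_round) {
      sched <- fed_schedule(total_epochs %/% E, E, eta, decay, batch_size)
      init <- mlp_init(n_pcs, hidden, n_classes, seed = mix_seed(seed, 21L, t))
      fit <- run_fedavg(init, prep$clients, sched,
                        seed = mix_seed(seed, 22L, t, E))
      val_all <- list(X = do.call(rbind, lapply(prep$clients, function(cl) cl$val$X)),
                      y = unlist(lapply(prep$clients, function(cl) cl$val$y)))
      acc_final <- accuracy(val_all$y, mlp_predict(fit$final_params, val_all$X))
      acc_best <- accuracy(val_all$y, mlp_predict(fit$params, val_all$X))
      summaries[[length(summaries) + 1L]] <- tibble::tibble(
        fold = t, model = "federated", epochs_per_round = E,
        rounds = sched$rounds,
        final_val_loss = fit$val_loss_by_round[sched$rounds, 1],
        best_val_loss = fit$best_loss,
        final_val_accuracy = acc_final, best_val_accuracy = acc_best,
        model_bytes = max(fit$log$cum_bytes), pca_bytes = pca_bytes)
      logs[[length(logs) + 1L]] <- dplyr::mutate(fit$log, fold = t,
                                                 epochs_per_round = E)
    }
    # centralized MLP on the same (federated) PC features
    pooled <- list(
      train = list(X = do.call(rbind, lapply(prep$clients, function(cl) cl$train$X)),
                   y = unlist(lapply(prep$clients, function(cl) cl$train$y))),
      val = list(X = do.call(rbind, lapply(prep$clients, function(cl) cl$val$X)),
                 y = unlist(lapply(prep$clients, function(cl) cl$val$y))))
    sched_c <- fed_schedule(total_epochs %/% 8L, 8L, eta, decay, batch_size)
    cen <- train_single(mlp_init(n_pcs, hidden, n_classes,
                                 seed = mix_seed(seed, 21L, t)),
                        pooled, sched_c, seed = mix_seed(seed, 23L, t))
    summaries[[length(summaries) + 1L]] <- tibble::tibble(
      fold = t, model = "centralized", epochs_per_round = NA_integer_,
      rounds = sched_c$rounds,
      final_val_loss = cen$val_loss_by_round[nrow(cen$val_loss_by_round), 1],
      best_val_loss = cen$best_loss,
      final_val_accuracy = accuracy(pooled$val$y,
                                    mlp_predict(cen$final_params, pooled$val$X)),
      best_val_accuracy = accuracy(pooled$val$y,
                                   mlp_predict(cen$params, pooled$val$X)),
      model_bytes = 0, pca_bytes = pca_bytes)
  }
  structure(list(summary = dplyr::bind_rows(summaries),
                 round_logs = dplyr::bind_rows(logs),
                 n_snps = n_snps),
            class = "ancestry_experiment")
}

#' Federated vs centralized PCA input-size sweep
#'
#' Relaxes the pruning threshold to produce shared variant sets of
#' increasing size, runs federated and centralized PCA on each, trains the
#' same centrally-optimized classifier on both, and reports paired train and
#' validation accuracies per fold.
#'
#' @param nodes Simulated continental-regime nodes; folds assigned if
#'   absent.
#' @param r2_grid Pruning thresholds to sweep (looser keeps more variants).
#' @param n_folds,cv_iterations CV controls.
#' @param n_pcs Shared PCs.
#' @param hidden,eta,decay,batch_size,total_epochs Classifier settings.
#' @param seed Integer seed.
#' @return Tibble of class `pca_sweep`: fold, `r2_max`, `n_snps`,
#'   `pca_mode`, train/val accuracy.
#' @export
run_pca_sweep <- function(nodes, r2_grid = c(0.05, 0.1, 0.2, 0.5, 0.95),
                          n_folds = 10L, cv_iterations = NULL, n_pcs = 20L,
                          hidden = c(64L, 32L), eta = 0.1, decay = 0.9999,
                          batch_size = 64L, total_epochs = 64L, seed = 1) {
  if (is.null(nodes[[1]]$folds)) nodes <- assign_folds(nodes, n_folds, seed)
  cv_iterations <- cv_iterations %||% (seq_len(n_folds) - 1L)
  n_classes <- length(unique(unlist(lapply(nodes, function(nd) nd$pheno$population))))
  rows <- list()
  for (t in cv_iterations) {
    splits <- lapply(nodes, function(nd) fold_split(nd$folds, t, n_folds))
    for (r2m in r2_grid) {
      ids <- ancestry_feature_union(nodes, splits, prune_r2 = r2m)
      for (mode in c("federated", "centralized")) {
        prep <- ancestry_client_data(nodes, splits, ids, n_pcs, mode = mode)
        pooled <- list(
          train = list(X = do.call(rbind, lapply(prep$clients,
                                                 function(cl) cl$train$X)),
                       y = unlist(lapply(prep$clients, function(cl) cl$train$y))),
          val = list(X = do.call(rbind, lapply(prep$clients,
                                               function(cl) cl$val$X)),
                     y = unlist(lapply(prep$clients, function(cl) cl$val$y))))
        sched <- fed_schedule(max(1L, total_epochs %/% 8L), 8L, eta, decay,
                              batch_size)
        fit <- train_single(mlp_init(n_pcs, hidden, n_classes,
                                     seed = mix_seed(seed, 31L, t)),
                            pooled, sched, seed = mix_seed(seed, 32L, t))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          fold = t, r2_max = r2m, n_snps = length(ids), pca_mode = mode,
          train_accuracy = accuracy(pooled$train$y,
                                    mlp_predict(fit$params, pooled$train$X)),
          val_accuracy = accuracy(pooled$val$y,
                                  mlp_predict(fit$params, pooled$val$X)))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pca_sweep", class(out))
  out
}
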