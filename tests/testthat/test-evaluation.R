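test_that("fold assignment partitions each node evenly and deterministically", {
  pm <- population_model(1, 0, 20)
  fr <- draw_population_frequencies(pm, 1)
  nodes <- simulate_genotypes(fr, list(node_spec("A", 100, 1),
                                       node_spec("B", 57, 1)), 0, 1)
  a <- assign_folds(nodes, 10, seed = 3)
  expect_true(all(table(a[[1]]$folds) == 10))
  sizes_b <- table(a[[2]]$folds)
  expect_lte(max(sizes_b) - min(sizes_b), 1)
  b <- assign_folds(nodes, 10, seed = 3)
  expect_identical(a[[1]]$folds, b[[1]]$folds)
  expect_error(assign_folds(list(nodes[[1]], simulate_genotypes(
    fr, list(node_spec("C", 5, 1)), 0, 1)[[1]]), 10, 1), "need >= 10")
})

test_that("each CV rotation is a disjoint cover with the documented roles", {
  folds <- rep(0:9, each = 7)
  for (t in c(0, 5, 9)) {
    sp <- fold_split(folds, t, 10)
    expect_equal(sort(c(sp$train, sp$val, sp$test)), seq_along(folds))
    expect_true(all(folds[sp$test] == t))
    expect_true(all(folds[sp$val] == (t + 1) %% 10))
    expect_equal(length(sp$train), 56)
  }
})

test_that("fold quantiles follow the linear-interpolation rule", {
  q <- fold_quantiles(1:10)
  expect_equal(q$median, 5.5)
  expect_equal(q$q10, 1.9)
  expect_equal(q$q90, 9.1)
  d <- fold_quantiles(1:10, mode = "drop_extremes")
  expect_equal(d$q10, 2)
  expect_equal(d$q90, 9)
  expect_equal(d$median, 5.5)
})

test_that("no training statistic depends on validation or test rows", {
  fx <- make_trait_node(n = 120, m = 60, seed = 21)
  node <- fx$node
  node <- assign_folds(list(node), 10, 5)[[1]]
  sp <- fold_split(node$folds, 0, 10)
  mangled <- node
  mangled$pheno$phenotype[sp$test] <- 99
  mangled$block$geno[sp$val, ] <- 0L
  expect_identical(gwas_node(node, rows = sp$train, n_pcs = 5),
                   gwas_node(mangled, rows = sp$train, n_pcs = 5))
  tr_block <- block_subset(node$block, samples = sp$train)
  tr_block_m <- block_subset(mangled$block, samples = sp$train)
  expect_identical(federated_pca(list(tr_block), n_pcs = 3)$loadings,
                   federated_pca(list(tr_block_m), n_pcs = 3)$loadings)
})

test_that("a zero-heritability trait brings every model down to the covariate baseline", {
  reg <- simulate_regime("biobank", n_nodes = 5, samples_per_node = 300,
                         n_variants = 80, n_causal = 10, heritability = 0,
                         missing_rate = 0, seed = 31)
  res <- run_phenotype_experiment(reg$nodes, n_folds = 10, top_m = 20,
                                  n_pcs = 5,
                                  schedule = fed_schedule(4L, 4L, 5e-3, 0.99, 16L),
                                  L = 8, qc = FALSE, seed = 31)
  med <- res |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(r2 = stats::median(.data$r2))
  base <- med$r2[med$model == "covariates_centralized"]
  for (m in c("local", "local_meta", "federated", "centralized")) {
    expect_lt(abs(med$r2[med$model == m] - base), 0.05)
  }
})

test_that("phenotype experiment output is tidy with bracketing quantiles", {
  reg <- simulate_regime("biobank", n_nodes = 3, samples_per_node = 120,
                         n_variants = 60, n_causal = 10, heritability = 0.5,
                         missing_rate = 0, seed = 32)
  res <- run_phenotype_experiment(reg$nodes, n_folds = 10,
                                  cv_iterations = 0:2, top_m = 20, n_pcs = 5,
                                  schedule = fed_schedule(4L, 4L, 5e-3, 0.99, 16L),
                                  L = 8, qc = FALSE, seed = 32)
  expect_tibble(res)
  expect_setequal(unique(res$fold), 0:2)
  summ <- tidy(res)
  expect_true(all(summ$q10 <= summ$median & summ$median <= summ$q90))
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("federated and centralized PCs give the same classifier accuracy", {
  reg <- simulate_regime("continental", samples_per_node = 120,
                         n_variants = 150, missing_rate = 0, seed = 33)
  sweep <- run_pca_sweep(reg$nodes, r2_grid = c(0.1, 0.95), n_folds = 10,
                         cv_iterations = 0:4, n_pcs = 10,
                         hidden = c(32L, 16L), total_epochs = 48L, seed = 33)
  expect_tibble(sweep)
  med <- sweep |>
    dplyr::group_by(.data$r2_max, .data$pca_mode) |>
    dplyr::summarise(val = stats::median(.data$val_accuracy),
                     train = stats::median(.data$train_accuracy),
                     .groups = "drop")
  for (r2 in unique(med$r2_max)) {
    pair <- med[med$r2_max == r2, ]
    expect_lt(abs(pair$val[1] - pair$val[2]), 0.02)
  }
  # training fit is at least as good as validation (median)
  expect_true(all(med$train >= med$val - 1e-9))
  # looser pruning keeps more variants
  expect_gt(max(sweep$n_snps), min(sweep$n_snps))
  expect_s3_class(autoplot(sweep), "ggplot")
})

test_that("reports write tables and figures, and warn on empty input", {
  dir <- withr::local_tempdir()
  expect_warning(report(list(), dir = dir), "empty")

  reg <- simulate_regime("biobank", n_nodes = 3, samples_per_node = 100,
                         n_variants = 40, n_causal = 5, heritability = 0.5,
                         missing_rate = 0, seed = 34)
  res <- run_phenotype_experiment(reg$nodes, n_folds = 10,
                                  cv_iterations = 0L, top_m = 10, n_pcs = 3,
                                  schedule = fed_schedule(2L, 4L, 5e-3, 0.99, 16L),
                                  L = 6, qc = FALSE, seed = 34)
  paths <- report(list(phenotype = res), dir = dir)
  expect_true(file.exists(file.path(dir, "phenotype.tsv")))
  expect_true(file.exists(file.path(dir, "phenotype.png")))
  expect_gt(file.info(file.path(dir, "phenotype.png"))$size, 0)
  tab <- utils::read.delim(file.path(dir, "phenotype.tsv"))
  expect_true(all(c("model", "node", "median", "q10", "q90") %in% names(tab)))
})

test_that("experiment reruns under one seed are bit-identical", {
  reg <- simulate_regime("biobank", n_nodes = 3, samples_per_node = 100,
                         n_variants = 40, n_causal = 5, heritability = 0.5,
                         missing_rate = 0, seed = 35)
  args <- list(reg$nodes, n_folds = 10, cv_iterations = 0L, top_m = 10,
               n_pcs = 3, schedule = fed_schedule(2L, 4L, 5e-3, 0.99, 16L),
               L = 6, qc = FALSE, seed = 35)
  r1 <- do.call(run_phenotype_experiment, args)
  r2 <- do.call(run_phenotype_experiment, args)
  expect_identical(r1$r2, r2$r2)
})
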