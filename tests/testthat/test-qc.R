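test_that("the HWE chi-square matches its closed form", {
  # observed equals expected: chi2 = 0, p = 1
  expect_equal(hwe_test(25, 50, 25), 1)
  # (50, 0, 50): expected (25, 50, 25), chi2 = 25 + 50 + 25 = 100
  expect_equal(hwe_test(50, 0, 50), pchisq(100, 1, lower.tail = FALSE))
  expect_lt(hwe_test(50, 0, 50), 1e-20)
  # monomorphic: nothing to test
  expect_equal(hwe_test(30, 0, 0), 1)
  expect_error(hwe_test(0, 0, 0), "sum")
})

test_that("variant QC removes planted violators with the right reasons", {
  set.seed(7)
  n <- 100
  clean <- replicate(5, rbinom(n, 2, 0.4))
  rare <- rbinom(n, 2, 0.02)                      # MAF ~0.02 < 0.05
  gappy <- rbinom(n, 2, 0.4); gappy[1:8] <- NA    # 8% missing > 2%
  off_hwe <- rep(c(0L, 2L), n / 2)                # no hets at MAF 0.5
  block <- geno_block(cbind(clean, rare, gappy, off_hwe))
  res <- variant_qc(block, qc_thresholds())
  rep <- res$report
  expect_true(all(rep$kept[1:5]))
  expect_equal(rep$reason[6], "maf")
  expect_equal(rep$reason[7], "missingness")
  expect_equal(rep$reason[8], "hwe")
  expect_equal(ncol(res$block$geno), 5)
  # counts reconcile
  expect_equal(sum(rep$kept) + sum(!rep$kept), attr(rep, "n_before"))
  expect_equal(sum(rep$kept), attr(rep, "n_after"))
})

test_that("variant QC is idempotent and tolerates monomorphic-only input", {
  nodes <- make_two_pop_nodes(n_per_node = 80, n_variants = 120,
                              missing_rate = 0.01)
  once <- variant_qc(nodes[[1]]$block)
  twice <- variant_qc(once$block)
  expect_identical(twice$block$geno, once$block$geno)
  expect_true(all(twice$report$kept))

  mono <- geno_block(matrix(0L, 20, 3))
  res <- variant_qc(mono)
  expect_equal(ncol(res$block$geno), 0)
  expect_true(all(res$report$reason == "maf"))
})

test_that("KING kinship matches its formula on constructed pairs", {
  set.seed(1)
  g <- sample(0:2, 1000, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  # identical samples: phi = n_het / (2 n_het) = 0.5
  expect_equal(king_kinship(g, g), 0.5)
  # all opposite homozygotes, no heterozygous site: undefined
  expect_true(is.na(king_kinship(rep(c(0L, 2L), 50), rep(c(2L, 0L), 50))))
  # pairwise-complete handling
  g2 <- g; g2[1:100] <- NA
  expect_equal(king_kinship(g, g2), king_kinship(g2, g))
})

test_that("KING is near zero for unrelated samples under HWE", {
  p <- runif(10000, 0.1, 0.9)
  set.seed(2)
  gi <- rbinom(10000, 2, p)
  gj <- rbinom(10000, 2, p)
  expect_lt(abs(king_kinship(gi, gj)), 0.02)
})

test_that("the pairwise KING matrix agrees with the two-sample estimator", {
  nodes <- make_two_pop_nodes(n_per_node = 15, n_variants = 400,
                              missing_rate = 0.05)
  g <- nodes[[1]]$block$geno
  phi <- fedgeno:::king_matrix(g)
  for (pair in list(c(1, 2), c(3, 9), c(14, 15))) {
    expect_equal(phi[pair[1], pair[2]],
                 king_kinship(g[pair[1], ], g[pair[2], ]))
  }
  expect_equal(phi, t(phi))
})

test_that("sample QC removes high-missingness samples and one of each related pair", {
  set.seed(3)
  p <- runif(5000, 0.2, 0.8)
  g <- t(replicate(30, rbinom(5000, 2, p)))
  g[1, sample(5000, 350)] <- NA   # 7% missing > 6%
  g <- rbind(g, g[2, , drop = FALSE]) # duplicate of sample 2
  block <- geno_block(g)
  res <- sample_qc(block, qc_thresholds())
  rep <- res$report
  expect_equal(rep$reason[1], "missingness")
  dup_pair <- rep$reason[c(2, 31)]
  expect_equal(sum(dup_pair == "kinship", na.rm = TRUE), 1)
  expect_equal(sum(!rep$kept), 2)
  expect_equal(attr(rep, "n_after"), 29)
})

test_that("an unrelated simulated node loses no samples to kinship", {
  pm <- population_model(1, 0, 2000)
  fr <- draw_population_frequencies(pm, 5)
  nodes <- simulate_genotypes(fr, list(node_spec("A", 200, 1)), 0, 5)
  res <- sample_qc(nodes[[1]]$block, qc_thresholds())
  expect_true(all(res$report$kept))
})

test_that("LD pruning drops exactly one of a duplicated variant pair", {
  set.seed(4)
  base <- rbinom(200, 2, 0.45)
  others <- replicate(6, rbinom(200, 2, 0.5))
  block <- geno_block(cbind(base, others[, 1:3], base, others[, 4:6]))
  kept <- ld_prune(block, window = 8, step = 4, r2_max = 0.2)
  dup_ids <- block$variants$id[c(1, 5)]
  expect_equal(sum(dup_ids %in% kept), 1)
  expect_equal(length(kept), 7)
})

test_that("pruning keeps independent variants and never leaves a hot pair", {
  pm <- population_model(1, 0, 60)
  fr <- draw_population_frequencies(pm, 6)
  nodes <- simulate_genotypes(fr, list(node_spec("A", 2000, 1)), 0, 6)
  block <- nodes[[1]]$block
  kept <- ld_prune(block, window = 20, step = 5, r2_max = 0.1)
  expect_gte(length(kept), 0.95 * 60)
  # exhaustive re-check: no surviving within-window pair above the ceiling
  j <- match(kept, block$variants$id)
  g <- fedgeno:::impute_dosages(block$geno[, j, drop = FALSE])
  r2 <- stats::cor(g)^2
  diag(r2) <- 0
  for (s in seq(1, length(j) - 1, by = 5)) {
    win <- s:min(s + 19, length(j))
    expect_lte(max(r2[win, win]), 0.1)
  }
})

test_that("pruning edge cases behave as documented", {
  single <- geno_block(matrix(rbinom(50, 2, 0.5), 50, 1))
  expect_equal(length(ld_prune(single, window = 5, step = 1, r2_max = 0.5)), 1)
  expect_error(ld_prune(single, window = 1, step = 1, r2_max = 0.5), "window")
})

test_that("the variant union respects catalog order", {
  catalog <- sprintf("v%02d", 1:30)
  expect_equal(variant_union(list(catalog[1:10]), catalog), catalog[1:10])
  expect_equal(variant_union(list(catalog[1:10], catalog[11:25]), catalog),
               catalog[1:25])
  expect_equal(variant_union(list(catalog[5:10], catalog[1:20]), catalog),
               catalog[1:20])
  shuffled <- list(c("v09", "v03"), c("v01", "v20"))
  expect_equal(variant_union(shuffled, catalog), c("v01", "v03", "v09", "v20"))
})

test_that("both QC orderings run end to end with reconciling reports", {
  nodes <- make_two_pop_nodes(n_per_node = 60, n_variants = 150,
                              missing_rate = 0.02)
  for (ord in c("samples_first", "variants_first")) {
    res <- run_qc(nodes[[1]]$block, qc_thresholds(), order = ord)
    vr <- res$variant_report
    sr <- res$sample_report
    expect_equal(sum(vr$kept), attr(vr, "n_after"))
    expect_equal(nrow(res$block$geno), attr(sr, "n_after"))
    expect_equal(ncol(res$block$geno), attr(vr, "n_after"))
  }
})
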