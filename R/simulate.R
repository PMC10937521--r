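#' Population-structure model
#'
#' Describes a set of diverged populations under the Balding–Nichols model:
#' each variant has an ancestral allele frequency, and population `k` draws
#' its own frequency from `Beta(p(1-F_k)/F_k, (1-p)(1-F_k)/F_k)`, so `F_k`
#' acts as an interpretable divergence (FST) dial. `F_k = 0` collapses to the
#' ancestral frequency.
#'
#' @param n_populations Number of populations.
#' @param fst Per-population divergence in `[0, 1)`; recycled if scalar.
#' @param ancestral_freq_range Interval inside `(0.01, 0.99)` from which
#'   ancestral frequencies are drawn uniformly.
#' @param n_variants Number of variants.
#' @param superpop_assignment Character vector mapping each population to a
#'   superpopulation label; defaults to one superpopulation per population.
#' @return An object of class `population_model`.
#' @export
population_model <- function(n_populations, fst, n_variants,
                             ancestral_freq_range = c(0.1, 0.9),
                             superpop_assignment = NULL) {
  n_populations <- check_count(n_populations, "n_populations")
  n_variants <- check_count(n_variants, "n_variants")
  fst <- rep_len(as.double(fst), n_populations)
  if (any(fst < 0) || any(fst >= 1)) abort("fst values must lie in [0, 1)")
  r <- as.double(ancestral_freq_range)
  if (length(r) != 2 || r[1] >= r[2] || r[1] < 0.01 || r[2] > 0.99) {
    abort("ancestral_freq_range must be an increasing interval within (0.01, 0.99)")
  }
  superpop_assignment <- superpop_assignment %||% sprintf("SUPER%d", seq_len(n_populations))
  superpop_assignment <- rep_len(as.character(superpop_assignment), n_populations)
  structure(list(n_populations = n_populations, fst = fst,
                 ancestral_freq_range = r, n_variants = n_variants,
                 superpop = superpop_assignment),
            class = "population_model")
}

#' Trait architecture
#'
#' An additive quantitative-trait model: `n_causal` variants carry nonzero
#' effects, covariates (age, sex) add small fixed effects, and Gaussian noise
#' is scaled so the genetic score explains a `heritability` share of the
#' phenotypic variance. If `noise_sd` is given it is used directly and
#' `heritability` is ignored for scaling.
#'
#' @param n_causal Number of causal variants.
#' @param heritability Fraction of phenotypic variance attributable to the
#'   genetic score, in `[0, 1]`.
#' @param covariate_effects Named numeric vector with `age` and `sex` effects.
#' @param noise_sd Optional residual standard deviation override.
#' @return An object of class `trait_model`.
#' @export
trait_model <- function(n_causal, heritability = 0.5,
                        covariate_effects = c(age = 0.01, sex = 0.1),
                        noise_sd = NULL) {
  n_causal <- check_count(n_causal, "n_causal", min = 0L)
  check_number(heritability, "heritability", 0, 1)
  structure(list(n_causal = n_causal, heritability = heritability,
                 covariate_effects = covariate_effects, noise_sd = noise_sd),
            class = "trait_model")
}

#' Node specification
#'
#' @param node_id Node label.
#' @param n_samples Samples on the node (>= 2).
#' @param population_mixture Nonnegative weights over populations, summing
#'   to 1.
#' @return An object of class `node_spec`.
#' @export
node_spec <- function(node_id, n_samples, population_mixture) {
  n_samples <- check_count(n_samples, "n_samples", min = 2L)
  w <- as.double(population_mixture)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    abort("population_mixture must be nonnegative and sum to 1")
  }
  structure(list(node_id = as.character(node_id), n_samples = n_samples,
                 population_mixture = w),
            class = "node_spec")
}

#' Draw per-population allele frequencies
#'
#' Samples ancestral frequencies uniformly from the model's range, then one
#' Balding–Nichols draw per population and variant. Populations with `F = 0`
#' receive the ancestral frequency exactly.
#'
#' @param model A [population_model()].
#' @param seed Integer seed; identical inputs give identical matrices.
#' @return A `n_populations x n_variants` matrix of allele frequencies.
#' @export
draw_population_frequencies <- function(model, seed) {
  stopifnot(inherits(model, "population_model"))
  with_seed(mix_seed(seed, 101L), {
    p <- runif(model$n_variants, model$ancestral_freq_range[1],
               model$ancestral_freq_range[2])
    freqs <- matrix(0, model$n_populations, model$n_variants)
    for (k in seq_len(model$n_populations)) {
      f <- model$fst[k]
      if (f == 0) {
        freqs[k, ] <- p
      } else {
        freqs[k, ] <- rbeta(model$n_variants,
                            p * (1 - f) / f, (1 - p) * (1 - f) / f)
      }
    }
    attr(freqs, "ancestral") <- p
    freqs
  })
}

#' Simulate per-node genotype datasets
#'
#' Each sample's population is drawn from its node's mixture, dosages are
#' `Binomial(2, population frequency)` per variant, and calls are masked
#' missing completely at random at `missing_rate`.
#'
#' @param freqs Allele-frequency matrix from [draw_population_frequencies()].
#' @param specs List of [node_spec()] objects.
#' @param missing_rate Missing-call fraction in `[0, 0.2]`.
#' @param seed Integer seed.
#' @param superpop Optional population -> superpopulation map (character
#'   vector, one entry per population); defaults to one superpopulation per
#'   population.
#' @return A list of [node_data()] objects, one per spec.
#' @export
simulate_genotypes <- function(freqs, specs, missing_rate = 0, seed = 1,
                               superpop = NULL) {
  if (length(specs) == 0) abort("at least one node spec is required")
  check_number(missing_rate, "missing_rate", 0, 0.2)
  n_pop <- nrow(freqs)
  m <- ncol(freqs)
  superpop <- superpop %||% sprintf("SUPER%d", seq_len(n_pop))
  variants <- tibble::tibble(
    chrom = "1", id = sprintf("var%06d", seq_len(m)), cm = 0,
    pos = seq_len(m), a1 = "A", a2 = "B"
  )
  purrr::imap(specs, function(sp, idx) {
    stopifnot(inherits(sp, "node_spec"))
    with_seed(mix_seed(seed, 202L, idx), {
      n <- sp$n_samples
      pop <- sample.int(n_pop, n, replace = TRUE, prob = sp$population_mixture)
      g <- matrix(rbinom(n * m, 2L, freqs[pop, ]), nrow = n)
      if (missing_rate > 0) {
        g[runif(n * m) < missing_rate] <- NA_integer_
      }
      samples <- tibble::tibble(
        sample_id = sprintf("%s_s%05d", sp$node_id, seq_len(n))
      )
      pheno <- tibble::tibble(
        sample_id = samples$sample_id,
        node_id = sp$node_id,
        population = sprintf("POP%d", pop),
        superpopulation = superpop[pop]
      )
      node_data(geno_block(g, variants = variants, samples = samples), pheno)
    })
  })
}

#' Simulate a quantitative phenotype on a node
#'
#' Adds `age`, `sex` and `phenotype` columns:
#' `y = G beta + age*b_age + sex*b_sex + e`, with missing dosages
#' mean-imputed before scoring, `age ~ U{40..70}`, `sex ~ Bernoulli(0.5)`.
#' The residual SD comes from `trait$noise_sd` when set, otherwise from
#' [calibrate_noise_sd()] logic applied to this node's own genetic-score
#' variance. With `heritability = 0` the genetic term is dropped entirely.
#'
#' @param node A [node_data()].
#' @param trait A [trait_model()].
#' @param causal_effects Per-variant effect sizes (shared by every node).
#' @param seed Integer seed.
#' @return The node with phenotype and covariate columns filled in.
#' @export
simulate_phenotype <- function(node, trait, causal_effects, seed = 1) {
  stopifnot(inherits(node, "node_data"), inherits(trait, "trait_model"))
  m <- ncol(node$block$geno)
  if (length(causal_effects) != m) {
    abort("causal_effects must have one entry per variant")
  }
  h2 <- trait$heritability
  if (h2 > 0 && all(causal_effects == 0)) {
    abort("nonzero heritability with all-zero causal effects is undefined")
  }
  with_seed(mix_seed(seed, 303L), {
    n <- nrow(node$block$geno)
    g <- impute_dosages(node$block$geno)
    score <- if (h2 > 0) drop(g %*% causal_effects) else rep(0, n)
    age <- sample(40:70, n, replace = TRUE)
    sex <- rbinom(n, 1L, 0.5)
    ce <- trait$covariate_effects
    cov_part <- age * (ce[["age"]] %||% 0) + sex * (ce[["sex"]] %||% 0)
    noise_sd <- trait$noise_sd %||% derive_noise_sd(var(score), trait)
    y <- score + cov_part + rnorm(n, 0, noise_sd)
    node$pheno$age <- age
    node$pheno$sex <- sex
    node$pheno$phenotype <- y
    node$pheno$genetic_score <- score
    node
  })
}

# Residual SD giving Var(genetic)/Var(y) ~= h2 when the covariate share is
# small: sigma^2 = Var_g * (1 - h2) / h2. h2 = 0 means no genetic term; the
# residual then defaults to unit variance.
derive_noise_sd <- function(var_g, trait) {
  h2 <- trait$heritability
  if (h2 == 0) return(1)
  if (h2 == 1) return(0)
  if (var_g <= 0) abort("genetic score has zero variance; cannot scale noise")
  sqrt(var_g * (1 - h2) / h2)
}

#' Calibrate a shared residual SD across nodes
#'
#' Computes the genetic-score variance pooled over all nodes and returns the
#' residual SD that yields the trait's heritability, so every node can be
#' simulated under one common true model.
#'
#' @param nodes List of [node_data()] objects.
#' @param trait A [trait_model()].
#' @param causal_effects Shared per-variant effects.
#' @return A single residual SD.
#' @export
calibrate_noise_sd <- function(nodes, trait, causal_effects) {
  if (trait$heritability == 0) return(1)
  scores <- unlist(lapply(nodes, function(nd) {
    drop(impute_dosages(nd$block$geno) %*% causal_effects)
  }))
  derive_noise_sd(var(scores), trait)
}

#' Draw sparse causal effects
#'
#' Selects `n_causal` variants at random and assigns standard-normal effect
#' sizes; all other variants get zero.
#'
#' @param n_variants Total variants.
#' @param n_causal Causal variants (<= `n_variants`).
#' @param seed Integer seed.
#' @return Length-`n_variants` numeric effect vector.
#' @export
draw_causal_effects <- function(n_variants, n_causal, seed = 1) {
  if (n_causal > n_variants) abort("n_causal must not exceed n_variants")
  with_seed(mix_seed(seed, 404L), {
    beta <- numeric(n_variants)
    idx <- sample.int(n_variants, n_causal)
    beta[idx] <- rnorm(n_causal)
    beta
  })
}

#' Inject linkage-disequilibrium proxy pairs
#'
#' Variants are otherwise exchangeable (no chromosome map); LD pruning still
#' needs correlated pairs to act on. This rewrites a fraction of variants as
#' stochastic copies of their left neighbour: per sample, the dosage is taken
#' from the partner with probability `rho` (drawn per pair from `rho_range`)
#' and kept otherwise. The pairing and `rho` values are shared by every node,
#' so the induced correlation is population-level structure, not node noise.
#'
#' @param nodes List of [node_data()] objects (same variant catalog).
#' @param fraction Fraction of variants turned into proxies.
#' @param rho_range Copy-probability interval.
#' @param seed Integer seed.
#' @return The nodes with rewritten proxy columns.
#' @export
inject_ld_proxies <- function(nodes, fraction = 0.3, rho_range = c(0.5, 0.98),
                              seed = 1) {
  m <- ncol(nodes[[1]]$block$geno)
  n_pairs <- floor(fraction * m / 2)
  if (n_pairs < 1) return(nodes)
  with_seed(mix_seed(seed, 909L), {
    targets <- sort(sample(seq(2L, m, by = 2L), n_pairs))
    rho <- runif(n_pairs, rho_range[1], rho_range[2])
  })
  purrr::imap(nodes, function(nd, k) {
    g <- nd$block$geno
    with_seed(mix_seed(seed, 910L, k), {
      for (i in seq_along(targets)) {
        j <- targets[i]
        copy <- runif(nrow(g)) < rho[i]
        g[copy, j] <- g[copy, j - 1L]
      }
    })
    nd$block$geno <- g
    nd
  })
}

#' Simulate a full multi-node study regime
#'
#' Two presets mirror the package's study designs. `"biobank"` is the
#' many-node, low-heterogeneity regime: 19 nodes drawing from near-identical
#' populations (`F` in `[0.001, 0.01]`), a shared additive quantitative trait
#' and age/sex covariates. `"continental"` is the few-node, high-heterogeneity
#' regime: 5 nodes equal to 5 disjoint superpopulations with 26 nested
#' population labels (`F` in `[0.05, 0.15]`) and no quantitative trait.
#'
#' @param regime `"biobank"` or `"continental"`.
#' @param n_nodes,samples_per_node,n_variants Scale knobs; defaults are the
#'   regime's standard conditions.
#' @param n_causal,heritability Trait architecture (biobank regime).
#' @param missing_rate Missing-call fraction.
#' @param seed Integer seed.
#' @return List with `nodes` (list of [node_data()]), `effects`, `freqs`,
#'   and `model`.
#' @export
simulate_regime <- function(regime = c("biobank", "continental"),
                            n_nodes = NULL, samples_per_node = NULL,
                            n_variants = NULL, n_causal = 50,
                            heritability = 0.5, missing_rate = 0.01,
                            seed = 1) {
  regime <- match.arg(regime)
  if (regime == "biobank") {
    n_nodes <- n_nodes %||% 19L
    samples_per_node <- samples_per_node %||% 2000L
    n_variants <- n_variants %||% 1000L
    with_seed(mix_seed(seed, 505L), {
      fst <- runif(n_nodes, 0.001, 0.01)
    })
    model <- population_model(n_nodes, fst, n_variants,
                              superpop_assignment = rep("EUR", n_nodes))
    freqs <- draw_population_frequencies(model, seed)
    specs <- lapply(seq_len(n_nodes), function(k) {
      w <- numeric(n_nodes); w[k] <- 1
      node_spec(sprintf("node%02d", k), samples_per_node, w)
    })
    nodes <- simulate_genotypes(freqs, specs, missing_rate, seed,
                                superpop = model$superpop)
    effects <- draw_causal_effects(n_variants, n_causal, seed)
    trait <- trait_model(n_causal, heritability)
    trait$noise_sd <- calibrate_noise_sd(nodes, trait, effects)
    nodes <- purrr::imap(nodes, function(nd, k) {
      simulate_phenotype(nd, trait, effects, seed = mix_seed(seed, 606L, k))
    })
    list(nodes = nodes, effects = effects, freqs = freqs, model = model,
         trait = trait)
  } else {
    n_nodes <- n_nodes %||% 5L
    samples_per_node <- samples_per_node %||% 600L
    n_variants <- n_variants %||% 800L
    n_pop <- 26L
    supers <- c("AFR", "AMR", "EAS", "EUR", "SAS")[seq_len(n_nodes)]
    # 26 populations nested in the nodes' superpopulations, balanced
    superpop_of <- supers[rep_len(seq_len(n_nodes), n_pop)]
    with_seed(mix_seed(seed, 707L), {
      fst <- runif(n_pop, 0.05, 0.15)
    })
    model <- population_model(n_pop, fst, n_variants,
                              superpop_assignment = superpop_of)
    freqs <- draw_population_frequencies(model, seed)
    specs <- lapply(seq_len(n_nodes), function(k) {
      w <- as.numeric(superpop_of == supers[k])
      node_spec(supers[k], samples_per_node, w / sum(w))
    })
    nodes <- simulate_genotypes(freqs, specs, missing_rate, seed,
                                superpop = superpop_of)
    nodes <- inject_ld_proxies(nodes, fraction = 0.3, seed = seed)
    list(nodes = nodes, effects = NULL, freqs = freqs, model = model,
         trait = NULL)
  }
}
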