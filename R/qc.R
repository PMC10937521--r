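#' QC thresholds
#'
#' The standard per-node quality-control settings: sample missingness 6%,
#' KING kinship 0.0884 (second-degree relatives), minor allele frequency 5%,
#' variant missingness 2%, Hardy-Weinberg p 1e-6.
#'
#' @param sample_missingness_max,kinship_cutoff,maf_min,variant_missingness_max,hwe_p_min
#'   Individual thresholds; see defaults.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(sample_missingness_max = 0.06,
                          kinship_cutoff = 0.0884,
                          maf_min = 0.05,
                          variant_missingness_max = 0.02,
                          hwe_p_min = 1e-6) {
  check_number(sample_missingness_max, "sample_missingness_max", 0, 1)
  check_number(maf_min, "maf_min", 0, 0.5)
  check_number(variant_missingness_max, "variant_missingness_max", 0, 1)
  check_number(hwe_p_min, "hwe_p_min", 0, 1)
  structure(list(sample_missingness_max = sample_missingness_max,
                 kinship_cutoff = kinship_cutoff,
                 maf_min = maf_min,
                 variant_missingness_max = variant_missingness_max,
                 hwe_p_min = hwe_p_min),
            class = "qc_thresholds")
}

#' Hardy-Weinberg equilibrium test
#'
#' One-degree-of-freedom chi-square goodness-of-fit of the observed genotype
#' counts against the expected counts `(n p^2, 2 n p q, n q^2)` under the
#' sample allele frequency. Monomorphic input returns p = 1 by convention.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (dosage 2, 1, 0).
#' @return Two-sided p-value.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (any(c(n_AA, n_Aa, n_aa) < 0) || n < 1) {
    abort("genotype counts must be nonnegative and sum to >= 1")
  }
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p == 0 || p == 1) return(1)
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((c(n_AA, n_Aa, n_aa) - expected)^2 / expected)
  pchisq(chi2, df = 1, lower.tail = FALSE)
}

# Per-variant QC statistics on non-missing calls.
variant_stats <- function(geno) {
  n <- nrow(geno)
  miss <- unname(colMeans(is.na(geno)))
  af <- unname(colMeans(geno, na.rm = TRUE)) / 2
  af[!is.finite(af)] <- 0
  maf <- pmin(af, 1 - af)
  hwe_p <- vapply(seq_len(ncol(geno)), function(j) {
    g <- geno[, j]
    g <- g[!is.na(g)]
    if (!length(g)) return(1)
    hwe_test(sum(g == 2L), sum(g == 1L), sum(g == 0L))
  }, numeric(1))
  tibble::tibble(id = colnames(geno) %||% as.character(seq_len(ncol(geno))),
                 maf = maf, missingness = miss, hwe_p = hwe_p)
}

#' Per-node variant quality control
#'
#' Removes variants with minor allele frequency below `maf_min`, missingness
#' above `variant_missingness_max`, or Hardy-Weinberg p below `hwe_p_min`.
#' MAF and HWE are computed on non-missing calls. Applying the filter twice
#' equals applying it once.
#'
#' @param block A [geno_block()].
#' @param t A [qc_thresholds()].
#' @return List with the filtered `block` and a `report` tibble (per-variant
#'   `maf`, `missingness`, `hwe_p`, `kept`, `reason`) carrying `n_before` /
#'   `n_after` attributes.
#' @export
variant_qc <- function(block, t = qc_thresholds()) {
  stats <- variant_stats(block$geno)
  reason <- dplyr::case_when(
    stats$maf < t$maf_min ~ "maf",
    stats$missingness > t$variant_missingness_max ~ "missingness",
    stats$hwe_p < t$hwe_p_min ~ "hwe",
    TRUE ~ NA_character_
  )
  report <- dplyr::mutate(stats, kept = is.na(reason), reason = reason)
  keep <- which(report$kept)
  out <- block_subset(block, variants = keep)
  attr(report, "n_before") <- ncol(block$geno)
  attr(report, "n_after") <- length(keep)
  list(block = out, report = report)
}

#' KING-robust kinship between two samples
#'
#' The between-family estimator
#' `(N_AaAa - 2 N_AAaa) / (N_Aa(i) + N_Aa(j))`, where `N_AaAa` counts sites
#' with both samples heterozygous, `N_AAaa` sites with opposite homozygotes,
#' and `N_Aa(.)` heterozygous sites per sample, all over pairwise-complete
#' sites. Returns `NA` when neither sample has a heterozygous site.
#'
#' @param g_i,g_j Dosage vectors of equal length.
#' @return Kinship estimate (0.5 for duplicates, ~0 for unrelated).
#' @export
king_kinship <- function(g_i, g_j) {
  if (length(g_i) != length(g_j)) abort("dosage vectors must have equal length")
  ok <- !is.na(g_i) & !is.na(g_j)
  gi <- g_i[ok]; gj <- g_j[ok]
  n_het_both <- sum(gi == 1L & gj == 1L)
  n_opp_hom <- sum((gi == 0L & gj == 2L) | (gi == 2L & gj == 0L))
  denom <- sum(gi == 1L) + sum(gj == 1L)
  if (denom == 0) return(NA_real_)
  (n_het_both - 2 * n_opp_hom) / denom
}

# Full pairwise KING matrix (vectorized over samples).
king_matrix <- function(geno) {
  het <- (!is.na(geno) & geno == 1L) * 1
  hom0 <- (!is.na(geno) & geno == 0L) * 1
  hom2 <- (!is.na(geno) & geno == 2L) * 1
  nm <- (!is.na(geno)) * 1
  n_het_both <- tcrossprod(het)
  n_opp <- tcrossprod(hom0, hom2)
  n_opp <- n_opp + t(n_opp)
  het_i <- tcrossprod(het, nm) # hets of i at sites where j is called
  denom <- het_i + t(het_i)
  phi <- (n_het_both - 2 * n_opp) / denom
  phi[denom == 0] <- NA_real_
  diag(phi) <- NA_real_
  phi
}

#' Per-node sample quality control
#'
#' Removes samples whose missing-call rate exceeds
#' `sample_missingness_max`, then greedily breaks every remaining pair with
#' KING kinship at or above `kinship_cutoff` by dropping the member with the
#' higher missingness (ties drop the later sample in file order) until no
#' related pair remains.
#'
#' @param block A [geno_block()].
#' @param t A [qc_thresholds()].
#' @return List with the filtered `block` and a per-sample `report` tibble.
#' @export
sample_qc <- function(block, t = qc_thresholds()) {
  miss <- unname(rowMeans(is.na(block$geno)))
  reason <- ifelse(miss > t$sample_missingness_max, "missingness", NA_character_)
  alive <- which(is.na(reason))
  if (length(alive) > 1) {
    phi <- king_matrix(block$geno[alive, , drop = FALSE])
    repeat {
      related <- which(!is.na(phi) & phi >= t$kinship_cutoff, arr.ind = TRUE)
      related <- related[related[, 1] < related[, 2], , drop = FALSE]
      if (nrow(related) == 0) break
      i <- related[1, 1]; j <- related[1, 2]
      drop_local <- if (miss[alive[i]] > miss[alive[j]]) i
                    else if (miss[alive[j]] > miss[alive[i]]) j
                    else max(i, j)
      reason[alive[drop_local]] <- "kinship"
      phi <- phi[-drop_local, -drop_local, drop = FALSE]
      alive <- alive[-drop_local]
      if (length(alive) < 2) break
    }
  }
  report <- tibble::tibble(sample_id = block$samples$sample_id,
                           missingness = miss,
                           kept = is.na(reason), reason = reason)
  keep <- which(report$kept)
  attr(report, "n_before") <- nrow(block$geno)
  attr(report, "n_after") <- length(keep)
  list(block = block_subset(block, samples = keep), report = report)
}

#' Sliding-window LD pruning
#'
#' Slides a window of `window` variants advancing by `step`; within each
#' window, while any pair of kept variants has squared Pearson correlation
#' (on mean-imputed dosages) above `r2_max`, the member with the lower MAF is
#' removed (ties remove the later variant in file order). The returned ids
#' preserve file order, and no surviving within-window pair exceeds `r2_max`.
#'
#' @param block A [geno_block()].
#' @param window Window size in variants (>= 2).
#' @param step Window advance in variants.
#' @param r2_max Squared-correlation ceiling in `(0, 1]`.
#' @return Character vector of kept variant ids.
#' @export
ld_prune <- function(block, window = 50L, step = 5L, r2_max = 0.1) {
  window <- check_count(window, "window", min = 2L)
  step <- check_count(step, "step", min = 1L)
  check_number(r2_max, "r2_max", lower = 1e-12, upper = 1)
  g <- impute_dosages(block$geno)
  m <- ncol(g)
  maf <- pmin(colMeans(g) / 2, 1 - colMeans(g) / 2)
  kept <- rep(TRUE, m)
  starts <- unique(c(seq(1L, max(1L, m - 1L), by = step)))
  for (s in starts) {
    idx <- s:min(s + window - 1L, m)
    repeat {
      live <- idx[kept[idx]]
      if (length(live) < 2) break
      r2 <- suppressWarnings(stats::cor(g[, live, drop = FALSE]))^2
      r2[!is.finite(r2)] <- 0
      diag(r2) <- 0
      if (max(r2) <= r2_max) break
      worst <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
      a <- live[worst[1]]; b <- live[worst[2]]
      drop <- if (maf[a] < maf[b]) a else if (maf[b] < maf[a]) b else max(a, b)
      kept[drop] <- FALSE
    }
  }
  block$variants$id[kept]
}

#' Union of per-node kept variants
#'
#' The cross-node feature-harmonization step: only variant ids are shared,
#' and the union is returned in global catalog order.
#'
#' @param kept_lists List of per-node variant-id character vectors.
#' @param catalog Global variant-id ordering; defaults to first appearance
#'   across the lists.
#' @return Character vector of the ordered union.
#' @export
variant_union <- function(kept_lists, catalog = NULL) {
  if (length(kept_lists) == 0) abort("at least one node's list is required")
  u <- unique(unlist(kept_lists))
  catalog <- catalog %||% u
  catalog[catalog %in% u]
}

#' Run a node's full QC flow
#'
#' Two fixed orderings are supported: `"samples_first"` (sample missingness,
#' relatedness, then variant QC — the many-node biobank flow) and
#' `"variants_first"` (variant QC then sample QC — the continental flow).
#'
#' @param block A [geno_block()].
#' @param t A [qc_thresholds()].
#' @param order `"samples_first"` or `"variants_first"`.
#' @return List with `block`, `sample_report`, `variant_report`.
#' @export
run_qc <- function(block, t = qc_thresholds(), order = "samples_first") {
  if (order == "samples_first") {
    s <- sample_qc(block, t)
    v <- variant_qc(s$block, t)
    list(block = v$block, sample_report = s$report, variant_report = v$report)
  } else if (order == "variants_first") {
    v <- variant_qc(block, t)
    s <- sample_qc(v$block, t)
    list(block = s$block, sample_report = s$report, variant_report = v$report)
  } else {
    abort("order must be 'samples_first' or 'variants_first'")
  }
}
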