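# Per-node GWAS and cross-node random-effects meta-analysis: the feature
# selection path for the polygenic model. The per-variant OLS uses the
# Frisch-Waugh residualization identity so that all variants are fit in a
# handful of matrix operations while remaining exactly equal to the full
# per-variant regression with covariates.

# Top-d PC scores of a (mean-imputed, centered) dosage matrix.
local_pc_scores <- function(geno, d) {
  g <- impute_dosages(geno)
  g <- sweep(g, 2, colMeans(g))
  d <- min(d, nrow(g) - 1L, ncol(g))
  if (d < 1) return(matrix(0, nrow(g), 0))
  sv <- svd(g, nu = d, nv = 0)
  sv$u %*% diag(sv$d[seq_len(d)], d, d)
}

#' Per-node genome-wide association scan
#'
#' For each variant, fits ordinary least squares of the phenotype on
#' (dosage, age, sex, local PCs, intercept), with missing dosages
#' mean-imputed, and reports the dosage term's effect, standard error and
#' two-sided t-test p-value. PCs are computed from the node's own rows
#' (normally the training folds).
#'
#' @param node A [node_data()] with `phenotype`, `age`, `sex` columns.
#' @param rows Optional integer index of samples to use (training folds);
#'   default all.
#' @param n_pcs Number of local principal components used as covariates.
#' @return A tibble of summary statistics: `id`, `beta`, `se`, `p`, `n`,
#'   `reason` (`NA` for fitted variants, `"zero_variance"` for skipped ones).
#' @export
gwas_node <- function(node, rows = NULL, n_pcs = 20L) {
  stopifnot(inherits(node, "node_data"))
  rows <- rows %||% seq_len(nrow(node$block$geno))
  geno <- node$block$geno[rows, , drop = FALSE]
  ph <- node$pheno[rows, ]
  y <- ph$phenotype
  n <- length(y)
  g <- impute_dosages(geno)
  pcs <- local_pc_scores(geno, n_pcs)
  C <- cbind(1, ph$age, ph$sex, pcs)
  qrC <- qr(C)
  p_cov <- qrC$rank
  e_y <- qr.resid(qrC, y)
  e_g <- qr.resid(qrC, g)
  ss_x <- unname(colSums(e_g^2))
  fitted_ok <- ss_x > 1e-12
  xy <- unname(drop(crossprod(e_g, e_y)))
  beta <- ifelse(fitted_ok, xy / ss_x, NA_real_)
  df <- n - p_cov - 1L
  ss_y <- sum(e_y^2)
  if (ss_y <= 1e-20 * n) {
    # phenotype fully explained by the covariates (e.g. constant)
    beta[fitted_ok] <- 0
    se <- ifelse(fitted_ok, 0, NA_real_)
    p <- ifelse(fitted_ok, 1, NA_real_)
  } else {
    sigma2 <- pmax(ss_y - beta^2 * ss_x, 0) / df
    se <- sqrt(sigma2 / ss_x)
    p <- 2 * pt(-abs(beta / se), df = df)
    # exact linear fits leave (numerically) zero residual variance: report
    # the smallest representable p rather than an unstable t-tail
    exact <- fitted_ok & sigma2 <= 1e-20 * ss_y / df
    p[exact] <- .Machine$double.xmin
    p <- pmin(pmax(p, .Machine$double.xmin), 1)
  }
  tibble::tibble(
    id = node$block$variants$id,
    beta = beta,
    se = ifelse(fitted_ok, se, NA_real_),
    p = ifelse(fitted_ok, p, NA_real_),
    n = n,
    reason = ifelse(fitted_ok, NA_character_, "zero_variance")
  )
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Pools per-node association results by variant id. Fixed-effect weights
#' `w_i = 1/se_i^2` give `Q = sum w_i (beta_i - beta_FE)^2`; the
#' between-study variance is
#' `tau^2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`; random-effects
#' weights `1/(se_i^2 + tau^2)` give the pooled estimate, its standard error
#' `(sum w*)^(-1/2)` and a normal-approximation p-value. Variants reported by
#' a single node pool to that node's estimate with `tau^2 = 0`.
#'
#' @param stats List of per-node summary-statistic tibbles from
#'   [gwas_node()].
#' @return A tibble with `id`, `beta`, `se`, `p`, `tau2`, `q`, `k`.
#' @export
meta_random_effects <- function(stats) {
  if (length(stats) == 0) abort("at least one node's summary statistics required")
  long <- dplyr::bind_rows(stats, .id = "node") |>
    dplyr::filter(!is.na(.data$beta), !is.na(.data$se), .data$se > 0)
  if (nrow(long) == 0) {
    return(tibble::tibble(id = character(), beta = numeric(), se = numeric(),
                          p = numeric(), tau2 = numeric(), q = numeric(),
                          k = integer()))
  }
  ids <- unique(stats[[1]]$id)
  ids <- unique(c(ids, long$id))
  out <- long |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      k = dplyr::n(),
      {
        w <- 1 / se^2
        b_fe <- sum(w * beta) / sum(w)
        q <- sum(w * (beta - b_fe)^2)
        cval <- sum(w) - sum(w^2) / sum(w)
        tau2 <- if (dplyr::n() == 1 || cval <= 0) 0 else max(0, (q - (dplyr::n() - 1)) / cval)
        ws <- 1 / (se^2 + tau2)
        pooled_b <- sum(ws * beta) / sum(ws)
        pooled_se <- 1 / sqrt(sum(ws))
        tibble::tibble(beta = pooled_b, se = pooled_se,
                       p = pmax(2 * pnorm(-abs(pooled_b / pooled_se)),
                                .Machine$double.xmin),
                       tau2 = tau2, q = q)
      },
      .groups = "drop"
    )
  out <- out[match(ids[ids %in% out$id], out$id), ]
  dplyr::relocate(out, "id", "beta", "se", "p", "tau2", "q", "k")
}

#' Select the most significant variants
#'
#' Orders by ascending p-value, breaking ties by larger absolute pooled
#' effect and then catalog (input) order, and returns the top `m` ids.
#'
#' @param meta A meta-analysis (or single-node summary-statistic) tibble
#'   with `id`, `beta`, `p`.
#' @param m Number of variants to select.
#' @return Ordered character vector of at most `m` variant ids.
#' @export
select_top_snps <- function(meta, m) {
  m <- check_count(m, "m")
  usable <- dplyr::filter(meta, !is.na(.data$p))
  if (m > nrow(usable)) {
    warn(sprintf("requested %d variants but only %d available", m, nrow(usable)))
    m <- nrow(usable)
  }
  ord <- order(usable$p, -abs(usable$beta), seq_len(nrow(usable)))
  usable$id[ord[seq_len(m)]]
}
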