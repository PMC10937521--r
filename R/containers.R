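#' Genotype block
#'
#' The basic genotype container: a samples x variants matrix of minor-allele
#' dosages (0, 1, 2, or `NA` for a missing call) plus variant and sample
#' metadata kept in file order. File order is the single source of ordering;
#' no operation in the package silently reorders rows or columns.
#'
#' @param geno Integer matrix, samples in rows, variants in columns; entries
#'   in `{0, 1, 2, NA}`.
#' @param variants Tibble with one row per variant: `chrom`, `id`, `cm`,
#'   `pos`, `a1`, `a2`. Defaults are generated if omitted.
#' @param samples Tibble with one row per sample; must contain `sample_id`.
#' @return An object of class `geno_block`.
#' @export
geno_block <- function(geno, variants = NULL, samples = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  bad <- geno[!is.na(geno)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    abort("dosages must be 0, 1, 2 or NA")
  }
  m <- ncol(geno)
  n <- nrow(geno)
  if (is.null(variants)) {
    variants <- tibble::tibble(
      chrom = "1", id = sprintf("var%06d", seq_len(m)), cm = 0,
      pos = seq_len(m), a1 = "A", a2 = "B"
    )
  }
  variants <- tibble::as_tibble(variants)
  if (nrow(variants) != m) abort("variant metadata rows must match ncol(geno)")
  if (anyDuplicated(variants$id)) abort("variant ids must be unique")
  if (any(variants$pos < 1)) abort("variant positions must be >= 1")
  if (is.null(samples)) {
    samples <- tibble::tibble(sample_id = sprintf("s%06d", seq_len(n)))
  }
  samples <- tibble::as_tibble(samples)
  if (nrow(samples) != n) abort("sample metadata rows must match nrow(geno)")
  colnames(geno) <- variants$id
  rownames(geno) <- samples$sample_id
  structure(list(geno = geno, variants = variants, samples = samples),
            class = "geno_block")
}

#' @export
print.geno_block <- function(x, ...) {
  cat(sprintf("<geno_block> %d samples x %d variants (%.2f%% missing)\n",
              nrow(x$geno), ncol(x$geno), 100 * mean(is.na(x$geno))))
  invisible(x)
}

#' @export
dim.geno_block <- function(x) dim(x$geno)

#' Subset a genotype block
#'
#' Subsets by sample and/or variant index, keeping metadata in step and
#' preserving order.
#'
#' @param block A [geno_block()].
#' @param samples,variants Integer indices (default all).
#' @return A [geno_block()].
#' @export
block_subset <- function(block, samples = NULL, variants = NULL) {
  i <- samples %||% seq_len(nrow(block$geno))
  j <- variants %||% seq_len(ncol(block$geno))
  geno_block(block$geno[i, j, drop = FALSE],
             variants = block$variants[j, , drop = FALSE],
             samples = block$samples[i, , drop = FALSE])
}

#' Bind genotype blocks sample-wise
#'
#' Requires an identical variant set and order across blocks.
#'
#' @param blocks List of [geno_block()]s.
#' @return A pooled [geno_block()].
#' @export
block_rbind <- function(blocks) {
  ids <- lapply(blocks, function(b) b$variants$id)
  if (!all(vapply(ids, identical, logical(1), y = ids[[1]]))) {
    abort("blocks must share an identical variant set and order")
  }
  geno_block(do.call(rbind, lapply(blocks, function(b) b$geno)),
             variants = blocks[[1]]$variants,
             samples = dplyr::bind_rows(lapply(blocks, function(b) b$samples)))
}

#' One client's dataset
#'
#' Bundles a node's genotype block with its phenotype/covariate table and
#' cross-validation fold assignment. `pheno` carries one row per sample, in
#' block order: `sample_id`, `node_id`, `population`, `superpopulation`, and
#' after phenotype simulation also `age`, `sex`, `phenotype`.
#'
#' @param block A [geno_block()].
#' @param pheno Tibble of per-sample phenotype/covariate/label data.
#' @param folds Optional integer vector of fold indices (0-based), one per
#'   sample.
#' @return An object of class `node_data`.
#' @export
node_data <- function(block, pheno, folds = NULL) {
  stopifnot(inherits(block, "geno_block"))
  pheno <- tibble::as_tibble(pheno)
  if (nrow(pheno) != nrow(block$geno)) abort("pheno rows must match samples")
  if (!identical(pheno$sample_id, block$samples$sample_id)) {
    abort("pheno must be in block sample order")
  }
  if (!is.null(folds) && length(folds) != nrow(pheno)) {
    abort("folds must have one entry per sample")
  }
  structure(list(block = block, pheno = pheno, folds = folds),
            class = "node_data")
}

#' @export
print.node_data <- function(x, ...) {
  cat(sprintf("<node_data> node '%s': %d samples x %d variants\n",
              x$pheno$node_id[1] %||% "?", nrow(x$block$geno), ncol(x$block$geno)))
  invisible(x)
}

# Mean-impute missing dosages; returns a double matrix. Column means are
# computed on non-missing calls; an all-missing column imputes to 0.
impute_dosages <- function(geno, center = NULL) {
  g <- matrix(as.double(geno), nrow = nrow(geno),
              dimnames = dimnames(geno))
  if (anyNA(g)) {
    mu <- center %||% colMeans(g, na.rm = TRUE)
    mu[!is.finite(mu)] <- 0
    idx <- which(is.na(g), arr.ind = TRUE)
    g[idx] <- mu[idx[, 2]]
  }
  g
}
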