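# Run configuration: a flat YAML key-value file validated against a schema of
# documented defaults. The defaults collect the pipeline's standard settings:
# QC thresholds, feature selection size, PCA width, and the two models'
# training schedules.

config_schema <- function() {
  list(
    experiment = list(default = "phenotype",
                      check = function(x) x %in% c("phenotype", "ancestry")),
    seed = list(default = 1L, check = function(x) is.numeric(x) && x == floor(x)),
    out_dir = list(default = "fedgeno_out", check = is.character),
    # QC thresholds
    sample_missingness_max = list(default = 0.06, check = function(x) x >= 0 && x <= 1),
    kinship_cutoff = list(default = 0.0884, check = function(x) x >= 0 && x <= 0.5),
    maf_cutoff = list(default = 0.05, check = function(x) x >= 0 && x <= 0.5),
    variant_missingness_max = list(default = 0.02, check = function(x) x >= 0 && x <= 1),
    hwe_p_min = list(default = 1e-6, check = function(x) x >= 0 && x <= 1),
    qc_order = list(default = "samples_first",
                    check = function(x) x %in% c("samples_first", "variants_first")),
    # LD pruning
    prune_window = list(default = 50L, check = function(x) x >= 2),
    prune_step = list(default = 5L, check = function(x) x >= 1),
    prune_r2_max = list(default = 0.1, check = function(x) x > 0 && x <= 1),
    # feature selection / PCA
    top_snps = list(default = 10000L, check = function(x) x >= 1),
    n_pcs = list(default = 20L, check = function(x) x >= 1),
    # LASSO bank schedule
    lasso_batch_size = list(default = 16L, check = function(x) x >= 1),
    lasso_lr = list(default = 5e-3, check = function(x) x > 0),
    lasso_decay = list(default = 0.99, check = function(x) x > 0 && x <= 1),
    lasso_total_epochs = list(default = 256L, check = function(x) x >= 1),
    lasso_epochs_per_round = list(default = 8L, check = function(x) x >= 1),
    lasso_n_lambda = list(default = 32L, check = function(x) x >= 1),
    # MLP schedule
    mlp_batch_size = list(default = 64L, check = function(x) x >= 1),
    mlp_lr = list(default = 0.1, check = function(x) x > 0),
    mlp_decay = list(default = 0.9999, check = function(x) x > 0 && x <= 1),
    mlp_total_epochs = list(default = 16384L, check = function(x) x >= 1),
    mlp_epochs_per_round = list(default = 32L,
                                check = function(x) x %in% c(1L, 2L, 4L, 8L, 16L, 32L)),
    mlp_hidden = list(default = c(800L, 200L),
                      check = function(x) is.numeric(x) && all(x >= 1)),
    n_folds = list(default = 10L, check = function(x) x >= 2)
  )
}

#' Load a run configuration
#'
#' Reads a YAML key-value file, fills missing keys from the documented
#' defaults, rejects unknown keys and out-of-range values (naming the
#' offending key), and returns the fully resolved configuration.
#'
#' @param path Path to a YAML config file, or `NULL` for all defaults.
#' @return A named list of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  schema <- config_schema()
  user <- list()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path) %||% list()
  }
  unknown <- setdiff(names(user), names(schema))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- purrr::imap(schema, function(entry, key) {
    val <- if (key %in% names(user)) user[[key]] else entry$default
    if (!isTRUE(entry$check(val))) {
      abort(sprintf("config key '%s' has an invalid value: %s",
                    key, paste(format(val), collapse = ", ")))
    }
    if (is.numeric(entry$default) && is.numeric(val) &&
        all(entry$default == floor(entry$default))) {
      val <- as.integer(val)
    }
    val
  })
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x)) {
    cat(sprintf("  %s: %s\n", k, paste(format(x[[k]]), collapse = ", ")))
  }
  invisible(x)
}
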