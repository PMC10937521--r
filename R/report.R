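# Report generation: fold-quantile summaries (median with 0.1-0.9 interval),
# the standard figures for each study design, and TSV tables.

#' Median and 0.1-0.9 quantile interval across folds
#'
#' Linear interpolation of the empirical CDF (R quantile type 7) by
#' default; `mode = "drop_extremes"` instead reports the range left after
#' removing the single largest and smallest value.
#'
#' @param x Numeric vector (one value per fold).
#' @param mode `"interpolate"` or `"drop_extremes"`.
#' @return Tibble with `median`, `q10`, `q90`.
#' @export
fold_quantiles <- function(x, mode = c("interpolate", "drop_extremes")) {
  mode <- match.arg(mode)
  if (mode == "interpolate") {
    q <- quantile(x, c(0.1, 0.5, 0.9), type = 7, names = FALSE)
    tibble::tibble(median = q[2], q10 = q[1], q90 = q[3])
  } else {
    s <- sort(x)
    trimmed <- if (length(s) > 2) s[-c(1, length(s))] else s
    tibble::tibble(median = stats::median(x), q10 = min(trimmed),
                   q90 = max(trimmed))
  }
}

#' Summarise a phenotype experiment across folds
#'
#' @param x A [run_phenotype_experiment()] result.
#' @param ... Unused.
#' @return Tibble with per (model, node) median and 0.1-0.9 quantiles of
#'   R-squared.
#' @method tidy pheno_experiment
#' @export
tidy.pheno_experiment <- function(x, ...) {
  x |>
    dplyr::group_by(.data$model, .data$node) |>
    dplyr::summarise(fold_quantiles(.data$r2), n_folds = dplyr::n(),
                     .groups = "drop")
}

#' @method autoplot pheno_experiment
#' @export
autoplot.pheno_experiment <- function(object, ...) {
  summ <- tidy.pheno_experiment(object)
  ggplot2::ggplot(summ,
                  ggplot2::aes(x = .data$node, y = .data$median,
                               colour = .data$model)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$q10, ymax = .data$q90),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = "node", y = expression(R^2),
                  title = "Local vs federated vs centralized phenotype models",
                  colour = "model") +
    ggplot2::theme_minimal()
}

#' @method autoplot ancestry_experiment
#' @export
autoplot.ancestry_experiment <- function(object, ...) {
  summ <- object$summary |>
    dplyr::filter(.data$model == "federated") |>
    dplyr::group_by(.data$epochs_per_round) |>
    dplyr::summarise(fold_quantiles(.data$final_val_loss), .groups = "drop")
  ggplot2::ggplot(summ,
                  ggplot2::aes(x = factor(.data$epochs_per_round),
                               y = .data$median)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$q10, ymax = .data$q90)) +
    ggplot2::labs(x = "local epochs per communication round",
                  y = "final validation loss",
                  title = "Communication frequency vs convergence") +
    ggplot2::theme_minimal()
}

#' Per-round client training-loss trace
#'
#' Visualizes the aggregation spikes: the client loss evaluated at the
#' freshly aggregated parameters against the loss after local fitting.
#'
#' @param experiment A [run_ancestry_experiment()] result.
#' @param epochs_per_round Which schedule to show (default the largest).
#' @param fold Which fold to show (default the first present).
#' @return A ggplot object.
#' @export
plot_client_drift <- function(experiment, epochs_per_round = NULL,
                              fold = NULL) {
  logs <- experiment$round_logs
  epochs_per_round <- epochs_per_round %||% max(logs$epochs_per_round)
  fold <- fold %||% min(logs$fold)
  df <- logs |>
    dplyr::filter(.data$epochs_per_round == !!epochs_per_round,
                  .data$fold == !!fold) |>
    tidyr::pivot_longer(c("pre_loss", "post_loss"), names_to = "when",
                        values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$round, y = .data$loss,
                                   colour = factor(.data$client),
                                   linetype = .data$when)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = sprintf("Client loss, %d epochs/round",
                                  epochs_per_round),
                  colour = "client", linetype = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot pca_sweep
#' @export
autoplot.pca_sweep <- function(object, ...) {
  summ <- object |>
    tidyr::pivot_longer(c("train_accuracy", "val_accuracy"),
                        names_to = "split", values_to = "accuracy") |>
    dplyr::group_by(.data$n_snps, .data$pca_mode, .data$split) |>
    dplyr::summarise(fold_quantiles(.data$accuracy), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$n_snps, y = .data$median,
                                     colour = .data$pca_mode,
                                     linetype = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q10, ymax = .data$q90,
                                      fill = .data$pca_mode), alpha = 0.15,
                         colour = NA) +
    ggplot2::labs(x = "input SNPs", y = "accuracy",
                  title = "Classifier accuracy vs PCA input size") +
    ggplot2::theme_minimal()
}

#' Write figures and tables for completed experiments
#'
#' Emits one TSV of fold-quantile summaries and one PNG per supplied
#' result. An empty result list produces an empty report with a warning.
#'
#' @param results Named list of experiment results (any of the three
#'   experiment classes).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
report <- function(results, dir = "fedgeno_report") {
  if (length(results) == 0) {
    warn("no results supplied; writing an empty report")
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    return(invisible(character()))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in names(results)) {
    x <- results[[nm]]
    tab <- if (inherits(x, "pheno_experiment")) {
      tidy.pheno_experiment(x)
    } else if (inherits(x, "ancestry_experiment")) {
      x$summary |>
        dplyr::group_by(.data$model, .data$epochs_per_round) |>
        dplyr::summarise(fold_quantiles(.data$final_val_accuracy),
                         .groups = "drop")
    } else if (inherits(x, "pca_sweep")) {
      x |>
        dplyr::group_by(.data$n_snps, .data$pca_mode) |>
        dplyr::summarise(fold_quantiles(.data$val_accuracy), .groups = "drop")
    } else {
      tibble::as_tibble(x)
    }
    tsv <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, tsv)
    plt <- tryCatch(ggplot2::autoplot(x), error = function(e) NULL)
    if (!is.null(plt)) {
      png_path <- file.path(dir, paste0(nm, ".png"))
      grDevices::png(png_path, width = 900, height = 600)
      print(plt)
      grDevices::dev.off()
      paths <- c(paths, png_path)
    }
  }
  invisible(paths)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
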