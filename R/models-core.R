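# Model parameters as a flat, ordered collection of named numeric tensors --
# the unit that federated averaging linearly combines, independent of what
# model the tensors belong to.

#' Model parameter collection
#'
#' @param tensors Named list of numeric vectors/matrices (ordered).
#' @param kind Model kind tag (`"lasso_bank"` or `"mlp"`).
#' @return An object of class `model_params`.
#' @export
model_params <- function(tensors, kind) {
  stopifnot(is.list(tensors), !is.null(names(tensors)))
  structure(list(tensors = tensors, kind = kind), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params:%s> %d tensors, %d values\n",
              x$kind, length(x$tensors), n_params(x)))
  invisible(x)
}

#' Total parameter count
#' @param params A [model_params()].
#' @return Integer count of scalar parameters.
#' @export
n_params <- function(params) {
  sum(vapply(params$tensors, length, numeric(1)))
}

#' Flatten parameters to one numeric vector
#' @param params A [model_params()].
#' @return Numeric vector in tensor order.
#' @export
flatten_params <- function(params) {
  unlist(lapply(params$tensors, as.numeric), use.names = FALSE)
}

#' Rebuild parameters from a flat vector
#' @param flat Numeric vector from [flatten_params()].
#' @param template A [model_params()] giving shapes and names.
#' @return A [model_params()] with the template's structure.
#' @export
unflatten_params <- function(flat, template) {
  offset <- 0L
  tensors <- lapply(template$tensors, function(t) {
    k <- length(t)
    v <- flat[(offset + 1L):(offset + k)]
    offset <<- offset + k
    if (is.matrix(t)) matrix(v, nrow(t), ncol(t), dimnames = dimnames(t)) else
      setNames(v, names(t))
  })
  if (offset != length(flat)) abort("flat vector length does not match template")
  model_params(tensors, template$kind)
}

# Elementwise linear combination of conformable parameter sets.
params_combine <- function(params_list, weights) {
  template <- params_list[[1]]
  tensors <- lapply(seq_along(template$tensors), function(i) {
    acc <- template$tensors[[i]] * weights[1]
    for (k in seq_along(params_list)[-1]) {
      t_k <- params_list[[k]]$tensors[[i]]
      if (!identical(dim(t_k), dim(template$tensors[[i]])) ||
          length(t_k) != length(template$tensors[[i]])) {
        abort("client parameters have mismatched shapes")
      }
      acc <- acc + t_k * weights[k]
    }
    acc
  })
  names(tensors) <- names(template$tensors)
  model_params(tensors, template$kind)
}

#' Coefficient of determination
#'
#' `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`; negative for predictors
#' worse than the mean.
#'
#' @param y_true,y_pred Numeric vectors of equal length (>= 2).
#' @return R-squared.
#' @export
r2_score <- function(y_true, y_pred) {
  if (length(y_true) < 2 || length(y_true) != length(y_pred)) {
    abort("need >= 2 paired observations")
  }
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) abort("y_true has zero variance; R^2 undefined")
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Classification accuracy
#'
#' @param labels_true,labels_pred Label vectors of equal length.
#' @return Fraction of exact matches.
#' @export
accuracy <- function(labels_true, labels_pred) {
  if (length(labels_true) != length(labels_pred)) abort("length mismatch")
  mean(labels_true == labels_pred)
}

#' Write a model checkpoint
#'
#' Serializes a parameter collection as a plain-text archive: a JSON
#' manifest (`<prefix>.json` — kind, tensor names, shapes, optional penalty
#' grid) plus one flat value file (`<prefix>.values.tsv`). Stable across
#' runs, so checkpoints can serve as fixtures.
#'
#' @param params A [model_params()].
#' @param prefix Output path prefix.
#' @param lambda Optional penalty grid to record (bank models).
#' @return `prefix`, invisibly.
#' @export
write_checkpoint <- function(params, prefix, lambda = NULL) {
  manifest <- list(
    kind = params$kind,
    tensors = lapply(params$tensors, function(t) {
      list(dim = if (is.matrix(t)) dim(t) else length(t))
    }),
    lambda = lambda
  )
  jsonlite::write_json(manifest, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.table(data.frame(value = flatten_params(params)),
                     paste0(prefix, ".values.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Read a model checkpoint
#'
#' @param prefix Path prefix used by [write_checkpoint()].
#' @return List with `params` ([model_params()]) and `lambda` (or `NULL`).
#' @export
read_checkpoint <- function(prefix) {
  manifest <- jsonlite::read_json(paste0(prefix, ".json"),
                                  simplifyVector = TRUE)
  values <- utils::read.table(paste0(prefix, ".values.tsv"), header = TRUE,
                              sep = "\t")$value
  tensors <- list()
  offset <- 0L
  for (nm in names(manifest$tensors)) {
    d <- manifest$tensors[[nm]]$dim
    k <- prod(d)
    v <- values[(offset + 1L):(offset + k)]
    offset <- offset + as.integer(k)
    tensors[[nm]] <- if (length(d) == 2) matrix(v, d[1], d[2]) else v
  }
  if (offset != length(values)) abort("checkpoint values do not match manifest")
  list(params = model_params(tensors, manifest$kind),
       lambda = manifest$lambda)
}
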