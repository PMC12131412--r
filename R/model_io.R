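#' Save a trained model to an HDF5 container
#'
#' Stores weight matrices, biases, the architecture, the training gene list
#' and the coordinate normalizer in one file, so prediction and
#' weight-backtracking can run in a later session.
#'
#' @param model a `trained_model`.
#' @param path output `.h5` path (overwritten).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  h5w <- function(obj, name) rhdf5::h5write(obj, path, name)
  for (grp in c("weights", "biases", "spec", "normalizer")) {
    rhdf5::h5createGroup(path, grp)
  }
  for (i in seq_along(model$weights)) {
    h5w(model$weights[[i]], sprintf("weights/W%d", i))
    h5w(model$biases[[i]], sprintf("biases/b%d", i))
  }
  h5w(layer_dims(model$spec), "spec/dims")
  h5w(model$spec$dropout_rate, "spec/dropout_rate")
  h5w(model$spec$l1_lambda, "spec/l1_lambda")
  if (!is.null(model$gene_ids)) h5w(model$gene_ids, "gene_ids")
  if (!is.null(model$normalizer)) {
    nz <- model$normalizer
    h5w(nz$system, "normalizer/system")
    h5w(nz$min, "normalizer/min")
    h5w(nz$max, "normalizer/max")
    if (!is.null(nz$polar_center)) h5w(nz$polar_center, "normalizer/center")
  }
  if (!is.null(model$history)) h5w(as.matrix(model$history), "history")
  h5w(model$mean_pred_corr, "mean_pred_corr")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Load a trained model saved by [write_model()]
#'
#' @param path `.h5` path.
#' @return A `trained_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) {
    stop_stmap("stmap_parse_error", "model file not found: %s", path)
  }
  contents <- rhdf5::h5ls(path)
  slots <- sub("^/", "", file.path(sub("^/$", "", contents$group),
                                   contents$name))
  has <- function(p) p %in% slots
  dims <- as.integer(rhdf5::h5read(path, "spec/dims"))
  spec <- model_spec(
    n_genes = dims[1], out_dim = dims[length(dims)],
    hidden_widths = dims[-c(1, length(dims))],
    dropout_rate = as.numeric(rhdf5::h5read(path, "spec/dropout_rate")),
    l1_lambda = as.numeric(rhdf5::h5read(path, "spec/l1_lambda"))
  )
  L <- length(dims) - 1L
  weights <- lapply(seq_len(L), function(i)
    as.matrix(rhdf5::h5read(path, sprintf("weights/W%d", i))))
  biases <- lapply(seq_len(L), function(i)
    as.numeric(rhdf5::h5read(path, sprintf("biases/b%d", i))))
  normalizer <- NULL
  if (has("normalizer/system")) {
    normalizer <- structure(list(
      system = as.character(rhdf5::h5read(path, "normalizer/system")),
      min = as.numeric(rhdf5::h5read(path, "normalizer/min")),
      max = as.numeric(rhdf5::h5read(path, "normalizer/max")),
      polar_center = if (has("normalizer/center"))
        as.numeric(rhdf5::h5read(path, "normalizer/center"))
    ), class = "coord_normalizer")
  }
  history <- NULL
  if (has("history")) {
    hm <- rhdf5::h5read(path, "history")
    history <- as.data.frame(hm)
    colnames(history) <- c("epoch", "loss", "val_loss", "lr")
  }
  structure(list(
    spec = spec, weights = weights, biases = biases,
    gene_ids = if (has("gene_ids"))
      as.character(rhdf5::h5read(path, "gene_ids")),
    normalizer = normalizer, history = history,
    mean_pred_corr = as.numeric(rhdf5::h5read(path, "mean_pred_corr"))
  ), class = "trained_model")
}
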