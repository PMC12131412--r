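#' Gene importance by backward weight aggregation
#'
#' Scores each input gene's contribution to the location prediction by
#' walking the trained weight matrices backward. For the last matrix the
#' score of row `j` is the plain absolute row sum. For every earlier matrix
#' `i`, only columns `k` whose downstream node score `S_{i+1,k}` strictly
#' exceeds the `percentile_r`-th percentile of `S_{i+1}` contribute:
#' `S_{i,j} = sum_k 1[S_{i+1,k} > Percentile(S_{i+1}, r)] |W_{i,j,k}|`.
#' The returned `S_1` has one raw score per input gene; genes feeding the
#' consistently high-weight paths to the output score highest, which is how
#' spatially informative genes surface.
#'
#' @param weights list of shape-chained weight matrices (or a
#'   `trained_model`).
#' @param percentile_r percentile in (0, 100) for the node mask; default 50
#'   (the median, linear-interpolation convention).
#' @return Numeric vector `S_1`, one non-negative score per input row of the
#'   first matrix.
#' @export
backtrack_importance <- function(weights, percentile_r = 50) {
  if (inherits(weights, "trained_model")) weights <- weights$weights
  if (!length(weights)) {
    stop_stmap("stmap_validation_error", "empty weight list")
  }
  if (percentile_r <= 0 || percentile_r >= 100) {
    stop_stmap("stmap_validation_error", "percentile_r must be in (0, 100)")
  }
  L <- length(weights)
  for (i in seq_len(L - 1L)) {
    if (ncol(weights[[i]]) != nrow(weights[[i + 1L]])) {
      stop_stmap("stmap_validation_error",
                 "weight matrices %d and %d do not chain (%d cols vs %d rows)",
                 i, i + 1L, ncol(weights[[i]]), nrow(weights[[i + 1L]]))
    }
  }
  S <- rowSums(abs(weights[[L]]))
  if (L == 1L) return(S)
  for (i in rev(seq_len(L - 1L))) {
    thr <- as.numeric(quantile(S, percentile_r / 100, names = FALSE))
    keep <- S > thr
    W <- abs(weights[[i]])
    S <- if (any(keep)) rowSums(W[, keep, drop = FALSE]) else
      numeric(nrow(W))
  }
  S
}

#' Normalize raw importance scores
#'
#' Rescales raw backtracked scores so they sum to `mean_corr * scaler`:
#' `S_norm_j = S_j / sum(S) * mean_corr * scaler`. `mean_corr` is the mean
#' Pearson correlation between predicted and reference coordinates on
#' held-out data, so scores from a badly fit model shrink toward zero and
#' scores are comparable across models and tissues.
#'
#' @param raw non-negative raw scores with positive sum.
#' @param mean_corr the model's held-out coordinate correlation (`r-bar`).
#' @param scaler positive scale factor, default 1000.
#' @return Numeric vector of normalized scores.
#' @export
normalize_importance <- function(raw, mean_corr, scaler = 1000) {
  if (scaler <= 0) stop_stmap("stmap_validation_error", "scaler must be > 0")
  s <- sum(raw)
  if (s <= 0) {
    stop_stmap("stmap_degenerate_model_error",
               "all raw importance scores are zero")
  }
  raw / s * mean_corr * scaler
}

#' Importance scores for a trained model
#'
#' Convenience wrapper running [backtrack_importance()] and
#' [normalize_importance()] on a trained model.
#'
#' @param model a `trained_model` with recorded gene ids.
#' @param percentile_r node-mask percentile, default 50.
#' @param scaler normalization scale factor, default 1000.
#' @return An `importance_scores` object: `gene_ids`, `raw`, `normalized`,
#'   `percentile_r`, `scaler`, `mean_corr`.
#' @export
importance_scores <- function(model, percentile_r = 50, scaler = 1000) {
  stopifnot(inherits(model, "trained_model"))
  raw <- backtrack_importance(model$weights, percentile_r)
  gene_ids <- model$gene_ids
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_along(raw))
  names(raw) <- gene_ids
  structure(list(
    gene_ids = gene_ids, raw = raw,
    normalized = normalize_importance(raw, model$mean_pred_corr, scaler),
    percentile_r = percentile_r, scaler = scaler,
    mean_corr = model$mean_pred_corr
  ), class = "importance_scores")
}

#' Fold-aggregated importance scores from a cross-validation
#'
#' Averages the raw and normalized backtracked scores over the per-fold
#' models of a [crossvalidate()] run (`keep_models = TRUE`). Averaging over
#' folds damps the run-to-run variability of any single trained network, so
#' the aggregated ranking is the recommended basis for calling spatially
#' variable genes. The normalized scores still sum to the (fold-averaged)
#' held-out correlation times `scaler`.
#'
#' @param cv a `cv_result` carrying fold models.
#' @inheritParams importance_scores
#' @return An `importance_scores` object.
#' @export
cv_importance_scores <- function(cv, percentile_r = 50, scaler = 1000) {
  stopifnot(inherits(cv, "cv_result"))
  if (is.null(cv$models)) {
    stop_stmap("stmap_validation_error",
               "cross-validation was run without keep_models = TRUE")
  }
  per_fold <- lapply(cv$models, importance_scores,
                     percentile_r = percentile_r, scaler = scaler)
  gene_ids <- per_fold[[1]]$gene_ids
  structure(list(
    gene_ids = gene_ids,
    raw = rowMeans(vapply(per_fold, `[[`, numeric(length(gene_ids)), "raw")),
    normalized = rowMeans(vapply(per_fold, `[[`,
                                 numeric(length(gene_ids)), "normalized")),
    percentile_r = percentile_r, scaler = scaler,
    mean_corr = mean(vapply(per_fold, `[[`, numeric(1), "mean_corr"))
  ), class = "importance_scores")
}

#' Rank spatially variable genes by importance
#'
#' @param scores an [importance_scores()] object.
#' @param top_n number of genes to return (default all).
#' @return Character vector of gene ids sorted by normalized score
#'   descending, ties broken lexicographically by gene id.
#' @export
rank_svgs <- function(scores, top_n = length(scores$gene_ids)) {
  stopifnot(inherits(scores, "importance_scores"))
  if (top_n > length(scores$gene_ids)) {
    stop_stmap("stmap_validation_error", "top_n exceeds the number of genes")
  }
  ord <- order(-scores$normalized, scores$gene_ids)
  scores$gene_ids[ord][seq_len(top_n)]
}

#' @export
print.importance_scores <- function(x, ...) {
  cat(sprintf(
    "importance_scores: %d genes, r-bar = %.3f, top genes: %s\n",
    length(x$gene_ids), x$mean_corr,
    paste(utils::head(rank_svgs(x, min(5L, length(x$gene_ids))), 5),
          collapse = ", ")))
  invisible(x)
}
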