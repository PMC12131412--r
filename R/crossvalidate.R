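#' Fivefold cross-validated benchmarking
#'
#' Partitions the observations into `n_folds` disjoint folds (seeded), and
#' for each fold trains the network on the remaining folds and predicts the
#' left-out spots. Pairwise Pearson r and pairwise RMSE are computed per
#' fold between the true and predicted coordinates in the fold normalizer's
#' unit (min-max normalized) space; pooled metrics over all left-out spots
#' are computed in a global min-max space. An optional bootstrap resamples
#' the pooled left-out spots with replacement to attach error bars to the
#' pooled metrics.
#'
#' @param dataset a `spatial_dataset` with coordinates, expression already
#'   normalized (and gene-selected if a query set exists).
#' @param spec a [model_spec()]; its `n_genes` must match the dataset.
#' @param config a [train_config()]; per-fold seeds derive from `seed`.
#' @param n_folds number of folds (>= 2), default 5.
#' @param system coordinate system for the per-fold normalizer.
#' @param bootstrap number of bootstrap replicates over the pooled left-out
#'   spots (0 = none; 200 is the conventional choice).
#' @param keep_models retain the trained per-fold models in the result (used
#'   e.g. to aggregate gene-importance scores across folds).
#' @param seed integer seed for the fold partition and bootstrap.
#' @return A `cv_result` list: `folds` (per-fold data.frame with
#'   `pairwise_r`, `pairwise_rmse`, `mean_pred_corr`), `mean_r`,
#'   `mean_rmse`, `pooled_r`, `pooled_rmse`, `predictions` (data.frame of
#'   obs id, fold, true and predicted raw coordinates), and `bootstrap`
#'   (mean/sd per metric) when requested, and `models` (per-fold
#'   `trained_model`s) when `keep_models` is set.
#' @export
crossvalidate <- function(dataset, spec, config = train_config(),
                          n_folds = 5L, system = "cartesian",
                          bootstrap = 0L, keep_models = FALSE,
                          seed = config$seed) {
  stopifnot(inherits(dataset, "spatial_dataset"))
  if (is.null(dataset$coords)) {
    stop_stmap("stmap_validation_error", "dataset has no coordinates")
  }
  n <- nrow(dataset$expr)
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stop_stmap("stmap_validation_error", "n_folds must be >= 2")
  if (n / n_folds < 3) {
    stop_stmap("stmap_validation_error",
               "folds of fewer than 3 observations are not usable")
  }
  fold_of <- local_seed(derive_seed(seed, "folds"),
                        sample(rep(seq_len(n_folds), length.out = n)))

  d <- ncol(dataset$coords)
  fold_stats <- data.frame(fold = seq_len(n_folds), pairwise_r = NA_real_,
                           pairwise_rmse = NA_real_,
                           mean_pred_corr = NA_real_)
  pred_raw <- matrix(NA_real_, n, d)
  models <- if (keep_models) vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    test_idx <- which(fold_of == f)
    train_ds <- dataset[-test_idx, ]
    test_ds <- dataset[test_idx, ]
    normalizer <- fit_coord_normalizer(train_ds$coords, system)
    fold_config <- config
    fold_config$seed <- derive_seed(seed, paste0("fold", f))
    model <- build_model(spec, seed = fold_config$seed)
    model <- train_model(model, train_ds, normalizer, fold_config)
    pred_unit <- predict(model, test_ds)
    true_unit <- normalize_coords(test_ds$coords, normalizer)
    fold_stats$pairwise_r[f] <- pairwise_pearson_r(true_unit, pred_unit)
    fold_stats$pairwise_rmse[f] <- pairwise_rmse(true_unit, pred_unit)
    fold_stats$mean_pred_corr[f] <- model$mean_pred_corr
    pred_raw[test_idx, ] <- denormalize_coords(pred_unit, normalizer)
    if (keep_models) models[[f]] <- model
    msg_log("crossvalidate", "fold %d/%d: pairwise r %.3f, pairwise RMSE %.3f",
            f, n_folds, fold_stats$pairwise_r[f], fold_stats$pairwise_rmse[f])
  }

  global_norm <- fit_coord_normalizer(dataset$coords, "cartesian")
  true_unit_all <- normalize_coords(dataset$coords, global_norm)
  pred_unit_all <- normalize_coords(pred_raw, global_norm)
  pooled_r <- pairwise_pearson_r(true_unit_all, pred_unit_all)
  pooled_rmse <- pairwise_rmse(true_unit_all, pred_unit_all)

  boot <- NULL
  if (bootstrap > 0L) {
    reps <- local_seed(derive_seed(seed, "bootstrap"), {
      t(vapply(seq_len(bootstrap), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        idx <- idx[!duplicated(idx)]   # duplicated spots give zero distances
        c(r = pairwise_pearson_r(true_unit_all[idx, , drop = FALSE],
                                 pred_unit_all[idx, , drop = FALSE]),
          rmse = pairwise_rmse(true_unit_all[idx, , drop = FALSE],
                               pred_unit_all[idx, , drop = FALSE]))
      }, numeric(2)))
    })
    boot <- data.frame(metric = c("pairwise_r", "pairwise_rmse"),
                       mean = c(mean(reps[, "r"]), mean(reps[, "rmse"])),
                       sd = c(sd(reps[, "r"]), sd(reps[, "rmse"])),
                       replicates = bootstrap)
  }

  predictions <- data.frame(obs_id = dataset$obs_ids, fold = fold_of,
                            dataset$coords, pred_raw)
  colnames(predictions) <- c("obs_id", "fold",
                             paste0("true_", seq_len(d)),
                             paste0("pred_", seq_len(d)))
  structure(list(folds = fold_stats,
                 mean_r = mean(fold_stats$pairwise_r),
                 mean_rmse = mean(fold_stats$pairwise_rmse),
                 pooled_r = pooled_r, pooled_rmse = pooled_rmse,
                 predictions = predictions, bootstrap = boot,
                 models = models, n_folds = n_folds, seed = seed),
            class = "cv_result")
}

#' Pairwise RMSE of a label-permuted mapping
#'
#' Null baseline for [crossvalidate()]: the correspondence between
#' observations and predicted positions is destroyed by permutation and the
#' pairwise RMSE recomputed; the median over `n_perm` permutations is the
#' RMSE a random assignment of the same predicted point cloud would achieve.
#'
#' @param true_coords,pred_coords coordinate matrices (normalized units).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return List with `rmse` (median permuted pairwise RMSE) and `r` (median
#'   permuted pairwise r).
#' @export
permuted_baseline <- function(true_coords, pred_coords, n_perm = 20L,
                              seed = 1L) {
  true_coords <- as.matrix(true_coords)
  pred_coords <- as.matrix(pred_coords)
  local_seed(seed, {
    stats <- t(vapply(seq_len(n_perm), function(p) {
      perm <- sample.int(nrow(pred_coords))
      c(rmse = pairwise_rmse(true_coords, pred_coords[perm, , drop = FALSE]),
        r = pairwise_pearson_r(true_coords, pred_coords[perm, , drop = FALSE]))
    }, numeric(2)))
    list(rmse = stats::median(stats[, "rmse"]), r = stats::median(stats[, "r"]))
  })
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "cv_result: %d folds; mean pairwise r %.3f, mean pairwise RMSE %.3f (pooled: %.3f / %.3f)\n",
    x$n_folds, x$mean_r, x$mean_rmse, x$pooled_r, x$pooled_rmse))
  invisible(x)
}
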