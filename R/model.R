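#' Architecture of the coordinate-regression network
#'
#' A fully connected network mapping a normalized expression profile to
#' unit-interval spatial coordinates: ReLU hidden layers, a sigmoid output
#' layer (so predictions are bounded in (0,1) like the min-max normalized
#' targets), dropout on the input and the first five hidden layers, and an
#' L1 penalty on all weight matrices. Defaults follow the reference
#' configuration: six hidden layers of 4096, 1024, 256, 64, 16 and 4 nodes,
#' dropout 0.05, lambda 1e-8.
#'
#' @param n_genes number of input genes.
#' @param out_dim coordinate dimensionality, 2 or 3.
#' @param hidden_widths integer vector of hidden-layer widths (may be empty
#'   for a degenerate linear-sigmoid model).
#' @param dropout_rate dropout probability in `[0, 1)`.
#' @param l1_lambda non-negative L1 coefficient.
#' @return A `model_spec`.
#' @export
model_spec <- function(n_genes, out_dim = 2L,
                       hidden_widths = c(4096L, 1024L, 256L, 64L, 16L, 4L),
                       dropout_rate = 0.05, l1_lambda = 1e-8) {
  n_genes <- as.integer(n_genes)
  out_dim <- as.integer(out_dim)
  hidden_widths <- as.integer(hidden_widths)
  if (n_genes < 1L) stop_stmap("stmap_validation_error", "n_genes must be >= 1")
  if (!out_dim %in% c(2L, 3L)) {
    stop_stmap("stmap_validation_error", "out_dim must be 2 or 3")
  }
  if (length(hidden_widths) && any(hidden_widths < 1L)) {
    stop_stmap("stmap_validation_error", "hidden widths must be positive")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop_stmap("stmap_validation_error", "dropout_rate must be in [0, 1)")
  }
  if (l1_lambda < 0) {
    stop_stmap("stmap_validation_error", "l1_lambda must be non-negative")
  }
  structure(list(n_genes = n_genes, out_dim = out_dim,
                 hidden_widths = hidden_widths, dropout_rate = dropout_rate,
                 l1_lambda = l1_lambda),
            class = "model_spec")
}

#' Training configuration
#'
#' Adam at learning rate 0.001 (moments 0.9/0.999, epsilon 1e-7), learning
#' rate halved after `lr_patience` epochs without validation improvement
#' down to `min_lr`, early stopping after `early_stopping_patience` epochs
#' without improvement, at most `max_epochs` epochs. The batch size default
#' of 4096 suits datasets of 10^4+ observations; for Visium-scale data
#' (10^2-10^3 spots) 16-128 is the appropriate range.
#'
#' @param learning_rate initial Adam step size.
#' @param batch_size mini-batch size (clamped to the training-set size with
#'   a warning when larger).
#' @param max_epochs epoch cap.
#' @param lr_factor,lr_patience,min_lr reduce-on-plateau schedule.
#' @param early_stopping_patience epochs without improvement before stopping.
#' @param validation_fraction fraction of observations held out to monitor
#'   validation loss.
#' @param restarts maximum number of re-initializations (with seeds derived
#'   deterministically from `seed`) when a run never escapes the
#'   mean-predictor plateau; see [train_model()].
#' @param seed integer seed controlling initialization, the validation split
#'   and batch shuffling.
#' @return A `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 4096L,
                         max_epochs = 500L, lr_factor = 0.5,
                         lr_patience = 20L, min_lr = 1e-5,
                         early_stopping_patience = 50L,
                         validation_fraction = 0.1, restarts = 2L,
                         seed = 1L) {
  if (min_lr > learning_rate) {
    stop_stmap("stmap_validation_error", "min_lr must be <= learning_rate")
  }
  if (lr_patience < 1L || early_stopping_patience < 1L) {
    stop_stmap("stmap_validation_error", "patience values must be >= 1")
  }
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    stop_stmap("stmap_validation_error",
               "validation_fraction must be in (0, 1)")
  }
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), lr_factor = lr_factor,
                 lr_patience = as.integer(lr_patience), min_lr = min_lr,
                 early_stopping_patience = as.integer(early_stopping_patience),
                 validation_fraction = validation_fraction,
                 restarts = as.integer(restarts),
                 seed = as.integer(seed)),
            class = "train_config")
}

layer_dims <- function(spec) {
  c(spec$n_genes, spec$hidden_widths, spec$out_dim)
}

#' Initialize an untrained model
#'
#' Weights drawn from the Glorot (Xavier) normal distribution,
#' `sd = sqrt(2 / (fan_in + fan_out))`; biases zero. The same seed gives
#' bit-identical weights.
#'
#' @param spec a [model_spec()].
#' @param seed integer seed.
#' @param gene_ids optional gene ids recorded for prediction-time checks.
#' @return A `trained_model` with empty history.
#' @export
build_model <- function(spec, seed = 1L, gene_ids = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  dims <- layer_dims(spec)
  local_seed(seed, {
    weights <- lapply(seq_len(length(dims) - 1L), function(i) {
      fan_in <- dims[i]
      fan_out <- dims[i + 1L]
      matrix(rnorm(fan_in * fan_out, sd = sqrt(2 / (fan_in + fan_out))),
             nrow = fan_in, ncol = fan_out)
    })
    biases <- lapply(dims[-1], numeric)
    structure(list(spec = spec, weights = weights, biases = biases,
                   gene_ids = gene_ids, normalizer = NULL,
                   history = NULL, mean_pred_corr = NA_real_),
              class = "trained_model")
  })
}

relu <- function(z) pmax(z, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

# layers whose *outputs* (input features count as layer 0) receive dropout:
# the input and the first five hidden layers
dropout_layers <- function(spec) {
  seq_len(min(5L, length(spec$hidden_widths)) + 1L) - 1L
}

nn_forward <- function(model, X, dropout_masks = NULL) {
  L <- length(model$weights)
  acts <- vector("list", L + 1L)
  pre <- vector("list", L)
  a <- X
  if (!is.null(dropout_masks) && !is.null(dropout_masks[[1]])) {
    a <- a * dropout_masks[[1]]
  }
  acts[[1]] <- a
  for (i in seq_len(L)) {
    z <- a %*% model$weights[[i]]
    z <- sweep(z, 2, model$biases[[i]], "+")
    pre[[i]] <- z
    a <- if (i < L) relu(z) else sigmoid(z)
    if (i < L && !is.null(dropout_masks) && !is.null(dropout_masks[[i + 1L]])) {
      a <- a * dropout_masks[[i + 1L]]
    }
    acts[[i + 1L]] <- a
  }
  list(pred = a, acts = acts, pre = pre)
}

make_dropout_masks <- function(spec, n_rows) {
  if (spec$dropout_rate <= 0) return(NULL)
  dims <- layer_dims(spec)
  masks <- vector("list", length(dims) - 1L)
  keep <- 1 - spec$dropout_rate
  for (l in dropout_layers(spec)) {
    width <- dims[l + 1L]
    masks[[l + 1L]] <-
      matrix((runif(n_rows * width) < keep) / keep, nrow = n_rows)
  }
  masks
}

#' Root-mean-square coordinate error
#'
#' `sqrt(sum_t ||y_t - yhat_t||^2 / N)` where the squared difference sums
#' over coordinate components and `N` is the number of observations; the
#' training loss of the network (before the L1 penalty).
#'
#' @param y,y_hat coordinate matrices of equal shape.
#' @return Non-negative scalar.
#' @export
rmse <- function(y, y_hat) {
  y <- as.matrix(y)
  y_hat <- as.matrix(y_hat)
  if (!all(dim(y) == dim(y_hat))) {
    stop_stmap("stmap_validation_error", "rmse: shape mismatch (%s vs %s)",
               paste(dim(y), collapse = "x"),
               paste(dim(y_hat), collapse = "x"))
  }
  sqrt(sum((y - y_hat)^2) / nrow(y))
}

#' Penalized training loss
#'
#' [rmse()] plus `lambda` times the sum of absolute values of all weight
#' matrix entries (biases excluded).
#'
#' @inheritParams rmse
#' @param weights list of weight matrices.
#' @param l1_lambda non-negative penalty coefficient.
#' @return Non-negative scalar.
#' @export
total_loss <- function(y, y_hat, weights, l1_lambda) {
  if (l1_lambda < 0) {
    stop_stmap("stmap_validation_error", "l1_lambda must be non-negative")
  }
  rmse(y, y_hat) + l1_lambda * sum(vapply(weights,
                                          function(w) sum(abs(w)), numeric(1)))
}

# Analytic gradient of the penalized loss for one (mini-)batch.
# Returns list(loss, gW = list, gb = list). Dropout masks, when supplied,
# must be the masks used in the corresponding forward pass.
nn_loss_grad <- function(model, X, Y, dropout_masks = NULL) {
  L <- length(model$weights)
  fw <- nn_forward(model, X, dropout_masks)
  pred <- fw$pred
  N <- nrow(X)
  lambda <- model$spec$l1_lambda
  rm_val <- sqrt(sum((Y - pred)^2) / N)
  loss <- rm_val + lambda * sum(vapply(model$weights, function(w) sum(abs(w)),
                                       numeric(1)))
  gW <- vector("list", L)
  gb <- vector("list", L)
  # d(rmse)/d(pred); zero residual has zero gradient
  G <- if (rm_val > 0) (pred - Y) / (N * rm_val) else matrix(0, N, ncol(Y))
  delta <- G * pred * (1 - pred)          # sigmoid output layer
  for (i in rev(seq_len(L))) {
    gW[[i]] <- crossprod(fw$acts[[i]], delta) + lambda * sign(model$weights[[i]])
    gb[[i]] <- colSums(delta)
    if (i > 1L) {
      back <- delta %*% t(model$weights[[i]])
      if (!is.null(dropout_masks) && !is.null(dropout_masks[[i]])) {
        back <- back * dropout_masks[[i]]
      }
      delta <- back * (fw$pre[[i - 1L]] > 0)
    }
  }
  list(loss = loss, rmse = rm_val, gW = gW, gb = gb)
}

#' Train the coordinate-regression network
#'
#' Minimizes the penalized RMSE by mini-batch Adam on a seeded 90/10
#' train/validation split. The learning rate is halved after `lr_patience`
#' epochs without validation-loss improvement (down to `min_lr`); training
#' stops early after `early_stopping_patience` epochs without improvement,
#' restoring the best-validation weights. Dropout is active during training
#' only.
#'
#' @param model an untrained model from [build_model()] (or a trained one to
#'   continue training).
#' @param reference a `spatial_dataset` with coordinates; expression must
#'   already be normalized and gene-selected.
#' @param normalizer a [fit_coord_normalizer()] fit, stored with the model
#'   and used to produce the unit-interval targets.
#' @param config a [train_config()].
#' @return A `trained_model` with `history` (per-epoch training and
#'   validation loss, learning rate) and `mean_pred_corr`, the mean over
#'   coordinate axes of the Pearson correlation between predicted and
#'   reference normalized coordinates on the validation split.
#'
#' @details Deep rectifier networks with narrow bottleneck layers
#' occasionally start on a plateau where they only predict the mean
#' coordinate and the plateau outlasts the early-stopping patience. When a
#' run's best validation loss fails to at least halve its starting value,
#' or any output axis shows (near-)zero validation correlation (a single
#' collapsed axis), training is re-initialized with a seed derived
#' deterministically from `config$seed`, up to `config$restarts` extra
#' attempts; the attempt with the lowest validation loss is returned. The
#' whole procedure is reproducible for a fixed seed.
#' @export
train_model <- function(model, reference, normalizer, config = train_config()) {
  stopifnot(inherits(model, "trained_model"), inherits(config, "train_config"))
  fit <- train_attempt(model, reference, normalizer, config, config$seed)
  attempt <- 0L
  best <- fit
  while (!fit$escaped && attempt < config$restarts) {
    attempt <- attempt + 1L
    seed_k <- derive_seed(config$seed, paste0("restart", attempt))
    msg_log("train", "validation loss plateaued; restart %d (seed %d)",
            attempt, seed_k)
    retry_model <- build_model(model$spec, seed = seed_k)
    fit <- train_attempt(retry_model, reference, normalizer, config, seed_k)
    if (fit$best_val < best$best_val) best <- fit
  }
  best$model
}

train_attempt <- function(model, reference, normalizer, config, seed) {
  if (is.null(reference$coords)) {
    stop_stmap("stmap_validation_error", "reference has no coordinates")
  }
  X_all <- unname(as.matrix(reference$expr))
  if (ncol(X_all) != model$spec$n_genes) {
    stop_stmap("stmap_validation_error",
               "reference has %d genes but the model expects %d",
               ncol(X_all), model$spec$n_genes)
  }
  Y_all <- unname(normalize_coords(reference$coords, normalizer))
  model$gene_ids <- reference$gene_ids
  model$normalizer <- normalizer

  local_seed(seed, {
    n <- nrow(X_all)
    n_val <- max(1L, round(config$validation_fraction * n))
    val_idx <- sample.int(n, n_val)
    X_tr <- X_all[-val_idx, , drop = FALSE]
    Y_tr <- Y_all[-val_idx, , drop = FALSE]
    X_va <- X_all[val_idx, , drop = FALSE]
    Y_va <- Y_all[val_idx, , drop = FALSE]

    batch_size <- config$batch_size
    if (batch_size > nrow(X_tr)) {
      warning(sprintf("batch size %d exceeds %d training observations; clamped",
                      batch_size, nrow(X_tr)))
      batch_size <- nrow(X_tr)
    }

    L <- length(model$weights)
    mW <- lapply(model$weights, function(w) w * 0)
    vW <- mW
    mb <- lapply(model$biases, function(b) b * 0)
    vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-7
    t_step <- 0L
    lr <- config$learning_rate

    best_val <- Inf
    best_weights <- model$weights
    best_biases <- model$biases
    lr_wait <- 0L
    stop_wait <- 0L
    hist <- list(loss = numeric(0), val_loss = numeric(0), lr = numeric(0))

    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(nrow(X_tr))
      starts <- seq(1L, nrow(X_tr), by = batch_size)
      epoch_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + batch_size - 1L, nrow(X_tr))]
        Xb <- X_tr[idx, , drop = FALSE]
        Yb <- Y_tr[idx, , drop = FALSE]
        masks <- make_dropout_masks(model$spec, nrow(Xb))
        g <- nn_loss_grad(model, Xb, Yb, masks)
        if (!is.finite(g$loss)) {
          stop_stmap("stmap_numeric_error",
                     "NaN/Inf loss at epoch %d; reduce the learning rate",
                     epoch)
        }
        epoch_loss <- epoch_loss + g$loss * length(idx)
        t_step <- t_step + 1L
        corr1 <- 1 - beta1^t_step
        corr2 <- 1 - beta2^t_step
        for (i in seq_len(L)) {
          mW[[i]] <- beta1 * mW[[i]] + (1 - beta1) * g$gW[[i]]
          vW[[i]] <- beta2 * vW[[i]] + (1 - beta2) * g$gW[[i]]^2
          model$weights[[i]] <- model$weights[[i]] -
            lr * (mW[[i]] / corr1) / (sqrt(vW[[i]] / corr2) + eps)
          mb[[i]] <- beta1 * mb[[i]] + (1 - beta1) * g$gb[[i]]
          vb[[i]] <- beta2 * vb[[i]] + (1 - beta2) * g$gb[[i]]^2
          model$biases[[i]] <- model$biases[[i]] -
            lr * (mb[[i]] / corr1) / (sqrt(vb[[i]] / corr2) + eps)
        }
      }
      val_pred <- nn_forward(model, X_va)$pred
      val_loss <- total_loss(Y_va, val_pred, model$weights,
                             model$spec$l1_lambda)
      hist$loss <- c(hist$loss, epoch_loss / nrow(X_tr))
      hist$val_loss <- c(hist$val_loss, val_loss)
      hist$lr <- c(hist$lr, lr)

      if (val_loss < best_val) {
        best_val <- val_loss
        best_weights <- model$weights
        best_biases <- model$biases
        lr_wait <- 0L
        stop_wait <- 0L
      } else {
        lr_wait <- lr_wait + 1L
        stop_wait <- stop_wait + 1L
        if (lr_wait >= config$lr_patience && lr > config$min_lr) {
          lr <- max(lr * config$lr_factor, config$min_lr)
          lr_wait <- 0L
        }
        if (stop_wait >= config$early_stopping_patience) break
      }
    }

    model$weights <- best_weights
    model$biases <- best_biases
    model$history <- data.frame(epoch = seq_along(hist$loss),
                                loss = hist$loss, val_loss = hist$val_loss,
                                lr = hist$lr)
    val_pred <- nn_forward(model, X_va)$pred
    axis_corr <- vapply(seq_len(ncol(Y_va)), function(d) {
      if (sd(val_pred[, d]) == 0 || sd(Y_va[, d]) == 0) return(0)
      cor(val_pred[, d], Y_va[, d])
    }, numeric(1))
    model$mean_pred_corr <- mean(axis_corr)
    # degenerate fit: the validation loss never left the mean-predictor
    # plateau, or an output axis carries no signal at all
    list(model = model, best_val = best_val,
         escaped = best_val < 0.5 * hist$val_loss[1] && min(axis_corr) > 0.1)
  })
}

#' Predict spatial coordinates from expression
#'
#' Deterministic forward pass (dropout off) returning sigmoid-bounded
#' coordinates in `(0,1)^d`; use [denormalize_coords()] with the model's
#' stored normalizer to recover raw units. With `mc_dropout = TRUE` the mean
#' of `mc_samples` stochastic forward passes with dropout active is returned
#' instead (Monte-Carlo dropout).
#'
#' @param object a `trained_model`.
#' @param expr expression matrix or `spatial_dataset`; columns must match
#'   the model's training gene list in order (no silent reindexing).
#' @param mc_dropout average stochastic dropout passes instead of one
#'   deterministic pass.
#' @param mc_samples number of stochastic passes.
#' @param seed seed for the stochastic passes.
#' @param ... ignored.
#' @return Matrix of normalized coordinates, one row per observation.
#' @export
predict.trained_model <- function(object, expr, mc_dropout = FALSE,
                                  mc_samples = 30L, seed = 1L, ...) {
  if (inherits(expr, "spatial_dataset")) {
    gene_ids <- expr$gene_ids
    expr <- as.matrix(expr$expr)
  } else {
    expr <- as.matrix(expr)
    gene_ids <- colnames(expr)
  }
  if (ncol(expr) != object$spec$n_genes) {
    stop_stmap("stmap_validation_error",
               "input has %d genes but the model expects %d", ncol(expr),
               object$spec$n_genes)
  }
  if (!is.null(object$gene_ids) && !is.null(gene_ids) &&
      !identical(as.character(gene_ids), as.character(object$gene_ids))) {
    stop_stmap("stmap_validation_error",
               "gene ids/order differ from the model's training gene list")
  }
  if (!mc_dropout) {
    return(nn_forward(object, expr)$pred)
  }
  local_seed(seed, {
    acc <- 0
    for (s in seq_len(mc_samples)) {
      masks <- make_dropout_masks(object$spec, nrow(expr))
      acc <- acc + nn_forward(object, expr, masks)$pred
    }
    acc / mc_samples
  })
}

#' @export
print.trained_model <- function(x, ...) {
  dims <- layer_dims(x$spec)
  cat(sprintf("trained_model: %s%s\n",
              paste(dims, collapse = " -> "),
              if (is.null(x$history)) " (untrained)" else
                sprintf(", %d epochs, val corr %.3f", nrow(x$history),
                        x$mean_pred_corr)))
  invisible(x)
}
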