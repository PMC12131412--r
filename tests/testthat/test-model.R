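test_that("build_model produces the right shape chain, deterministically", {
  spec <- model_spec(n_genes = 3, hidden_widths = 4L)
  m <- build_model(spec, seed = 7)
  expect_length(m$weights, 2)
  expect_equal(dim(m$weights[[1]]), c(3, 4))
  expect_equal(dim(m$weights[[2]]), c(4, 2))
  expect_true(all(vapply(m$biases, function(b) all(b == 0), logical(1))))
  m2 <- build_model(spec, seed = 7)
  expect_identical(m$weights, m2$weights)
  expect_false(identical(m$weights, build_model(spec, seed = 8)$weights))
  # degenerate linear-sigmoid model
  m0 <- build_model(model_spec(n_genes = 5, hidden_widths = integer(0)))
  expect_length(m0$weights, 1)
  expect_equal(dim(m0$weights[[1]]), c(5, 2))
  expect_error(model_spec(n_genes = 3, hidden_widths = c(4, 0)),
               class = "stmap_validation_error")
})

test_that("rmse matches hand computations and is homogeneous", {
  y <- rbind(c(0, 0))
  expect_equal(rmse(y, rbind(c(3, 4))), 5)
  expect_equal(rmse(y, y), 0)
  set.seed(1)
  a <- matrix(rnorm(20), 10)
  b <- matrix(rnorm(20), 10)
  expect_equal(rmse(a, a + 3 * (b - a)), 3 * rmse(a, b))
  expect_error(rmse(a, b[1:5, ]), class = "stmap_validation_error")
})

test_that("total_loss adds a linear L1 penalty over weights only", {
  y <- matrix(c(0.2, 0.8), 1)
  w <- list(matrix(c(2, -3), 2, 1))
  expect_identical(total_loss(y, y, w, 0), rmse(y, y))
  expect_equal(total_loss(y, y, w, 0.1), 0.5)
  set.seed(2)
  yh <- y + 0.1
  expect_equal(total_loss(y, yh, w, 0.2) - rmse(y, yh),
               2 * (total_loss(y, yh, w, 0.1) - rmse(y, yh)))
  expect_error(total_loss(y, y, w, -1), class = "stmap_validation_error")
})

test_that("analytic gradients match central finite differences", {
  spec <- model_spec(n_genes = 3, hidden_widths = c(4, 2), dropout_rate = 0,
                     l1_lambda = 1e-3)
  m <- build_model(spec, seed = 2)
  set.seed(4)
  X <- matrix(rnorm(18), 6, 3)
  Y <- matrix(runif(12), 6, 2)
  g <- stmap:::nn_loss_grad(m, X, Y)
  eps <- 1e-6
  for (i in seq_along(m$weights)) {
    num <- m$weights[[i]] * 0
    for (j in seq_along(num)) {
      up <- m; up$weights[[i]][j] <- up$weights[[i]][j] + eps
      dn <- m; dn$weights[[i]][j] <- dn$weights[[i]][j] - eps
      num[j] <- (stmap:::nn_loss_grad(up, X, Y)$loss -
                   stmap:::nn_loss_grad(dn, X, Y)$loss) / (2 * eps)
    }
    expect_lt(max(abs(num - g$gW[[i]]) / pmax(abs(num), 1e-6)), 1e-4)
  }
})

test_that("training learns a coordinate encoded in the expression", {
  # x-coordinate equals the rescaled expression of one gene; the rest is noise
  set.seed(21)
  n <- 400
  coords <- cbind(x = runif(n, 0, 100), y = runif(n, 0, 100))
  expr <- cbind(coords[, 1] / 100, coords[, 2] / 100,
                matrix(runif(n * 50), n))
  ds <- spatial_dataset(expr, gene_ids = paste0("g", 1:52), coords = coords)
  nz <- fit_coord_normalizer(coords)
  spec <- model_spec(n_genes = 52, hidden_widths = c(128, 32),
                     dropout_rate = 0.05)
  config <- train_config(batch_size = 64, max_epochs = 60, seed = 9)
  m0 <- build_model(spec, seed = 9)
  trained <- suppressWarnings(train_model(m0, ds, nz, config))
  unit <- normalize_coords(coords, nz)
  expect_lt(rmse(unit, predict(trained, ds)),
            rmse(unit, predict(m0, as.matrix(expr))))
  expect_gt(trained$mean_pred_corr, 0.5)
  expect_gt(nrow(trained$history), 1)
})

test_that("seeded training is reproducible and lambda shrinks weights", {
  fix <- small_reference(n_spots = 200, n_genes = 30, seed = 6)
  ds <- fix$norm
  nz <- fit_coord_normalizer(ds$coords)
  spec <- model_spec(n_genes = 30, hidden_widths = c(32, 8))
  config <- train_config(batch_size = 64, max_epochs = 15, seed = 3)
  run <- function(sp) train_model(build_model(sp, seed = 3), ds, nz, config)
  expect_identical(run(spec)$history, run(spec)$history)
  l1 <- function(m) sum(vapply(m$weights, function(w) sum(abs(w)), numeric(1)))
  big <- model_spec(n_genes = 30, hidden_widths = c(32, 8), l1_lambda = 1e3)
  none <- model_spec(n_genes = 30, hidden_widths = c(32, 8), l1_lambda = 0)
  expect_lt(l1(run(big)), l1(run(none)))
})

test_that("prediction is bounded, pointwise and strict about gene order", {
  spec <- model_spec(n_genes = 4, hidden_widths = c(8, 4))
  m <- build_model(spec, seed = 1)
  X <- matrix(runif(20, 0, 5), 5, 4)
  p <- predict(m, X)
  expect_true(all(p > 0 & p < 1))
  expect_equal(predict(m, X[c(1, 1), ])[1, ], predict(m, X[c(1, 1), ])[2, ])
  # all-zero expression propagates the biases only
  expect_equal(unname(predict(m, matrix(0, 1, 4))[1, ]), c(0.5, 0.5))
  m$gene_ids <- paste0("g", 1:4)
  colnames(X) <- paste0("g", c(2, 1, 3, 4))
  expect_error(predict(m, X), class = "stmap_validation_error")
  expect_error(predict(m, X[, 1:3]), class = "stmap_validation_error")
})

test_that("monte-carlo dropout prediction is seeded and near the deterministic pass", {
  spec <- model_spec(n_genes = 6, hidden_widths = c(16, 8),
                     dropout_rate = 0.05)
  m <- build_model(spec, seed = 2)
  X <- matrix(runif(60, 0, 3), 10, 6)
  a <- predict(m, X, mc_dropout = TRUE, mc_samples = 50, seed = 5)
  b <- predict(m, X, mc_dropout = TRUE, mc_samples = 50, seed = 5)
  expect_identical(a, b)
  expect_lt(max(abs(a - predict(m, X))), 0.2)
})

test_that("model serialization round-trips weights, gene list and normalizer", {
  fix <- small_reference(n_spots = 150, n_genes = 20, seed = 12)
  ds <- fix$norm
  nz <- fit_coord_normalizer(ds$coords)
  spec <- model_spec(n_genes = 20, hidden_widths = c(16, 4))
  m <- train_model(build_model(spec, seed = 2), ds, nz,
                   train_config(batch_size = 64, max_epochs = 5, seed = 2))
  path <- withr::local_tempfile(fileext = ".h5")
  write_model(m, path)
  back <- read_model(path)
  expect_equal(back$weights, m$weights)
  expect_identical(back$gene_ids, m$gene_ids)
  expect_equal(back$normalizer$min, unname(m$normalizer$min))
  expect_equal(predict(back, ds), predict(m, ds))
  expect_equal(back$mean_pred_corr, m$mean_pred_corr)
})
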