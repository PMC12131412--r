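test_that("inverse-distance weights follow 100/d below the threshold", {
  sw <- build_spatial_weights(rbind(c(0, 0), c(4, 0)), "inverse_distance",
                              threshold = 10)
  expect_equal(as.matrix(sw$w), matrix(c(0, 25, 25, 0), 2))
  expect_equal(sw$W, 50)
  expect_true(all(Matrix::diag(sw$w) == 0))
  # beyond the threshold every weight is zero -> degenerate
  expect_error(build_spatial_weights(rbind(c(0, 0), c(11, 0)),
                                     "inverse_distance", threshold = 10),
               class = "stmap_degenerate_geometry_error")
  expect_error(build_spatial_weights(rbind(c(1, 1), c(1, 1)),
                                     "inverse_distance", threshold = 10),
               class = "stmap_validation_error")
})

test_that("knn weights are the symmetric union of neighbour relations", {
  pts <- rbind(c(0, 0), c(1, 0), c(2, 0))
  sw <- build_spatial_weights(pts, "knn", k = 1)
  w <- as.matrix(sw$w)
  expect_equal(w[1, 2], 1)  # middle point is everyone's nearest neighbour
  expect_equal(w[3, 2], 1)
  expect_equal(w[2, 1], 1)  # symmetrized even though 1 is not 2's nearest
  expect_equal(w[1, 3], 0)
  expect_error(build_spatial_weights(pts, "knn", k = 3),
               class = "stmap_validation_error")
})

test_that("morans_i matches hand computation and is location/scale invariant", {
  sw <- build_spatial_weights(rbind(c(0, 0), c(4, 0)), "inverse_distance",
                              threshold = 10)
  expect_equal(morans_i(c(-1, 1), sw), -1)
  set.seed(6)
  pts <- matrix(runif(40, 0, 10), 20)
  sw2 <- build_spatial_weights(pts, "knn", k = 4)
  x <- rnorm(20)
  expect_equal(morans_i(x, sw2), morans_i(x + 7, sw2))
  expect_equal(morans_i(x, sw2), morans_i(3.2 * x, sw2))
  expect_error(morans_i(rep(1, 20), sw2),
               class = "stmap_degenerate_statistic_error")
})

test_that("morans_i matches a dense double-loop oracle to 1e-12", {
  set.seed(26)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    pts <- matrix(runif(2 * n, 0, 10), n)
    sw <- build_spatial_weights(pts, "inverse_distance", threshold = 8)
    x <- rnorm(n)
    expect_lt(abs(morans_i(x, sw) - oracle_morans_i(x, as.matrix(sw$w))),
              1e-12)
  }
})

test_that("bivariate moran reduces to moran and is affine invariant", {
  set.seed(7)
  pts <- matrix(runif(60, 0, 10), 30)
  sw <- build_spatial_weights(pts, "knn", k = 5)
  x <- rnorm(30)
  y <- rnorm(30)
  expect_equal(bivariate_morans_i(x, x, sw), morans_i(x, sw),
               tolerance = 1e-12)
  expect_equal(bivariate_morans_i(x, 2 * x + 5, sw), morans_i(x, sw),
               tolerance = 1e-12)
  expect_equal(bivariate_morans_i(x, y, sw), bivariate_morans_i(y, x, sw),
               tolerance = 1e-12)
  sw2 <- build_spatial_weights(rbind(c(0, 0), c(4, 0)), "inverse_distance",
                               threshold = 10)
  expect_equal(bivariate_morans_i(c(-1, 1), c(1, -1), sw2), 1)
})

test_that("pairwise distances use the canonical ordering", {
  expect_length(pairwise_distances(rbind(c(0, 0), c(1, 1))), 1)
  expect_length(pairwise_distances(matrix(runif(8), 4)), 6)
  sq <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  expect_equal(sort(pairwise_distances(sq)),
               sort(c(1, 1, 1, 1, sqrt(2), sqrt(2))))
})

test_that("pairwise metrics are exact under rigid motions", {
  set.seed(9)
  pts <- matrix(runif(50, 0, 1), 25)
  expect_equal(pairwise_pearson_r(pts, pts), 1)
  expect_equal(pairwise_rmse(pts, pts), 0)
  for (angle in c(0.3, pi / 2, 2.1)) {
    moved <- rigid_transform(pts, angle, shift = c(5, -3))
    expect_equal(pairwise_pearson_r(pts, moved), 1)
    expect_equal(pairwise_rmse(pts, moved), 0, tolerance = 1e-12)
  }
  refl <- pts %*% diag(c(-1, 1))
  expect_equal(pairwise_pearson_r(pts, refl), 1)
  expect_equal(pairwise_rmse(pts, refl), 0, tolerance = 1e-12)
})

test_that("collapsed predictions give the analytic RMSE and no correlation", {
  set.seed(10)
  pts <- matrix(runif(30, 0, 1), 15)
  collapsed <- matrix(0.5, 15, 2)
  expect_equal(pairwise_rmse(pts, collapsed),
               sqrt(mean(pairwise_distances(pts)^2)))
  expect_error(pairwise_pearson_r(pts, collapsed),
               class = "stmap_degenerate_statistic_error")
})

test_that("rank AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  score <- c(rnorm(30, 1), rnorm(40))
  label <- rep(c(TRUE, FALSE), c(30, 40))
  expect_equal(score_auroc(score, label),
               as.numeric(pROC::auc(pROC::roc(label, score, quiet = TRUE))))
})

test_that("cross-validation partitions are disjoint, exhaustive and seeded", {
  fix <- small_reference(n_spots = 150, n_genes = 25, seed = 8)
  ds <- fix$norm
  spec <- model_spec(n_genes = 25, hidden_widths = c(16, 4))
  config <- train_config(batch_size = 64, max_epochs = 3, seed = 5)
  cv1 <- suppressMessages(crossvalidate(ds, spec, config, n_folds = 5,
                                        seed = 5))
  expect_setequal(cv1$predictions$fold, 1:5)
  expect_identical(sort(cv1$predictions$obs_id), sort(ds$obs_ids))
  expect_identical(nrow(cv1$predictions), nrow(ds$expr))
  expect_false(any(is.na(cv1$predictions$pred_1)))
  cv2 <- suppressMessages(crossvalidate(ds, spec, config, n_folds = 5,
                                        seed = 5))
  expect_identical(cv1$predictions$fold, cv2$predictions$fold)
  expect_equal(cv1$folds, cv2$folds)
  expect_error(crossvalidate(ds[1:10, ], spec, config, n_folds = 5, seed = 1),
               class = "stmap_validation_error")
})

test_that("cross-validated mapping beats a label-permuted baseline", {
  fix <- small_reference(n_spots = 300, n_genes = 40, seed = 30)
  ds <- fix$norm
  spec <- model_spec(n_genes = 40, hidden_widths = c(256, 64, 16, 4))
  config <- train_config(batch_size = 64, max_epochs = 50, seed = 30)
  cv <- suppressMessages(crossvalidate(ds, spec, config, n_folds = 5,
                                       seed = 30, bootstrap = 50))
  gn <- fit_coord_normalizer(ds$coords)
  tu <- normalize_coords(ds$coords, gn)
  pu <- normalize_coords(as.matrix(cv$predictions[, c("pred_1", "pred_2")]),
                         gn)
  base <- permuted_baseline(tu, pu, seed = 30)
  expect_gt(cv$mean_r, base$r)
  expect_lt(cv$pooled_rmse, base$rmse)
  # bootstrap means track the point estimates
  expect_lt(abs(cv$bootstrap$mean[1] - cv$pooled_r), 0.1)
  expect_lt(abs(cv$bootstrap$mean[2] - cv$pooled_rmse), 0.1)
})
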