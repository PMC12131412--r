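#' Build a spatial weights matrix
#'
#' Two neighborhood schemes used by the autocorrelation statistics:
#' \describe{
#'   \item{`inverse_distance`}{`w_ij = 100 / d_ij` for pairs closer than
#'     `threshold`, 0 otherwise (100 is a scale factor); used for the
#'     bivariate consistency score.}
#'   \item{`knn`}{binary symmetric k-nearest-neighbour weights (union of the
#'     neighbour relations), the common default for per-gene Moran's I;
#'     `k = 6` by default.}
#' }
#'
#' @param coords numeric matrix of positions (>= 2 observations).
#' @param mode `"inverse_distance"` or `"knn"`.
#' @param threshold distance cutoff for inverse-distance mode.
#' @param k neighbour count for knn mode.
#' @return A `spatial_weights` object: sparse symmetric matrix `w` with zero
#'   diagonal, total `W`, plus the mode parameters.
#' @export
build_spatial_weights <- function(coords, mode = c("inverse_distance", "knn"),
                                  threshold = NULL, k = 6L) {
  mode <- match.arg(mode)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2L) stop_stmap("stmap_validation_error", "need >= 2 observations")
  D <- as.matrix(dist(coords))
  if (mode == "inverse_distance") {
    if (is.null(threshold)) {
      # default: double the 95th percentile of nearest-neighbour distances
      nn <- apply(D + diag(Inf, n), 1, min)
      threshold <- 2 * as.numeric(quantile(nn, 0.95))
      msg_log("spatial_weights",
              "no threshold given; using 2 x 95th pct NN distance = %g",
              threshold)
    }
    dup <- which(D == 0 & upper.tri(D), arr.ind = TRUE)
    if (nrow(dup) > 0) {
      stop_stmap("stmap_validation_error",
                 "duplicate coordinates (observations %d and %d) give zero distance",
                 dup[1, 1], dup[1, 2])
    }
    w <- matrix(0, n, n)
    sel <- D < threshold & upper.tri(D)
    w[sel] <- 100 / D[sel]
    w <- w + t(w)
  } else {
    k <- as.integer(k)
    if (k < 1L || k >= n) {
      stop_stmap("stmap_validation_error", "k must be in [1, n-1]")
    }
    w <- matrix(0, n, n)
    diag(D) <- Inf
    for (i in seq_len(n)) {
      w[i, order(D[i, ])[seq_len(k)]] <- 1
    }
    w <- pmax(w, t(w))   # union of neighbour relations
  }
  W <- sum(w)
  if (W <= 0) {
    stop_stmap("stmap_degenerate_geometry_error",
               "all spatial weights are zero (threshold too small?)")
  }
  structure(list(w = methods::as(w, "CsparseMatrix"), W = W, mode = mode,
                 threshold = if (mode == "inverse_distance") threshold,
                 k = if (mode == "knn") k, n = n),
            class = "spatial_weights")
}

check_sw_vector <- function(x, sw, name) {
  if (length(x) != sw$n) {
    stop_stmap("stmap_validation_error",
               "%s has length %d but weights cover %d observations", name,
               length(x), sw$n)
  }
  if (var(x) == 0 || anyNA(x)) {
    stop_stmap("stmap_degenerate_statistic_error",
               "%s is constant or has missing values; the statistic is undefined",
               name)
  }
}

#' Moran's I spatial autocorrelation
#'
#' `I = (N/W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`.
#' Positive values mean neighbouring observations have similar expression -
#' the signature of a spatially variable gene.
#'
#' @param x numeric vector (one gene across observations); must not be
#'   constant.
#' @param sw a [build_spatial_weights()] object over the same observations.
#' @return Scalar Moran's I.
#' @export
morans_i <- function(x, sw) {
  stopifnot(inherits(sw, "spatial_weights"))
  check_sw_vector(x, sw, "x")
  xc <- x - mean(x)
  num <- as.numeric(t(xc) %*% (sw$w %*% xc))
  (sw$n / sw$W) * num / sum(xc^2)
}

#' Bivariate Moran's I between two expression vectors
#'
#' Cross-variable spatial autocorrelation between a gene's expression in the
#' reference (`x`) and in a reconstruction (`y`) on the same spatial
#' support:
#' `I = (N/W) * sum_ij w_ij (x_i - xbar)(y_j - ybar) /
#'  (sqrt(sum (x_i - xbar)^2) sqrt(sum (y_i - ybar)^2))`.
#' Reduces exactly to [morans_i()] when `y = x`; invariant to positive
#' affine rescaling of either argument.
#'
#' @param x,y numeric vectors of equal length, neither constant.
#' @inheritParams morans_i
#' @return Scalar bivariate Moran's I.
#' @export
bivariate_morans_i <- function(x, y, sw) {
  stopifnot(inherits(sw, "spatial_weights"))
  check_sw_vector(x, sw, "x")
  check_sw_vector(y, sw, "y")
  xc <- x - mean(x)
  yc <- y - mean(y)
  num <- as.numeric(t(xc) %*% (sw$w %*% yc))
  (sw$n / sw$W) * num / (sqrt(sum(xc^2)) * sqrt(sum(yc^2)))
}

#' All pairwise Euclidean distances
#'
#' Canonical pair ordering (i < j, as produced by [stats::dist()]), shared
#' by both arguments of the pairwise benchmarking metrics.
#'
#' @param coords numeric coordinate matrix, >= 2 rows.
#' @return Numeric vector of `n(n-1)/2` distances.
#' @export
pairwise_distances <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2L) {
    stop_stmap("stmap_validation_error", "need >= 2 points")
  }
  as.vector(dist(coords))
}

#' Pairwise Pearson correlation between true and predicted geometry
#'
#' Pearson correlation between the vectors of all intercellular distances
#' of the true and the predicted coordinates. Because only distances enter,
#' the metric is invariant to rigid motions (rotation, reflection,
#' translation) of either coordinate set; it measures whether the mapping
#' preserves relative geometry.
#'
#' @param true_coords,pred_coords coordinate matrices with matching rows
#'   (>= 3 points), in the benchmarking convention both in min-max
#'   normalized units.
#' @return Scalar in `[-1, 1]`.
#' @export
pairwise_pearson_r <- function(true_coords, pred_coords) {
  dt <- pairwise_distances(true_coords)
  dp <- pairwise_distances(pred_coords)
  if (length(dt) != length(dp)) {
    stop_stmap("stmap_validation_error", "point counts differ")
  }
  if (nrow(as.matrix(true_coords)) < 3L) {
    stop_stmap("stmap_validation_error", "need >= 3 points for correlation")
  }
  if (sd(dt) == 0 || sd(dp) == 0) {
    stop_stmap("stmap_degenerate_statistic_error",
               "a pairwise-distance vector has zero variance")
  }
  cor(dt, dp)
}

#' Pairwise RMSE between true and predicted geometry
#'
#' Root-mean-square difference between the two pairwise-distance vectors,
#' in the (min-max normalized) units of the coordinates.
#'
#' @inheritParams pairwise_pearson_r
#' @return Non-negative scalar.
#' @export
pairwise_rmse <- function(true_coords, pred_coords) {
  dt <- pairwise_distances(true_coords)
  dp <- pairwise_distances(pred_coords)
  if (length(dt) != length(dp)) {
    stop_stmap("stmap_validation_error", "point counts differ")
  }
  sqrt(mean((dt - dp)^2))
}

#' Area under the ROC curve for a score separating two classes
#'
#' Rank-based (Mann-Whitney) AUROC of `score` for `label` (logical; TRUE =
#' positive class). Used to quantify how well importance scores separate
#' known spatially variable genes from noise genes.
#'
#' @param score numeric scores, higher = more positive.
#' @param label logical class labels.
#' @return AUROC in `[0, 1]`.
#' @export
score_auroc <- function(score, label) {
  label <- as.logical(label)
  n_pos <- sum(label)
  n_neg <- sum(!label)
  if (n_pos == 0 || n_neg == 0) {
    stop_stmap("stmap_validation_error", "need both classes for AUROC")
  }
  r <- rank(score)
  (sum(r[label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
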