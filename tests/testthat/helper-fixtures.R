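# Shared fixture builders; everything is generated in code at test time.

tiny_counts <- function() {
  m <- matrix(c(1, 0, 2,
                1, 3, 0,
                2, 1, 4), nrow = 3, byrow = TRUE)
  spatial_dataset(m, gene_ids = c("gA", "gB", "gC"),
                  obs_ids = c("s1", "s2", "s3"),
                  coords = cbind(x = c(0, 10, 5), y = c(0, 20, 10)))
}

random_cloud <- function(n, d = 2, seed = 1) {
  set.seed(seed)
  matrix(runif(n * d, -50, 50), ncol = d)
}

# random shape-chained weight list for backtracking tests
random_weight_chain <- function(n_mat, widths) {
  lapply(seq_len(n_mat), function(i) {
    matrix(rnorm(widths[i] * widths[i + 1]), widths[i], widths[i + 1])
  })
}

# Independent brute-force oracle for backward importance: materializes the
# 0/1 mask matrix for every layer explicitly, never shares code with the
# implementation.
oracle_backtrack <- function(weights, r = 50) {
  I <- length(weights)
  S_next <- NULL
  for (i in I:1) {
    W <- weights[[i]]
    S <- numeric(nrow(W))
    if (i == I) {
      for (j in seq_len(nrow(W))) S[j] <- sum(abs(W[j, ]))
    } else {
      thr <- unname(stats::quantile(S_next, r / 100))
      mask <- matrix(0, nrow(W), ncol(W))
      for (k in seq_len(ncol(W))) if (S_next[k] > thr) mask[, k] <- 1
      for (j in seq_len(nrow(W))) S[j] <- sum(mask[j, ] * abs(W[j, ]))
    }
    S_next <- S
  }
  S_next
}

# Independent W1 oracle: integrates |Qu - Qv| over probability breakpoints
# (quantile-function route, distinct from the CDF-support integration used
# by the implementation).
oracle_wasserstein <- function(u, v) {
  su <- sort(u); sv <- sort(v)
  nu <- length(su); nv <- length(sv)
  ps <- sort(unique(c(seq_len(nu) / nu, seq_len(nv) / nv)))
  lo <- c(0, ps[-length(ps)])
  tot <- 0
  for (i in seq_along(ps)) {
    mid <- (lo[i] + ps[i]) / 2
    qu <- su[ceiling(mid * nu)]
    qv <- sv[ceiling(mid * nv)]
    tot <- tot + abs(qu - qv) * (ps[i] - lo[i])
  }
  tot
}

# Dense double-loop Moran's I oracle
oracle_morans_i <- function(x, w_dense) {
  n <- length(x)
  xc <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- num + w_dense[i, j] * xc[i] * xc[j]
  }
  (n / sum(w_dense)) * num / sum(xc^2)
}

rigid_transform <- function(coords, angle, shift) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  sweep(coords %*% R, 2, shift, "+")
}

# quick trainable fixture: coordinates driven by a handful of genes
small_reference <- function(n_spots = 300, n_genes = 40, seed = 5) {
  ref <- generate_reference(synth_config(
    n_spots = n_spots, n_genes = n_genes, n_svg = 15, mean_depth = 1200,
    seed = seed))
  list(norm = normalize_counts(ref$dataset), truth = ref$truth)
}
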