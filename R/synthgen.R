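#' Configuration for the synthetic ST generator
#'
#' The generator emulates a sequencing-based spatial-transcriptomics assay:
#' spots at known positions in a square tissue, a minority of genes whose
#' expected expression follows a smooth spatial surface (the true SVGs),
#' spatially flat noise genes, negative-binomial counts with lognormal
#' per-spot depth variation, and an optional batch-shifted query set.
#'
#' @param n_spots number of reference spots.
#' @param layout spot layout: `"uniform"` (random in the box), `"grid"`, or
#'   `"annulus"` (ring-shaped tissue, useful with polar coordinates).
#' @param n_genes total genes.
#' @param n_svg number of spatially patterned genes (<= `n_genes`).
#' @param pattern_kinds spatial surface families to draw from:
#'   `"linear"` (gradient), `"bump"` (Gaussian spot), `"ring"`
#'   (concentric ring), `"step"` (half-plane).
#' @param mean_depth expected UMI count per spot.
#' @param dispersion negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param amplitude fold-change of a pattern between its low and high
#'   regions; all surfaces share this dynamic range so SVG difficulty is
#'   governed by depth and dispersion.
#' @param depth_sdlog lognormal sd of per-spot depth factors.
#' @param box_size side length of the square tissue (interpreted as um).
#' @param seed integer seed.
#' @return A `synth_config`.
#' @export
synth_config <- function(n_spots = 1500L, layout = c("uniform", "grid", "annulus"),
                         n_genes = 150L, n_svg = 40L,
                         pattern_kinds = c("linear", "bump", "ring", "step"),
                         mean_depth = 2000, dispersion = 10,
                         amplitude = 16, depth_sdlog = 0.3,
                         box_size = 1000, seed = 1L) {
  layout <- match.arg(layout)
  pattern_kinds <- match.arg(pattern_kinds, several.ok = TRUE)
  if (n_svg > n_genes) {
    stop_stmap("stmap_validation_error", "n_svg exceeds n_genes")
  }
  if (mean_depth <= 0 || dispersion <= 0 || amplitude <= 1) {
    stop_stmap("stmap_validation_error",
               "mean_depth and dispersion must be positive, amplitude > 1")
  }
  structure(list(n_spots = as.integer(n_spots), layout = layout,
                 n_genes = as.integer(n_genes), n_svg = as.integer(n_svg),
                 pattern_kinds = pattern_kinds, mean_depth = mean_depth,
                 dispersion = dispersion, amplitude = amplitude,
                 depth_sdlog = depth_sdlog, box_size = box_size,
                 seed = as.integer(seed)),
            class = "synth_config")
}

synth_layout <- function(config) {
  n <- config$n_spots
  b <- config$box_size
  switch(config$layout,
    uniform = cbind(x = runif(n, 0, b), y = runif(n, 0, b)),
    grid = {
      side <- ceiling(sqrt(n))
      g <- expand.grid(x = seq(0, b, length.out = side),
                       y = seq(0, b, length.out = side))
      as.matrix(g[seq_len(n), ])
    },
    annulus = {
      r <- sqrt(runif(n, 0.25, 1)) * b / 2   # uniform in area on [b/4, b/2]
      a <- runif(n, -pi, pi)
      cbind(x = b / 2 + r * cos(a), y = b / 2 + r * sin(a))
    })
}

# Smooth surface on [0,1]^2 -> [0,1]; params drawn here and recorded.
synth_pattern <- function(kind, u, v) {
  s <- switch(kind,
    linear = {
      theta <- runif(1, 0, 2 * pi)
      list(values = u * cos(theta) + v * sin(theta),
           params = c(theta = theta))
    },
    bump = {
      cx <- runif(1, 0.25, 0.75); cy <- runif(1, 0.25, 0.75)
      sigma <- runif(1, 0.1, 0.2)
      list(values = exp(-((u - cx)^2 + (v - cy)^2) / (2 * sigma^2)),
           params = c(cx = cx, cy = cy, sigma = sigma))
    },
    ring = {
      r0 <- runif(1, 0.15, 0.4); sigma <- runif(1, 0.05, 0.12)
      r <- sqrt((u - 0.5)^2 + (v - 0.5)^2)
      list(values = exp(-(r - r0)^2 / (2 * sigma^2)),
           params = c(r0 = r0, sigma = sigma))
    },
    step = {
      theta <- runif(1, 0, 2 * pi); cutoff <- runif(1, -0.2, 0.2)
      proj <- (u - 0.5) * cos(theta) + (v - 0.5) * sin(theta)
      list(values = as.numeric(proj > cutoff),
           params = c(theta = theta, cutoff = cutoff))
    })
  rng <- range(s$values)
  s$values <- if (diff(rng) > 0) (s$values - rng[1]) / diff(rng) else
    rep(0.5, length(s$values))
  s
}

synth_rates <- function(config, coords, base_abundance, patterns) {
  u <- coords[, 1] / config$box_size
  v <- coords[, 2] / config$box_size
  rates <- matrix(rep(base_abundance, each = nrow(coords)),
                  nrow = nrow(coords))
  for (g in seq_len(config$n_svg)) {
    p <- patterns[[g]]
    surf <- switch(p$kind,
      linear = u * cos(p$params["theta"]) + v * sin(p$params["theta"]),
      bump = exp(-((u - p$params["cx"])^2 + (v - p$params["cy"])^2) /
                   (2 * p$params["sigma"]^2)),
      ring = exp(-(sqrt((u - 0.5)^2 + (v - 0.5)^2) - p$params["r0"])^2 /
                   (2 * p$params["sigma"]^2)),
      step = as.numeric((u - 0.5) * cos(p$params["theta"]) +
                          (v - 0.5) * sin(p$params["theta"]) >
                          p$params["cutoff"]))
    rng <- p$range
    surf <- if (diff(rng) > 0) (surf - rng[1]) / diff(rng) else
      rep(0.5, length(surf))
    # common dynamic range: multiplier amplitude^(s - 1/2)
    rates[, g] <- rates[, g] * config$amplitude^(surf - 0.5)
  }
  rates
}

synth_counts <- function(config, rates) {
  n <- nrow(rates)
  depth <- config$mean_depth *
    exp(rnorm(n, -config$depth_sdlog^2 / 2, config$depth_sdlog))
  p <- rates / rowSums(rates)
  mu <- p * depth
  counts <- matrix(rnbinom(length(mu), size = config$dispersion, mu = mu),
                   nrow = n)
  counts
}

#' Generate a synthetic ST reference with known ground truth
#'
#' @param config a [synth_config()].
#' @return List with `dataset` (a `spatial_dataset` of raw counts with
#'   coordinates) and `truth`: `svg_ids`, `patterns` (per-SVG kind and
#'   parameters), `base_abundance`, and the config. The first `n_svg` genes
#'   are the spatially patterned ones.
#' @export
generate_reference <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  local_seed(config$seed, {
    coords <- synth_layout(config)
    gene_ids <- sprintf("gene_%03d", seq_len(config$n_genes))
    svg_ids <- gene_ids[seq_len(config$n_svg)]
    base_abundance <- exp(rnorm(config$n_genes, 0, 1))
    u <- coords[, 1] / config$box_size
    v <- coords[, 2] / config$box_size
    patterns <- lapply(seq_len(config$n_svg), function(g) {
      kind <- sample(config$pattern_kinds, 1)
      s <- synth_pattern(kind, u, v)
      # record the raw surface range so query cells reuse the same map
      raw <- switch(kind,
        linear = u * cos(s$params["theta"]) + v * sin(s$params["theta"]),
        bump = s$values, ring = s$values, step = s$values)
      list(kind = kind, params = s$params,
           range = if (kind == "linear") range(raw) else c(0, 1))
    })
    rates <- synth_rates(config, coords, base_abundance, patterns)
    counts <- synth_counts(config, rates)
    ds <- spatial_dataset(counts, gene_ids = gene_ids,
                          obs_ids = sprintf("spot_%04d", seq_len(config$n_spots)),
                          coords = coords)
    list(dataset = ds,
         truth = list(svg_ids = svg_ids, patterns = patterns,
                      base_abundance = base_abundance, config = config))
  })
}

#' Generate a query set from a synthetic reference
#'
#' Cells are placed at new random positions in the same tissue, expression
#' is drawn from the same spatial surfaces and depth model, then the counts
#' are library-size normalized and log-transformed and a constant batch
#' shift is added, on that normalized scale, to a random subset of genes.
#' The true positions are withheld from the returned dataset but recorded
#' in the ground truth for accuracy scoring.
#'
#' @param reference a [generate_reference()] result.
#' @param n_cells number of query cells.
#' @param batch_shift_genes number of genes receiving the shift.
#' @param batch_shift_size shift added on the log-normalized scale.
#' @param seed integer seed.
#' @return List with `dataset` (normalized, shifted expression, no
#'   coordinates), `true_coords`, `shifted_genes`, and `counts` (the raw
#'   pre-shift count dataset).
#' @export
generate_query <- function(reference, n_cells = 1000L, batch_shift_genes = 0L,
                           batch_shift_size = 0, seed = 2L) {
  truth <- reference$truth
  config <- truth$config
  local_seed(seed, {
    coords <- cbind(x = runif(n_cells, 0, config$box_size),
                    y = runif(n_cells, 0, config$box_size))
    q_config <- config
    q_config$n_spots <- as.integer(n_cells)
    rates <- synth_rates(q_config, coords, truth$base_abundance,
                         truth$patterns)
    counts <- synth_counts(q_config, rates)
    counts_ds <- spatial_dataset(counts, gene_ids = reference$dataset$gene_ids,
                                 obs_ids = sprintf("cell_%04d",
                                                   seq_len(n_cells)))
    normed <- normalize_counts(counts_ds)
    shifted <- character(0)
    if (batch_shift_genes > 0L) {
      shifted <- sample(normed$gene_ids, batch_shift_genes)
      expr <- as.matrix(normed$expr)
      expr[, shifted] <- expr[, shifted] + batch_shift_size
      normed$expr <- expr
    }
    normed$coords <- NULL
    list(dataset = normed, true_coords = coords, shifted_genes = shifted,
         counts = counts_ds)
  })
}
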