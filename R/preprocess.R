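#' Library-size normalize and log-transform counts
#'
#' Each observation's counts are scaled to a common total (default 10,000
#' UMIs) and transformed with `ln(1 + x)`, the standard single-cell
#' normalization the coordinate regression is trained on.
#'
#' @param dataset a `spatial_dataset` of non-negative counts.
#' @param target_sum per-observation total after scaling.
#' @return A new `spatial_dataset`; the input is not modified.
#' @export
normalize_counts <- function(dataset, target_sum = 10000) {
  stopifnot(inherits(dataset, "spatial_dataset"))
  if (target_sum <= 0) {
    stop_stmap("stmap_validation_error", "target_sum must be positive")
  }
  sums <- Matrix::rowSums(dataset$expr)
  if (any(sums <= 0)) {
    bad <- dataset$obs_ids[sums <= 0]
    stop_stmap("stmap_validation_error",
               "all-zero observations: %s",
               paste(utils::head(bad, 10), collapse = ", "))
  }
  scaled <- dataset$expr * (target_sum / sums)
  out <- dataset
  out$expr <- if (is(scaled, "Matrix")) {
    res <- as(scaled, "CsparseMatrix")
    res@x <- log1p(res@x)
    res
  } else {
    log1p(scaled)
  }
  dimnames(out$expr) <- list(out$obs_ids, out$gene_ids)
  out
}

#' 1D Wasserstein distance between two empirical distributions
#'
#' The earth-mover's distance between the empirical distributions of `u` and
#' `v`: the integral of `|U - V|` over the real line, where U and V are the
#' empirical CDFs with equal mass `1/n` per observation. Used to flag genes
#' whose expression distributions differ between reference and query data
#' (batch effects).
#'
#' @param u,v non-empty numeric vectors.
#' @return Non-negative scalar; 0 iff the empirical distributions coincide.
#' @export
wasserstein_1d <- function(u, v) {
  if (length(u) == 0L || length(v) == 0L) {
    stop_stmap("stmap_validation_error", "empty vector in wasserstein_1d")
  }
  su <- sort(u)
  sv <- sort(v)
  support <- sort(c(su, sv))
  deltas <- diff(support)
  if (length(deltas) == 0L) return(0)
  pts <- support[-length(support)]
  U <- findInterval(pts, su) / length(su)
  V <- findInterval(pts, sv) / length(sv)
  sum(abs(U - V) * deltas)
}

#' Genes common to two datasets
#'
#' @param a,b `spatial_dataset`s.
#' @return Character vector: the gene-id intersection in `a`'s order.
#' @export
intersect_genes <- function(a, b) {
  a$gene_ids[a$gene_ids %in% b$gene_ids]
}

#' Select genes with comparable reference/query distributions
#'
#' Computes the 1D Wasserstein distance between each common gene's
#' expression distribution in the reference and in the query (both already
#' normalized with [normalize_counts()]) and keeps genes with distance
#' strictly below `threshold`. Genes shifted by a batch effect of size `c`
#' have distance about `|c|` and are dropped at the default threshold 0.1.
#'
#' @param reference,query normalized `spatial_dataset`s.
#' @param threshold non-negative distance cutoff (strict `<`).
#' @return Character vector of selected gene ids in reference order, with a
#'   `distances` attribute (named W1 distances for all common genes).
#' @export
select_genes <- function(reference, query, threshold = 0.1) {
  common <- intersect_genes(reference, query)
  if (length(common) == 0L) {
    stop_stmap("stmap_validation_error",
               "reference and query share no genes")
  }
  ref_expr <- reference$expr[, common, drop = FALSE]
  qry_expr <- query$expr[, common, drop = FALSE]
  d <- vapply(seq_along(common), function(j) {
    wasserstein_1d(as.numeric(ref_expr[, j]), as.numeric(qry_expr[, j]))
  }, numeric(1))
  names(d) <- common
  keep <- common[d < threshold]
  msg_log("select_genes",
          "%d reference genes, %d in common with query, %d selected (W1 < %g)",
          length(reference$gene_ids), length(common), length(keep), threshold)
  structure(keep, distances = d)
}
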