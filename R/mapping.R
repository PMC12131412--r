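#' Assign predicted cell positions to reference beads
#'
#' A predicted position rarely coincides with a bead center, and several
#' cells can land near one bead. Each bead collects every cell whose
#' Euclidean distance to its center is at most `cutoff` (the bead radius for
#' the assay: around 15 um for Slide-seqV2-like, 110 um for Visium-like
#' data, in the units of the coordinates). A cell may belong to several
#' beads; a bead may be empty.
#'
#' @param pred_coords cell positions (denormalized, same units as beads).
#' @param bead_coords reference bead centers; rownames used as bead ids.
#' @param cutoff positive distance cutoff.
#' @return A `bead_assignment`: `bead_ids`, `members` (data.frame with
#'   `bead`, `cell`, `distance`), `cutoff`, `bead_coords`.
#' @export
assign_to_beads <- function(pred_coords, bead_coords, cutoff) {
  pred_coords <- as.matrix(pred_coords)
  bead_coords <- as.matrix(bead_coords)
  if (ncol(pred_coords) != ncol(bead_coords)) {
    stop_stmap("stmap_validation_error",
               "cell coordinates are %dD but bead coordinates are %dD",
               ncol(pred_coords), ncol(bead_coords))
  }
  if (cutoff <= 0) stop_stmap("stmap_validation_error", "cutoff must be > 0")
  bead_ids <- rownames(bead_coords)
  if (is.null(bead_ids)) bead_ids <- paste0("bead_", seq_len(nrow(bead_coords)))
  # cross-distance via the expansion ||a-b||^2 = |a|^2 + |b|^2 - 2 a.b
  d2 <- outer(rowSums(bead_coords^2), rowSums(pred_coords^2), "+") -
    2 * bead_coords %*% t(pred_coords)
  d2[d2 < 0] <- 0
  D <- sqrt(d2)
  hits <- which(D <= cutoff, arr.ind = TRUE)
  members <- data.frame(
    bead = bead_ids[hits[, 1]],
    cell = hits[, 2],
    distance = D[hits],
    stringsAsFactors = FALSE
  )
  members <- members[order(match(members$bead, bead_ids), members$cell), ,
                     drop = FALSE]
  rownames(members) <- NULL
  n_unmapped <- nrow(pred_coords) - length(unique(members$cell))
  if (n_unmapped > 0) {
    msg_log("assign_to_beads",
            "%d of %d cells fall farther than %g from every bead",
            n_unmapped, nrow(pred_coords), cutoff)
  }
  structure(list(bead_ids = bead_ids, members = members, cutoff = cutoff,
                 bead_coords = bead_coords),
            class = "bead_assignment")
}

#' Inverse-distance reconstruction weights
#'
#' For the `k` cells assigned to one bead, cell `j` gets weight
#' `(1/d_j) / sum_i (1/d_i)`; weights sum to 1. A cell exactly at the bead
#' center (distance 0) takes the limit: all weight is shared equally among
#' zero-distance cells.
#'
#' @param distances non-negative distances of the member cells.
#' @return Weight vector summing to 1.
#' @export
reconstruction_weights <- function(distances) {
  if (length(distances) == 0L) {
    stop_stmap("stmap_validation_error", "no member cells")
  }
  if (any(distances < 0)) {
    stop_stmap("stmap_validation_error", "negative distance")
  }
  zero <- distances == 0
  if (any(zero)) {
    w <- numeric(length(distances))
    w[zero] <- 1 / sum(zero)
    return(w)
  }
  inv <- 1 / distances
  inv / sum(inv)
}

#' Reconstruct bead-level expression from mapped cells
#'
#' Each non-empty bead's expression is the inverse-distance weighted average
#' of its member cells' expression (a convex combination, so every gene
#' stays within its members' range). Empty beads are returned with `NA`
#' expression, not zeros, and flagged in the result.
#'
#' @param assignment a [assign_to_beads()] result.
#' @param query_expr cell expression matrix (cells x genes) or
#'   `spatial_dataset`; row order must match the cell indices of the
#'   assignment.
#' @return A `spatial_dataset` of beads x genes with bead coordinates; empty
#'   beads have `NA` rows and are listed in `attr(, "empty_beads")`.
#' @export
reconstruct_bead_expression <- function(assignment, query_expr) {
  stopifnot(inherits(assignment, "bead_assignment"))
  if (inherits(query_expr, "spatial_dataset")) {
    gene_ids <- query_expr$gene_ids
    query_expr <- as.matrix(query_expr$expr)
  } else {
    query_expr <- as.matrix(query_expr)
    gene_ids <- colnames(query_expr)
    if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(ncol(query_expr)))
  }
  if (nrow(assignment$members) > 0 &&
      max(assignment$members$cell) > nrow(query_expr)) {
    stop_stmap("stmap_validation_error",
               "assignment refers to cell %d but query has %d cells",
               max(assignment$members$cell), nrow(query_expr))
  }
  out <- matrix(NA_real_, nrow = length(assignment$bead_ids),
                ncol = ncol(query_expr))
  by_bead <- split(assignment$members[c("cell", "distance")],
                   factor(assignment$members$bead,
                          levels = assignment$bead_ids))
  for (b in seq_along(by_bead)) {
    mem <- by_bead[[b]]
    if (nrow(mem) == 0L) next
    w <- reconstruction_weights(mem$distance)
    out[b, ] <- crossprod(query_expr[mem$cell, , drop = FALSE], w)
  }
  empty <- assignment$bead_ids[!vapply(by_bead, nrow, integer(1)) > 0]
  ds <- spatial_dataset(out, gene_ids = gene_ids,
                        obs_ids = assignment$bead_ids,
                        coords = assignment$bead_coords)
  attr(ds, "empty_beads") <- empty
  ds
}

#' Per-bead membership table with weights
#'
#' @param assignment a `bead_assignment`.
#' @return data.frame with `bead`, `cell`, `distance`, `weight`.
#' @export
assignment_table <- function(assignment) {
  stopifnot(inherits(assignment, "bead_assignment"))
  m <- assignment$members
  if (nrow(m) == 0L) return(cbind(m, weight = numeric(0)))
  w <- unlist(lapply(split(m$distance, factor(m$bead, levels = unique(m$bead))),
                     reconstruction_weights), use.names = FALSE)
  m$weight <- w
  m
}
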