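#' Spatial expression dataset
#'
#' The central container of the package: an observations x genes expression
#' matrix (dense or sparse) with gene identifiers, observation identifiers,
#' optional per-observation spatial coordinates (2D or 3D) and optional
#' labels. Reference spatial-transcriptomics (ST) data carry coordinates;
#' query scRNA-seq data usually do not.
#'
#' @param expr numeric matrix or `Matrix::dgCMatrix`, observations in rows,
#'   genes in columns; entries must be non-negative (NA allowed only for
#'   beads flagged as missing by reconstruction).
#' @param gene_ids character vector of unique gene identifiers, one per
#'   column of `expr`.
#' @param obs_ids character vector of unique observation identifiers, one per
#'   row of `expr`. Defaults to rownames of `expr` or `obs_1 ... obs_n`.
#' @param coords optional numeric matrix (observations x 2 or 3) of spatial
#'   positions, same row order as `expr`.
#' @param labels optional character vector of per-observation labels.
#' @return An object of class `spatial_dataset`.
#' @export
spatial_dataset <- function(expr, gene_ids, obs_ids = NULL, coords = NULL,
                            labels = NULL) {
  if (is.data.frame(expr)) expr <- as.matrix(expr)
  if (!(is.matrix(expr) || is(expr, "Matrix"))) {
    stop_stmap("stmap_validation_error", "expr must be a matrix or Matrix")
  }
  gene_ids <- as.character(gene_ids)
  if (is.null(obs_ids)) {
    obs_ids <- if (!is.null(rownames(expr))) rownames(expr) else
      paste0("obs_", seq_len(nrow(expr)))
  }
  obs_ids <- as.character(obs_ids)
  if (ncol(expr) != length(gene_ids)) {
    stop_stmap("stmap_validation_error",
               "expr has %d columns but %d gene ids", ncol(expr),
               length(gene_ids))
  }
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    stop_stmap("stmap_validation_error", "duplicated gene ids: %s",
               paste(utils::head(dup, 5), collapse = ", "))
  }
  if (nrow(expr) != length(obs_ids)) {
    stop_stmap("stmap_validation_error",
               "expr has %d rows but %d obs ids", nrow(expr), length(obs_ids))
  }
  if (anyDuplicated(obs_ids)) {
    stop_stmap("stmap_validation_error", "duplicated observation ids")
  }
  vals <- if (is(expr, "Matrix")) expr@x else expr
  if (any(vals < 0, na.rm = TRUE)) {
    stop_stmap("stmap_validation_error", "expr contains negative entries")
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    storage.mode(coords) <- "double"
    if (nrow(coords) != nrow(expr)) {
      stop_stmap("stmap_validation_error",
                 "coords has %d rows but expr has %d", nrow(coords), nrow(expr))
    }
    if (!ncol(coords) %in% c(2L, 3L)) {
      stop_stmap("stmap_validation_error",
                 "coords must have 2 or 3 columns, got %d", ncol(coords))
    }
    rownames(coords) <- obs_ids
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(expr)) {
      stop_stmap("stmap_validation_error", "labels length mismatch")
    }
  }
  dimnames(expr) <- list(obs_ids, gene_ids)
  structure(list(expr = expr, gene_ids = gene_ids, obs_ids = obs_ids,
                 coords = coords, labels = labels),
            class = "spatial_dataset")
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("spatial_dataset: %d observations x %d genes%s%s\n",
              nrow(x$expr), ncol(x$expr),
              if (!is.null(x$coords))
                sprintf(", %dD coordinates", ncol(x$coords)) else "",
              if (!is.null(x$labels)) ", labelled" else ""))
  invisible(x)
}

#' @export
dim.spatial_dataset <- function(x) dim(x$expr)

#' Subset a spatial dataset
#'
#' @param x a `spatial_dataset`.
#' @param i observation (row) index.
#' @param j gene index: integer, logical, or gene ids.
#' @param ... ignored.
#' @return A `spatial_dataset`.
#' @export
`[.spatial_dataset` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$expr))
  if (missing(j)) j <- seq_len(ncol(x$expr))
  if (is.character(j)) j <- match(j, x$gene_ids)
  if (anyNA(j)) stop_stmap("stmap_validation_error", "unknown gene id in subset")
  spatial_dataset(x$expr[i, j, drop = FALSE],
                  gene_ids = x$gene_ids[j],
                  obs_ids = x$obs_ids[i],
                  coords = if (!is.null(x$coords)) x$coords[i, , drop = FALSE],
                  labels = if (!is.null(x$labels)) x$labels[i])
}

#' Read a spatial dataset from disk
#'
#' Three layouts are supported:
#' \describe{
#'   \item{`delimited`}{`path` is a tab-delimited observations x genes count
#'     table with a header row of gene ids and the first column holding
#'     observation ids. An optional coordinate sidecar (`coords_path`) is a
#'     delimited table keyed by observation id with 2 or 3 coordinate
#'     columns.}
#'   \item{`mtx`}{`path` is a MatrixMarket triplet file; `barcodes_path` and
#'     `features_path` are one-id-per-line sidecars for observations and
#'     genes (the standard single-cell MTX trio, genes x cells orientation
#'     controlled by `transpose`). `coords_path` as above.}
#'   \item{`h5`}{`path` is an HDF5 single-cell container with the expression
#'     matrix in `X` (dense, or a CSR group with `data`/`indices`/`indptr`
#'     and a `shape` attribute), ids in `obs/_index` and `var/_index`, and
#'     coordinates, when present, in `obsm/spatial`.}
#' }
#'
#' @param path main file path.
#' @param format one of `"delimited"`, `"mtx"`, `"h5"`.
#' @param coords_path optional coordinate sidecar (delimited, mtx).
#' @param barcodes_path,features_path id sidecars for `mtx`.
#' @param transpose for `mtx`: matrix stored genes x cells (default TRUE, the
#'   common convention).
#' @return A `spatial_dataset`.
#' @export
read_dataset <- function(path, format = c("delimited", "mtx", "h5"),
                         coords_path = NULL, barcodes_path = NULL,
                         features_path = NULL, transpose = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_stmap("stmap_parse_error", "file not found: %s", path)
  }
  switch(format,
    delimited = read_dataset_delimited(path, coords_path),
    mtx = read_dataset_mtx(path, barcodes_path, features_path, coords_path,
                           transpose),
    h5 = read_dataset_h5(path)
  )
}

read_dataset_delimited <- function(path, coords_path) {
  tab <- tryCatch(
    read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop_stmap("stmap_parse_error",
                                   "cannot parse %s: %s", path, conditionMessage(e)))
  if (ncol(tab) < 2L) {
    stop_stmap("stmap_parse_error",
               "%s: expected an id column plus gene columns", path)
  }
  obs_ids <- as.character(tab[[1]])
  expr <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(expr)) {
    bad <- which(!vapply(tab[-1], is.numeric, logical(1)))[1]
    stop_stmap("stmap_parse_error", "%s: non-numeric gene column '%s'",
               path, colnames(tab)[-1][bad])
  }
  coords <- if (!is.null(coords_path)) read_coords_sidecar(coords_path, obs_ids)
  spatial_dataset(expr, gene_ids = colnames(tab)[-1], obs_ids = obs_ids,
                  coords = coords)
}

read_coords_sidecar <- function(path, obs_ids) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) {
    stop_stmap("stmap_parse_error",
               "%s: coordinate sidecar needs id + >=2 coordinate columns", path)
  }
  idx <- match(obs_ids, as.character(tab[[1]]))
  if (anyNA(idx)) {
    stop_stmap("stmap_parse_error",
               "%s: missing coordinates for observations: %s", path,
               paste(utils::head(obs_ids[is.na(idx)], 5), collapse = ", "))
  }
  m <- as.matrix(tab[idx, -1, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

read_dataset_mtx <- function(path, barcodes_path, features_path, coords_path,
                             transpose) {
  if (is.null(barcodes_path) || is.null(features_path)) {
    stop_stmap("stmap_validation_error",
               "mtx format needs barcodes_path and features_path")
  }
  m <- tryCatch(Matrix::readMM(path), error = function(e)
    stop_stmap("stmap_parse_error", "cannot parse %s: %s", path,
               conditionMessage(e)))
  barcodes <- readLines(barcodes_path)
  features <- readLines(features_path)
  # features files are often multi-column (id, symbol, type); keep column 1
  features <- vapply(strsplit(features, "\t"), `[[`, character(1), 1L)
  barcodes <- vapply(strsplit(barcodes, "\t"), `[[`, character(1), 1L)
  if (transpose) m <- Matrix::t(m)
  m <- as(m, "CsparseMatrix")
  if (nrow(m) != length(barcodes)) {
    stop_stmap("stmap_parse_error",
               "%s: %d matrix rows vs %d barcodes (transpose=%s)", path,
               nrow(m), length(barcodes), transpose)
  }
  if (ncol(m) != length(features)) {
    stop_stmap("stmap_parse_error", "%s: %d matrix columns vs %d features",
               path, ncol(m), length(features))
  }
  coords <- if (!is.null(coords_path)) read_coords_sidecar(coords_path, barcodes)
  spatial_dataset(m, gene_ids = features, obs_ids = barcodes, coords = coords)
}

read_dataset_h5 <- function(path) {
  contents <- rhdf5::h5ls(path)
  paths <- file.path(contents$group, contents$name)
  paths <- sub("^/", "", sub("^//", "/", paths))
  has <- function(p) p %in% paths
  if (!has("X")) stop_stmap("stmap_parse_error", "%s: no X slot", path)
  x_is_group <- contents$otype[match("X", paths)] == "H5I_GROUP"
  if (x_is_group) {
    grp <- rhdf5::h5read(path, "X")
    shape <- rhdf5::h5readAttributes(path, "X")$shape
    if (is.null(shape)) {
      stop_stmap("stmap_parse_error", "%s: sparse X group lacks shape attribute",
                 path)
    }
    expr <- Matrix::sparseMatrix(
      j = as.integer(grp$indices) + 1L,
      p = as.integer(grp$indptr),
      x = as.numeric(grp$data),
      dims = as.integer(shape)
    )
  } else {
    expr <- rhdf5::h5read(path, "X")
    # HDF5 is row-major; datasets written by this package store obs x genes
    # transposed so R reads them back in the native orientation
    expr <- t(expr)
  }
  read_ids <- function(slot) as.character(rhdf5::h5read(path, slot))
  obs_ids <- if (has("obs/_index")) read_ids("obs/_index") else
    if (has("obs_ids")) read_ids("obs_ids") else
      stop_stmap("stmap_parse_error", "%s: no observation id slot", path)
  gene_ids <- if (has("var/_index")) read_ids("var/_index") else
    if (has("gene_ids")) read_ids("gene_ids") else
      stop_stmap("stmap_parse_error", "%s: no gene id slot", path)
  coords <- NULL
  if (has("obsm/spatial")) {
    coords <- rhdf5::h5read(path, "obsm/spatial")
    if (nrow(coords) %in% c(2L, 3L) && ncol(coords) == length(obs_ids)) {
      coords <- t(coords)
    }
  }
  spatial_dataset(expr, gene_ids = gene_ids, obs_ids = obs_ids, coords = coords)
}

#' Write a spatial dataset to disk
#'
#' Inverse of [read_dataset()] for the same three layouts; see that help page
#' for the file conventions. For `delimited` and `mtx` the coordinate sidecar
#' is written when the dataset has coordinates.
#'
#' @param x a `spatial_dataset`.
#' @param path output path (for `mtx`, the matrix file; sidecars derive from
#'   the other arguments).
#' @inheritParams read_dataset
#' @return `path`, invisibly.
#' @export
write_dataset <- function(x, path, format = c("delimited", "mtx", "h5"),
                          coords_path = NULL, barcodes_path = NULL,
                          features_path = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(x, "spatial_dataset"))
  if (format == "delimited") {
    tab <- data.frame(obs_id = x$obs_ids, as.matrix(x$expr),
                      check.names = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(x$coords) && !is.null(coords_path)) {
      ctab <- data.frame(obs_id = x$obs_ids, x$coords, check.names = FALSE)
      colnames(ctab) <- c("obs_id", c("x", "y", "z")[seq_len(ncol(x$coords))])
      write.table(ctab, coords_path, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
  } else if (format == "mtx") {
    if (is.null(barcodes_path) || is.null(features_path)) {
      stop_stmap("stmap_validation_error",
                 "mtx format needs barcodes_path and features_path")
    }
    m <- Matrix::t(as(as(x$expr, "dMatrix"), "CsparseMatrix"))
    Matrix::writeMM(m, path)
    writeLines(x$obs_ids, barcodes_path)
    writeLines(x$gene_ids, features_path)
    if (!is.null(x$coords) && !is.null(coords_path)) {
      ctab <- data.frame(obs_id = x$obs_ids, x$coords, check.names = FALSE)
      write.table(ctab, coords_path, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
  } else {
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    expr <- as.matrix(x$expr)
    rhdf5::h5write(t(expr), path, "X")
    rhdf5::h5write(x$obs_ids, path, "obs_ids")
    rhdf5::h5write(x$gene_ids, path, "gene_ids")
    if (!is.null(x$coords)) {
      rhdf5::h5createGroup(path, "obsm")
      rhdf5::h5write(x$coords, path, "obsm/spatial")
    }
    rhdf5::h5closeAll()
  }
  invisible(path)
}
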