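#' Read Visium HD 2-micron square data from Space Ranger output
#'
#' Loads the filtered feature-barcode matrix (MatrixMarket triplet with
#' sibling features/barcodes files), the square positions table
#' (parquet or CSV), and the scale-factors JSON, and assembles the square
#' lattice in full-resolution pixel coordinates.
#'
#' The positions table must provide columns \code{barcode},
#' \code{array_row}, \code{array_col}, \code{pxl_row_in_fullres},
#' \code{pxl_col_in_fullres} (an \code{in_tissue} column is carried along
#' when present). Pixel row maps to y and pixel column to x. The square
#' side length in pixels is \code{2 / microns_per_pixel}, i.e. a 2-micron
#' square at the image's stated resolution.
#'
#' @param matrix_path directory containing \code{matrix.mtx},
#'   \code{features.tsv} (or \code{genes.tsv}) and \code{barcodes.tsv}, or
#'   the path of the \code{.mtx} file itself.
#' @param positions_path parquet or CSV positions file.
#' @param scalefactors_path JSON file containing \code{microns_per_pixel}.
#' @return A list with elements \code{grid} (a \code{\link{square_grid}})
#'   and \code{counts} (sparse genes x squares integer matrix). Every
#'   barcode present in the matrix has a grid entry.
#' @export
read_visiumhd <- function(matrix_path, positions_path, scalefactors_path) {
  m <- read_mtx_dir(matrix_path)
  if (any(m@x != round(m@x))) stop("count matrix contains non-integer values")
  pos <- read_positions(positions_path)
  missing <- setdiff(colnames(m), pos$barcode)
  if (length(missing)) {
    stop("barcodes present in matrix but absent from positions: ",
         paste(utils::head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) sprintf(" (and %d more)", length(missing) - 10L))
  }
  sf <- jsonlite::fromJSON(scalefactors_path)
  mpp <- sf$microns_per_pixel
  if (is.null(mpp) || !is.finite(mpp) || mpp <= 0) {
    stop("scale factors must provide a positive `microns_per_pixel`")
  }
  size_px <- 2 / mpp
  pos <- pos[match(colnames(m), pos$barcode), , drop = FALSE]
  grid <- square_grid(
    data.frame(square_id = pos$barcode,
               x = pos$pxl_col_in_fullres,
               y = pos$pxl_row_in_fullres,
               row = pos$array_row,
               col = pos$array_col),
    size_px = size_px
  )
  list(grid = grid, counts = m)
}

read_mtx_dir <- function(path) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    dirp <- path
  } else {
    mtx <- path
    dirp <- dirname(path)
  }
  if (!file.exists(mtx)) stop("matrix file not found: ", mtx)
  feat <- file.path(dirp, "features.tsv")
  if (!file.exists(feat)) feat <- file.path(dirp, "genes.tsv")
  bc <- file.path(dirp, "barcodes.tsv")
  if (!file.exists(feat) || !file.exists(bc)) {
    stop("features/barcodes files must accompany the matrix in ", dirp)
  }
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  features <- utils::read.delim(feat, header = FALSE, stringsAsFactors = FALSE)
  barcodes <- utils::read.delim(bc, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(features) != nrow(m) || nrow(barcodes) != ncol(m)) {
    stop("features/barcodes dimensions do not match the matrix")
  }
  # 10x convention: gene id, gene symbol, ...; single-column files use it directly
  sym <- if (ncol(features) >= 2L) features[[2L]] else features[[1L]]
  rownames(m) <- make.unique(sym)
  colnames(m) <- barcodes[[1L]]
  m
}

read_positions <- function(path) {
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("reading parquet positions requires the `arrow` package")
    }
    pos <- as.data.frame(arrow::read_parquet(path))
  } else {
    pos <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("barcode", "array_row", "array_col",
            "pxl_row_in_fullres", "pxl_col_in_fullres")
  if (!all(need %in% names(pos))) {
    stop("positions file must have columns: ", paste(need, collapse = ", "))
  }
  pos
}

#' Write a sparse count matrix in MatrixMarket + features/barcodes layout
#'
#' @param counts genes x units sparse (or dense) matrix with dimnames.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_mtx_dir <- function(counts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  Matrix::writeMM(counts, file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(id = rownames(counts), symbol = rownames(counts)),
                     file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Write a square grid as a CSV positions table plus scale-factors JSON
#'
#' Inverse of the loading convention used by \code{\link{read_visiumhd}}.
#'
#' @param grid a \code{\link{square_grid}}.
#' @param positions_path output CSV path.
#' @param scalefactors_path optional output JSON path.
#' @return \code{positions_path}, invisibly.
#' @export
write_positions <- function(grid, positions_path, scalefactors_path = NULL) {
  df <- data.frame(barcode = grid$square_id, in_tissue = 1L,
                   array_row = grid$row, array_col = grid$col,
                   pxl_row_in_fullres = grid$y, pxl_col_in_fullres = grid$x)
  utils::write.csv(df, positions_path, row.names = FALSE, quote = FALSE)
  if (!is.null(scalefactors_path)) {
    jsonlite::write_json(list(microns_per_pixel = 2 / grid_size_px(grid)),
                         scalefactors_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(positions_path)
}

#' Read nuclei segmentation polygons from GeoJSON
#'
#' Accepts an RFC 7946 FeatureCollection of Polygon features in the same
#' full-resolution pixel frame as the square grid. Only the exterior ring
#' of each polygon is kept (interior rings are ignored: nuclei are simple
#' blobs). Non-polygon geometries are skipped with a warning;
#' self-intersecting contours are rejected with a warning.
#'
#' @param path GeoJSON file.
#' @return List of \code{\link{nucleus_polygon}} objects.
#' @export
read_nuclei_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  out <- list()
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    geom <- f$geometry
    if (is.null(geom) || !identical(geom$type, "Polygon")) {
      warning(sprintf("feature %d: skipping non-polygon geometry (%s)",
                      i, if (is.null(geom)) "none" else geom$type))
      next
    }
    ring <- geom$coordinates[[1L]]
    contour <- do.call(rbind, lapply(ring, function(p) c(p[[1L]], p[[2L]])))
    id <- f$id
    if (is.null(id)) id <- f$properties$id
    if (is.null(id)) id <- as.character(i)
    if (poly_self_intersects(dedup_closing(contour))) {
      warning(sprintf("nucleus %s: rejecting self-intersecting contour", id))
      next
    }
    out[[length(out) + 1L]] <- nucleus_polygon(id, contour)
  }
  out
}

dedup_closing <- function(contour) {
  n <- nrow(contour)
  if (n > 1L && all(contour[1L, ] == contour[n, ])) contour[-n, , drop = FALSE]
  else contour
}

#' Write nuclei polygons as GeoJSON
#'
#' @param nuclei list of \code{\link{nucleus_polygon}} objects.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_nuclei_geojson <- function(nuclei, path) {
  feats <- lapply(nuclei, function(nu) {
    ring <- rbind(nu$contour, nu$contour[1L, , drop = FALSE])
    list(type = "Feature",
         properties = list(id = nu$nucleus_id),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)), function(i)
                           as.numeric(ring[i, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a generic count matrix plus cell coordinates
#'
#' Platform-agnostic entry point: any gene x cell count matrix (CSV with
#' gene names in the first column, or a MatrixMarket directory) plus a CSV
#' coordinate table with columns \code{cell}, \code{x}, \code{y}. Cells
#' are aligned by id across the two inputs; any mismatch is an error.
#'
#' @param counts_path CSV file or MatrixMarket directory.
#' @param coords_path CSV file of cell coordinates.
#' @return A \code{\link{cell_matrix}}.
#' @export
read_generic <- function(counts_path, coords_path) {
  if (dir.exists(counts_path) || grepl("\\.mtx$", counts_path)) {
    counts <- read_mtx_dir(counts_path)
  } else {
    df <- utils::read.csv(counts_path, stringsAsFactors = FALSE, check.names = FALSE)
    counts <- as.matrix(df[, -1L, drop = FALSE])
    rownames(counts) <- df[[1L]]
  }
  coords <- utils::read.csv(coords_path, stringsAsFactors = FALSE)
  need <- c("cell", "x", "y")
  if (!all(need %in% names(coords))) {
    stop("coordinates file must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(coords$cell)) stop("duplicate cell ids in coordinates file")
  if (anyDuplicated(colnames(counts))) stop("duplicate cell ids in count matrix")
  if (!setequal(coords$cell, colnames(counts))) {
    stop("cell ids differ between counts and coordinates: ",
         paste(utils::head(c(setdiff(coords$cell, colnames(counts)),
                             setdiff(colnames(counts), coords$cell)), 10L),
               collapse = ", "))
  }
  xy <- as.matrix(coords[match(colnames(counts), coords$cell), c("x", "y")])
  rownames(xy) <- colnames(counts)
  cell_matrix(counts, xy)
}

#' Write a \code{cell_matrix} as MatrixMarket counts plus coordinate CSV
#'
#' @param cells a \code{\link{cell_matrix}}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_cell_matrix <- function(cells, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mtx_dir(cells$counts, dir)
  df <- data.frame(cell = colnames(cells$counts),
                   x = cells$coords[, 1L], y = cells$coords[, 2L])
  if (!is.null(cells$meta)) df <- cbind(df, cells$meta)
  if (!is.null(cells$clusters)) df$cluster <- cells$clusters
  utils::write.csv(df, file.path(dir, "cells.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a transcript table
#'
#' @param path CSV (or parquet) file with columns \code{x}, \code{y},
#'   \code{gene}, \code{cell} (gold-standard cell id, empty or "UNASSIGNED"
#'   for unassigned transcripts).
#' @return data.frame with columns \code{x}, \code{y}, \code{gene},
#'   \code{cell}; unassigned entries normalized to \code{"UNASSIGNED"}.
#' @export
read_transcripts <- function(path) {
  tx <- if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("reading parquet transcripts requires the `arrow` package")
    }
    as.data.frame(arrow::read_parquet(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("x", "y", "gene")
  if (!all(need %in% names(tx))) {
    stop("transcript table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(!nzchar(tx$gene))) stop("transcript table has empty gene names")
  if (is.null(tx$cell)) tx$cell <- "UNASSIGNED"
  tx$cell[is.na(tx$cell) | !nzchar(tx$cell)] <- "UNASSIGNED"
  tx[, c("x", "y", "gene", "cell")]
}

#' Read gene sets in GMT format
#'
#' @param path GMT file (one set per line: name, description, genes...).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}
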