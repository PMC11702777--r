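#' Nucleus polygon
#'
#' A segmented cell nucleus: an ordered, implicitly closed contour in
#' full-resolution pixel coordinates together with its shoelace area and
#' centroid. Contours must be simple (non-self-intersecting) and have at
#' least three vertices.
#'
#' @param nucleus_id identifier (coerced to character).
#' @param contour numeric N x 2 matrix of (x, y) vertices.
#' @param area optional precomputed area; must agree with the shoelace area
#'   within 1e-6 relative tolerance, otherwise an error is raised.
#' @return An object of class \code{nucleus_polygon} with fields
#'   \code{nucleus_id}, \code{contour}, \code{area}, \code{centroid}.
#' @export
nucleus_polygon <- function(nucleus_id, contour, area = NULL) {
  contour <- as.matrix(contour)
  storage.mode(contour) <- "double"
  if (ncol(contour) != 2L) stop("contour must have two columns (x, y)")
  # drop an explicit closing vertex if present
  n <- nrow(contour)
  if (n > 1L && all(contour[1L, ] == contour[n, ])) {
    contour <- contour[-n, , drop = FALSE]
  }
  if (nrow(contour) < 3L) stop("contour must have at least 3 distinct vertices")
  if (!all(is.finite(contour))) stop("contour coordinates must be finite")
  a <- poly_area(contour)
  if (!is.null(area) && abs(area - a) > 1e-6 * max(abs(area), 1e-12)) {
    stop(sprintf("stored area %g disagrees with shoelace area %g for nucleus %s",
                 area, a, nucleus_id))
  }
  structure(
    list(nucleus_id = as.character(nucleus_id), contour = contour,
         area = a, centroid = poly_centroid(contour)),
    class = "nucleus_polygon"
  )
}

#' @export
print.nucleus_polygon <- function(x, ...) {
  cat(sprintf("<nucleus_polygon %s: %d vertices, area %.2f px^2, centroid (%.1f, %.1f)>\n",
              x$nucleus_id, nrow(x$contour), x$area, x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' Square grid
#'
#' The lattice of measurement squares. Each square is axis-aligned and
#' half-open, occupying \code{[x - size/2, x + size/2)} by
#' \code{[y - size/2, y + size/2)} around its center, so the lattice tiles
#' the plane without double-counting boundary points.
#'
#' @param squares data.frame with columns \code{square_id}, \code{x},
#'   \code{y} (centers, full-resolution pixels), \code{row}, \code{col}
#'   (array lattice indices).
#' @param size_px side length of a square in pixels (> 0).
#' @return Object of class \code{square_grid}: the data.frame with a
#'   \code{size_px} attribute.
#' @export
square_grid <- function(squares, size_px) {
  squares <- as.data.frame(squares)
  need <- c("square_id", "x", "y", "row", "col")
  if (!all(need %in% names(squares))) {
    stop("squares must have columns: ", paste(need, collapse = ", "))
  }
  if (!is.numeric(size_px) || length(size_px) != 1L || size_px <= 0) {
    stop("`size_px` must be a single positive number")
  }
  squares$square_id <- as.character(squares$square_id)
  if (anyDuplicated(squares$square_id)) stop("duplicate square ids")
  if (anyDuplicated(squares[, c("row", "col")])) {
    stop("duplicate (row, col) lattice positions")
  }
  structure(squares, size_px = size_px, class = c("square_grid", "data.frame"))
}

#' @export
print.square_grid <- function(x, ...) {
  cat(sprintf("<square_grid: %d squares, size %.3f px>\n", nrow(x), attr(x, "size_px")))
  invisible(x)
}

#' Grid square side length
#' @param grid a \code{square_grid}.
#' @return Side length in pixels.
#' @export
grid_size_px <- function(grid) attr(grid, "size_px")

#' Single-cell expression matrix with spatial coordinates
#'
#' Container for aggregated (or directly measured) single-cell expression:
#' a sparse genes x cells count matrix, per-cell 2D coordinates, optional
#' per-cell metadata (nucleus and expanded areas, square counts) and
#' optional cluster labels.
#'
#' @param counts genes x cells matrix (coerced to \code{dgCMatrix});
#'   non-negative, with unique row and column names.
#' @param coords cells x 2 numeric matrix of (x, y); rownames must match
#'   the columns of \code{counts}.
#' @param meta optional data.frame of per-cell metadata (rownames = cells).
#' @param clusters optional integer vector of per-cell cluster labels.
#' @return Object of class \code{cell_matrix}.
#' @export
cell_matrix <- function(counts, coords, meta = NULL, clusters = NULL) {
  counts <- methods::as(methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                                "dMatrix"), "generalMatrix"), "CsparseMatrix")
  # a zero-cell matrix (everything filtered) is legal; Matrix normalizes
  # character(0) dimnames to NULL, so skip the name check for it
  if (is.null(rownames(counts)) ||
      (ncol(counts) > 0L && is.null(colnames(counts)))) {
    stop("counts must carry gene (row) and cell (column) names")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate gene names")
  if (anyDuplicated(colnames(counts))) stop("duplicate cell ids")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 2L) stop("coords must have two columns")
  if (nrow(coords) != ncol(counts)) stop("coords rows must match counts columns")
  if (!is.null(rownames(coords))) {
    if (!identical(rownames(coords), colnames(counts))) {
      if (!setequal(rownames(coords), colnames(counts))) {
        stop("coords rownames do not match cell ids")
      }
      coords <- coords[colnames(counts), , drop = FALSE]
    }
  } else {
    rownames(coords) <- colnames(counts)
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  colnames(coords) <- c("x", "y")
  if (!is.null(clusters)) {
    clusters <- as.integer(clusters)
    if (length(clusters) != ncol(counts)) stop("clusters length must match cells")
  }
  structure(
    list(counts = counts, coords = coords, meta = meta, clusters = clusters),
    class = "cell_matrix"
  )
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("<cell_matrix: %d genes x %d cells%s>\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$clusters)) "" else
                sprintf(", %d clusters", length(unique(x$clusters)))))
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

#' Subset a cell_matrix by cells (and optionally genes)
#'
#' @param x a \code{cell_matrix}.
#' @param cells cell ids or index vector.
#' @param genes optional gene names or index vector.
#' @return A \code{cell_matrix} restricted to the requested cells/genes.
#' @export
subset_cells <- function(x, cells, genes = NULL) {
  stopifnot(inherits(x, "cell_matrix"))
  counts <- x$counts[, cells, drop = FALSE]
  if (!is.null(genes)) counts <- counts[genes, , drop = FALSE]
  keep <- colnames(counts)
  cell_matrix(counts, x$coords[keep, , drop = FALSE],
              meta = if (!is.null(x$meta)) x$meta[keep, , drop = FALSE],
              clusters = if (!is.null(x$clusters)) {
                x$clusters[match(keep, colnames(x$counts))]
              })
}
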