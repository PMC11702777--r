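#' Filter out abnormally large nuclei
#'
#' Removes segmentation artifacts (merged nuclei, smears) by thresholding
#' log areas: a nucleus is dropped when its natural-log area exceeds the
#' mean log area plus two sample standard deviations.
#'
#' @param nuclei non-empty list of \code{\link{nucleus_polygon}} objects.
#' @return The retained sublist. With a single nucleus the standard
#'   deviation is undefined; the nucleus is retained with a warning.
#' @export
filter_large_nuclei <- function(nuclei) {
  if (length(nuclei) == 0L) stop("no nuclei supplied")
  la <- log(vapply(nuclei, function(nu) nu$area, numeric(1)))
  if (length(la) == 1L) {
    warning("single nucleus: size filter skipped (sd undefined)")
    return(nuclei)
  }
  cutoff <- mean(la) + 2 * stats::sd(la)
  # tolerance absorbs floating-point noise when all areas are (near) equal,
  # where sd is a few ulps and no nucleus is a genuine outlier
  nuclei[la <= cutoff + 1e-10 * max(1, abs(cutoff))]
}

# numeric-aware ordering key for opaque nucleus ids: "10" sorts after "9"
# when all ids are numeric, lexicographic otherwise
.id_rank <- function(ids) {
  num <- suppressWarnings(as.numeric(ids))
  if (!anyNA(num)) rank(num, ties.method = "first") else rank(ids, ties.method = "first")
}

#' Assign lattice squares to nuclei by largest approximate overlap
#'
#' Each considered square is assigned to the polygon with which it shares
#' the largest approximate overlap area (the 10 x 10 subsquare centroid
#' count, \code{\link{approximate_overlap}}). Squares with zero overlap for
#' every polygon stay unassigned. Ties are broken deterministically in
#' favor of the smallest nucleus id. When an existing assignment is given,
#' only currently unassigned squares are considered and previous
#' assignments are never changed (the second, expanded-nucleus pass).
#'
#' @param grid a \code{\link{square_grid}}.
#' @param polygons list of \code{\link{nucleus_polygon}} (original or
#'   expanded).
#' @param existing optional assignment from a previous pass.
#' @param stage label recorded for squares assigned in this pass,
#'   \code{"NUCLEUS"} or \code{"EXPANDED"}.
#' @return A data.frame (one row per grid square, aligned with the grid)
#'   with columns \code{square_id}, \code{cell_id} (NA when unassigned),
#'   \code{stage}, \code{overlap}.
#' @export
assign_squares <- function(grid, polygons, existing = NULL, stage = "NUCLEUS") {
  size <- grid_size_px(grid)
  half <- size / 2
  cx <- grid$x - half
  cy <- grid$y - half
  n_sq <- nrow(grid)
  if (is.null(existing)) {
    existing <- data.frame(square_id = grid$square_id,
                           cell_id = NA_character_,
                           stage = NA_character_,
                           overlap = 0,
                           stringsAsFactors = FALSE)
  } else {
    stopifnot(identical(existing$square_id, grid$square_id))
    existing <- existing[, c("square_id", "cell_id", "stage", "overlap")]
  }
  open <- is.na(existing$cell_id)
  if (!any(open) || length(polygons) == 0L) return(existing)

  best_overlap <- rep(0, n_sq)
  best_cell <- rep(NA_character_, n_sq)
  best_rank <- rep(Inf, n_sq)
  ranks <- .id_rank(vapply(polygons, function(p) p$nucleus_id, character(1)))

  offs <- (seq_len(10L) - 0.5) * size / 10
  sub_dx <- rep(offs, times = 10L)
  sub_dy <- rep(offs, each = 10L)
  sub_area <- size^2 / 100

  for (pi in seq_along(polygons)) {
    poly <- polygons[[pi]]
    bb <- apply(poly$contour, 2L, range)
    cand <- which(open &
                    cx < bb[2L, 1L] & cx + size > bb[1L, 1L] &
                    cy < bb[2L, 2L] & cy + size > bb[1L, 2L])
    if (!length(cand)) next
    px <- rep(cx[cand], each = 100L) + rep.int(sub_dx, length(cand))
    py <- rep(cy[cand], each = 100L) + rep.int(sub_dy, length(cand))
    hits <- points_in_polygon(px, py, poly$contour)
    cnt <- colSums(matrix(hits, nrow = 100L))
    pos <- cnt > 0
    if (!any(pos)) next
    idx <- cand[pos]
    ov <- cnt[pos] * sub_area
    better <- ov > best_overlap[idx] |
      (ov == best_overlap[idx] & ranks[pi] < best_rank[idx])
    upd <- idx[better]
    best_overlap[upd] <- ov[better]
    best_cell[upd] <- poly$nucleus_id
    best_rank[upd] <- ranks[pi]
  }

  newly <- open & !is.na(best_cell)
  existing$cell_id[newly] <- best_cell[newly]
  existing$stage[newly] <- stage
  existing$overlap[newly] <- best_overlap[newly]
  existing
}

#' Remove abnormal cells after square assignment
#'
#' A cell is abnormal when (a) no square is assigned to it, (b) the total
#' area of its assigned squares is less than half the cell's area (by
#' default the expanded-nucleus area, which approximates the whole cell),
#' or (c) its assigned squares do not form a single 4-connected component
#' on the (row, col) lattice.
#'
#' @param assignment assignment data.frame from \code{\link{assign_squares}}
#'   (both passes complete).
#' @param grid the \code{\link{square_grid}}.
#' @param nuclei retained original nuclei (list).
#' @param expanded matching expanded nuclei (list, same order).
#' @param area_reference \code{"expanded"} (default) or \code{"nucleus"}:
#'   which area rule (b) compares against.
#' @return Character vector of retained cell ids.
#' @export
remove_abnormal_cells <- function(assignment, grid, nuclei, expanded,
                                  area_reference = c("expanded", "nucleus")) {
  area_reference <- match.arg(area_reference)
  size <- grid_size_px(grid)
  ids <- vapply(nuclei, function(nu) nu$nucleus_id, character(1))
  ref <- if (area_reference == "expanded") expanded else nuclei
  ref_area <- vapply(ref, function(nu) nu$area, numeric(1))
  names(ref_area) <- ids
  assigned <- !is.na(assignment$cell_id)
  keep <- character(0)
  for (cid in ids) {
    sel <- assigned & assignment$cell_id == cid
    n_sq <- sum(sel)
    if (n_sq == 0L) next                                   # rule (a)
    if (n_sq * size^2 < 0.5 * ref_area[[cid]]) next        # rule (b)
    rc <- cbind(grid$row[sel], grid$col[sel])
    if (!.single_component4(rc)) next                      # rule (c)
    keep <- c(keep, cid)
  }
  keep
}

# TRUE when the lattice points form one 4-connected component (flood fill)
.single_component4 <- function(rc) {
  n <- nrow(rc)
  if (n <= 1L) return(TRUE)
  key <- paste(rc[, 1L], rc[, 2L])
  idx <- stats::setNames(seq_len(n), key)
  seen <- logical(n)
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack)) {
    i <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    nb <- c(paste(rc[i, 1L] + 1L, rc[i, 2L]), paste(rc[i, 1L] - 1L, rc[i, 2L]),
            paste(rc[i, 1L], rc[i, 2L] + 1L), paste(rc[i, 1L], rc[i, 2L] - 1L))
    for (k in nb) {
      j <- idx[k]
      if (!is.na(j) && !seen[[j]]) {
        seen[[j]] <- TRUE
        stack <- c(stack, j)
      }
    }
  }
  all(seen)
}

#' Aggregate square counts into a single-cell matrix
#'
#' Sums each gene's counts over the squares assigned to every retained
#' cell. The cell coordinate is the nucleus centroid; per-cell metadata
#' records nucleus area, expanded area, and the number of squares.
#'
#' @param assignment assignment data.frame (both passes complete).
#' @param square_counts sparse genes x squares count matrix whose columns
#'   match \code{assignment$square_id}.
#' @param retained cell ids to keep (from
#'   \code{\link{remove_abnormal_cells}}).
#' @param nuclei,expanded retained original and expanded nuclei lists.
#' @return A \code{\link{cell_matrix}} (zero cells when nothing is
#'   retained).
#' @export
aggregate_counts <- function(assignment, square_counts, retained, nuclei, expanded) {
  stopifnot(identical(assignment$square_id, colnames(square_counts)))
  ids <- vapply(nuclei, function(nu) nu$nucleus_id, character(1))
  sel_cells <- match(retained, ids)
  stopifnot(!anyNA(sel_cells))
  in_cell <- !is.na(assignment$cell_id) & assignment$cell_id %in% retained
  ncell <- length(retained)
  if (ncell == 0L || !any(in_cell)) {
    counts <- Matrix::Matrix(0, nrow(square_counts), 0, sparse = TRUE,
                             dimnames = list(rownames(square_counts), character(0)))
    return(cell_matrix(counts, matrix(numeric(0), 0, 2)))
  }
  j <- match(assignment$cell_id[in_cell], retained)
  ind <- Matrix::sparseMatrix(i = which(in_cell), j = j,
                              x = 1, dims = c(nrow(assignment), ncell),
                              dimnames = list(NULL, retained))
  counts <- square_counts %*% ind
  coords <- t(vapply(nuclei[sel_cells], function(nu) nu$centroid, numeric(2)))
  rownames(coords) <- retained
  meta <- data.frame(
    nucleus_area = vapply(nuclei[sel_cells], function(nu) nu$area, numeric(1)),
    expanded_area = vapply(expanded[sel_cells], function(nu) nu$area, numeric(1)),
    n_squares = as.integer(tabulate(j, ncell)),
    row.names = retained
  )
  cell_matrix(counts, coords, meta = meta)
}

#' Full square-to-cell assignment pipeline
#'
#' Chains nucleus size filtering, the nucleus-overlap assignment pass,
#' centroid-anchored nucleus expansion, the expanded-nucleus pass over the
#' remaining squares, abnormal-cell removal, and count aggregation.
#'
#' @param grid a \code{\link{square_grid}}.
#' @param square_counts sparse genes x squares counts (columns = square ids
#'   in grid order).
#' @param nuclei list of \code{\link{nucleus_polygon}}.
#' @param area_ratio expanded-to-original area ratio (default 2: whole
#'   cells are typically about twice their nucleus area).
#' @param linear_ratio see \code{\link{expand_nucleus}}.
#' @param area_reference see \code{\link{remove_abnormal_cells}}.
#' @return List with elements \code{cells} (a \code{\link{cell_matrix}}),
#'   \code{assignment} (square-level table), \code{nuclei} (retained
#'   originals) and \code{expanded}.
#' @export
assign_cells <- function(grid, square_counts, nuclei, area_ratio = 2,
                         linear_ratio = FALSE,
                         area_reference = c("expanded", "nucleus")) {
  stopifnot(identical(grid$square_id, colnames(square_counts)))
  retained_nuclei <- filter_large_nuclei(nuclei)
  pass1 <- assign_squares(grid, retained_nuclei, stage = "NUCLEUS")
  expanded <- lapply(retained_nuclei, expand_nucleus, area_ratio = area_ratio,
                     linear_ratio = linear_ratio)
  pass2 <- assign_squares(grid, expanded, existing = pass1, stage = "EXPANDED")
  keep <- remove_abnormal_cells(pass2, grid, retained_nuclei, expanded,
                                area_reference = area_reference)
  cells <- aggregate_counts(pass2, square_counts, keep, retained_nuclei, expanded)
  list(cells = cells, assignment = pass2,
       nuclei = retained_nuclei, expanded = expanded)
}
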