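#' Central rectangular subset of an evaluation dataset
#'
#' Restricts transcripts and segmentation to a rectangle centered at the
#' data bounding-box center whose width and height are \code{frac} of the
#' originals. Cells are kept when their nucleus centroid falls inside;
#' their transcripts follow. Unassigned transcripts are kept when they
#' fall inside the rectangle.
#'
#' @param transcripts data.frame (x, y, gene, cell).
#' @param nuclei list of \code{\link{nucleus_polygon}}.
#' @param cells optional matching list of whole-cell polygons.
#' @param frac side fraction in (0, 1].
#' @return List with the subset \code{transcripts}, \code{nuclei},
#'   \code{cells}; errors when the subset is empty.
#' @export
subset_rectangle <- function(transcripts, nuclei, cells = NULL, frac = 0.2) {
  if (frac <= 0 || frac > 1) stop("`frac` must be in (0, 1]")
  cx <- vapply(nuclei, function(nu) nu$centroid[1L], numeric(1))
  cy <- vapply(nuclei, function(nu) nu$centroid[2L], numeric(1))
  xr <- range(c(transcripts$x, cx)); yr <- range(c(transcripts$y, cy))
  mid <- c(mean(xr), mean(yr))
  half <- c(diff(xr), diff(yr)) * frac / 2
  inside <- function(x, y) x >= mid[1L] - half[1L] & x <= mid[1L] + half[1L] &
    y >= mid[2L] - half[2L] & y <= mid[2L] + half[2L]
  keep_nu <- inside(cx, cy)
  if (!any(keep_nu)) stop("rectangle subset contains no cells")
  ids <- vapply(nuclei, function(nu) nu$nucleus_id, character(1))[keep_nu]
  keep_tx <- transcripts$cell %in% ids |
    (transcripts$cell == "UNASSIGNED" & inside(transcripts$x, transcripts$y))
  list(transcripts = transcripts[keep_tx, , drop = FALSE],
       nuclei = nuclei[keep_nu],
       cells = if (!is.null(cells)) cells[keep_nu])
}

#' Remove control-probe transcripts
#'
#' Drops transcripts whose gene name starts with "NegControlProbe",
#' "NegControlCodeword", or "UnassignedCodeword".
#'
#' @param transcripts data.frame with a \code{gene} column.
#' @return The filtered data.frame.
#' @export
drop_controls <- function(transcripts) {
  bad <- grepl("^(NegControlProbe|NegControlCodeword|UnassignedCodeword)",
               transcripts$gene)
  transcripts[!bad, , drop = FALSE]
}

#' Tile a bounding box with a square lattice
#'
#' Axis-aligned half-open squares anchored at the box's minimum corner;
#' the lattice covers the box completely (the last row/column may extend
#' past the maximum edge).
#'
#' @param bounds numeric vector (xmin, xmax, ymin, ymax).
#' @param size_px square side length (> 0).
#' @return A \code{\link{square_grid}} with attribute \code{"origin"}.
#' @export
gridify <- function(bounds, size_px) {
  if (size_px <= 0) stop("`size_px` must be positive")
  xmin <- bounds[1L]; xmax <- bounds[2L]; ymin <- bounds[3L]; ymax <- bounds[4L]
  nx <- max(1L, ceiling((xmax - xmin) / size_px))
  ny <- max(1L, ceiling((ymax - ymin) / size_px))
  col <- rep(seq_len(nx) - 1L, times = ny)
  row <- rep(seq_len(ny) - 1L, each = nx)
  g <- square_grid(
    data.frame(square_id = paste0("sq_", row, "_", col),
               x = xmin + (col + 0.5) * size_px,
               y = ymin + (row + 0.5) * size_px,
               row = row, col = col),
    size_px = size_px
  )
  attr(g, "origin") <- c(xmin, ymin)
  g
}

#' Bin transcripts onto a square lattice
#'
#' @param transcripts data.frame (x, y, gene, ...).
#' @param grid a grid from \code{\link{gridify}}.
#' @return List: \code{counts} (sparse genes x squares) and
#'   \code{square} (per-transcript square id).
#' @export
bin_transcripts <- function(transcripts, grid) {
  size <- grid_size_px(grid)
  origin <- attr(grid, "origin")
  nx <- max(grid$col) + 1L; ny <- max(grid$row) + 1L
  col <- pmin(pmax(floor((transcripts$x - origin[1L]) / size), 0L), nx - 1L)
  row <- pmin(pmax(floor((transcripts$y - origin[2L]) / size), 0L), ny - 1L)
  sq <- paste0("sq_", row, "_", col)
  genes <- sort(unique(transcripts$gene))
  counts <- Matrix::sparseMatrix(
    i = match(transcripts$gene, genes),
    j = match(sq, grid$square_id),
    x = 1,
    dims = c(length(genes), nrow(grid)),
    dimnames = list(genes, grid$square_id)
  )
  list(counts = counts, square = sq)
}

#' 8-micron binning baseline
#'
#' The platform's default workflow pools squares into an 8-micron lattice
#' and treats squares as cells. For benchmarking, each whole cell is
#' assigned to the 8-micron square with the largest approximate overlap
#' (same subsquare approximation as the nucleus assignment); a square may
#' serve several cells, and each such cell receives all transcripts that
#' fall in its square.
#'
#' @param cells list of whole-cell polygons (\code{nucleus_polygon}
#'   objects).
#' @param grid8 8-micron grid from \code{\link{gridify}}.
#' @return data.frame with columns \code{cell_id}, \code{square_id}
#'   (NA when a cell overlaps no square).
#' @export
bin8_baseline <- function(cells, grid8) {
  size <- grid8_size <- grid_size_px(grid8)
  half <- size / 2
  cx <- grid8$x - half; cy <- grid8$y - half
  out <- data.frame(cell_id = vapply(cells, function(p) p$nucleus_id, character(1)),
                    square_id = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(cells)) {
    poly <- cells[[i]]
    bb <- apply(poly$contour, 2L, range)
    cand <- which(cx < bb[2L, 1L] & cx + size > bb[1L, 1L] &
                    cy < bb[2L, 2L] & cy + size > bb[1L, 2L])
    if (!length(cand)) next
    ov <- vapply(cand, function(j)
      approximate_overlap(cx[j], cy[j], size, poly$contour), numeric(1))
    if (max(ov) <= 0) next
    out$square_id[i] <- grid8$square_id[cand[which.max(ov)]]
  }
  out
}

#' Transcript mapping accuracy
#'
#' Proportion of transcripts whose predicted and gold-standard
#' assignments match: either both name the same cell or both are
#' \code{"UNASSIGNED"}.
#'
#' @param predicted,gold character vectors over the same transcripts.
#' @return Accuracy in [0, 1].
#' @export
mapping_accuracy <- function(predicted, gold) {
  stopifnot(length(predicted) == length(gold))
  mean(predicted == gold)
}

#' Resolve multiply-assigned squares to single cells
#'
#' For the binning baseline's accuracy metric only: each square claimed
#' by several cells is given to one of them uniformly at random (seeded),
#' making the square-to-cell map single-valued.
#'
#' @param map8 data.frame from \code{\link{bin8_baseline}}.
#' @param rng_seed seed for the random choice.
#' @return Named character vector: square id -> owning cell id.
#' @export
resolve_bin8_ties <- function(map8, rng_seed = 0) {
  set.seed(rng_seed)
  assigned <- map8[!is.na(map8$square_id), , drop = FALSE]
  vapply(split(assigned$cell_id, assigned$square_id), function(cc) {
    if (length(cc) == 1L) cc else sample(cc, 1L)
  }, character(1))
}

#' Median across-gene expression correlation between two count matrices
#'
#' Cells with at least \code{min_reads} total counts in both matrices are
#' log-normalized (scale factor 100), per-gene scaled, and compared cell
#' by cell with the Pearson correlation across genes; the median over
#' cells is returned. Cells whose values have zero variance in either
#' matrix are excluded with a warning.
#'
#' @param method_counts,gold_counts genes x cells count matrices sharing
#'   ids.
#' @param min_reads per-cell total-count threshold (default 10).
#' @param scale_factor normalization scale factor (default 100).
#' @return Median correlation.
#' @export
expression_agreement <- function(method_counts, gold_counts,
                                 min_reads = 10, scale_factor = 100) {
  genes <- intersect(rownames(method_counts), rownames(gold_counts))
  keep_m <- colnames(method_counts)[Matrix::colSums(method_counts) >= min_reads]
  keep_g <- colnames(gold_counts)[Matrix::colSums(gold_counts) >= min_reads]
  shared <- intersect(keep_m, keep_g)
  if (length(shared) < 3L) stop("fewer than 3 shared cells pass the read threshold")
  a <- .scale_rows(as.matrix(lognormalize(method_counts[genes, shared, drop = FALSE],
                                          scale_factor)))
  b <- .scale_rows(as.matrix(lognormalize(gold_counts[genes, shared, drop = FALSE],
                                          scale_factor)))
  cors <- vapply(seq_along(shared), function(j) {
    if (stats::sd(a[, j]) == 0 || stats::sd(b[, j]) == 0) return(NA_real_)
    stats::cor(a[, j], b[, j])
  }, numeric(1))
  if (anyNA(cors)) {
    warning(sprintf("%d cell(s) with zero variance excluded from the median",
                    sum(is.na(cors))))
  }
  stats::median(cors, na.rm = TRUE)
}

.scale_rows <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1L, stats::sd)
  s[s == 0] <- 1
  (m - mu) / s
}

#' Cell clustering agreement (adjusted Rand index)
#'
#' @param labels_a,labels_b partitions of the same cells (named vectors;
#'   aligned by name when names are present).
#' @return Permutation-model adjusted Rand index.
#' @export
clustering_agreement <- function(labels_a, labels_b) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    shared <- intersect(names(labels_a), names(labels_b))
    labels_a <- labels_a[shared]; labels_b <- labels_b[shared]
  }
  stopifnot(length(labels_a) == length(labels_b))
  mclust::adjustedRandIndex(labels_a, labels_b)
}

#' Benchmark square-to-cell assignment against a gold standard
#'
#' Runs the full nucleus-based assignment on a transcript-level dataset
#' with known whole-cell segmentation, plus the 8-micron binning
#' baseline, and reports the three benchmark metrics per method:
#' transcript mapping accuracy, median across-gene correlation of the
#' per-cell expression with the gold standard, and clustering agreement
#' (ARI) with clusters derived from the gold-standard expression.
#'
#' @param transcripts data.frame (x, y, gene, cell) with gold-standard
#'   cell assignments ("UNASSIGNED" allowed).
#' @param nuclei nucleus polygons.
#' @param cell_polys matching whole-cell polygons (gold segmentation).
#' @param size_px pixels per 2 microns (the fine lattice pitch; the
#'   baseline lattice is 4x coarser).
#' @param area_ratio nucleus expansion ratio.
#' @param rng_seed seed for the baseline's square-tie resolution.
#' @param cluster_args list of arguments for the clustering used in the
#'   ARI metric (n_pcs, resolution, seed).
#' @param min_reads read threshold for the correlation and ARI metrics.
#' @return data.frame with one row per method ("ctsvg", "bin8") and
#'   columns \code{accuracy}, \code{median_cor}, \code{ari}.
#' @export
evaluate_assignment <- function(transcripts, nuclei, cell_polys, size_px,
                                area_ratio = 2, rng_seed = 0,
                                cluster_args = list(n_pcs = 10,
                                                    resolution = 1.2,
                                                    seed = 0),
                                min_reads = 10) {
  transcripts <- drop_controls(transcripts)
  cx <- vapply(cell_polys, function(p) range(p$contour[, 1L]), numeric(2))
  cy <- vapply(cell_polys, function(p) range(p$contour[, 2L]), numeric(2))
  bounds <- c(min(transcripts$x, cx[1L, ]), max(transcripts$x, cx[2L, ]),
              min(transcripts$y, cy[1L, ]), max(transcripts$y, cy[2L, ]))
  gold <- transcripts$cell
  genes <- sort(unique(transcripts$gene))
  cell_ids <- vapply(cell_polys, function(p) p$nucleus_id, character(1))

  # nucleus-based fine-lattice assignment
  grid2 <- gridify(bounds, size_px)
  binned <- bin_transcripts(transcripts, grid2)
  asg <- assign_cells(grid2, binned$counts, nuclei, area_ratio = area_ratio)
  sq_cell <- stats::setNames(asg$assignment$cell_id, asg$assignment$square_id)
  retained <- colnames(asg$cells$counts)
  pred_ct <- sq_cell[binned$square]
  pred_ct[is.na(pred_ct) | !(pred_ct %in% retained)] <- "UNASSIGNED"
  acc_ct <- mapping_accuracy(unname(pred_ct), gold)

  # 8-micron baseline
  grid8 <- gridify(bounds, 4 * size_px)
  binned8 <- bin_transcripts(transcripts, grid8)
  map8 <- bin8_baseline(cell_polys, grid8)
  owner <- resolve_bin8_ties(map8, rng_seed = rng_seed)
  pred8 <- owner[binned8$square]
  pred8[is.na(pred8)] <- "UNASSIGNED"
  acc8 <- mapping_accuracy(unname(pred8), gold)

  # per-cell expression: gold, nucleus-based, baseline (double-counted)
  gold_counts <- .tx_cell_counts(transcripts, genes, cell_ids)
  ct_counts <- asg$cells$counts
  m8 <- map8[!is.na(map8$square_id), , drop = FALSE]
  tx8 <- transcripts[binned8$square %in% m8$square_id, , drop = FALSE]
  sq8 <- binned8$square[binned8$square %in% m8$square_id]
  cnt8 <- lapply(seq_len(nrow(m8)), function(i) {
    sel <- sq8 == m8$square_id[i]
    tabulate(match(tx8$gene[sel], genes), length(genes))
  })
  bin8_counts <- do.call(cbind, cnt8)
  dimnames(bin8_counts) <- list(genes, m8$cell_id)
  bin8_counts <- Matrix::Matrix(bin8_counts, sparse = TRUE)

  cor_ct <- expression_agreement(ct_counts, gold_counts, min_reads = min_reads)
  cor_8 <- expression_agreement(bin8_counts, gold_counts, min_reads = min_reads)

  cl_of <- function(counts) {
    keep <- colnames(counts)[Matrix::colSums(counts) >= min_reads]
    cm <- counts[, keep, drop = FALSE]
    cl <- cluster_cells(cm, n_pcs = min(cluster_args$n_pcs, min(dim(cm)) - 1L),
                        resolution = cluster_args$resolution,
                        seed = cluster_args$seed, scale_factor = 100)
    cl$labels
  }
  gold_cl <- cl_of(gold_counts)
  ari_ct <- clustering_agreement(cl_of(ct_counts), gold_cl)
  ari_8 <- clustering_agreement(cl_of(bin8_counts), gold_cl)

  data.frame(method = c("ctsvg", "bin8"),
             accuracy = c(acc_ct, acc8),
             median_cor = c(cor_ct, cor_8),
             ari = c(ari_ct, ari_8),
             stringsAsFactors = FALSE)
}

.tx_cell_counts <- function(transcripts, genes, cell_ids) {
  sel <- transcripts$cell %in% cell_ids
  Matrix::sparseMatrix(
    i = match(transcripts$gene[sel], genes),
    j = match(transcripts$cell[sel], cell_ids),
    x = 1,
    dims = c(length(genes), length(cell_ids)),
    dimnames = list(genes, cell_ids)
  )
}
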