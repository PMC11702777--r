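#' Quality-control filtering of cells and genes
#'
#' Cells with positive expression in at least \code{min_genes} genes are
#' retained first; genes with positive expression in at least
#' \code{min_cell_frac} of the retained cells are kept second. The gene
#' threshold compares the raw count of positive cells to
#' \code{min_cell_frac * n} with \code{>=} (no rounding).
#'
#' @param cells a \code{\link{cell_matrix}} of raw counts.
#' @param min_genes minimum number of positively expressed genes per cell.
#' @param min_cell_frac minimum fraction of retained cells in which a gene
#'   must be positive.
#' @return The filtered \code{\link{cell_matrix}}.
#' @export
qc_filter <- function(cells, min_genes = 300, min_cell_frac = 0.01) {
  stopifnot(inherits(cells, "cell_matrix"))
  pos <- cells$counts > 0
  keep_cells <- Matrix::colSums(pos) >= min_genes
  if (!any(keep_cells)) stop("QC removed every cell; lower `min_genes`")
  pos <- pos[, keep_cells, drop = FALSE]
  keep_genes <- Matrix::rowSums(pos) >= min_cell_frac * sum(keep_cells)
  subset_cells(cells, colnames(cells$counts)[keep_cells],
               genes = rownames(cells$counts)[keep_genes])
}

#' Library-size log-normalization
#'
#' Standard log normalization: each count is divided by its cell's total,
#' multiplied by \code{scale_factor}, and log1p-transformed:
#' \code{ln(1 + count / total * scale_factor)}. Zeros are preserved and
#' the transform is monotone within each cell.
#'
#' @param x a \code{\link{cell_matrix}} or a genes x cells count matrix.
#' @param scale_factor library-size scale factor (default 1e4; imaging
#'   panels with few genes typically use 100).
#' @return Sparse genes x cells matrix of normalized values.
#' @export
lognormalize <- function(x, scale_factor = 1e4) {
  counts <- if (inherits(x, "cell_matrix")) x$counts else
    methods::as(Matrix::Matrix(x, sparse = TRUE), "CsparseMatrix")
  totals <- Matrix::colSums(counts)
  if (any(totals <= 0)) stop("cells with zero total counts cannot be normalized")
  norm <- counts %*% Matrix::Diagonal(x = scale_factor / totals)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  methods::as(norm, "CsparseMatrix")
}

.quiet <- function(expr) suppressWarnings(suppressMessages(expr))

#' Dimension reduction and seeded graph clustering
#'
#' The standard single-cell recipe: highly variable gene selection
#' (vst, 2000 genes), per-gene scaling to mean 0 / sd 1 clipped at 10,
#' PCA, a shared-nearest-neighbor graph on the top PCs (k = 20), and
#' Louvain community detection at the given resolution with the given
#' random seed. Identical input and seed give identical labels. The SNN
#' graph is retained so that community detection can be re-run under
#' different seeds without recomputing the embedding
#' (\code{\link{reseed_clusters}}).
#'
#' @param x a \code{\link{cell_matrix}} of raw counts, or a genes x cells
#'   matrix. Matrices are treated as raw counts unless
#'   \code{normalized = TRUE}, in which case log-normalization is skipped
#'   and the values are used as-is.
#' @param n_pcs number of principal components (default 10).
#' @param resolution Louvain resolution (default 1.2).
#' @param seed random seed for community detection.
#' @param n_hvg number of highly variable genes.
#' @param k neighbors for the kNN graph.
#' @param normalized set TRUE when \code{x} already holds normalized
#'   expression.
#' @param scale_factor passed to the internal log-normalization.
#' @return Object of class \code{ctsvg_clusters}: list with \code{labels}
#'   (named integer vector, contiguous from 0), \code{seed},
#'   \code{resolution}, \code{n_pcs}, \code{snn} (the SNN graph), and
#'   \code{cell_ids}.
#' @export
cluster_cells <- function(x, n_pcs = 10, resolution = 1.2, seed = 0,
                          n_hvg = 2000, k = 20, normalized = FALSE,
                          scale_factor = 1e4) {
  mat <- if (inherits(x, "cell_matrix")) x$counts else x
  if (ncol(mat) < 2L) stop("clustering needs at least 2 cells")
  if (n_pcs > min(dim(mat)) - 1L) {
    stop("`n_pcs` must be smaller than min(n_cells, n_genes)")
  }
  so <- .quiet(Seurat::CreateSeuratObject(counts = mat,
                                          min.cells = 0, min.features = 0))
  if (normalized) {
    m <- as.matrix(mat)
    rownames(m) <- rownames(so)
    .quiet(SeuratObject::LayerData(so, "data") <- m)
  } else {
    so <- .quiet(Seurat::NormalizeData(so, scale.factor = scale_factor,
                                       verbose = FALSE))
  }
  so <- .quiet(Seurat::FindVariableFeatures(so, nfeatures = n_hvg, verbose = FALSE))
  so <- .quiet(Seurat::ScaleData(so, verbose = FALSE))
  so <- .quiet(Seurat::RunPCA(so, npcs = n_pcs, verbose = FALSE))
  so <- .quiet(Seurat::FindNeighbors(so, dims = seq_len(n_pcs), k.param = k,
                                     verbose = FALSE))
  snn <- so[[grep("_snn$", SeuratObject::Graphs(so), value = TRUE)[1L]]]
  labels <- .louvain_labels(snn, resolution, seed)
  structure(list(labels = labels, seed = seed, resolution = resolution,
                 n_pcs = n_pcs, snn = snn, cell_ids = names(labels)),
            class = "ctsvg_clusters")
}

.louvain_labels <- function(snn, resolution, seed) {
  res <- .quiet(Seurat::FindClusters(snn, resolution = resolution,
                                     random.seed = seed, algorithm = 1,
                                     verbose = FALSE))
  raw <- as.integer(as.character(res[[1L]]))
  # enforce contiguous labels from 0 (Seurat already emits them this way)
  labels <- match(raw, sort(unique(raw))) - 1L
  names(labels) <- rownames(res)
  labels
}

#' @export
print.ctsvg_clusters <- function(x, ...) {
  cat(sprintf("<ctsvg_clusters: %d cells, %d clusters (resolution %.2f, seed %d)>\n",
              length(x$labels), length(unique(x$labels)), x$resolution, x$seed))
  invisible(x)
}

#' Re-run community detection under a different seed
#'
#' Reuses the stored SNN graph; only the Louvain seed changes, mirroring
#' how clustering uncertainty is probed in the significance test.
#'
#' @param clusters a \code{ctsvg_clusters} object.
#' @param seed new random seed.
#' @return Named integer label vector (contiguous from 0).
#' @export
reseed_clusters <- function(clusters, seed) {
  stopifnot(inherits(clusters, "ctsvg_clusters"))
  .louvain_labels(clusters$snn, clusters$resolution, seed)
}
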