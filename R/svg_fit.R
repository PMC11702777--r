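#' Spatial isolation filter
#'
#' Computes, for every cell in a cluster, the mean Euclidean distance to
#' its k nearest neighbors within the cluster, where k is 1% of the
#' cluster size rounded half-up and clamped to [10, 50] (and to n - 1).
#' Cells whose isolation score exceeds the mean score plus six standard
#' deviations are flagged as spatially isolated and removed before any
#' spatial fitting.
#'
#' @param coords n x 2 coordinate matrix (rownames = cell ids).
#' @return Named logical vector: TRUE for retained cells. The scores and
#'   the k used are attached as attributes \code{"scores"} and \code{"k"}.
#' @export
remove_isolated_cells <- function(coords) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  keep <- rep(TRUE, n)
  names(keep) <- rownames(coords)
  if (n <= 1L) {
    warning("isolation filter needs at least 2 cells; returning input unchanged")
    return(keep)
  }
  k <- isolation_k(n)
  scores <- numeric(n)
  block <- 1024L
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(rowSums(coords[idx, , drop = FALSE]^2), rowSums(coords^2), `+`) -
      2 * coords[idx, , drop = FALSE] %*% t(coords)
    d2[cbind(seq_along(idx), idx)] <- Inf      # exclude self
    d2[d2 < 0] <- 0
    scores[idx] <- apply(d2, 1L, function(r) mean(sqrt(sort.int(r, partial = k)[seq_len(k)])))
  }
  cutoff <- mean(scores) + 6 * stats::sd(scores)
  keep[] <- scores <= cutoff
  attr(keep, "scores") <- scores
  attr(keep, "k") <- k
  keep
}

#' Neighborhood size for the isolation score
#'
#' 1% of n rounded half-up, clamped to a minimum of 10 and a maximum of 50
#' cells, and never more than n - 1.
#'
#' @param n cluster size.
#' @return Integer k.
#' @export
isolation_k <- function(n) {
  k <- floor(0.01 * n + 0.5)
  as.integer(min(max(k, 10L), 50L, n - 1L))
}

#' Per-cluster gene filter
#'
#' Keeps genes with positive counts in at least \code{min_frac} of the
#' cluster's retained cells.
#'
#' @param counts genes x cells count (or expression) matrix for the
#'   cluster after isolation filtering.
#' @param min_frac minimum fraction of positive cells.
#' @return Character vector of retained gene names.
#' @export
filter_cluster_genes <- function(counts, min_frac = 0.01) {
  npos <- Matrix::rowSums(counts > 0)
  rownames(counts)[npos >= min_frac * ncol(counts)]
}

#' Build the tensor-product cubic B-spline design matrix
#'
#' For each spatial dimension a cubic B-spline basis with K equidistant
#' internal knots spanning the observed coordinate range is constructed,
#' giving K + 3 basis functions per dimension (the standard basis without
#' an intercept column, so the full design stays full rank). The design
#' holds an intercept, both sets of main effects, and all pairwise
#' products (row-major: the dimension-1 index varies slowest), for
#' p = 1 + 2(K+3) + (K+3)^2 columns. Its QR factorization is computed once
#' and shared by every gene fitted against it.
#'
#' @param coords n x 2 coordinate matrix.
#' @param K number of equidistant internal knots per dimension.
#' @return Object of class \code{spline_design}: list with the design
#'   matrix \code{X}, its \code{qr}, the effective column count \code{p},
#'   \code{K}, and \code{n}. Collinear columns arising from degenerate
#'   geometry are dropped with a warning and \code{p} reduced accordingly.
#' @export
build_design <- function(coords, K = 2) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  q <- K + 3L
  p <- 1L + 2L * q + q * q
  if (n <= p) {
    stop(sprintf("n = %d cells cannot support p = %d design columns; reduce K", n, p))
  }
  if (diff(range(coords[, 1L])) == 0 || diff(range(coords[, 2L])) == 0) {
    stop("coordinates are constant in one dimension; no spatial surface can be fitted")
  }
  B1 <- .bspline_basis(coords[, 1L], K)
  B2 <- .bspline_basis(coords[, 2L], K)
  tensor <- matrix(0, n, q * q)
  for (k1 in seq_len(q)) {
    tensor[, (k1 - 1L) * q + seq_len(q)] <- B1[, k1] * B2
  }
  X <- cbind(1, B1, B2, tensor)
  colnames(X) <- c("(Intercept)",
                   paste0("s1.", seq_len(q)), paste0("s2.", seq_len(q)),
                   paste0("s1.", rep(seq_len(q), each = q), ".s2.",
                          rep(seq_len(q), q)))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    warning(sprintf("design rank %d < %d columns; dropping dependent columns",
                    qrX$rank, ncol(X)))
    X <- X[, sort(keep), drop = FALSE]
    qrX <- qr(X)
  }
  structure(list(X = X, qr = qrX, p = ncol(X), K = K, n = n),
            class = "spline_design")
}

.bspline_basis <- function(x, K) {
  r <- range(x)
  knots <- if (K > 0L) seq(r[1L], r[2L], length.out = K + 2L)[-c(1L, K + 2L)] else NULL
  splines::bs(x, knots = knots, degree = 3L, intercept = FALSE,
              Boundary.knots = r)
}

#' @export
print.spline_design <- function(x, ...) {
  cat(sprintf("<spline_design: n = %d, K = %d, p = %d>\n", x$n, x$K, x$p))
  invisible(x)
}

#' Fit all genes against a shared spline design
#'
#' Ordinary least squares for every gene at once through the cached QR
#' factorization (a single multi-column solve). The per-gene overall
#' F statistic is \eqn{F_i = ((TSS_i - RSS_i)/(p-1)) / (RSS_i/(n-p))};
#' a constant gene (zero total sum of squares) is assigned F = 0 by
#' convention.
#'
#' @param design a \code{\link{spline_design}}.
#' @param Y genes x cells expression matrix (log-normalized), columns in
#'   design order.
#' @return Object of class \code{gene_fit}: list with named vector
#'   \code{F}, fitted-value matrix \code{fitted} (genes x cells),
#'   coefficient matrix \code{coef} (p x genes), residual variances
#'   \code{sigma2}, and \code{df1}, \code{df2}, \code{p}, \code{n}.
#' @export
fit_genes <- function(design, Y) {
  stopifnot(inherits(design, "spline_design"))
  Y <- as.matrix(Y)
  if (!all(is.finite(Y))) stop("expression values must be finite")
  if (ncol(Y) != design$n) stop("Y columns must match the design's cells")
  n <- design$n
  p <- design$p
  yt <- t(Y)                                # n x m
  beta <- qr.coef(design$qr, yt)            # p x m
  fitted_t <- design$X %*% beta             # n x m
  res <- yt - fitted_t
  rss <- colSums(res^2)
  tss <- colSums(yt^2) - n * colMeans(yt)^2
  expl <- pmax(tss - rss, 0)
  Fstat <- ifelse(tss <= .Machine$double.eps * n,
                  0,
                  (expl / (p - 1)) / (rss / (n - p)))
  names(Fstat) <- rownames(Y)
  structure(list(F = Fstat, fitted = t(fitted_t), coef = beta,
                 sigma2 = rss / (n - p), df1 = p - 1L, df2 = n - p,
                 p = p, n = n),
            class = "gene_fit")
}

#' @export
print.gene_fit <- function(x, ...) {
  cat(sprintf("<gene_fit: %d genes over %d cells (p = %d)>\n",
              length(x$F), x$n, x$p))
  invisible(x)
}

#' Standardize fitted expression surfaces
#'
#' Scales each gene's fitted values across cells to mean 0 and (sample)
#' standard deviation 1. Constant surfaces map to all-zero with a warning.
#'
#' @param fits a \code{gene_fit} or a genes x cells fitted-value matrix.
#' @return Standardized genes x cells matrix.
#' @export
standardize_fits <- function(fits) {
  m <- if (inherits(fits, "gene_fit")) fits$fitted else as.matrix(fits)
  mu <- rowMeans(m)
  s <- apply(m, 1L, stats::sd)
  const <- s <= .Machine$double.eps * max(1, max(abs(m)))
  if (any(const)) {
    warning(sprintf("%d constant fitted surface(s) standardized to zero", sum(const)))
    s[const] <- 1
  }
  out <- (m - mu) / s
  out[const, ] <- 0
  out
}
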