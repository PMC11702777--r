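#' Jaccard index between two cell-id sets
#'
#' @param a,b vectors of cell ids drawn from the same universe.
#' @return \code{|a n b| / |a u b|}; 0 when both sets are empty.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Build matched reassigned clusters under re-seeded community detection
#'
#' Community detection is re-run with seeds 1..n_seeds on the stored SNN
#' graph. For every original cluster, the best-Jaccard reassigned cluster
#' from each seed is recorded; the top \code{keep} matches across seeds
#' are retained (ties broken by the smaller seed). Two original clusters
#' may match the same reassigned cluster; matching is independent per
#' original cluster.
#'
#' @param clusters a \code{ctsvg_clusters} object.
#' @param n_seeds number of re-clustering seeds (1..n_seeds).
#' @param keep number of matches to retain per original cluster.
#' @return Object of class \code{ctsvg_reassignments}: per original
#'   cluster, a list of matches, each with fields \code{cells},
#'   \code{jaccard}, \code{seed}.
#' @export
build_reassignments <- function(clusters, n_seeds = 1000, keep = 100) {
  stopifnot(inherits(clusters, "ctsvg_clusters"))
  if (keep > n_seeds) stop("`keep` cannot exceed `n_seeds`")
  orig <- clusters$labels
  orig_ids <- sort(unique(orig))
  cand <- stats::setNames(vector("list", length(orig_ids)), as.character(orig_ids))
  for (s in seq_len(n_seeds)) {
    lab <- reseed_clusters(clusters, s)
    tab <- table(orig, lab)
    n_orig <- rowSums(tab)
    n_new <- colSums(tab)
    for (oi in seq_along(orig_ids)) {
      inter <- tab[oi, ]
      jac <- inter / (n_orig[oi] + n_new - inter)
      best <- which.max(jac)
      cand[[oi]][[s]] <- list(
        cells = names(lab)[lab == as.integer(colnames(tab)[best])],
        jaccard = as.numeric(jac[best]),
        seed = s
      )
    }
  }
  out <- lapply(cand, function(matches) {
    jc <- vapply(matches, `[[`, numeric(1), "jaccard")
    sd_ <- vapply(matches, `[[`, numeric(1), "seed")
    ord <- order(-jc, sd_)
    matches[ord[seq_len(keep)]]
  })
  structure(out, class = "ctsvg_reassignments")
}

#' @export
print.ctsvg_reassignments <- function(x, ...) {
  cat(sprintf("<ctsvg_reassignments: %d original clusters, %d matches each>\n",
              length(x), length(x[[1L]])))
  invisible(x)
}

#' Null F statistics from permuted reassigned clusters
#'
#' For each retained reassigned cluster the isolation filter is applied,
#' the cells' coordinate pairs are permuted uniformly at random (x and y
#' move together, so the coordinate multiset is unchanged), the spline
#' design is rebuilt, and the cluster's retained genes are refitted,
#' yielding one null F statistic per gene per reassigned cluster.
#'
#' @param expr genes x cells normalized expression over the whole sample.
#' @param coords all-cell coordinate matrix (rownames = cell ids).
#' @param matches list of reassigned-cluster matches for one original
#'   cluster (an element of \code{\link{build_reassignments}}).
#' @param genes genes to refit (the original cluster's retained genes).
#' @param K spline knots per dimension.
#' @param rng_seed seed controlling the coordinate permutations.
#' @param min_nulls minimum usable reassigned clusters; fewer aborts.
#' @return genes x n_nulls matrix of null F statistics.
#' @export
null_statistics <- function(expr, coords, matches, genes, K = 2,
                            rng_seed = 0, min_nulls = 30) {
  set.seed(rng_seed)
  q <- K + 3L
  p_full <- 1L + 2L * q + q * q
  nulls <- list()
  for (m in matches) {
    cells <- intersect(m$cells, rownames(coords))
    if (length(cells) <= p_full) {
      warning(sprintf("reassigned cluster of %d cells too small for p = %d; skipped",
                      length(cells), p_full))
      next
    }
    xy <- coords[cells, , drop = FALSE]
    keep <- remove_isolated_cells(xy)
    xy <- xy[keep, , drop = FALSE]
    if (nrow(xy) <= p_full) {
      warning("reassigned cluster too small after isolation filtering; skipped")
      next
    }
    perm <- sample.int(nrow(xy))
    xy_perm <- xy[perm, , drop = FALSE]
    rownames(xy_perm) <- rownames(xy)
    design <- build_design(xy_perm, K)
    fit <- fit_genes(design, as.matrix(expr[genes, rownames(xy), drop = FALSE]))
    nulls[[length(nulls) + 1L]] <- fit$F
  }
  if (length(nulls) < min_nulls) {
    stop(sprintf("only %d usable reassigned clusters (< %d); cannot build the null",
                 length(nulls), min_nulls))
  }
  out <- do.call(cbind, nulls)
  rownames(out) <- genes
  out
}

#' Gamma tail p-value against permutation nulls
#'
#' Fits a Gamma distribution to the null statistics by maximum likelihood
#' (method-of-moments initialization) and returns the upper-tail
#' probability at the observed statistic. Null values of zero are replaced
#' by the smallest positive null times 1e-3. If the fit fails, the
#' empirical permutation p-value \code{(1 + #\{null >= obs\}) / (1 + #nulls)}
#' is used instead.
#'
#' @param observed observed F statistic.
#' @param nulls numeric vector of null statistics; at least
#'   \code{min_nulls} are required for a stable fit.
#' @param min_nulls minimum number of nulls (default 30; reduced-scale
#'   runs with fewer retained reassignments lower this bound to match).
#' @return p-value in [0, 1].
#' @export
gamma_pvalue <- function(observed, nulls, min_nulls = 30) {
  if (length(nulls) < min_nulls) {
    stop(sprintf("at least %d null statistics are required", min_nulls))
  }
  if (any(nulls <= 0)) {
    posmin <- min(nulls[nulls > 0])
    if (!is.finite(posmin)) posmin <- 1e-6
    nulls[nulls <= 0] <- posmin * 1e-3
  }
  fit <- .fit_gamma(nulls)
  if (is.null(fit)) {
    return((1 + sum(nulls >= observed)) / (1 + length(nulls)))
  }
  stats::pgamma(observed, shape = fit[["shape"]], rate = fit[["rate"]],
                lower.tail = FALSE)
}

.fit_gamma <- function(x) {
  m <- mean(x); v <- stats::var(x)
  if (!is.finite(v) || v <= 0) return(NULL)
  start <- list(shape = m^2 / v, rate = m / v)
  tryCatch({
    # fitdistrplus prints optimizer errors before signalling; capture them
    log <- utils::capture.output(
      f <- .quiet(fitdistrplus::fitdist(x, "gamma", method = "mle",
                                        start = start)))
    est <- f$estimate
    if (any(!is.finite(est)) || any(est <= 0)) NULL else est
  }, error = function(e) NULL)
}

#' Benjamini-Hochberg false discovery rates
#'
#' Standard step-up BH adjustment with monotonicity enforcement.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return Adjusted FDR values, same order as the input.
#' @export
adjust_bh <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BH")
}

#' Parametric F-test p-value (no clustering-uncertainty correction)
#'
#' Upper tail of the F(p - 1, n - p) distribution at the observed
#' statistic: the baseline that treats inferred clusters as fixed.
#'
#' @param observed observed F statistic(s).
#' @param n number of cells.
#' @param p number of design columns.
#' @return p-value(s).
#' @export
parametric_pvalue_baseline <- function(observed, n, p) {
  stats::pf(observed, p - 1, n - p, lower.tail = FALSE)
}

#' Cell-type-specific spatially variable gene test
#'
#' Per original cluster: spatially isolated cells are removed, genes
#' positive in at least \code{min_frac} of the remaining cells are
#' retained, every retained gene's spatial surface is fitted against the
#' shared tensor B-spline design and its observed F statistic recorded.
#' The null distribution propagates clustering uncertainty: community
#' detection is re-seeded, reassigned clusters are matched by Jaccard
#' index, cell coordinates within each matched cluster are permuted, and
#' the same genes refitted, giving \code{keep} null F statistics per gene.
#' A Gamma distribution fitted per gene to its nulls converts the observed
#' statistic into an upper-tail p-value; Benjamini-Hochberg adjustment is
#' applied within the cluster.
#'
#' @param expr genes x cells log-normalized expression matrix.
#' @param coords cells x 2 coordinate matrix (rownames = cell ids).
#' @param clusters a \code{ctsvg_clusters} object over the same cells.
#' @param K internal spline knots per dimension (default 2, p = 36).
#' @param n_seeds,keep re-clustering seeds and matches retained per
#'   cluster (1000/100 at full scale; reduce for small studies).
#' @param fdr significance cutoff on the adjusted p-value.
#' @param rng_seed seed for the coordinate permutations.
#' @param min_frac per-cluster gene filter fraction.
#' @param min_nulls minimum usable nulls per cluster; clusters below this
#'   are skipped with a warning. Defaults to 30, lowered automatically to
#'   \code{keep} for reduced-scale runs.
#' @param reassignments optional precomputed
#'   \code{\link{build_reassignments}} result.
#' @return Object of class \code{ctsvg_svg}: list with \code{results}
#'   (per-cluster data.frames: gene, F, p, fdr, rank, significant, the
#'   fitted Gamma parameters, and null summary), \code{fits} (per-cluster
#'   \code{gene_fit}), \code{cells} (retained cell ids per cluster), and
#'   the call parameters.
#' @export
test_svgs <- function(expr, coords, clusters, K = 2, n_seeds = 1000,
                      keep = 100, fdr = 0.05, rng_seed = 0,
                      min_frac = 0.01, min_nulls = min(30, keep),
                      reassignments = NULL) {
  stopifnot(inherits(clusters, "ctsvg_clusters"))
  expr <- methods::as(Matrix::Matrix(expr, sparse = TRUE), "CsparseMatrix")
  coords <- as.matrix(coords)
  if (is.null(rownames(coords))) stop("coords must carry cell ids as rownames")
  cells_all <- intersect(colnames(expr), names(clusters$labels))
  if (!length(cells_all)) stop("no shared cells between expression and clustering")
  if (is.null(reassignments)) {
    reassignments <- build_reassignments(clusters, n_seeds = n_seeds, keep = keep)
  }
  q <- K + 3L
  p_full <- 1L + 2L * q + q * q
  results <- list(); fits <- list(); kept_cells <- list()
  for (cl in names(reassignments)) {
    cc <- cells_all[clusters$labels[cells_all] == as.integer(cl)]
    if (length(cc) <= p_full) {
      warning(sprintf("cluster %s has %d cells (<= p = %d); skipped",
                      cl, length(cc), p_full))
      next
    }
    xy <- coords[cc, , drop = FALSE]
    iso <- remove_isolated_cells(xy)
    cc <- cc[iso]
    if (length(cc) <= p_full) {
      warning(sprintf("cluster %s too small after isolation filtering; skipped", cl))
      next
    }
    genes <- filter_cluster_genes(expr[, cc, drop = FALSE], min_frac = min_frac)
    if (!length(genes)) {
      warning(sprintf("cluster %s retains no genes; skipped", cl))
      next
    }
    design <- build_design(coords[cc, , drop = FALSE], K)
    fit <- fit_genes(design, as.matrix(expr[genes, cc, drop = FALSE]))
    nulls <- tryCatch(
      null_statistics(expr, coords, reassignments[[cl]], genes, K = K,
                      rng_seed = rng_seed + as.integer(cl), min_nulls = min_nulls),
      error = function(e) {
        warning(sprintf("cluster %s: %s; skipped", cl, conditionMessage(e)))
        NULL
      })
    if (is.null(nulls)) next
    pv <- vapply(seq_along(genes), function(i)
      gamma_pvalue(fit$F[[i]], nulls[i, ], min_nulls = min_nulls), numeric(1))
    fd <- adjust_bh(pv)
    df <- data.frame(gene = genes, F = unname(fit$F), p = pv, fdr = fd,
                     significant = fd <= fdr,
                     null_mean = rowMeans(nulls),
                     n_nulls = ncol(nulls),
                     stringsAsFactors = FALSE)
    df <- df[order(df$p, -df$F), , drop = FALSE]
    df$rank <- seq_len(nrow(df))
    rownames(df) <- NULL
    results[[cl]] <- df
    fits[[cl]] <- fit
    kept_cells[[cl]] <- cc
  }
  structure(list(results = results, fits = fits, cells = kept_cells,
                 params = list(K = K, n_seeds = n_seeds, keep = keep,
                               fdr = fdr, rng_seed = rng_seed,
                               min_frac = min_frac)),
            class = "ctsvg_svg")
}

#' @export
print.ctsvg_svg <- function(x, ...) {
  nsig <- vapply(x$results, function(df) sum(df$significant), integer(1))
  cat(sprintf("<ctsvg_svg: %d cluster(s); significant genes: %s>\n",
              length(x$results),
              paste(sprintf("%s=%d", names(nsig), nsig), collapse = ", ")))
  invisible(x)
}
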