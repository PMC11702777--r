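#' Group spatially variable genes into modules by k-means
#'
#' Rows of the standardized fitted-surface matrix are clustered with
#' k-means for k = 1..k_max. The proportion of within-cluster to total
#' sum of squares traces an elbow curve; the module count is the k with
#' the maximum perpendicular distance to the chord joining the curve's
#' endpoints (both axes rescaled to [0, 1] so the rule is unit-free).
#' The final partition is recomputed at the chosen k under a fixed seed
#' with 25 restarts.
#'
#' @param std_fits genes x cells matrix of standardized fitted values.
#' @param k_max largest module count considered.
#' @param seed RNG seed for k-means.
#' @return List of class \code{ctsvg_modules}: one element per module with
#'   fields \code{id}, \code{genes}, \code{metagene} (per-cell mean of the
#'   members' standardized fits); the within/total SS curve and chosen k
#'   are attached as attributes \code{"curve"} and \code{"k"}. Fewer than
#'   two genes yield a single module.
#' @export
cluster_gene_modules <- function(std_fits, k_max = 15, seed = 0) {
  std_fits <- as.matrix(std_fits)
  g <- nrow(std_fits)
  if (g < 2L) {
    mods <- list(list(id = 1L, genes = rownames(std_fits),
                      metagene = colMeans(std_fits)))
    return(structure(mods, curve = NULL, k = 1L, class = "ctsvg_modules"))
  }
  n_distinct <- nrow(unique(std_fits))
  k_hi <- min(k_max, n_distinct)
  center <- colMeans(std_fits)
  totss <- sum(sweep(std_fits, 2L, center)^2)
  if (totss <= 1e-12 || k_hi == 1L) {
    chosen <- 1L
    curve <- NULL
  } else {
    ks <- seq_len(k_hi)
    ratio <- vapply(ks, function(k) {
      set.seed(seed)
      km <- tryCatch(
        stats::kmeans(std_fits, centers = k, nstart = 25, iter.max = 50),
        error = function(e) NULL)   # k can be unachievable (duplicate rows)
      if (is.null(km)) NA_real_ else km$tot.withinss / totss
    }, numeric(1))
    ok <- !is.na(ratio)
    ks <- ks[ok]; ratio <- ratio[ok]
    curve <- data.frame(k = ks, within_over_total = ratio)
    chosen <- .elbow_k(ks, ratio)
  }
  set.seed(seed)
  km <- stats::kmeans(std_fits, centers = chosen, nstart = 25, iter.max = 50)
  mods <- lapply(seq_len(chosen), function(i) {
    genes <- rownames(std_fits)[km$cluster == i]
    list(id = i, genes = genes,
         metagene = metagene(genes, std_fits))
  })
  structure(mods, curve = curve, k = chosen, class = "ctsvg_modules")
}

# maximum perpendicular distance to the chord between the curve endpoints,
# after rescaling both axes to [0, 1]
.elbow_k <- function(ks, ratio) {
  if (length(ks) < 3L) return(ks[which.min(ratio)])
  x <- (ks - ks[1L]) / (ks[length(ks)] - ks[1L])
  rng <- range(ratio)
  y <- if (diff(rng) > 0) (ratio - rng[1L]) / diff(rng) else ratio * 0
  x0 <- x[1L]; y0 <- y[1L]
  dx <- x[length(x)] - x0; dy <- y[length(y)] - y0
  d <- abs(dx * (y0 - y) - (x0 - x) * dy) / sqrt(dx^2 + dy^2)
  ks[which.max(d)]
}

#' @export
print.ctsvg_modules <- function(x, ...) {
  cat(sprintf("<ctsvg_modules: %d module(s) of sizes %s>\n", length(x),
              paste(vapply(x, function(m) length(m$genes), integer(1)),
                    collapse = ", ")))
  invisible(x)
}

#' Metagene of a gene module
#'
#' Unweighted per-cell mean of the members' standardized fitted values.
#'
#' @param genes member gene names.
#' @param std_fits genes x cells standardized fitted matrix.
#' @return Per-cell numeric vector.
#' @export
metagene <- function(genes, std_fits) {
  colMeans(std_fits[genes, , drop = FALSE])
}

#' Cluster marker genes by Wilcoxon rank-sum test
#'
#' Each cluster is compared against all other cells, gene by gene, on
#' log-normalized expression using the rank-sum test with the normal
#' approximation, tie correction, and continuity correction. Clusters are
#' first downsampled to at most \code{max_cells_per_cluster} cells
#' (seeded). Per cluster the \code{top_n} genes with the smallest
#' p-values are reported (ties broken by descending absolute log fold
#' change), along with their union across clusters.
#'
#' @param expr genes x cells log-normalized expression.
#' @param labels per-cell cluster labels (named by cell id).
#' @param max_cells_per_cluster downsampling cap per cluster.
#' @param top_n markers per cluster.
#' @param seed RNG seed for downsampling.
#' @return List of class \code{ctsvg_markers}: \code{per_cluster} (named
#'   list of data.frames: gene, p, lfc) and \code{union} (character).
#'   Clusters with fewer than 3 cells are skipped with a warning.
#' @export
find_markers <- function(expr, labels, max_cells_per_cluster = 5000,
                         top_n = 50, seed = 0) {
  expr <- as.matrix(expr)
  cells <- intersect(colnames(expr), names(labels))
  labels <- labels[cells]
  if (length(unique(labels)) < 2L) stop("at least 2 clusters are required")
  set.seed(seed)
  keep <- unlist(lapply(split(cells, labels[cells]), function(cc) {
    if (length(cc) > max_cells_per_cluster) sample(cc, max_cells_per_cluster) else cc
  }), use.names = FALSE)
  expr <- expr[, keep, drop = FALSE]
  labels <- labels[keep]
  per_cluster <- list()
  for (cl in sort(unique(labels))) {
    in_cl <- labels == cl
    if (sum(in_cl) < 3L) {
      warning(sprintf("cluster %s has fewer than 3 cells; skipped", cl))
      next
    }
    p <- .wilcox_rows(expr, in_cl)
    lfc <- rowMeans(expr[, in_cl, drop = FALSE]) -
      rowMeans(expr[, !in_cl, drop = FALSE])
    ord <- order(p, -abs(lfc))
    top <- ord[seq_len(min(top_n, length(ord)))]
    per_cluster[[as.character(cl)]] <- data.frame(
      gene = rownames(expr)[top], p = p[top], lfc = lfc[top],
      stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(list(per_cluster = per_cluster,
                 union = unique(unlist(lapply(per_cluster, `[[`, "gene")))),
            class = "ctsvg_markers")
}

# two-sided rank-sum p-values for every row, group `in1` vs the rest:
# normal approximation with tie and continuity correction
.wilcox_rows <- function(m, in1) {
  n1 <- sum(in1); n2 <- sum(!in1); N <- n1 + n2
  vapply(seq_len(nrow(m)), function(i) {
    r <- rank(m[i, ])
    U <- sum(r[in1]) - n1 * (n1 + 1) / 2
    ties <- table(m[i, ])
    sig2 <- (n1 * n2 / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sig2 <= 0) return(1)
    z <- U - n1 * n2 / 2
    z <- sign(z) * max(abs(z) - 0.5, 0) / sqrt(sig2)
    2 * stats::pnorm(-abs(z))
  }, numeric(1))
}

#' @export
print.ctsvg_markers <- function(x, ...) {
  cat(sprintf("<ctsvg_markers: %d cluster(s), union of %d genes>\n",
              length(x$per_cluster), length(x$union)))
  invisible(x)
}

#' Fraction of top-ranked SVGs that are not cluster markers
#'
#' @param svg_ranking gene names ordered by SVG rank (best first).
#' @param markers a \code{ctsvg_markers} object (or a character vector of
#'   marker genes).
#' @param top_k how many top SVGs to examine; clamped to the ranking
#'   length with a warning.
#' @return Fraction in [0, 1] of the top-k SVGs absent from the marker
#'   union.
#' @export
svg_marker_overlap <- function(svg_ranking, markers, top_k = 10) {
  union_set <- if (inherits(markers, "ctsvg_markers")) markers$union else markers
  if (top_k > length(svg_ranking)) {
    warning("`top_k` exceeds the ranking length; clamped")
    top_k <- length(svg_ranking)
  }
  top <- svg_ranking[seq_len(top_k)]
  length(setdiff(top, union_set)) / top_k
}

#' Over-representation of gene sets in a module
#'
#' One-sided hypergeometric test of each gene set against the module,
#' restricted to the supplied gene universe, with Benjamini-Hochberg
#' adjustment. Sets with FDR at or below \code{fdr} are retained and
#' ordered by decreasing fold change (observed over expected overlap).
#'
#' @param module_genes genes in the module.
#' @param universe all genes eligible for membership.
#' @param gene_sets named list of character vectors (e.g. from
#'   \code{\link{read_gmt}}).
#' @param fdr retention cutoff.
#' @return data.frame: set, overlap, set_size, p, fdr, fold_change;
#'   zero rows when nothing is enriched.
#' @export
enrich_gene_sets <- function(module_genes, universe, gene_sets, fdr = 0.05) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty gene universe")
  module_genes <- intersect(unique(module_genes), universe)
  res <- lapply(names(gene_sets), function(nm) {
    set_u <- intersect(gene_sets[[nm]], universe)
    k <- length(intersect(module_genes, set_u))
    if (!length(set_u)) return(NULL)
    p <- stats::phyper(k - 1, length(set_u), length(universe) - length(set_u),
                       length(module_genes), lower.tail = FALSE)
    expected <- length(module_genes) * length(set_u) / length(universe)
    data.frame(set = nm, overlap = k, set_size = length(set_u), p = p,
               fold_change = if (expected > 0) k / expected else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res) || !nrow(res)) {
    return(data.frame(set = character(0), overlap = integer(0),
                      set_size = integer(0), p = numeric(0),
                      fdr = numeric(0), fold_change = numeric(0)))
  }
  res$fdr <- adjust_bh(res$p)
  res <- res[res$fdr <= fdr, , drop = FALSE]
  res <- res[order(-res$fold_change), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("set", "overlap", "set_size", "p", "fdr", "fold_change")]
}
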