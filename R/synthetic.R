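#' Specification for a synthetic tissue
#'
#' Defines the study conditions the generator emulates: an arena in pixel
#' units, cells of several types placed by Gaussian blobs, log-normal
#' nucleus sizes, whole cells as centroid-anchored expansions of their
#' nuclei (area ratio 2, matching the typical whole-cell to nucleus area
#' ratio), per-type gene expression rates, optional spatially variable
#' genes whose rates are modulated by a smooth field evaluated at the cell
#' centroid, and a per-gene Poisson transcript count model.
#'
#' @param arena width/height of the square arena in pixels.
#' @param n_cells number of cells to place.
#' @param n_types number of cell types.
#' @param type_centers optional n_types x 2 matrix of blob centers
#'   (defaults to points spread around the arena).
#' @param type_sd spatial standard deviation of each type's blob.
#' @param nucleus_meanlog,nucleus_sdlog log-normal nucleus area (pixel^2).
#' @param area_ratio whole-cell to nucleus area ratio.
#' @param rates genes x types matrix of expected transcripts per cell; by
#'   default 40 genes with 10 markers per type (high rate in their type)
#'   plus shared background genes.
#' @param svg data.frame (gene, type, field, effect) declaring spatially
#'   variable genes; \code{field} is "linear" or "radial"; empty by
#'   default.
#' @param background_rate expected unassigned background transcripts per
#'   1000 px^2.
#' @param size_px lattice pitch in pixels corresponding to 2 microns.
#' @param seed RNG seed; the generator is a pure function of spec + seed.
#' @return List of class \code{tissue_spec}.
#' @export
tissue_spec <- function(arena = c(400, 400), n_cells = 80, n_types = 2,
                        type_centers = NULL, type_sd = NULL,
                        nucleus_meanlog = log(600), nucleus_sdlog = 0.25,
                        area_ratio = 2, rates = NULL, svg = NULL,
                        background_rate = 0.2, size_px = 8, seed = 1) {
  if (is.null(type_centers)) {
    ang <- 2 * pi * (seq_len(n_types) - 1) / max(n_types, 2)
    type_centers <- cbind(arena[1L] / 2 + arena[1L] / 4 * cos(ang),
                          arena[2L] / 2 + arena[2L] / 4 * sin(ang))
  }
  if (is.null(type_sd)) type_sd <- mean(arena) / 5
  if (is.null(rates)) {
    n_marker <- 10L
    genes <- c(paste0("mk", rep(seq_len(n_types), each = n_marker), "_",
                      seq_len(n_marker)),
               paste0("bg", seq_len(20L)))
    rates <- matrix(2, length(genes), n_types,
                    dimnames = list(genes, paste0("type", seq_len(n_types))))
    for (t in seq_len(n_types)) {
      rates[(t - 1L) * n_marker + seq_len(n_marker), ] <- 0.4
      rates[(t - 1L) * n_marker + seq_len(n_marker), t] <- 8
    }
  }
  if (is.null(svg)) {
    svg <- data.frame(gene = character(0), type = integer(0),
                      field = character(0), effect = numeric(0))
  }
  stopifnot(all(svg$gene %in% rownames(rates)), all(svg$type <= ncol(rates)))
  structure(list(arena = arena, n_cells = n_cells, n_types = n_types,
                 type_centers = type_centers, type_sd = type_sd,
                 nucleus_meanlog = nucleus_meanlog,
                 nucleus_sdlog = nucleus_sdlog, area_ratio = area_ratio,
                 rates = rates, svg = svg, background_rate = background_rate,
                 size_px = size_px, seed = seed),
            class = "tissue_spec")
}

.ellipse_contour <- function(center, area, ecc, theta, n_pts = 24L) {
  a <- sqrt(area / pi / ecc)
  b <- area / pi / a
  t <- 2 * pi * (seq_len(n_pts) - 1L) / n_pts
  x <- a * cos(t); y <- b * sin(t)
  cbind(center[1L] + x * cos(theta) - y * sin(theta),
        center[2L] + x * sin(theta) + y * cos(theta))
}

.sample_in_polygon <- function(n, contour) {
  if (n == 0L) return(matrix(numeric(0), 0L, 2L))
  bb <- apply(contour, 2L, range)
  out <- matrix(numeric(0), 0L, 2L)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    px <- stats::runif(m, bb[1L, 1L], bb[2L, 1L])
    py <- stats::runif(m, bb[1L, 2L], bb[2L, 2L])
    ok <- points_in_polygon(px, py, contour)
    out <- rbind(out, cbind(px[ok], py[ok]))
  }
  out[seq_len(n), , drop = FALSE]
}

.svg_field <- function(kind, coords, arena) {
  switch(kind,
         linear = coords[, 1L] / arena[1L],
         radial = {
           d2 <- (coords[, 1L] - arena[1L] / 2)^2 + (coords[, 2L] - arena[2L] / 2)^2
           exp(-d2 / (2 * (mean(arena) / 4)^2))
         },
         none = rep(0.5, nrow(coords)),
         stop("unknown field kind: ", kind))
}

#' Generate a synthetic tissue with full ground truth
#'
#' Places non-overlapping elliptical nuclei (rejection sampling on the
#' expanded-cell bounding radii), derives whole cells by similarity
#' expansion, samples per-cell transcripts from per-type Poisson rates
#' (modulated by any declared spatial fields at the cell centroid) with
#' positions uniform inside the whole-cell polygon, adds background
#' transcripts, and bins everything on the 2-micron lattice.
#'
#' @param spec a \code{\link{tissue_spec}}.
#' @return List: \code{nuclei}, \code{cells} (expanded polygons),
#'   \code{transcripts} (x, y, gene, cell gold assignment), \code{grid},
#'   \code{counts} (genes x squares), \code{types} (named per-cell type),
#'   \code{spec}.
#' @export
generate_tissue <- function(spec) {
  stopifnot(inherits(spec, "tissue_spec"))
  set.seed(spec$seed)
  arena <- spec$arena
  nuclei <- vector("list", spec$n_cells)
  cells <- vector("list", spec$n_cells)
  centers <- matrix(0, spec$n_cells, 2L)
  radii <- numeric(spec$n_cells)
  types <- integer(spec$n_cells)
  placed <- 0L
  attempts <- 0L
  while (placed < spec$n_cells) {
    attempts <- attempts + 1L
    if (attempts > 1e4) {
      stop("could not place the requested cells without overlap; enlarge the arena")
    }
    ty <- sample.int(spec$n_types, 1L)
    ctr <- spec$type_centers[ty, ] + stats::rnorm(2L, 0, spec$type_sd)
    area <- stats::rlnorm(1L, spec$nucleus_meanlog, spec$nucleus_sdlog)
    ecc <- stats::runif(1L, 0.7, 1)
    theta <- stats::runif(1L, 0, pi)
    r_exp <- sqrt(spec$area_ratio) * sqrt(area / pi / ecc) + 1
    if (any(ctr < r_exp) || ctr[1L] > arena[1L] - r_exp ||
        ctr[2L] > arena[2L] - r_exp) next
    if (placed > 0L) {
      d <- sqrt(colSums((t(centers[seq_len(placed), , drop = FALSE]) - ctr)^2))
      if (any(d < radii[seq_len(placed)] + r_exp)) next
    }
    placed <- placed + 1L
    centers[placed, ] <- ctr
    radii[placed] <- r_exp
    types[placed] <- ty
    nu <- nucleus_polygon(sprintf("cell%03d", placed),
                          .ellipse_contour(ctr, area, ecc, theta))
    nuclei[[placed]] <- nu
    cells[[placed]] <- expand_nucleus(nu, spec$area_ratio)
  }
  ids <- vapply(nuclei, function(nu) nu$nucleus_id, character(1))
  names(types) <- ids

  genes <- rownames(spec$rates)
  tx <- list()
  for (j in seq_len(spec$n_cells)) {
    lam <- spec$rates[, types[j]]
    if (nrow(spec$svg)) {
      for (r in seq_len(nrow(spec$svg))) {
        if (spec$svg$type[r] == types[j]) {
          f <- .svg_field(spec$svg$field[r],
                          matrix(nuclei[[j]]$centroid, 1L), arena)
          g <- spec$svg$gene[r]
          lam[g] <- lam[g] * (1 + spec$svg$effect[r] * f)
        }
      }
    }
    cnt <- stats::rpois(length(lam), lam)
    total <- sum(cnt)
    if (total == 0L) next
    pts <- .sample_in_polygon(total, cells[[j]]$contour)
    tx[[j]] <- data.frame(x = pts[, 1L], y = pts[, 2L],
                          gene = rep(genes, cnt), cell = ids[j],
                          stringsAsFactors = FALSE)
  }
  n_bg <- stats::rpois(1L, spec$background_rate * prod(arena) / 1000)
  if (n_bg > 0L) {
    bg <- data.frame(x = stats::runif(n_bg, 0, arena[1L]),
                     y = stats::runif(n_bg, 0, arena[2L]),
                     gene = sample(genes, n_bg, replace = TRUE),
                     cell = "UNASSIGNED", stringsAsFactors = FALSE)
    # background points landing inside a cell belong to it (gold standard
    # is point-in-whole-cell-polygon)
    for (j in seq_len(spec$n_cells)) {
      inside <- points_in_polygon(bg$x, bg$y, cells[[j]]$contour)
      bg$cell[inside] <- ids[j]
    }
    tx[[length(tx) + 1L]] <- bg
  }
  transcripts <- do.call(rbind, tx)
  rownames(transcripts) <- NULL
  grid <- gridify(c(0, arena[1L], 0, arena[2L]), spec$size_px)
  binned <- bin_transcripts(transcripts, grid)
  counts <- binned$counts[genes[genes %in% rownames(binned$counts)], ,
                          drop = FALSE]
  missing <- setdiff(genes, rownames(counts))
  if (length(missing)) {
    zero <- Matrix::Matrix(0, length(missing), ncol(counts), sparse = TRUE,
                           dimnames = list(missing, colnames(counts)))
    counts <- rbind(counts, zero)[genes, , drop = FALSE]
  }
  list(nuclei = nuclei, cells = cells, transcripts = transcripts,
       grid = grid, counts = counts, types = types, spec = spec)
}

#' Generate an ideal lattice-nested tissue
#'
#' Cells are axis-aligned squares made of whole lattice squares, separated
#' by one-square gaps; each nucleus is its cell shrunk about the center by
#' the square root of the area ratio, so the expanded nucleus reproduces
#' the whole cell exactly and every lattice square lies entirely inside
#' one cell or in the gap. On this tissue a correct assignment maps every
#' transcript to its gold-standard cell.
#'
#' @param n_side cells per arena side.
#' @param squares_per_cell lattice squares per cell side.
#' @param size_px lattice pitch in pixels.
#' @param mean_tx expected transcripts per cell and gene.
#' @param n_genes number of genes.
#' @param area_ratio nucleus expansion ratio.
#' @param seed RNG seed.
#' @return Same structure as \code{\link{generate_tissue}} (without
#'   \code{spec}; \code{types} are all 1).
#' @export
generate_ideal_tissue <- function(n_side = 4, squares_per_cell = 5,
                                  size_px = 8, mean_tx = 4, n_genes = 20,
                                  area_ratio = 2, seed = 1) {
  set.seed(seed)
  cell_px <- squares_per_cell * size_px
  pitch <- (squares_per_cell + 1L) * size_px   # one-square gap between cells
  arena <- n_side * pitch + size_px
  nuclei <- list(); cells <- list(); tx <- list()
  idx <- 0L
  genes <- paste0("g", seq_len(n_genes))
  for (i in seq_len(n_side)) for (j in seq_len(n_side)) {
    idx <- idx + 1L
    id <- sprintf("cell%03d", idx)
    x0 <- size_px + (i - 1L) * pitch
    y0 <- size_px + (j - 1L) * pitch
    cell <- rbind(c(x0, y0), c(x0 + cell_px, y0),
                  c(x0 + cell_px, y0 + cell_px), c(x0, y0 + cell_px))
    ctr <- c(x0 + cell_px / 2, y0 + cell_px / 2)
    s <- 1 / sqrt(area_ratio)
    nuc <- sweep(sweep(cell, 2L, ctr), 2L, c(s, s), `*`)
    nuc <- sweep(nuc, 2L, ctr, `+`)
    nuclei[[idx]] <- nucleus_polygon(id, nuc)
    cells[[idx]] <- nucleus_polygon(id, cell)
    cnt <- stats::rpois(n_genes, mean_tx)
    total <- sum(cnt)
    if (total > 0L) {
      eps <- 1e-6 * cell_px
      tx[[idx]] <- data.frame(
        x = stats::runif(total, x0 + eps, x0 + cell_px - eps),
        y = stats::runif(total, y0 + eps, y0 + cell_px - eps),
        gene = rep(genes, cnt), cell = id, stringsAsFactors = FALSE)
    }
  }
  transcripts <- do.call(rbind, tx)
  rownames(transcripts) <- NULL
  grid <- gridify(c(0, arena, 0, arena), size_px)
  binned <- bin_transcripts(transcripts, grid)
  counts <- binned$counts
  types <- stats::setNames(rep(1L, idx),
                           vapply(nuclei, function(nu) nu$nucleus_id, character(1)))
  list(nuclei = nuclei, cells = cells, transcripts = transcripts,
       grid = grid, counts = counts, types = types)
}

#' Sample-wide coordinate permutation (null dataset)
#'
#' Permutes the coordinate pairs uniformly at random across all cells
#' while leaving expression untouched: the null design under which no
#' gene is spatially variable.
#'
#' @param cells a \code{\link{cell_matrix}}.
#' @param rng_seed seed.
#' @return A \code{\link{cell_matrix}} with permuted coordinates.
#' @export
generate_null <- function(cells, rng_seed = 0) {
  stopifnot(inherits(cells, "cell_matrix"), ncol(cells$counts) >= 2L)
  set.seed(rng_seed)
  perm <- sample.int(nrow(cells$coords))
  coords <- cells$coords[perm, , drop = FALSE]
  rownames(coords) <- rownames(cells$coords)
  cell_matrix(cells$counts, coords, meta = cells$meta,
              clusters = cells$clusters)
}

#' Simulate expression with planted spatially variable genes
#'
#' SVG genes follow a smooth spatial field (linear gradient or radial
#' bump, alternating) scaled by \code{effect} plus Gaussian noise; null
#' genes are pure noise. Truth flags are returned for sensitivity and
#' FDR evaluation.
#'
#' @param coords n x 2 coordinate matrix (rownames = cell ids).
#' @param n_svg,n_null numbers of planted and null genes.
#' @param effect field amplitude.
#' @param noise_sd Gaussian noise standard deviation.
#' @param rng_seed seed.
#' @return List: \code{expr} (genes x cells), \code{is_svg} (named
#'   logical).
#' @export
generate_svg_expression <- function(coords, n_svg = 20, n_null = 180,
                                    effect = 3, noise_sd = 1, rng_seed = 0) {
  set.seed(rng_seed)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  xr <- range(coords[, 1L]); yr <- range(coords[, 2L])
  fields <- c("linear", "radial")
  rows <- vector("list", n_svg + n_null)
  for (i in seq_len(n_svg)) {
    kind <- fields[(i - 1L) %% 2L + 1L]
    f <- if (kind == "linear") {
      w <- stats::rnorm(2L); w <- w / sqrt(sum(w^2))
      z <- (coords[, 1L] - xr[1L]) / diff(xr) * w[1L] +
        (coords[, 2L] - yr[1L]) / diff(yr) * w[2L]
      (z - min(z)) / max(diff(range(z)), 1e-12)
    } else {
      ctr <- c(stats::runif(1L, xr[1L], xr[2L]), stats::runif(1L, yr[1L], yr[2L]))
      sig <- mean(c(diff(xr), diff(yr))) / 4
      d2 <- (coords[, 1L] - ctr[1L])^2 + (coords[, 2L] - ctr[2L])^2
      exp(-d2 / (2 * sig^2))
    }
    rows[[i]] <- effect * f + stats::rnorm(n, 0, noise_sd)
  }
  for (i in seq_len(n_null)) {
    rows[[n_svg + i]] <- stats::rnorm(n, 0, noise_sd)
  }
  expr <- do.call(rbind, rows)
  rownames(expr) <- c(sprintf("svg%03d", seq_len(n_svg)),
                      sprintf("null%03d", seq_len(n_null)))
  colnames(expr) <- rownames(coords)
  is_svg <- stats::setNames(rep(c(TRUE, FALSE), c(n_svg, n_null)), rownames(expr))
  list(expr = expr, is_svg = is_svg)
}

#' Simulate sparse counts with cell-type structure
#'
#' Poisson counts mimicking aggregated single-cell data: per-type marker
#' genes (rate \code{marker_rate} in their own type, \code{base_rate}
#' elsewhere), sparse noise genes with log-uniform rates, and log-normal
#' library-size variation across cells. This is the count model used in
#' null-calibration studies, where the spiky log-normalized values are
#' what breaks parametric F calibration.
#'
#' @param types integer per-cell type labels (named by cell id).
#' @param n_marker markers per type.
#' @param n_noise sparse noise genes.
#' @param marker_rate,base_rate marker Poisson rates inside/outside the
#'   own type.
#' @param noise_rate_range range of the log-uniform noise-gene rates.
#' @param libsize_sdlog sd(log) of the per-cell library-size factor.
#' @param rng_seed seed.
#' @return Sparse genes x cells integer count matrix.
#' @export
generate_type_counts <- function(types, n_marker = 20, n_noise = 460,
                                 marker_rate = 3, base_rate = 0.2,
                                 noise_rate_range = c(0.02, 0.6),
                                 libsize_sdlog = 0.3, rng_seed = 0) {
  set.seed(rng_seed)
  n <- length(types)
  tys <- sort(unique(types))
  lam_mk <- matrix(base_rate, n_marker * length(tys), n)
  for (ti in seq_along(tys)) {
    rows <- (ti - 1L) * n_marker + seq_len(n_marker)
    lam_mk[rows, types == tys[ti]] <- marker_rate
  }
  g_rates <- exp(stats::runif(n_noise, log(noise_rate_range[1L]),
                              log(noise_rate_range[2L])))
  lam <- rbind(lam_mk, matrix(rep(g_rates, n), n_noise, n))
  lib <- exp(stats::rnorm(n, 0, libsize_sdlog))
  lam <- sweep(lam, 2L, lib, `*`)
  counts <- matrix(stats::rpois(length(lam), lam), nrow(lam), n)
  rownames(counts) <- c(paste0("mk", rep(tys, each = n_marker), "_",
                               seq_len(n_marker)),
                        paste0("ns", seq_len(n_noise), recycle0 = TRUE))
  colnames(counts) <- names(types)
  Matrix::Matrix(counts, sparse = TRUE)
}

#' Simulate expression with cell-type structure
#'
#' Marker genes are shifted by \code{effect} in their own type; noise
#' genes are shared. Used to drive realistic clustering (and clustering
#' uncertainty) in calibration studies.
#'
#' @param types integer per-cell type labels (named by cell id).
#' @param n_marker markers per type.
#' @param n_noise additional pure-noise genes.
#' @param effect marker shift.
#' @param noise_sd Gaussian noise sd.
#' @param rng_seed seed.
#' @return genes x cells matrix.
#' @export
generate_type_expression <- function(types, n_marker = 20, n_noise = 100,
                                     effect = 2, noise_sd = 1, rng_seed = 0) {
  set.seed(rng_seed)
  n <- length(types)
  tys <- sort(unique(types))
  expr <- matrix(stats::rnorm((n_marker * length(tys) + n_noise) * n, 0, noise_sd),
                 ncol = n)
  rn <- c(paste0("mk", rep(tys, each = n_marker), "_", seq_len(n_marker)),
          paste0("ns", seq_len(n_noise), recycle0 = TRUE))
  rownames(expr) <- rn
  colnames(expr) <- names(types)
  for (ti in seq_along(tys)) {
    rows <- (ti - 1L) * n_marker + seq_len(n_marker)
    expr[rows, types == tys[ti]] <- expr[rows, types == tys[ti]] + effect
  }
  expr
}
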