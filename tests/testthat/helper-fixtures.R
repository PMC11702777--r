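# shared fixture builders; everything is generated in code at test time

unit_square <- function(x0 = 0, y0 = 0, side = 1) {
  rbind(c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side), c(x0, y0 + side))
}

# rectangle polygon as a nucleus_polygon
rect_nucleus <- function(id, x0, y0, w, h) {
  nucleus_polygon(id, rbind(c(x0, y0), c(x0 + w, y0),
                            c(x0 + w, y0 + h), c(x0, y0 + h)))
}

# regular-polygon approximation of an ellipse
ellipse_poly <- function(cx, cy, a, b, theta = 0, n = 32) {
  t <- 2 * pi * (seq_len(n) - 1) / n
  x <- a * cos(t); y <- b * sin(t)
  cbind(cx + x * cos(theta) - y * sin(theta),
        cy + x * sin(theta) + y * cos(theta))
}

# minimal grid of n_row x n_col squares of side `size`, corner at origin
toy_grid <- function(n_row = 3, n_col = 3, size = 1) {
  col <- rep(seq_len(n_col) - 1L, times = n_row)
  row <- rep(seq_len(n_row) - 1L, each = n_col)
  g <- square_grid(
    data.frame(square_id = paste0("s", row, "_", col),
               x = (col + 0.5) * size, y = (row + 0.5) * size,
               row = row, col = col),
    size_px = size)
  attr(g, "origin") <- c(0, 0)
  g
}

# sparse genes x squares counts with the given dimensions
toy_counts <- function(grid, n_genes = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * nrow(grid), 2), n_genes, nrow(grid))
  rownames(m) <- paste0("g", seq_len(n_genes))
  colnames(m) <- grid$square_id
  Matrix::Matrix(m, sparse = TRUE)
}

# well-separated two-type expression plus random coordinates, used by the
# clustering and testing fixtures
blob_dataset <- function(n = 300, n_marker = 15, n_noise = 60, effect = 3,
                         seed = 1, arena = 100) {
  set.seed(seed)
  coords <- cbind(runif(n, 0, arena), runif(n, 0, arena))
  rownames(coords) <- paste0("c", seq_len(n))
  types <- stats::setNames(rep(1:2, length.out = n), rownames(coords))
  expr <- generate_type_expression(types, n_marker = n_marker,
                                   n_noise = n_noise, effect = effect,
                                   rng_seed = seed + 1)
  list(expr = expr, coords = coords, types = types)
}
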