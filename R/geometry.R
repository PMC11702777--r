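#' Polygon geometry primitives
#'
#' Planar geometry used by the square-to-cell assignment stage. All
#' coordinates are continuous 2D pixel coordinates with the image
#' convention: origin at the top-left, y increasing downward. Polygons are
#' ordered vertex matrices (N x 2), implicitly closed.
#'
#' @name geometry
#' @keywords internal
NULL

#' Signed polygon area by the shoelace formula
#'
#' @param contour numeric N x 2 matrix of vertices, implicitly closed.
#' @return Signed area; positive when vertices wind counter-clockwise in a
#'   y-up frame (clockwise on screen in the image convention).
#' @keywords internal
shoelace_signed <- function(contour) {
  x <- contour[, 1L]; y <- contour[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Polygon area (shoelace)
#'
#' @param contour numeric N x 2 matrix of vertices, implicitly closed.
#' @return Non-negative area in squared coordinate units.
#' @export
poly_area <- function(contour) {
  abs(shoelace_signed(contour))
}

#' Polygon centroid
#'
#' Area-weighted centroid of a simple polygon; degenerate (zero-area)
#' contours fall back to the vertex mean.
#'
#' @param contour numeric N x 2 matrix of vertices, implicitly closed.
#' @return Length-2 numeric vector (x, y).
#' @export
poly_centroid <- function(contour) {
  x <- contour[, 1L]; y <- contour[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps * max(1, max(abs(contour)))^2) {
    return(c(mean(x), mean(y)))
  }
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Point-in-polygon test (even-odd rule, boundary counts as inside)
#'
#' Vectorized over query points; loops over polygon edges. Points lying
#' exactly on an edge are inside, applied consistently across the package.
#'
#' @param px,py numeric vectors of query coordinates.
#' @param contour numeric N x 2 polygon vertex matrix.
#' @return Logical vector, one entry per query point.
#' @export
points_in_polygon <- function(px, py, contour) {
  n <- length(px)
  nv <- nrow(contour)
  inside <- logical(n)
  on_edge <- logical(n)
  xs <- contour[, 1L]; ys <- contour[, 2L]
  j <- nv
  for (i in seq_len(nv)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    # even-odd ray crossing (ray towards +x)
    denom <- yj - yi
    crosses <- (yi > py) != (yj > py)
    if (any(crosses)) {
      xint <- xi + (xj - xi) * (py - yi) / denom
      inside <- xor(inside, crosses & (px < xint))
    }
    # on-segment: zero cross product and within the segment's bounding box
    cross <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    seglen <- sqrt((xj - xi)^2 + (yj - yi)^2)
    tol <- 1e-9 * max(seglen, 1)
    on <- abs(cross) <= tol &
      px >= pmin(xi, xj) - tol & px <= pmax(xi, xj) + tol &
      py >= pmin(yi, yj) - tol & py <= pmax(yi, yj) + tol
    on_edge <- on_edge | on
    j <- i
  }
  inside | on_edge
}

# orientation of ordered triple: >0 counter-clockwise, <0 clockwise, 0 collinear
.orient <- function(ax, ay, bx, by, cx, cy) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}

#' Test whether a closed contour self-intersects
#'
#' Checks all pairs of non-adjacent edges for proper crossings and for
#' collinear overlap. Used to reject invalid segmentation records.
#'
#' @param contour numeric N x 2 polygon vertex matrix.
#' @return TRUE when any two non-adjacent edges intersect.
#' @export
poly_self_intersects <- function(contour) {
  nv <- nrow(contour)
  if (nv < 4L) return(FALSE)
  p <- rbind(contour, contour[1L, , drop = FALSE])
  for (i in seq_len(nv - 2L)) {
    jmax <- if (i == 1L) nv - 1L else nv
    for (j in (i + 2L):jmax) {
      if (j > nv) break
      d1 <- .orient(p[i, 1], p[i, 2], p[i + 1, 1], p[i + 1, 2], p[j, 1], p[j, 2])
      d2 <- .orient(p[i, 1], p[i, 2], p[i + 1, 1], p[i + 1, 2], p[j + 1, 1], p[j + 1, 2])
      d3 <- .orient(p[j, 1], p[j, 2], p[j + 1, 1], p[j + 1, 2], p[i, 1], p[i, 2])
      d4 <- .orient(p[j, 1], p[j, 2], p[j + 1, 1], p[j + 1, 2], p[i + 1, 1], p[i + 1, 2])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Approximate square/polygon overlap by subsquare counting
#'
#' The square is divided into an \code{n_sub} x \code{n_sub} lattice of
#' subsquares (100 subsquares by default) and the overlap area is estimated
#' as the number of subsquare centroids falling inside the polygon times the
#' subsquare area. This deliberately coarse primitive is what the
#' square-to-cell assignment uses; it is fast, deterministic, and accurate
#' to within roughly one subsquare width times the polygon perimeter.
#'
#' @param corner_x,corner_y coordinates of the square's minimum corner; the
#'   square occupies the half-open region \code{[corner, corner + size)}.
#' @param size side length of the square.
#' @param contour polygon vertex matrix.
#' @param n_sub number of subsquares per side (default 10, i.e. 100 total).
#' @return Estimated overlap area (same squared units as the inputs).
#' @export
approximate_overlap <- function(corner_x, corner_y, size, contour, n_sub = 10L) {
  offs <- (seq_len(n_sub) - 0.5) * size / n_sub
  px <- rep(corner_x + offs, times = n_sub)
  py <- rep(corner_y + offs, each = n_sub)
  sum(points_in_polygon(px, py, contour)) * size^2 / n_sub^2
}

#' Exact square/polygon overlap by polygon clipping
#'
#' Sutherland-Hodgman clipping of the polygon against the axis-aligned
#' square, followed by the shoelace formula. Exact for convex polygons;
#' used as an independent reference for \code{\link{approximate_overlap}}.
#'
#' @inheritParams approximate_overlap
#' @return Overlap area.
#' @export
exact_overlap <- function(corner_x, corner_y, size, contour) {
  clipped <- clip_polygon_rect(contour, corner_x, corner_x + size,
                               corner_y, corner_y + size)
  if (is.null(clipped) || nrow(clipped) < 3L) return(0)
  poly_area(clipped)
}

#' Clip a polygon to an axis-aligned rectangle (Sutherland-Hodgman)
#'
#' @param contour polygon vertex matrix.
#' @param xmin,xmax,ymin,ymax rectangle bounds.
#' @return Clipped vertex matrix, or NULL when the intersection is empty.
#' @keywords internal
clip_polygon_rect <- function(contour, xmin, xmax, ymin, ymax) {
  clip_edge <- function(pts, keep, intersect) {
    if (is.null(pts) || nrow(pts) == 0L) return(NULL)
    out <- matrix(numeric(0), ncol = 2L)
    np <- nrow(pts)
    for (i in seq_len(np)) {
      cur <- pts[i, ]
      prv <- pts[if (i == 1L) np else i - 1L, ]
      cin <- keep(cur); pin <- keep(prv)
      if (cin) {
        if (!pin) out <- rbind(out, intersect(prv, cur))
        out <- rbind(out, cur)
      } else if (pin) {
        out <- rbind(out, intersect(prv, cur))
      }
    }
    if (nrow(out) == 0L) NULL else out
  }
  ix <- function(bound, coord) function(p, q) {
    t <- (bound - p[coord]) / (q[coord] - p[coord])
    p + t * (q - p)
  }
  pts <- contour
  pts <- clip_edge(pts, function(p) p[1] >= xmin, ix(xmin, 1L))
  pts <- clip_edge(pts, function(p) p[1] <= xmax, ix(xmax, 1L))
  pts <- clip_edge(pts, function(p) p[2] >= ymin, ix(ymin, 2L))
  pts <- clip_edge(pts, function(p) p[2] <= ymax, ix(ymax, 2L))
  pts
}

#' Expand a nucleus polygon about its centroid
#'
#' Similarity scaling that maps each contour point \eqn{(x_i, y_i)} to
#' \eqn{(s (x_i - x_0) + x_0,\; s (y_i - y_0) + y_0)} about the centroid
#' \eqn{(x_0, y_0)}. The linear factor is \eqn{s = \sqrt{r}} for an area
#' ratio \eqn{r}, so the expanded polygon's area is exactly \eqn{r} times
#' the original area. This approximates the whole-cell boundary from the
#' segmented nucleus; whole cells are typically about twice the area of
#' their nucleus, hence the default ratio of 2.
#'
#' Setting \code{linear_ratio = TRUE} instead uses \eqn{r} itself as the
#' linear factor (giving an area ratio of \eqn{r^2}); this compatibility
#' behavior is not the default because it breaks the stated area
#' relationship.
#'
#' @param nucleus a \code{nucleus_polygon} (see \code{\link{nucleus_polygon}}).
#' @param area_ratio target ratio of expanded to original area; must be >= 1.
#' @param linear_ratio use the ratio as the linear scale factor instead of
#'   its square root.
#' @return A \code{nucleus_polygon} with the same id, scaled contour, and
#'   updated area (centroid is invariant).
#' @export
expand_nucleus <- function(nucleus, area_ratio = 2, linear_ratio = FALSE) {
  stopifnot(inherits(nucleus, "nucleus_polygon"))
  if (area_ratio < 1) stop("`area_ratio` must be >= 1")
  s <- if (linear_ratio) area_ratio else sqrt(area_ratio)
  c0 <- nucleus$centroid
  contour <- sweep(sweep(nucleus$contour, 2L, c0), 2L, c(s, s), `*`)
  contour <- sweep(contour, 2L, c0, `+`)
  nucleus_polygon(nucleus$nucleus_id, contour)
}
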