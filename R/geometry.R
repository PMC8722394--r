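#' Polygon utilities for ROI geometry
#'
#' Polygons are closed 2D outlines stored as an n x 2 numeric matrix of
#' (x, y) vertex pairs in pixel coordinates (1-based pixel centers; the last
#' vertex is implicitly joined to the first). Point-in-polygon membership
#' uses the even-odd rule and is boundary-inclusive: a spot sitting exactly
#' on a drawn outline counts as inside.
#'
#' @name polygon-utils
NULL

as_polygon <- function(poly) {
  poly <- as.matrix(poly)
  if (!is.numeric(poly) || ncol(poly) != 2L || nrow(poly) < 3L)
    stop("a polygon must be a numeric matrix with >= 3 rows of (x, y) vertices")
  if (any(!is.finite(poly))) stop("polygon vertices must be finite")
  # drop a duplicated closing vertex if present
  n <- nrow(poly)
  if (isTRUE(all.equal(poly[1L, ], poly[n, ], check.attributes = FALSE)))
    poly <- poly[-n, , drop = FALSE]
  if (nrow(poly) < 3L) stop("polygon collapses to fewer than 3 distinct vertices")
  colnames(poly) <- c("x", "y")
  unname(poly) -> p
  colnames(p) <- c("x", "y")
  p
}

#' Signed and absolute polygon area (shoelace formula)
#' @param poly n x 2 matrix of (x, y) vertices.
#' @return Absolute enclosed area in square pixels.
#' @export
polygon_area <- function(poly) abs(polygon_signed_area(poly))

polygon_signed_area <- function(poly) {
  poly <- as_polygon(poly)
  x <- poly[, 1L]; y <- poly[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1L] - a[1L]) * (c[2L] - a[2L]) - (b[2L] - a[2L]) * (c[1L] - a[1L])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(a, b, c) {
    min(a[1L], b[1L]) <= c[1L] && c[1L] <= max(a[1L], b[1L]) &&
      min(a[2L], b[2L]) <= c[2L] && c[2L] <= max(a[2L], b[2L])
  }
  (d1 == 0 && on_seg(p3, p4, p1)) || (d2 == 0 && on_seg(p3, p4, p2)) ||
    (d3 == 0 && on_seg(p1, p2, p3)) || (d4 == 0 && on_seg(p1, p2, p4))
}

#' Test whether a polygon is simple (non-self-intersecting)
#' @param poly n x 2 matrix of (x, y) vertices.
#' @return Logical scalar.
#' @export
is_simple_polygon <- function(poly) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  idx <- function(i) ((i - 1L) %% n) + 1L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      # skip adjacent edges (they share a vertex by construction)
      if (j == i + 1L || (i == 1L && j == n)) next
      if (segments_intersect(poly[i, ], poly[idx(i + 1L), ],
                             poly[j, ], poly[idx(j + 1L), ])) return(FALSE)
    }
  }
  TRUE
}

#' Boundary-inclusive even-odd point-in-polygon test
#'
#' @param x,y Numeric vectors of point coordinates (recycled to a common
#'   length).
#' @param poly n x 2 matrix of (x, y) vertices.
#' @return Logical vector, `TRUE` where the point lies inside or on the
#'   polygon boundary.
#' @export
point_in_polygon <- function(x, y, poly) {
  poly <- as_polygon(poly)
  if (length(x) == 0L) return(logical(0L))
  pracma::inpolygon(x, y, poly[, 1L], poly[, 2L], boundary = TRUE)
}

#' Test whether one polygon is contained in another
#'
#' Containment is checked on the vertices of `inner` plus a deterministic
#' grid of interior sample points, all of which must fall inside `outer`.
#'
#' @param inner,outer Polygons as n x 2 (x, y) matrices.
#' @return Logical scalar.
#' @export
polygon_contains <- function(outer, inner) {
  inner <- as_polygon(inner); outer <- as_polygon(outer)
  if (!all(point_in_polygon(inner[, 1L], inner[, 2L], outer))) return(FALSE)
  # edge midpoints guard against vertices-in / edge-out configurations
  mid <- (inner + inner[c(2:nrow(inner), 1L), ]) / 2
  all(point_in_polygon(mid[, 1L], mid[, 2L], outer))
}

polygon_centroid <- function(poly) {
  poly <- as_polygon(poly)
  a <- polygon_signed_area(poly)
  x <- poly[, 1L]; y <- poly[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  c(x = sum((x + xn) * cr) / (6 * a), y = sum((y + yn) * cr) / (6 * a))
}

# Sutherland-Hodgman clip of a polygon against the half-plane
# {q : dot(q - p0, n) >= 0}
clip_halfplane <- function(poly, p0, n) {
  m <- nrow(poly)
  out <- matrix(numeric(0), 0L, 2L)
  side <- as.vector((poly[, 1L] - p0[1L]) * n[1L] + (poly[, 2L] - p0[2L]) * n[2L])
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    a <- poly[i, ]; b <- poly[j, ]
    sa <- side[i]; sb <- side[j]
    if (sa >= 0) out <- rbind(out, a)
    if ((sa > 0 && sb < 0) || (sa < 0 && sb > 0)) {
      t <- sa / (sa - sb)
      out <- rbind(out, a + t * (b - a))
    }
  }
  out
}

#' Offset a polygon inward by a fixed distance
#'
#' Computes the inward parallel offset ("negative buffer") of a convex
#' polygon by clipping it against each edge's inward-shifted half-plane.
#' This mirrors how an interior outline is drawn parallel to a cell border
#' to separate peri-membrane signal from cytoplasmic+nuclear signal.
#'
#' For convex polygons the result is the exact inward offset. For
#' non-convex simple polygons the half-plane intersection is a conservative
#' (never too large) approximation; cell outlines in this package's scenes
#' are convex.
#'
#' @param poly n x 2 matrix of (x, y) vertices.
#' @param distance_px Non-negative offset distance in pixels; must be less
#'   than the polygon inradius or the offset collapses.
#' @return The offset polygon as an m x 2 (x, y) matrix.
#' @export
offset_polygon_inward <- function(poly, distance_px) {
  poly <- as_polygon(poly)
  stopifnot(is.numeric(distance_px), length(distance_px) == 1L, is.finite(distance_px))
  if (distance_px < 0) stop("distance_px must be non-negative")
  if (distance_px == 0) return(poly)
  # orient counter-clockwise so the left edge normal points inward
  if (polygon_signed_area(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
  out <- poly
  n <- nrow(poly)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- poly[j, ] - poly[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    normal <- c(-e[2L], e[1L]) / len   # inward for CCW orientation
    out <- clip_halfplane(out, poly[i, ] + distance_px * normal, normal)
    if (nrow(out) < 3L)
      stop("inward offset of ", distance_px, " px collapses the polygon ",
           "(distance exceeds the polygon inradius)")
  }
  if (polygon_area(out) <= 0)
    stop("inward offset of ", distance_px, " px collapses the polygon ",
         "(distance exceeds the polygon inradius)")
  colnames(out) <- c("x", "y")
  out
}

#' Axis-aligned rectangle polygon
#' @param x0,y0,x1,y1 Corner coordinates with `x0 < x1`, `y0 < y1`.
#' @return A 4 x 2 (x, y) polygon matrix.
#' @export
rect_polygon <- function(x0, y0, x1, y1) {
  stopifnot(x0 < x1, y0 < y1)
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

#' Regular-polygon approximation of a disc
#' @param cx,cy Center coordinates. @param r Radius in pixels.
#' @param n_vertices Number of vertices (default 32).
#' @return An n x 2 (x, y) polygon matrix.
#' @export
disc_polygon <- function(cx, cy, r, n_vertices = 32L) {
  stopifnot(r > 0, n_vertices >= 3L)
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}
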