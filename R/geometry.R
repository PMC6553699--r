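# Planar polygon and polyline primitives shared by registration, centerline,
# binning and QC. Contours are n x 2 matrices of distinct vertices in mm,
# implicitly closed (last vertex connects back to the first).

#' Drop a duplicated closing vertex
#'
#' Accepts contours stored either open or with `first == last` and returns the
#' open (implicitly closed) representation used internally.
#' @param pts numeric matrix, n x 2.
#' @return matrix with any duplicated closing vertex removed.
#' @keywords internal
drop_closing_vertex <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n >= 2 && all(abs(pts[1, ] - pts[n, ]) < 1e-12)) pts <- pts[-n, , drop = FALSE]
  pts
}

#' Signed polygon area (shoelace formula)
#' @param pts implicitly closed contour, n x 2.
#' @return signed area in mm^2; positive for counter-clockwise orientation.
#' @keywords internal
polygon_signed_area <- function(pts) {
  pts <- drop_closing_vertex(pts)
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Ensure counter-clockwise orientation (viewed from +z)
#' @keywords internal
orient_ccw <- function(pts) {
  pts <- drop_closing_vertex(pts)
  if (polygon_signed_area(pts) < 0) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  pts
}

# Proper segment intersection test used by the simplicity check. Segments
# sharing an endpoint (adjacent edges) are not reported.
.segments_cross <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2); d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) && ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

#' Test whether a closed contour is simple (non self-intersecting)
#'
#' O(n^2) pairwise edge test; adequate for the contour sizes handled here
#' (tens to a few hundred vertices).
#' @param pts implicitly closed contour.
#' @return logical.
#' @keywords internal
polygon_is_simple <- function(pts) {
  pts <- drop_closing_vertex(pts)
  n <- nrow(pts)
  if (n < 3) return(FALSE)
  nxt <- c(seq_len(n)[-1], 1L)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # skip adjacent edges (they share a vertex)
      if (j == i || nxt[i] == j || nxt[j] == i) next
      if (.segments_cross(pts[i, ], pts[nxt[i], ], pts[j, ], pts[nxt[j], ])) return(FALSE)
    }
  }
  TRUE
}

#' Point-in-polygon test (even-odd ray casting), vectorized over points
#' @param px,py point coordinates.
#' @param poly implicitly closed contour.
#' @return logical vector; boundary points may fall on either side.
#' @keywords internal
point_in_polygon <- function(px, py, poly) {
  poly <- drop_closing_vertex(poly)
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]; xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Minimum distance from points to a closed polyline
#'
#' Exact point-to-segment distances, looped over edges with a running minimum
#' so memory stays linear in the number of query points.
#' @param px,py query coordinates.
#' @param poly implicitly closed contour.
#' @return numeric vector of distances in mm.
#' @keywords internal
dist_to_polygon <- function(px, py, poly) {
  poly <- drop_closing_vertex(poly)
  n <- nrow(poly)
  dmin <- rep(Inf, length(px))
  j <- n
  for (i in seq_len(n)) {
    ax <- poly[j, 1]; ay <- poly[j, 2]
    bx <- poly[i, 1]; by <- poly[i, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx * vx + vy * vy
    if (L2 < 1e-300) {
      d2 <- (px - ax)^2 + (py - ay)^2
    } else {
      t <- pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
      d2 <- (px - (ax + t * vx))^2 + (py - (ay + t * vy))^2
    }
    dmin <- pmin(dmin, d2)
    j <- i
  }
  sqrt(dmin)
}

#' Signed distance to a closed contour (negative inside)
#' @keywords internal
polygon_signed_distance <- function(px, py, poly) {
  d <- dist_to_polygon(px, py, poly)
  ifelse(point_in_polygon(px, py, poly), -d, d)
}

#' Resample a closed contour at (approximately) even arc-length spacing
#'
#' @param pts implicitly closed contour.
#' @param spacing_mm target arc spacing; the actual spacing is the perimeter
#'   divided by the rounded-up number of samples, so it never exceeds
#'   `spacing_mm`.
#' @return m x 2 matrix of points on the contour, implicitly closed.
#' @keywords internal
resample_contour <- function(pts, spacing_mm) {
  stopifnot(spacing_mm > 0)
  pts <- drop_closing_vertex(pts)
  closed <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  per <- sum(seg)
  if (per <= 0) stop("contour has zero perimeter")
  m <- max(nrow(pts), as.integer(ceiling(per / spacing_mm)))
  s_target <- per * (seq_len(m) - 1) / m
  s_cum <- c(0, cumsum(seg))
  idx <- findInterval(s_target, s_cum, rightmost.closed = TRUE)
  idx[idx >= length(s_cum)] <- length(s_cum) - 1L
  f <- (s_target - s_cum[idx]) / seg[idx]
  a <- closed[idx, , drop = FALSE]
  b <- closed[idx + 1L, , drop = FALSE]
  a + f * (b - a)
}

#' Validate a contour used as module input
#' @param pts candidate contour.
#' @param what label used in error messages.
#' @param check_simple run the O(n^2) self-intersection test.
#' @return oriented (CCW) open contour matrix.
#' @keywords internal
validate_contour <- function(pts, what = "contour", check_simple = TRUE) {
  pts <- drop_closing_vertex(as.matrix(pts))
  if (!is.numeric(pts) || ncol(pts) != 2)
    stop(what, ": expected an n x 2 numeric matrix")
  if (nrow(unique(round(pts, 12))) < 3)
    stop(what, ": needs at least 3 distinct vertices")
  if (abs(polygon_signed_area(pts)) < 1e-12)
    stop(what, ": degenerate (zero area)")
  if (check_simple && !polygon_is_simple(pts))
    stop(what, ": self-intersecting contour rejected")
  orient_ccw(pts)
}

#' Generate a regular polygon approximating a circle
#' @param center length-2 numeric.
#' @param radius radius in mm.
#' @param n number of vertices.
#' @param phase angular offset of the first vertex (radians).
#' @return n x 2 contour matrix.
#' @export
circle_contour <- function(center = c(0, 0), radius = 1, n = 72, phase = 0) {
  th <- phase + 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}
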