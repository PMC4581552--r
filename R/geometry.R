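# Low-level planar geometry used throughout the simulator.
# All coordinates are millimetres in the x-y working plane.

#' Cumulative arc length of a polyline
#'
#' @param xy two-column matrix of vertices (mm).
#' @return numeric vector of cumulative arc lengths, starting at 0.
#' @keywords internal
polyline_arclength <- function(xy) {
  d <- sqrt(rowSums(diff(xy)^2))
  c(0, cumsum(d))
}

#' Total length of a polyline
#' @keywords internal
polyline_length <- function(xy) {
  sum(sqrt(rowSums(diff(xy)^2)))
}

#' Resample a polyline at evenly spaced arc-length stations
#'
#' @param xy two-column matrix.
#' @param n number of output vertices.
#' @return `n` x 2 matrix; first and last vertices preserved.
#' @keywords internal
resample_polyline <- function(xy, n) {
  s <- polyline_arclength(xy)
  if (s[length(s)] <= 0) return(matrix(rep(xy[1, ], n), ncol = 2, byrow = TRUE))
  st <- seq(0, s[length(s)], length.out = n)
  cbind(stats::approx(s, xy[, 1], xout = st, ties = "ordered")$y,
        stats::approx(s, xy[, 2], xout = st, ties = "ordered")$y)
}

#' Interpolate a point at a given arc length along a polyline
#' @keywords internal
polyline_point_at <- function(xy, at) {
  s <- polyline_arclength(xy)
  at <- pmin(pmax(at, 0), s[length(s)])
  cbind(stats::approx(s, xy[, 1], xout = at, ties = "ordered")$y,
        stats::approx(s, xy[, 2], xout = at, ties = "ordered")$y)
}

#' Unit tangents of a polyline by central differences
#' @keywords internal
polyline_tangents <- function(xy) {
  n <- nrow(xy)
  tx <- c(xy[2, 1] - xy[1, 1],
          xy[3:n, 1] - xy[1:(n - 2), 1],
          xy[n, 1] - xy[n - 1, 1])
  ty <- c(xy[2, 2] - xy[1, 2],
          xy[3:n, 2] - xy[1:(n - 2), 2],
          xy[n, 2] - xy[n - 1, 2])
  len <- sqrt(tx^2 + ty^2)
  len[len == 0] <- 1
  cbind(tx / len, ty / len)
}

#' Signed curvature of a polyline at interior vertices
#'
#' Turning angle between consecutive edges divided by mean edge length;
#' endpoints copy their neighbours. Positive = left turn.
#' @keywords internal
polyline_curvature <- function(xy) {
  n <- nrow(xy)
  e <- diff(xy)
  len <- sqrt(rowSums(e^2))
  a <- atan2(e[, 2], e[, 1])
  dth <- diff(a)
  dth <- atan2(sin(dth), cos(dth))           # wrap to (-pi, pi]
  ds <- (len[-1] + len[-(n - 1)]) / 2
  k <- dth / ds
  c(k[1], k, k[length(k)])
}

#' Rotate points about a pivot
#'
#' @param xy n x 2 matrix.
#' @param angle_deg rotation angle, degrees, counter-clockwise.
#' @param pivot length-2 pivot point.
#' @keywords internal
rotate_about <- function(xy, angle_deg, pivot = c(0, 0)) {
  a <- angle_deg * pi / 180
  ca <- cos(a); sa <- sin(a)
  x <- xy[, 1] - pivot[1]; y <- xy[, 2] - pivot[2]
  cbind(pivot[1] + ca * x - sa * y, pivot[2] + sa * x + ca * y)
}

#' Vectorized even-odd point-in-polygon test
#'
#' Ray-crossing rule; points exactly on an edge may land on either side
#' (callers never depend on boundary points).
#'
#' @param px,py point coordinates.
#' @param poly closed or open polygon vertex matrix (closure implied).
#' @return logical vector.
#' @keywords internal
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  if (isTRUE(all.equal(poly[1, ], poly[n, ]))) {
    poly <- poly[-n, , drop = FALSE]
    n <- n - 1
  }
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Shoelace area of a simple polygon
#'
#' @return unsigned area (mm^2).
#' @keywords internal
polygon_area <- function(poly) {
  n <- nrow(poly)
  if (isTRUE(all.equal(poly[1, ], poly[n, ]))) poly <- poly[-n, , drop = FALSE]
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Parameters of intersections between one segment and all polygon edges
#'
#' For segment A->B and every edge (C_j, D_j) of `poly`, returns the
#' parameters t in \[0, 1\] along A->B at which a proper crossing occurs.
#'
#' @keywords internal
segment_polygon_crossings <- function(a, b, poly) {
  n <- nrow(poly)
  cx <- poly[-n, 1]; cy <- poly[-n, 2]
  dx <- poly[-1, 1]; dy <- poly[-1, 2]
  rx <- b[1] - a[1]; ry <- b[2] - a[2]
  sx <- dx - cx; sy <- dy - cy
  denom <- rx * sy - ry * sx
  qpx <- cx - a[1]; qpy <- cy - a[2]
  t <- (qpx * sy - qpy * sx) / denom
  u <- (qpx * ry - qpy * rx) / denom
  ok <- is.finite(t) & denom != 0 & t > 0 & t < 1 & u >= 0 & u < 1
  sort(t[ok])
}

#' Self-intersection check for a polyline or polygon boundary
#'
#' O(n^2) with bounding-box prefilter; adjacent edges are exempt.
#'
#' @param xy vertex matrix (closed rings should repeat the first vertex).
#' @return TRUE when some pair of non-adjacent edges crosses.
#' @keywords internal
polyline_self_intersects <- function(xy) {
  n <- nrow(xy) - 1
  if (n < 3) return(FALSE)
  x1 <- xy[1:n, 1]; y1 <- xy[1:n, 2]
  x2 <- xy[2:(n + 1), 1]; y2 <- xy[2:(n + 1), 2]
  closed <- isTRUE(all.equal(xy[1, ], xy[n + 1, ]))
  bxmin <- pmin(x1, x2); bxmax <- pmax(x1, x2)
  bymin <- pmin(y1, y2); bymax <- pmax(y1, y2)
  for (i in seq_len(n - 2)) {
    j <- (i + 2):n
    if (closed && i == 1) j <- j[j != n]     # first and last edge are adjacent
    cand <- j[bxmin[j] <= bxmax[i] & bxmax[j] >= bxmin[i] &
                bymin[j] <= bymax[i] & bymax[j] >= bymin[i]]
    if (!length(cand)) next
    rx <- x2[i] - x1[i]; ry <- y2[i] - y1[i]
    sx <- x2[cand] - x1[cand]; sy <- y2[cand] - y1[cand]
    denom <- rx * sy - ry * sx
    qpx <- x1[cand] - x1[i]; qpy <- y1[cand] - y1[i]
    t <- (qpx * sy - qpy * sx) / denom
    u <- (qpx * ry - qpy * rx) / denom
    hit <- is.finite(t) & denom != 0 & t > 1e-12 & t < 1 - 1e-12 &
      u > 1e-12 & u < 1 - 1e-12
    if (any(hit)) return(TRUE)
  }
  FALSE
}

#' Minimum distance from points to a polyline
#'
#' @param px,py point coordinates.
#' @param xy polyline vertex matrix.
#' @return numeric vector of distances.
#' @keywords internal
points_polyline_distance <- function(px, py, xy) {
  n <- nrow(xy) - 1
  ax <- xy[1:n, 1]; ay <- xy[1:n, 2]
  bx <- xy[2:(n + 1), 1]; by <- xy[2:(n + 1), 2]
  ex <- bx - ax; ey <- by - ay
  el2 <- ex^2 + ey^2
  el2[el2 == 0] <- 1e-300
  out <- numeric(length(px))
  for (k in seq_along(px)) {
    t <- ((px[k] - ax) * ex + (py[k] - ay) * ey) / el2
    t <- pmin(pmax(t, 0), 1)
    out[k] <- sqrt(min((px[k] - (ax + t * ex))^2 + (py[k] - (ay + t * ey))^2))
  }
  out
}
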