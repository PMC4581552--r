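# Logarithmic-spiral primitives. The spiral r(theta) = a * exp(b * theta),
# evaluated about a centre point in the x-y working plane, is the canonical
# manufactured shape of a preformed perimodiolar electrode array.

#' Evaluate a logarithmic spiral
#'
#' @param theta polar angles (radians).
#' @param a scale (mm), must be > 0.
#' @param b dimensionless growth rate.
#' @param center length-2 centre (mm).
#' @return matrix of points, one row per `theta`.
#' @export
log_spiral_points <- function(theta, a, b, center = c(0, 0)) {
  r <- a * exp(b * theta)
  cbind(center[1] + r * cos(theta), center[2] + r * sin(theta))
}

#' Arc length of a logarithmic spiral between two angles
#'
#' Closed form: s = a * sqrt(1 + b^2) / b * (exp(b*theta2) - exp(b*theta1)).
#' @export
log_spiral_arclength <- function(a, b, theta1, theta2) {
  if (abs(b) < 1e-12) return(a * abs(theta2 - theta1))
  a * sqrt(1 + b^2) / b * (exp(b * theta2) - exp(b * theta1))
}

#' Unsigned curvature of a logarithmic spiral at an angle
#'
#' kappa = 1 / (r * sqrt(1 + b^2)).
#' @export
log_spiral_curvature <- function(theta, a, b) {
  1 / (a * exp(b * theta) * sqrt(1 + b^2))
}

#' Orthogonal distance from points to a logarithmic spiral arc
#'
#' One-dimensional minimization per point over the polar angle, initialized
#' at the point's own (unwrapped) angle about the centre.
#'
#' @param pts n x 2 matrix.
#' @param a,b,center spiral parameters.
#' @param theta_hint optional per-point initial angles (radians, unwrapped).
#' @return list with `dist` (numeric) and `theta` (foot angles).
#' @keywords internal
spiral_orthogonal_distance <- function(pts, a, b, center, theta_hint = NULL) {
  n <- nrow(pts)
  if (is.null(theta_hint)) {
    theta_hint <- unwrap_angles(atan2(pts[, 2] - center[2],
                                      pts[, 1] - center[1]))
  }
  f <- function(th, p) {
    q <- c(center[1] + a * exp(b * th) * cos(th),
           center[2] + a * exp(b * th) * sin(th))
    sum((p - q)^2)
  }
  d <- numeric(n); th_out <- numeric(n)
  for (i in seq_len(n)) {
    o <- stats::optimize(f, lower = theta_hint[i] - pi,
                         upper = theta_hint[i] + pi, p = pts[i, ],
                         tol = 1e-12)
    d[i] <- sqrt(o$objective)
    th_out[i] <- o$minimum
  }
  list(dist = d, theta = th_out)
}

#' Unwrap a sequence of angles to a continuous branch
#' @keywords internal
unwrap_angles <- function(a) {
  d <- diff(a)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(a[1], d))
}
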