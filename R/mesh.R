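# 3D route to the 2D cochlear contours: a triangulated inner-ear surface is
# cut by a half-plane rotating in equal steps about the modiolar axis; per
# angle the extreme inner and outer lumen points are sampled, and the 3D
# sample cloud is flattened onto an orthogonal-distance-regression plane.

#' Modiolar rotation axis
#'
#' @param point a point on the axis, 3D mm.
#' @param direction axis direction (normalized internally), pointing from
#'   base toward apex.
#' @export
modiolar_axis <- function(point, direction) {
  d <- as.numeric(direction)
  nd <- sqrt(sum(d^2))
  if (nd < 1e-12) {
    stop(errorCondition("axis direction must be non-zero",
                        class = c("cochsim_invalid_input", "error")))
  }
  structure(list(point = as.numeric(point), direction = d / nd),
            class = "modiolar_axis")
}

#' Read a triangulated surface from an STL file (ASCII or binary)
#'
#' @param path file path.
#' @return a `surface_mesh`: list of three n x 3 matrices `v1`, `v2`, `v3`
#'   (triangle corners, mm).
#' @export
read_stl <- function(path) {
  head_raw <- readBin(path, "raw", n = 80)
  head_txt <- tolower(rawToChar(head_raw[head_raw != as.raw(0)]))
  is_ascii <- startsWith(trimws(head_txt), "solid") &&
    grepl("facet", tolower(paste(readLines(path, n = 10, warn = FALSE),
                                 collapse = " ")), fixed = TRUE)
  if (is_ascii) {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", txt, value = TRUE)
    nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x) {
      as.numeric(x[2:4])
    }))
    if (is.null(nums) || nrow(nums) %% 3 != 0) {
      stop(errorCondition("malformed ASCII STL",
                          class = c("cochsim_invalid_input", "error")))
    }
    idx <- seq_len(nrow(nums) / 3)
    mesh <- list(v1 = nums[3 * idx - 2, , drop = FALSE],
                 v2 = nums[3 * idx - 1, , drop = FALSE],
                 v3 = nums[3 * idx, , drop = FALSE])
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 80)
    ntri <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    rec <- readBin(con, "raw", n = ntri * 50)
    m <- matrix(rec, nrow = 50)
    tri <- vapply(seq_len(ntri), function(i) {
      readBin(m[13:48, i], "numeric", n = 9, size = 4, endian = "little")
    }, numeric(9))
    mesh <- list(v1 = t(tri[1:3, , drop = FALSE]),
                 v2 = t(tri[4:6, , drop = FALSE]),
                 v3 = t(tri[7:9, , drop = FALSE]))
  }
  structure(mesh, class = "surface_mesh")
}

#' Write a surface mesh as ASCII STL
#'
#' @param mesh a `surface_mesh`.
#' @param path output path.
#' @export
write_stl <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid cochsim", con)
  n <- nrow(mesh$v1)
  for (i in seq_len(n)) {
    e1 <- mesh$v2[i, ] - mesh$v1[i, ]
    e2 <- mesh$v3[i, ] - mesh$v1[i, ]
    nv <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    nv <- nv / max(sqrt(sum(nv^2)), 1e-300)
    writeLines(sprintf("  facet normal %.6e %.6e %.6e", nv[1], nv[2], nv[3]),
               con)
    writeLines("    outer loop", con)
    for (v in list(mesh$v1[i, ], mesh$v2[i, ], mesh$v3[i, ])) {
      writeLines(sprintf("      vertex %.6e %.6e %.6e", v[1], v[2], v[3]),
                 con)
    }
    writeLines("    endloop", con)
    writeLines("  endfacet", con)
  }
  writeLines("endsolid cochsim", con)
  invisible(path)
}

#' Triangulated tube around a 3D centerline (synthetic lumen fixture)
#'
#' Sweeps a circle of given radius along the polyline using parallel
#' transport frames.
#'
#' @param centerline n x 3 matrix, mm.
#' @param radius tube radius, mm (scalar or per-vertex).
#' @param n_circ vertices around the circumference.
#' @return a `surface_mesh`.
#' @export
synthesize_tube_mesh <- function(centerline, radius, n_circ = 24) {
  n <- nrow(centerline)
  r <- rep_len(radius, n)
  tang <- rbind(centerline[2, ] - centerline[1, ],
                centerline[3:n, ] - centerline[1:(n - 2), ],
                centerline[n, ] - centerline[n - 1, ])
  tang <- tang / sqrt(rowSums(tang^2))
  # parallel transport an initial normal along the curve
  up <- c(0, 0, 1)
  if (abs(sum(up * tang[1, ])) > 0.9) up <- c(1, 0, 0)
  nrm <- matrix(0, n, 3)
  nrm[1, ] <- up - sum(up * tang[1, ]) * tang[1, ]
  nrm[1, ] <- nrm[1, ] / sqrt(sum(nrm[1, ]^2))
  for (i in 2:n) {
    v <- nrm[i - 1, ] - sum(nrm[i - 1, ] * tang[i, ]) * tang[i, ]
    nrm[i, ] <- v / sqrt(sum(v^2))
  }
  bin <- cbind(tang[, 2] * nrm[, 3] - tang[, 3] * nrm[, 2],
               tang[, 3] * nrm[, 1] - tang[, 1] * nrm[, 3],
               tang[, 1] * nrm[, 2] - tang[, 2] * nrm[, 1])
  ang <- seq(0, 2 * pi, length.out = n_circ + 1)[-(n_circ + 1)]
  rings <- lapply(seq_len(n), function(i) {
    centerline[rep(i, n_circ), ] +
      outer(cos(ang) * r[i], nrm[i, ]) + outer(sin(ang) * r[i], bin[i, ])
  })
  v1 <- NULL; v2 <- NULL; v3 <- NULL
  for (i in seq_len(n - 1)) {
    a <- rings[[i]]; b <- rings[[i + 1]]
    j <- seq_len(n_circ); jn <- c(2:n_circ, 1)
    v1 <- rbind(v1, a[j, ], a[jn, ])
    v2 <- rbind(v2, b[j, ], b[jn, ])
    v3 <- rbind(v3, a[jn, ], b[j, ])
  }
  structure(list(v1 = v1, v2 = v2, v3 = v3), class = "surface_mesh")
}

#' Sample lumen cross sections with a rotating cutting half-plane
#'
#' The cutting plane contains the modiolar axis and is rotated in equal
#' angular steps (default 5 degrees) starting from
#' a reference plane. Per angle, the mesh-plane intersection points on the
#' half-plane side are reduced to the basal-most intersection loop, and the
#' extreme inner/outer points at the level of greatest lateral extent are
#' returned (automating what is otherwise a manual point-picking step).
#'
#' @param mesh a `surface_mesh`.
#' @param axis a `modiolar_axis`.
#' @param step_deg angular step, degrees.
#' @param start_plane reference angle, degrees (default 0: the plane through
#'   the round-window niche).
#' @param angle_range total swept angle, degrees (default 720: two turns).
#' @return list of `cross_section_sample`s (`plane_angle`, `inner_point`,
#'   `outer_point`).
#' @export
sample_cross_sections <- function(mesh, axis, step_deg = 5,
                                  start_plane = 0, angle_range = 720) {
  stopifnot(inherits(axis, "modiolar_axis"))
  ad <- axis$direction
  p0 <- axis$point
  # orthonormal basis perpendicular to the axis
  ref <- c(1, 0, 0)
  if (abs(sum(ref * ad)) > 0.9) ref <- c(0, 1, 0)
  e1 <- ref - sum(ref * ad) * ad
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(ad[2] * e1[3] - ad[3] * e1[2],
          ad[3] * e1[1] - ad[1] * e1[3],
          ad[1] * e1[2] - ad[2] * e1[1])
  angles <- seq(start_plane, start_plane + angle_range - step_deg,
                by = step_deg)
  all_pts <- rbind(mesh$v1, mesh$v2, mesh$v3)
  samples <- list()
  skipped <- 0L
  for (phi in angles) {
    a <- phi * pi / 180
    d <- cos(a) * e1 + sin(a) * e2       # in-plane radial direction
    nn <- -sin(a) * e1 + cos(a) * e2     # plane normal
    s1 <- (mesh$v1[, 1] - p0[1]) * nn[1] + (mesh$v1[, 2] - p0[2]) * nn[2] +
      (mesh$v1[, 3] - p0[3]) * nn[3]
    s2 <- (mesh$v2[, 1] - p0[1]) * nn[1] + (mesh$v2[, 2] - p0[2]) * nn[2] +
      (mesh$v2[, 3] - p0[3]) * nn[3]
    s3 <- (mesh$v3[, 1] - p0[1]) * nn[1] + (mesh$v3[, 2] - p0[2]) * nn[2] +
      (mesh$v3[, 3] - p0[3]) * nn[3]
    pts <- NULL
    for (pair in list(list(mesh$v1, s1, mesh$v2, s2),
                      list(mesh$v2, s2, mesh$v3, s3),
                      list(mesh$v3, s3, mesh$v1, s1))) {
      A <- pair[[1]]; sa <- pair[[2]]; B <- pair[[3]]; sb <- pair[[4]]
      hit <- (sa > 0) != (sb > 0)
      if (!any(hit)) next
      t <- sa[hit] / (sa[hit] - sb[hit])
      pts <- rbind(pts, A[hit, , drop = FALSE] +
                     (B[hit, , drop = FALSE] - A[hit, , drop = FALSE]) * t)
    }
    if (is.null(pts)) { skipped <- skipped + 1L; next }
    rel <- sweep(pts, 2, p0)
    rr <- rel %*% d
    hh <- rel %*% ad
    side <- rr > 0
    if (!any(side)) { skipped <- skipped + 1L; next }
    rr <- rr[side]; hh <- hh[side]
    # basal-most loop: cluster by axial height with a gap heuristic
    o <- order(hh)
    hs <- hh[o]; rs <- rr[o]
    gaps <- diff(hs)
    cut <- which(gaps > max(3 * stats::median(gaps), 0.5))
    starts <- c(1, cut + 1)
    ends <- c(cut, length(hs))
    ci <- 1                                # basal-most = lowest height
    sel <- starts[ci]:ends[ci]
    hs <- hs[sel]; rs <- rs[sel]
    h_star <- hs[which.max(rs)]
    band <- abs(hs - h_star) <= max(diff(range(hs)) * 0.25, 1e-6)
    r_in <- min(rs[band]); r_out <- max(rs[band])
    samples[[length(samples) + 1]] <- structure(list(
      plane_angle = phi,
      inner_point = p0 + r_in * d + h_star * ad,
      outer_point = p0 + r_out * d + h_star * ad),
      class = "cross_section_sample")
  }
  if (!length(samples)) {
    stop(errorCondition("cutting plane never intersected the mesh",
                        class = c("cochsim_invalid_mesh", "error")))
  }
  if (skipped > 0) {
    warning(sprintf("%d cutting angles had no mesh intersection and were skipped",
                    skipped))
  }
  samples
}

#' Project cross-section samples onto their orthogonal-distance-regression
#' plane
#'
#' Fits the plane minimizing orthogonal distances to all inner and outer
#' points (via SVD), projects the samples onto it, and assembles a 2D
#' contour pair ordered by plane angle, normalized to the package's
#' coordinate convention (cochleostomy at the origin, entry along -x, curl
#' matching the electrode handedness).
#'
#' @param samples list of `cross_section_sample`s (>= 6).
#' @return a `cochlea_contour`; attribute `plane` carries the fitted plane
#'   (`origin`, `normal`, max residual).
#' @export
project_to_plane <- function(samples) {
  if (length(samples) < 6) {
    stop(errorCondition("plane projection needs at least 6 samples",
                        class = c("cochsim_invalid_input", "error")))
  }
  ang <- vapply(samples, `[[`, numeric(1), "plane_angle")
  o <- order(ang)
  samples <- samples[o]
  inner3 <- do.call(rbind, lapply(samples, `[[`, "inner_point"))
  outer3 <- do.call(rbind, lapply(samples, `[[`, "outer_point"))
  pts <- rbind(inner3, outer3)
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  if (sv$d[2] < 1e-9) {
    stop(errorCondition("sample points are collinear; plane is degenerate",
                        class = c("cochsim_degenerate_plane", "error")))
  }
  e1 <- sv$v[, 1]; e2 <- sv$v[, 2]; nn <- sv$v[, 3]
  resid <- abs(sweep(pts, 2, ctr) %*% nn)
  to2d <- function(p3) cbind(sweep(p3, 2, ctr) %*% e1,
                             sweep(p3, 2, ctr) %*% e2)
  inner <- to2d(inner3)
  outer <- to2d(outer3)
  centerline <- (inner + outer) / 2
  # canonical handedness: heading decreasing (clockwise) going apical
  e <- diff(centerline)
  aa <- unwrap_angles(atan2(e[, 2], e[, 1]))
  if (aa[length(aa)] > aa[1]) {
    inner[, 2] <- -inner[, 2]; outer[, 2] <- -outer[, 2]
    centerline[, 2] <- -centerline[, 2]
  }
  # entry frame: basal centerline point to the origin, entry along -x
  e0 <- centerline[2, ] - centerline[1, ]
  rot <- (pi - atan2(e0[2], e0[1])) * 180 / pi
  org <- centerline[1, ]
  fix <- function(xy) {
    out <- rotate_about(sweep(xy, 2, org), rot, c(0, 0))
    out
  }
  inner <- fix(inner); outer <- fix(outer); centerline <- fix(centerline)
  w <- sqrt(rowSums((outer - inner)^2))
  cfg <- cochlea_default_config()
  cont <- new_cochlea_contour(inner, outer, centerline, w,
                              "projected", cfg)
  cont$distance_A <- tryCatch(measure_distance_A(cont),
                              error = function(e) NA_real_)
  attr(cont, "plane") <- list(origin = ctr, normal = nn,
                              max_residual = max(resid))
  cont
}
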