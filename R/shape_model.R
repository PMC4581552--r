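# Fitting a continuous shape model -- a logarithmic spiral plus up to three
# straight segments -- through digitized electrode landmarks (22 contact
# centres and the tip), ordered base to tip.

#' Orthogonal (total-least-squares) line fit
#' @return list with `point` (centroid), `dir` (unit), `rss`.
#' @keywords internal
fit_line_orth <- function(pts) {
  ctr <- colMeans(pts)
  x <- sweep(pts, 2, ctr)
  sv <- svd(x)
  dir <- sv$v[, 1]
  resid <- x %*% sv$v[, 2]
  list(point = ctr, dir = dir, rss = sum(resid^2))
}

#' Kasa algebraic circle fit (initializer for the spiral centre)
#' @keywords internal
fit_circle_kasa <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  A <- cbind(x, y, 1)
  rhs <- -(x^2 + y^2)
  sol <- tryCatch(stats::lm.fit(A, rhs)$coefficients, error = function(e) NULL)
  if (is.null(sol) || anyNA(sol)) return(colMeans(pts))
  c(-sol[1] / 2, -sol[2] / 2)
}

# Log-linear spiral fit for a fixed centre: regress log(rho) on unwrapped
# polar angle. Returns an approximate orthogonal RSS (radial residuals scaled
# by the pitch factor 1/sqrt(1+b^2)).
spiral_fit_fixed_center <- function(pts, center) {
  dxy <- sweep(pts, 2, center)
  rho <- sqrt(rowSums(dxy^2))
  if (any(rho < 1e-9)) return(NULL)
  phi <- unwrap_angles(atan2(dxy[, 2], dxy[, 1]))
  if (max(phi) - min(phi) < 1e-8) return(NULL)
  co <- stats::lm.fit(cbind(1, phi), log(rho))$coefficients
  a <- exp(co[1]); b <- co[2]
  rss <- sum((rho - a * exp(b * phi))^2) / (1 + b^2)
  list(center = center, a = a, b = b, phi = phi, rss = rss)
}

#' Full spiral fit: optimize the centre, then polish with true orthogonal
#' distances over (centre, log a, b).
#' @keywords internal
fit_spiral <- function(pts, polish = TRUE) {
  if (nrow(pts) < 5) return(NULL)
  c0 <- fit_circle_kasa(pts)
  obj_c <- function(ctr) {
    f <- spiral_fit_fixed_center(pts, ctr)
    if (is.null(f)) return(1e12)
    f$rss
  }
  o <- stats::optim(c0, obj_c, method = "Nelder-Mead",
                    control = list(maxit = 400, reltol = 1e-14))
  fit <- spiral_fit_fixed_center(pts, o$par)
  if (is.null(fit)) return(NULL)
  if (polish) {
    obj_full <- function(p) {
      ctr <- p[1:2]; a <- exp(p[3]); b <- p[4]
      dxy <- sweep(pts, 2, ctr)
      hint <- unwrap_angles(atan2(dxy[, 2], dxy[, 1]))
      sum(spiral_orthogonal_distance(pts, a, b, ctr, hint)$dist^2)
    }
    p0 <- c(fit$center, log(fit$a), fit$b)
    op <- tryCatch(
      stats::optim(p0, obj_full, method = "BFGS",
                   control = list(maxit = 200, reltol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(op) && op$value <= obj_full(p0)) {
      ctr <- op$par[1:2]
      fit <- list(center = ctr, a = exp(op$par[3]), b = op$par[4],
                  phi = unwrap_angles(atan2(pts[, 2] - ctr[2],
                                            pts[, 1] - ctr[1])),
                  rss = op$value)
    }
  }
  d <- spiral_orthogonal_distance(pts, fit$a, fit$b, fit$center, fit$phi)
  fit$rss <- sum(d$dist^2)
  fit$theta <- d$theta
  fit
}

# RSS of an orthogonal line fit for every contiguous run pts[i..j]; upper
# triangular matrix, runs of < 2 points are Inf.
segment_rss_table <- function(pts) {
  n <- nrow(pts)
  tab <- matrix(Inf, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tab[i, j] <- fit_line_orth(pts[i:j, , drop = FALSE])$rss
    }
  }
  tab
}

# Best split of pts[1..m] into k contiguous line pieces (total RSS and the
# piece boundaries); exhaustive over split points, n is small.
best_line_partition <- function(rss_tab, m, k) {
  if (k == 1) return(list(rss = rss_tab[1, m], bounds = c(1, m)))
  best <- list(rss = Inf, bounds = NULL)
  if (k == 2) {
    for (s1 in 2:(m - 1)) {
      v <- rss_tab[1, s1] + rss_tab[s1 + 1, m]
      if (v < best$rss) best <- list(rss = v, bounds = c(1, s1, m))
    }
  } else if (k == 3) {
    for (s1 in 2:(m - 3)) {
      for (s2 in (s1 + 2):(m - 1)) {
        v <- rss_tab[1, s1] + rss_tab[s1 + 1, s2] + rss_tab[s2 + 1, m]
        if (v < best$rss) best <- list(rss = v, bounds = c(1, s1, s2, m))
      }
    }
  }
  best
}

#' Fit the electrode shape model to digitized landmarks
#'
#' Fits a logarithmic spiral and up to three straight basal segments through
#' an ordered (base to tip) sequence of digitized points, minimizing the sum
#' of squared orthogonal point-to-curve distances. The number of straight
#' segments is chosen by increasing the count from 0 to 3 and accepting the
#' smallest count that the next one fails to improve by at least
#' `segment_rms_gain` (default 10 percent).
#'
#' @param points n x 2 matrix (or data frame) of landmark coordinates in mm,
#'   ordered base to tip; typically 23 rows (22 contacts + tip).
#' @param config optional list: `segment_rms_gain` (default 0.10),
#'   `fail_rms` (mm; fits with larger residual RMS raise a fit-failure
#'   condition, default 0.5), `collinear_tol` (mm, default 1e-9).
#' @return an object of class `shape_model`: list with `spiral` (centre, a,
#'   b, theta_range; NULL for a degenerate straight fit), `segments` (each
#'   with start, dir, length), `join_points` (arc-length positions of piece
#'   joins, mm from the basal end), `rms` (mm), `n_segments`.
#' @export
fit_shape_model <- function(points, config = list()) {
  pts <- as.matrix(points)
  if (!is.numeric(pts) || ncol(pts) != 2 || anyNA(pts)) {
    stop(errorCondition("points must be a numeric n x 2 matrix without NAs",
                        class = c("cochsim_invalid_input", "error")))
  }
  if (nrow(pts) < 5) {
    stop(errorCondition("at least 5 digitized points are required",
                        class = c("cochsim_invalid_input", "error")))
  }
  cfg <- utils::modifyList(list(segment_rms_gain = 0.10, fail_rms = 0.5,
                                collinear_tol = 1e-9), config)
  n <- nrow(pts)

  # Collinear degenerate case: the zero-curvature limit of the spiral is a
  # straight segment; return a pure-segment model.
  lf <- fit_line_orth(pts)
  if (sqrt(lf$rss / n) < cfg$collinear_tol) {
    p1 <- drop(lf$point + c((pts[1, ] - lf$point) %*% lf$dir) * lf$dir)
    p2 <- drop(lf$point + c((pts[n, ] - lf$point) %*% lf$dir) * lf$dir)
    seg <- list(start = p1, dir = (p2 - p1) / sqrt(sum((p2 - p1)^2)),
                length = sqrt(sum((p2 - p1)^2)))
    return(structure(list(spiral = NULL, segments = list(seg),
                          join_points = numeric(0), rms = sqrt(lf$rss / n),
                          n_segments = 1L, degenerate = TRUE),
                     class = "shape_model"))
  }

  rss_tab <- segment_rss_table(pts)
  spiral_cache <- vector("list", n + 1)    # index m+1: spiral over (m+1)..n
  spiral_over <- function(m) {
    key <- m + 1
    if (is.null(spiral_cache[[key]])) {
      f <- fit_spiral(pts[(m + 1):n, , drop = FALSE], polish = FALSE)
      spiral_cache[[key]] <<- if (is.null(f)) list(rss = Inf) else f
    }
    spiral_cache[[key]]
  }

  cand <- vector("list", 4)
  cand[[1]] <- list(k = 0L, m = 0L, rss = spiral_over(0)$rss, bounds = NULL)
  for (k in 1:3) {
    best <- list(rss = Inf)
    m_lo <- 2 * k
    m_hi <- n - 5
    if (m_lo <= m_hi) {
      for (m in m_lo:m_hi) {
        part <- best_line_partition(rss_tab, m, k)
        v <- part$rss + spiral_over(m)$rss
        if (v < best$rss) best <- list(rss = v, m = m, bounds = part$bounds)
      }
    }
    cand[[k + 1]] <- list(k = k, m = best$m, rss = best$rss,
                          bounds = best$bounds)
  }

  rms_k <- vapply(cand, function(cc) sqrt(cc$rss / n), numeric(1))
  pick <- 4L
  for (k in 0:2) {
    if (!is.finite(rms_k[k + 1])) next
    if (rms_k[k + 1] < 1e-7 ||     # numerically converged; stop adding
        !is.finite(rms_k[k + 2]) ||
        rms_k[k + 2] > (1 - cfg$segment_rms_gain) * rms_k[k + 1]) {
      pick <- k + 1L
      break
    }
  }
  ch <- cand[[pick]]
  if (!is.finite(ch$rss)) {
    stop(errorCondition("shape-model fit did not converge",
                        class = c("cochsim_fit_failure", "error"),
                        best_rms = min(rms_k, na.rm = TRUE)))
  }

  # Final model: polish the spiral over its region, then build a continuous
  # chain of segment pieces that joins the spiral exactly.
  sp_pts <- pts[(ch$m + 1):n, , drop = FALSE]
  sp <- fit_spiral(sp_pts, polish = TRUE)
  segments <- list()
  join_points <- numeric(0)
  arc_acc <- 0
  if (ch$k > 0) {
    bounds <- ch$bounds
    lines <- list()
    for (i in seq_len(ch$k)) {
      i0 <- if (i == 1) 1L else bounds[i] + 1L
      i1 <- bounds[i + 1]
      lines[[i]] <- fit_line_orth(pts[i0:i1, , drop = FALSE])
    }
    proj <- function(l, p) drop(l$point + c((p - l$point) %*% l$dir) * l$dir)
    verts <- list(proj(lines[[1]], pts[1, ]))
    if (ch$k > 1) {
      for (i in seq_len(ch$k - 1)) {
        pb <- pts[bounds[i + 1], ]
        verts[[i + 1]] <- (proj(lines[[i]], pb) + proj(lines[[i + 1]], pb)) / 2
      }
    }
    # Join to the spiral at the angle whose spiral point is nearest the last
    # line (the tangency point for a tangent configuration).
    lastl <- lines[[ch$k]]
    th_first <- sp$theta[1]
    distline <- function(th) {
      q <- drop(log_spiral_points(th, sp$a, sp$b, sp$center))
      v <- q - lastl$point
      sum((v - c(v %*% lastl$dir) * lastl$dir)^2)
    }
    # tangency lies at or before the first spiral-region point; do not let
    # the join wander onto a later near-approach of the spiral to the line
    into <- sign(sp$theta[length(sp$theta)] - th_first)
    oth <- if (into >= 0) {
      stats::optimize(distline, lower = th_first - pi,
                      upper = th_first + 0.05, tol = 1e-12)
    } else {
      stats::optimize(distline, lower = th_first - 0.05,
                      upper = th_first + pi, tol = 1e-12)
    }
    th_join <- oth$minimum
    verts[[ch$k + 1]] <- drop(log_spiral_points(th_join, sp$a, sp$b,
                                                sp$center))
    for (i in seq_len(ch$k)) {
      v0 <- verts[[i]]; v1 <- verts[[i + 1]]
      len <- sqrt(sum((v1 - v0)^2))
      segments[[i]] <- list(start = v0, dir = (v1 - v0) / len, length = len)
      arc_acc <- arc_acc + len
      join_points <- c(join_points, arc_acc)
    }
    theta_range <- sort(c(th_join, sp$theta[length(sp$theta)]))
  } else {
    theta_range <- range(sp$theta)
  }

  d_sp <- spiral_orthogonal_distance(sp_pts, sp$a, sp$b, sp$center, sp$theta)
  rss_final <- sum(d_sp$dist^2)
  if (ch$k > 0) {
    for (i in seq_len(ch$k)) {
      i0 <- if (i == 1) 1L else ch$bounds[i] + 1L
      i1 <- ch$bounds[i + 1]
      sg <- segments[[i]]
      for (j in i0:i1) {
        v <- pts[j, ] - sg$start
        rss_final <- rss_final + sum((v - c(v %*% sg$dir) * sg$dir)^2)
      }
    }
  }
  rms <- sqrt(rss_final / n)
  if (rms > cfg$fail_rms) {
    stop(errorCondition(
      sprintf("shape-model fit residual RMS %.4f mm exceeds %.4f mm",
              rms, cfg$fail_rms),
      class = c("cochsim_fit_failure", "error"), best_rms = rms))
  }
  structure(list(
    spiral = list(center = sp$center, a = unname(sp$a), b = unname(sp$b),
                  theta_range = theta_range),
    segments = segments, join_points = join_points, rms = rms,
    n_segments = as.integer(ch$k), degenerate = FALSE),
    class = "shape_model")
}

#' Evaluate a fitted shape model as a polyline (base to tip)
#'
#' @param model a `shape_model`.
#' @param n number of vertices.
#' @return n x 2 matrix.
#' @export
shape_model_curve <- function(model, n = 200) {
  pieces <- list()
  for (sg in model$segments) {
    pieces[[length(pieces) + 1]] <-
      rbind(sg$start, sg$start + sg$dir * sg$length)
  }
  if (!is.null(model$spiral)) {
    sp <- model$spiral
    th <- seq(sp$theta_range[1], sp$theta_range[2], length.out = max(n, 50))
    spc <- log_spiral_points(th, sp$a, sp$b, sp$center)
    # orient base -> tip: the chain ends where the segments join
    if (length(model$segments)) {
      last <- model$segments[[length(model$segments)]]
      endpt <- last$start + last$dir * last$length
      if (sum((spc[nrow(spc), ] - endpt)^2) < sum((spc[1, ] - endpt)^2)) {
        spc <- spc[nrow(spc):1, , drop = FALSE]
      }
    }
    pieces[[length(pieces) + 1]] <- spc
  }
  out <- do.call(rbind, pieces)
  resample_polyline(out, n)
}

#' @export
print.shape_model <- function(x, ...) {
  cat("<shape_model>\n")
  if (is.null(x$spiral)) {
    cat("  degenerate straight fit (zero-curvature limit)\n")
  } else {
    cat(sprintf("  spiral: a = %.4f mm, b = %.4f, theta in [%.3f, %.3f] rad\n",
                x$spiral$a, x$spiral$b,
                x$spiral$theta_range[1], x$spiral$theta_range[2]))
  }
  cat(sprintf("  straight segments: %d\n", x$n_segments))
  cat(sprintf("  orthogonal residual RMS: %.3g mm\n", x$rms))
  invisible(x)
}
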