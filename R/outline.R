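# Areal outline of the electrode array: a second polyline at constant
# 0.15 mm inner offset from the fitted central path, an outer offset
# tapering from 0.65 mm (base) to 0.45 mm (tip), and a conical tip cap of
# two straight lines. Total modelled width is therefore 0.8 mm at the base
# and 0.6 mm at the tip.

outline_default_config <- function() {
  list(
    inner_offset = 0.15,   # mm, constant
    outer_base = 0.65,     # mm at the basal end
    outer_tip = 0.45,      # mm at the tip
    cap_length = 0.5,      # mm, conical Softip cap beyond the path end
    n_stations = 90,       # cross-sections along the body
    n_cap = 8              # cross-sections along the cap
  )
}

#' Build the areal outline of an electrode shape state
#'
#' Offsets the central path by per-vertex normals with miter joins. Where
#' the path curvature radius falls below the offset the inner offset would
#' loop; such loops are trimmed station-wise and flagged.
#'
#' @param state a `shape_state` (or any list with `path` matrix and
#'   optionally `curl_sign`).
#' @param config overrides for [outline_default_config()].
#' @return an `electrode_outline`: closed `polygon`, `tip_region`
#'   sub-polygon, per-station geometry (path point, left normal, signed
#'   curvature, inner/outer signed offsets), `width` (mm per station),
#'   `arc` (station arc position, mm from base), `area` (mm^2),
#'   `trimmed` flag.
#' @export
build_outline <- function(state, config = list()) {
  cfg <- utils::modifyList(outline_default_config(), config)
  curl_sign <- if (!is.null(state$curl_sign)) state$curl_sign else -1
  path <- resample_polyline(state$path, cfg$n_stations)
  if (polyline_self_intersects(path)) {
    stop(errorCondition("central path is self-intersecting",
                        class = c("cochsim_invalid_input", "error")))
  }
  arc <- polyline_arclength(path)
  L <- arc[length(arc)]
  tn <- polyline_tangents(path)
  nl <- cbind(-tn[, 2], tn[, 1])                   # left normals
  kappa <- polyline_curvature(path)                # signed, left positive
  frac <- arc / L
  w_out <- cfg$outer_base + (cfg$outer_tip - cfg$outer_base) * frac
  # signed offsets in the left-normal coordinate u: the inner face lies on
  # the concave (curl-centre) side of the path
  u_in <- curl_sign * cfg$inner_offset
  u_out <- -curl_sign * w_out
  inner_pts <- path + nl * u_in
  outer_pts <- path + nl * u_out

  # loop trimming: an offset vertex moving against the path direction marks
  # a curvature violation (radius < offset); drop such stations
  trimmed <- FALSE
  keep <- rep(TRUE, nrow(path))
  for (side in list(inner_pts, outer_pts)) {
    e <- diff(side)
    back <- rowSums(e * diff(path)) < 0
    if (any(back)) {
      trimmed <- TRUE
      keep[c(FALSE, back)] <- FALSE
    }
  }
  keep[c(1, length(keep))] <- TRUE
  if (trimmed) {
    path <- path[keep, , drop = FALSE]; arc <- arc[keep]
    tn <- tn[keep, , drop = FALSE]; nl <- nl[keep, , drop = FALSE]
    kappa <- kappa[keep]; w_out <- w_out[keep]
    u_out <- u_out[keep]
    inner_pts <- inner_pts[keep, , drop = FALSE]
    outer_pts <- outer_pts[keep, , drop = FALSE]
  }
  n <- nrow(path)

  # conical cap: stations continue along the tip tangent, both faces
  # converging linearly on the apex
  tip_dir <- tn[n, ]
  cap_t <- seq(0, cfg$cap_length, length.out = cfg$n_cap + 1)[-1]
  shrink <- 1 - cap_t / cfg$cap_length
  cap_path <- cbind(path[n, 1] + tip_dir[1] * cap_t,
                    path[n, 2] + tip_dir[2] * cap_t)
  cap_nl <- matrix(nl[n, ], nrow = cfg$n_cap, ncol = 2, byrow = TRUE)
  cap_u_in <- u_in * shrink
  cap_u_out <- u_out[n] * shrink
  cap_inner <- cap_path + cap_nl * cap_u_in
  cap_outer <- cap_path + cap_nl * cap_u_out
  apex <- cap_path[cfg$n_cap, ]

  polygon <- rbind(inner_pts,
                   cap_inner[-cfg$n_cap, , drop = FALSE],
                   apex,
                   cap_outer[(cfg$n_cap - 1):1, , drop = FALSE],
                   outer_pts[n:1, , drop = FALSE],
                   inner_pts[1, ])
  tip_region <- rbind(inner_pts[n, ], cap_inner[-cfg$n_cap, , drop = FALSE],
                      apex, cap_outer[(cfg$n_cap - 1):1, , drop = FALSE],
                      outer_pts[n, ], inner_pts[n, ])

  st_path <- rbind(path, cap_path)
  st_nl <- rbind(nl, cap_nl)
  st_kappa <- c(kappa, rep(0, cfg$n_cap))
  st_u_in <- c(rep(u_in, n), cap_u_in)
  st_u_out <- c(u_out, cap_u_out)
  st_arc <- c(arc, L + cap_t)
  is_cap <- c(rep(FALSE, n), rep(TRUE, cfg$n_cap))

  structure(list(
    polygon = polygon, tip_region = tip_region,
    stations = st_path, normals = st_nl, kappa = st_kappa,
    u_in = st_u_in, u_out = st_u_out, arc = st_arc, is_cap = is_cap,
    width = abs(st_u_out - st_u_in),
    tip_dir = tip_dir, curl_sign = curl_sign,
    area = polygon_area(polygon), trimmed = trimmed,
    config = cfg), class = "electrode_outline")
}

#' Local outline width as a function of arc length
#'
#' @param outline an `electrode_outline`.
#' @param at arc positions (mm from the basal end).
#' @return widths, mm.
#' @export
outline_width_at <- function(outline, at) {
  stats::approx(outline$arc, outline$width, xout = at, rule = 2)$y
}

#' @export
print.electrode_outline <- function(x, ...) {
  body <- !x$is_cap
  cat(sprintf(
    "<electrode_outline>: %d stations + %d cap, width %.2f -> %.2f mm, area %.2f mm^2%s\n",
    sum(body), sum(x$is_cap), x$width[1], x$width[sum(body)], x$area,
    if (x$trimmed) " (loops trimmed)" else ""))
  invisible(x)
}
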