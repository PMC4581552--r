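# Synthetic 2D cochlear lumen contours: inner and outer walls as offset
# logarithmic spirals around a tapering lumen centerline, anchored with the
# cochleostomy at the origin and the entry direction along -x. Sizes are
# set by the greatest lateral dimension of the basal turn (Escude's
# distance A), the single metric used to class cochleae small/medium/large.

cochlea_default_config <- function() {
  list(
    turns = 2.25,              # spiral turns covered by the contours
    apex_fraction = 0.26,      # centerline radius at apex / at base
    width_base = 2.5,          # lumen width at the cochleostomy, mm
    width_apex = 1.4,          # lumen width at the apical end, mm
    width_scale = 1.0,         # global lumen-width factor (whole-labyrinth
                               # versus scala-tympani regimes)
    points_per_turn = 72,      # contour resolution (5 degree steps)
    gate_margin = 1.0          # see lumen gate below, mm
  )
}

# presets by distance A; ordered CS < CM < CL inside the plausible human
# range (config default 7.5-10.5 mm)
.cochlea_sizes <- c(CS = 8.0, CM = 9.0, CL = 10.0)

#' Synthesize a 2D cochlear contour pair
#'
#' @param size `"CS"`, `"CM"`, `"CL"`, or a numeric distance A target (mm).
#' @param turns number of spiral turns (>= 1.75).
#' @param config overrides for [cochlea_default_config()].
#' @param seed optional integer; adds small reproducible irregularity to the
#'   lumen width (real lumina are not perfectly smooth).
#' @return a `cochlea_contour`: `inner`/`outer` wall polylines,
#'   `centerline`, per-vertex lumen `width`, `cochleostomy` (origin),
#'   `entry_direction` (-x), `distance_A` (mm), `size_class`, and a closed
#'   `lumen_polygon`. A `narrow_warning` flag marks lumina narrower than the
#'   basal electrode width (0.8 mm) anywhere in the basal 180 degrees.
#' @export
synthesize_cochlea <- function(size = "CM", turns = NULL, config = list(),
                               seed = NULL) {
  cfg <- utils::modifyList(cochlea_default_config(), config)
  if (!is.null(turns)) cfg$turns <- turns
  if (cfg$turns < 1.75) {
    stop(errorCondition("a cochlear contour needs at least 1.75 turns",
                        class = c("cochsim_invalid_config", "error")))
  }
  if (is.character(size)) {
    size <- match.arg(size, names(.cochlea_sizes))
    A_target <- .cochlea_sizes[[size]]
    size_class <- size
  } else {
    A_target <- as.numeric(size)
    size_class <- "custom"
    if (A_target < 7.5 || A_target > 10.5) {
      stop(errorCondition(
        "distance A outside the plausible human range (7.5-10.5 mm)",
        class = c("cochsim_invalid_config", "error")))
    }
  }

  theta_max <- 2 * pi * cfg$turns
  n <- max(round(cfg$points_per_turn * cfg$turns), 60) + 1
  theta <- seq(0, theta_max, length.out = n)
  k <- -log(cfg$apex_fraction) / theta_max
  rho <- 3.8 * exp(-k * theta)            # provisional scale; rescaled below

  # clockwise-in-heading sweep to match the electrode curl handedness:
  # entry at theta = 0 heading -x, modiolar centre on the concave side
  raw <- cbind(rho * cos(-theta), rho * sin(-theta))
  e0 <- raw[2, ] - raw[1, ]
  a0 <- atan2(e0[2], e0[1])
  ctr <- rotate_about(raw, (pi - a0) * 180 / pi, raw[1, ])
  ctr <- sweep(ctr, 2, ctr[1, ])

  arc <- polyline_arclength(ctr)
  w <- cfg$width_base + (cfg$width_apex - cfg$width_base) *
    arc / arc[length(arc)]
  if (!is.null(seed)) {
    set.seed(as.integer(seed) %% .Machine$integer.max)
    bump <- stats::filter(stats::rnorm(n, 0, 0.04), rep(1 / 9, 9),
                          circular = TRUE)
    w <- w * (1 + as.numeric(bump))
  }
  w <- w * cfg$width_scale

  tn <- polyline_tangents(ctr)
  nl <- cbind(-tn[, 2], tn[, 1])
  inner <- ctr - nl * (w / 2)
  outer <- ctr + nl * (w / 2)

  contour <- new_cochlea_contour(inner, outer, ctr, w, size_class, cfg)
  A0 <- measure_distance_A(contour)
  sc <- A_target / A0
  contour <- new_cochlea_contour(inner * sc, outer * sc, ctr * sc, w * sc,
                                 size_class, cfg)
  contour$distance_A <- measure_distance_A(contour)
  contour
}

# assemble the contour object and its derived fields
new_cochlea_contour <- function(inner, outer, centerline, width, size_class,
                                cfg) {
  n <- nrow(centerline)
  lumen_polygon <- rbind(inner, outer[n:1, , drop = FALSE], inner[1, ])
  tn <- polyline_tangents(centerline)
  nl <- cbind(-tn[, 2], tn[, 1])
  half <- centerline[seq_len(max(2, round(n / 4))), , drop = FALSE]
  narrow <- any(width[seq_len(nrow(half))] < 0.8)
  structure(list(
    inner = inner, outer = outer, centerline = centerline,
    width = width, normals = nl,
    arc = polyline_arclength(centerline),
    cochleostomy = c(0, 0), entry_direction = c(-1, 0),
    distance_A = NA_real_, size_class = size_class,
    turns = cfg$turns, lumen_polygon = lumen_polygon,
    gate_x = 0, gate_y = width[1] / 2 + cfg$gate_margin,
    narrow_warning = narrow, config = cfg), class = "cochlea_contour")
}

#' Band contour from an explicit centerline (constructed fixtures)
#'
#' Builds a `cochlea_contour`-shaped lumen band of given width around an
#' arbitrary centerline polyline; used for controlled overlap fixtures.
#'
#' @param centerline n x 2 matrix.
#' @param width scalar or per-vertex lumen width, mm.
#' @param gate_x penetration gate (see [compute_overlap()]), default `Inf`
#'   so nothing is gated.
#' @export
band_contour <- function(centerline, width, gate_x = Inf) {
  n <- nrow(centerline)
  w <- rep_len(width, n)
  tn <- polyline_tangents(centerline)
  nl <- cbind(-tn[, 2], tn[, 1])
  inner <- centerline - nl * (w / 2)
  outer <- centerline + nl * (w / 2)
  cfg <- cochlea_default_config()
  out <- new_cochlea_contour(inner, outer, centerline, w, "custom", cfg)
  out$gate_x <- gate_x
  out$gate_y <- -Inf
  out
}

#' Measure Escude's distance A on a contour
#'
#' The greatest lateral dimension of the basal turn: the longest chord from
#' the round-window end of the outer wall to the opposing lateral wall
#' within the first full turn.
#'
#' @param contour a `cochlea_contour`.
#' @return distance A, mm.
#' @export
measure_distance_A <- function(contour) {
  outer <- contour$outer
  e <- diff(outer)
  ang <- unwrap_angles(atan2(e[, 2], e[, 1]))
  total_turn <- abs(ang[length(ang)] - ang[1])
  if (total_turn < 2 * pi * 0.995) {
    stop(errorCondition(
      "contour covers less than one full basal turn; cannot measure A",
      class = c("cochsim_insufficient_coverage", "error")))
  }
  turn1 <- c(TRUE, abs(ang - ang[1]) <= 2 * pi)
  pts <- outer[turn1, , drop = FALSE]
  p_rw <- outer[1, ]
  max(sqrt((pts[, 1] - p_rw[1])^2 + (pts[, 2] - p_rw[2])^2))
}

#' @export
print.cochlea_contour <- function(x, ...) {
  cat(sprintf(
    "<cochlea_contour '%s'>: A = %.2f mm, %.2f turns, lumen %.2f -> %.2f mm%s\n",
    x$size_class, x$distance_A, x$turns, x$width[1],
    x$width[length(x$width)],
    if (isTRUE(x$narrow_warning)) " [narrow lumen warning]" else ""))
  invisible(x)
}
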