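# Synthesis of electrode curling profiles: the shape of the array as a
# function of stylet extraction s. The distal arc of released length s takes
# the manufactured logarithmic-spiral shape; the proximal remainder keeps the
# slightly curved ("banana") start configuration. Joining the two curvature
# regimes and integrating the heading gives positional and tangential (C1)
# continuity at the release point by construction.

# Archetype presets. A logarithmic spiral's radius grows linearly with arc
# length (dr/ds = b / sqrt(1 + b^2)). A preformed perimodiolar array is
# manufactured to nest in the (scale-invariant) human cochlear spiral, so
# all archetypes share the lumen family's radial growth per unit arc
# (about 0.095 mm/mm, the rate of a 2.25-turn cochlea whose centerline
# radius falls to 26 percent of its basal value) and differ in how tightly
# the tip curls: the pronounced archetype wraps furthest toward the
# modiolus, the flat one stays most lateral.
.archetype_presets <- list(
  pronounced = list(r_tip = 1.25, r_base = 2.96),
  moderate   = list(r_tip = 1.60, r_base = 3.31),
  flat       = list(r_tip = 2.10, r_base = 3.81)
)

# growth rate b from tip/base radii and path length: dr/ds = b/sqrt(1+b^2)
archetype_growth_rate <- function(r_tip, r_base, L) {
  m <- (r_base - r_tip) / L
  m / sqrt(1 - m^2)
}

curling_default_config <- function() {
  list(
    L = 18,                 # total central-path length, mm
    s_max = 18,             # full stylet extraction, mm
    step = 0.2,             # extraction increment, mm (within [0.1, 0.25])
    n_vertices = 361,       # central-path vertices per state
    start_sagitta = 1.5,    # bow of the banana start configuration, mm
    curl_sign = -1,         # clockwise curl: heading decreases base -> tip
    contact_pitch = 0.7,    # arc spacing between contact centres, mm
    tip_offset = 0.4,       # arc distance tip -> most apical contact, mm
    marker_arclen = 7.6,    # white marker, mm behind the tip along the arc
    n_fine = 2880           # integration substeps for heading -> position
  )
}

# One shape state: integrate the piecewise curvature profile from the base
# (anchored at `origin` heading pi, i.e. pointing toward -x).
synthesize_state <- function(s, pars, cfg) {
  L <- cfg$L
  tf <- seq(0, L, length.out = cfg$n_fine + 1)
  m <- pars$b / sqrt(1 + pars$b^2)
  kf <- 1 / ((pars$r_tip + m * (L - tf)) * sqrt(1 + pars$b^2))
  k0 <- 8 * cfg$start_sagitta / L^2
  kappa <- ifelse(tf >= L - s - 1e-12, kf, k0) * cfg$curl_sign
  dt <- L / cfg$n_fine
  theta <- pi + c(0, cumsum((kappa[-1] + kappa[-length(kappa)]) / 2 * dt))
  cx <- c(0, cumsum((cos(theta)[-1] + cos(theta)[-length(theta)]) / 2 * dt))
  cy <- c(0, cumsum((sin(theta)[-1] + sin(theta)[-length(theta)]) / 2 * dt))
  idx <- round(seq(1, cfg$n_fine + 1, length.out = cfg$n_vertices))
  path <- cbind(cx[idx], cy[idx])
  # landmarks interpolated along the delivered polyline so that contact
  # positions lie on the central path exactly
  t_contact <- L - (cfg$tip_offset + cfg$contact_pitch * (21:0))
  contacts <- polyline_point_at(path, t_contact / L *
                                  polyline_length(path))
  rownames(contacts) <- sprintf("c%02d", 1:22)
  structure(list(
    s = s, path = path, contacts = contacts, tip = path[nrow(path), ],
    marker_arclen = cfg$marker_arclen,
    arc = polyline_arclength(path)), class = "shape_state")
}

#' Synthesize the curling profile of a preformed electrode array
#'
#' Generates the full series of shape states over stylet extraction for one
#' of three curling archetypes (`pronounced`, `moderate`, `flat`). The
#' release rule is immediate and complete: for extraction `s`, the distal arc
#' of length `s` has reverted to the manufactured spiral while the proximal
#' remainder retains the start configuration, a circular arc of configurable
#' sagitta. Arc length is conserved across states (inextensible body).
#'
#' @param archetype one of `"pronounced"`, `"moderate"`, `"flat"`.
#' @param variability_seed optional integer; adds small (about 2 percent)
#'   reproducible perturbations to the archetype parameters, emulating
#'   specimen-to-specimen variability.
#' @param config optional list overriding [curling_default_config()] entries
#'   (`L`, `s_max`, `step`, `start_sagitta`, `r_tip`, `b`, ...).
#' @return an object of class `curling_profile`: ordered `states` (one per
#'   extraction step), `s` values, `s_max`, `L`, `tip_trajectory`, `label`,
#'   and the resolved parameter set.
#' @export
synthesize_curling_profile <- function(archetype = c("pronounced", "moderate",
                                                     "flat"),
                                       variability_seed = NULL,
                                       config = list()) {
  archetype <- match.arg(archetype)
  cfg <- utils::modifyList(curling_default_config(), config)
  pars <- .archetype_presets[[archetype]]
  if (!is.null(config$r_tip)) pars$r_tip <- config$r_tip
  if (!is.null(config$r_base)) pars$r_base <- config$r_base
  if (!is.null(variability_seed)) {
    set.seed(as.integer(variability_seed) %% .Machine$integer.max)
    pars$r_tip <- pars$r_tip * (1 + stats::runif(1, -0.02, 0.02))
    pars$r_base <- pars$r_base * (1 + stats::runif(1, -0.02, 0.02))
    cfg$start_sagitta <- cfg$start_sagitta * (1 + stats::runif(1, -0.02, 0.02))
  }
  pars$b <- if (!is.null(config$b)) config$b else
    archetype_growth_rate(pars$r_tip, pars$r_base, cfg$L)
  if (cfg$s_max > cfg$L + 1e-9) {
    stop(errorCondition("s_max exceeds the total path length L",
                        class = c("cochsim_invalid_config", "error")))
  }
  if (cfg$step < 0.1 || cfg$step > 0.25) {
    stop(errorCondition("extraction step must lie in [0.1, 0.25] mm",
                        class = c("cochsim_invalid_config", "error")))
  }
  s_vals <- seq(0, cfg$s_max, by = cfg$step)
  if (s_vals[length(s_vals)] < cfg$s_max - 1e-9) {
    s_vals <- c(s_vals, cfg$s_max)
  }
  states <- lapply(s_vals, synthesize_state, pars = pars, cfg = cfg)
  # Common frame: with the stylet in, the array is a banana about the
  # straight stylet axis, so the insertion axis is the base->tip chord of
  # the start configuration. Rotate the whole family (rigidly, about the
  # anchored base) so that chord lies along -x, then shift the start
  # configuration's tip to the origin (the cochleostomy at pose zero).
  base0 <- states[[1]]$path[1, ]
  chord <- states[[1]]$tip - base0
  rot_deg <- (pi - atan2(chord[2], chord[1])) * 180 / pi
  states <- lapply(states, function(st) {
    st$path <- rotate_about(st$path, rot_deg, base0)
    st$contacts <- rotate_about(st$contacts, rot_deg, base0)
    st$tip <- drop(rotate_about(rbind(st$tip), rot_deg, base0))
    st$curl_sign <- cfg$curl_sign
    st
  })
  shift <- -states[[1]]$tip
  states <- lapply(states, function(st) {
    st$path <- sweep(st$path, 2, -shift)
    st$contacts <- sweep(st$contacts, 2, -shift)
    st$tip <- st$tip + shift
    st
  })
  tip_traj <- do.call(rbind, lapply(states, `[[`, "tip"))
  structure(list(
    states = states, s = s_vals, s_max = cfg$s_max, L = cfg$L,
    tip_trajectory = tip_traj, label = archetype, archetype = archetype,
    params = pars, config = cfg,
    base_point = states[[1]]$path[1, ],
    insertable_length = states[[1]]$path[1, 1]), class = "curling_profile")
}

#' Shape state at an arbitrary extraction value
#'
#' Returns the stored state when `s` matches a grid value; otherwise the two
#' neighbouring states are interpolated linearly per vertex (the grid spacing
#' of at most 0.25 mm makes linear interpolation sub-resolution).
#'
#' @param profile a `curling_profile`.
#' @param s extraction, mm.
#' @export
profile_state_at <- function(profile, s) {
  sv <- profile$s
  if (s < sv[1] - 1e-9 || s > sv[length(sv)] + 1e-9) {
    stop(errorCondition("requested s outside the profile's extraction range",
                        class = c("cochsim_invalid_plan", "error")))
  }
  i <- findInterval(s, sv, rightmost.closed = TRUE)
  if (abs(sv[i] - s) < 1e-9) return(profile$states[[i]])
  if (i >= length(sv)) return(profile$states[[length(sv)]])
  w <- (s - sv[i]) / (sv[i + 1] - sv[i])
  a <- profile$states[[i]]; b <- profile$states[[i + 1]]
  st <- a
  st$s <- s
  st$path <- (1 - w) * a$path + w * b$path
  st$contacts <- (1 - w) * a$contacts + w * b$contacts
  st$tip <- (1 - w) * a$tip + w * b$tip
  st$arc <- polyline_arclength(st$path)
  st
}

#' Curling-profile curve (tip trajectory)
#'
#' The trajectory of the electrode tip over stylet extraction, projected to
#' the x-y working plane; the array's kinematic fingerprint, used to compare
#' curling behaviour across arrays.
#'
#' @param profile a `curling_profile` with at least 3 states.
#' @return matrix of tip positions ordered by s.
#' @export
curling_profile_curve <- function(profile) {
  if (length(profile$states) < 3) {
    stop(errorCondition("curling-profile curve needs at least 3 states",
                        class = c("cochsim_invalid_input", "error")))
  }
  profile$tip_trajectory
}

#' Maximum tip deflection from the straight configuration
#'
#' Deflection of the tip from the straight configuration, measured as the
#' rotation of the tip tangent away from the straight insertion axis,
#' maximized over extraction steps (degrees). A pure position metric is
#' ambiguous for spiral shapes (a tightly wrapped tip can sit closer to the
#' straight tip position than a gently swept one); the tangent rotation
#' grows monotonically with curl and orders the archetypes
#' flat < moderate < pronounced by construction.
#'
#' @param profile a `curling_profile`.
#' @return maximum tip-tangent deflection, degrees.
#' @export
curling_deflection <- function(profile) {
  turn <- vapply(profile$states, function(st) {
    e <- diff(st$path)
    a <- unwrap_angles(atan2(e[, 2], e[, 1]))
    abs(a[length(a)] - a[1])
  }, numeric(1))
  max(turn) * 180 / pi
}

#' @export
print.curling_profile <- function(x, ...) {
  cat(sprintf(
    "<curling_profile '%s'>: %d states, s in [0, %.2f] mm, L = %.1f mm\n",
    x$label, length(x$states), x$s_max, x$L))
  cat(sprintf("  r_tip = %.3f mm, b = %.3f, max tip deflection = %.2f mm\n",
              x$params$r_tip, x$params$b, curling_deflection(x)))
  invisible(x)
}
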