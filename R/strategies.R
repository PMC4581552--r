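# Insertion strategies: the manual Advance Off-Stylet technique with
# intuitive rotational compensation (manAOS), the rigid automated insertion
# through a drill canal (autoAOS), and the step-by-step simulation loop.

strategy_default_config <- function() {
  list(
    dx0 = 7.6,             # initial feed: white marker (7.6 mm behind the
                           # tip) at the cochleostomy
    canal_diameter = 2.0,  # drill canal, mm (visual/reporting only)
    dphi_rate_cap = 5,     # manAOS: max rotation change per step, deg
    dphi_grid = 9,         # manAOS: candidate rotations per step
    weights = c(area = 1, depth = 0.5, regions = 0)
  )
}

# minimizer with inertia: among (near-)minimal candidates pick the one
# closest to the incumbent, so zero-cost ties do not drift the pose
argmin_near <- function(cand, cost, center) {
  best <- min(cost)
  near <- which(cost <= best + 1e-12)
  cand[near][which.min(abs(cand[near] - center))]
}

# step cost: overlap area plus a quadratic penalty on the deepest local
# penetration (deep point contacts are what the grade cascade punishes)
step_cost <- function(report, weights) {
  unname(weights[1] * report$total_overlap_area +
           weights[2] * report$max_penetration_depth^2 +
           weights[3] * report$contact_regions)
}

new_insertion_plan <- function(strategy, s, dx, dy, dphi, constraints) {
  structure(list(
    strategy = strategy,
    steps = data.frame(s = s, dx = dx, dy = dy, dphi = dphi),
    constraints_record = constraints), class = "insertion_plan")
}

#' Plan the automated drill-canal insertion (autoAOS)
#'
#' Feed is coupled one-to-one to stylet extraction (dx = dx0 + s); the
#' lateral offset and the rotation are frozen at their initial values after
#' initial positioning, as dictated by the guiding tube of an insertion
#' tool. The record carries the two parallel canal guide lines.
#'
#' @param profile a `curling_profile`.
#' @param contour a `cochlea_contour` (unused by the rigid plan itself;
#'   kept for a uniform strategy signature).
#' @param initial_pose optional `insertion_pose`; default: centred in the
#'   drill canal (dy = 0, dphi = 0) with the marker at the cochleostomy.
#' @param config overrides for [strategy_default_config()].
#' @return an `insertion_plan`.
#' @export
plan_autoAOS <- function(profile, contour = NULL, initial_pose = NULL,
                         config = list()) {
  cfg <- utils::modifyList(strategy_default_config(), config)
  p0 <- if (is.null(initial_pose)) insertion_pose(cfg$dx0, 0, 0) else
    initial_pose
  s <- profile$s
  new_insertion_plan(
    "autoAOS", s, dx = p0$dx + s,
    dy = rep(p0$dy, length(s)), dphi = rep(p0$dphi, length(s)),
    constraints = list(
      dy_locked = TRUE, dphi_locked = TRUE, feed_coupling = 1,
      canal_diameter = cfg$canal_diameter,
      canal_lines = list(y = c(p0$dy - cfg$canal_diameter / 2,
                               p0$dy + cfg$canal_diameter / 2))))
}

#' Plan the manual AOS insertion (manAOS)
#'
#' Feed coupled to extraction as in [plan_autoAOS()]; the lateral offset
#' stays frozen, but the surgeon's intuitive compensatory movement is
#' emulated by a per-step rotation chosen greedily to minimize the step
#' overlap cost, capped at `dphi_rate_cap` degrees per step to avoid abrupt
#' changes. The rigid (zero-rotation) choice is always among the candidates
#' when reachable, so each step does no worse than autoAOS.
#'
#' @inheritParams plan_autoAOS
#' @param config overrides for [strategy_default_config()].
#' @export
plan_manAOS <- function(profile, contour, initial_pose = NULL,
                        config = list()) {
  cfg <- utils::modifyList(strategy_default_config(), config)
  p0 <- if (is.null(initial_pose)) insertion_pose(cfg$dx0, 0, 0) else
    initial_pose
  s <- profile$s
  n <- length(s)
  dphi <- numeric(n)
  prev <- p0$dphi
  for (i in seq_len(n)) {
    st <- profile$states[[i]]
    o <- build_outline(st)
    cand <- seq(prev - cfg$dphi_rate_cap, prev + cfg$dphi_rate_cap,
                length.out = cfg$dphi_grid)
    if (p0$dphi >= min(cand) && p0$dphi <= max(cand)) {
      cand <- c(cand, p0$dphi)
    }
    cost <- vapply(cand, function(a) {
      pl <- place_electrode(o, insertion_pose(p0$dx + s[i], p0$dy, a),
                            contour$cochleostomy)
      step_cost(compute_overlap(pl, contour), cfg$weights)
    }, numeric(1))
    prev <- argmin_near(cand, cost, prev)
    dphi[i] <- prev
  }
  new_insertion_plan(
    "manAOS", s, dx = p0$dx + s, dy = rep(p0$dy, n), dphi = dphi,
    constraints = list(dy_locked = TRUE, dphi_locked = FALSE,
                       dphi_rate_cap = cfg$dphi_rate_cap,
                       feed_coupling = 1))
}

#' Simulate an insertion plan step by step
#'
#' Places the outline of the shape state at every plan step, computes the
#' overlap report, assigns the trauma-risk grade, and summarizes the grade
#' distribution normalized by the number of investigated steps.
#'
#' @param plan an `insertion_plan`.
#' @param profile the `curling_profile` the plan refers to.
#' @param contour the target `cochlea_contour`.
#' @param config list; `weights` for the per-step cost (see
#'   [strategy_default_config()]), `grade_config` passed to [grade()],
#'   `store_outlines` (default FALSE).
#' @return a `simulation_trace`: per-step data frame (`pose`, overlap
#'   features, `grade`), the `reports`, the normalized `histogram`,
#'   `total_cost`, and `total_overlap_area`.
#' @export
simulate_insertion <- function(plan, profile, contour, config = list()) {
  cfg <- utils::modifyList(
    c(strategy_default_config(), list(grade_config = list(),
                                      store_outlines = FALSE)), config)
  steps <- plan$steps
  if (any(steps$s < min(profile$s) - 1e-9 |
          steps$s > max(profile$s) + 1e-9)) {
    stop(errorCondition("plan steps outside the profile's extraction range",
                        class = c("cochsim_invalid_plan", "error")))
  }
  n <- nrow(steps)
  reports <- vector("list", n)
  outlines <- if (isTRUE(cfg$store_outlines)) vector("list", n) else NULL
  grades <- integer(n)
  for (i in seq_len(n)) {
    st <- profile_state_at(profile, steps$s[i])
    pl <- place_electrode(st, insertion_pose(steps$dx[i], steps$dy[i],
                                             steps$dphi[i]),
                          contour$cochleostomy)
    rep_i <- compute_overlap(pl, contour)
    reports[[i]] <- rep_i
    grades[i] <- as.integer(grade(rep_i, cfg$grade_config))
    if (!is.null(outlines)) outlines[[i]] <- pl
  }
  feat <- data.frame(
    s = steps$s, dx = steps$dx, dy = steps$dy, dphi = steps$dphi,
    body_penetration_fraction =
      vapply(reports, `[[`, numeric(1), "body_penetration_fraction"),
    tip_overlap_fraction =
      vapply(reports, `[[`, numeric(1), "tip_overlap_fraction"),
    total_overlap_area =
      vapply(reports, `[[`, numeric(1), "total_overlap_area"),
    max_penetration_depth =
      vapply(reports, `[[`, numeric(1), "max_penetration_depth"),
    contact_regions =
      vapply(reports, `[[`, integer(1), "contact_regions"),
    restraint_flag = vapply(reports, `[[`, logical(1), "restraint_flag"),
    far_outside_flag = vapply(reports, `[[`, logical(1),
                              "far_outside_flag"),
    grade = grades)
  structure(list(
    strategy = plan$strategy, steps = feat, reports = reports,
    outlines = outlines,
    histogram = grade_distribution(grades),
    mean_grade = mean(grades),
    total_cost = sum(vapply(reports, step_cost, numeric(1),
                            weights = cfg$weights)),
    total_overlap_area = sum(feat$total_overlap_area)),
    class = "simulation_trace")
}

#' @export
print.simulation_trace <- function(x, ...) {
  cat(sprintf("<simulation_trace '%s'>: %d steps, mean grade %.2f\n",
              x$strategy, nrow(x$steps), x$mean_grade))
  print(round(x$histogram, 3))
  invisible(x)
}
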