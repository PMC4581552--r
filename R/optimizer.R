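# Individualized insertion optimization (optIns): a constrained greedy
# forward sweep over insertion steps with per-step local minimization of the
# overlap cost, warm-started from the rigid autoAOS plan, followed by
# optional coordinate-descent smoothing passes. Constraints: monotone feed,
# full insertion with complete stylet removal (a fixed terminal feed), and
# rate caps on all pose parameters ("no abrupt changes").

#' Optimizer configuration
#'
#' @param weights step-cost weights (overlap area, max penetration depth,
#'   contact count); default `c(1, 0.5, 0)`.
#' @param rate_caps max per-step change: `dx` (mm beyond the 1:1 feed
#'   coupling), `dy` (mm), `dphi` (deg).
#' @param dx_monotone always TRUE: implant feed may never retract.
#' @param terminal list with `s_max`, `dx_final` and `slack`. With
#'   `dx_final = NA` the terminal feed is itself optimized within
#'   `slack` mm below the profile's insertable length (the feed at which
#'   the basal marker ribs reach the cochleostomy): full insertion up to a
#'   small under-insertion tolerance, mirroring the surgical practice of
#'   stopping at firm resistance. An explicit `dx_final` is honoured
#'   exactly.
#' @param solver `"greedy-sweep"` or `"coordinate-descent"` (greedy sweep
#'   plus smoothing passes).
#' @param max_iterations smoothing passes for coordinate descent.
#' @param seed integer; the solver is deterministic, the seed is recorded
#'   for provenance.
#' @export
optimization_config <- function(weights = c(area = 1, depth = 0.5,
                                            regions = 0),
                                rate_caps = c(dx = 0.5, dy = 0.2, dphi = 5),
                                dx_monotone = TRUE,
                                terminal = list(s_max = NA, dx_final = NA,
                                                slack = 2),
                                solver = c("coordinate-descent",
                                           "greedy-sweep"),
                                max_iterations = 2L, seed = 1L) {
  stopifnot(all(weights >= 0), any(weights > 0), all(rate_caps > 0))
  list(weights = weights, rate_caps = rate_caps, dx_monotone = TRUE,
       terminal = terminal, solver = match.arg(solver),
       max_iterations = as.integer(max_iterations), seed = as.integer(seed))
}

# feasible dx corridor at step i given the previous feed and the terminal
# condition (monotone feed + rate caps must still allow reaching dx_final)
dx_corridor <- function(i, prev_dx, ds, dx_final, cap) {
  n <- length(ds)
  reach <- if (i < n) sum(ds[(i + 1):n] + cap) else 0
  lo <- max(prev_dx + max(0, ds[i] - cap), dx_final - reach)
  hi <- min(prev_dx + ds[i] + cap, dx_final)
  c(lo, hi)
}

#' Optimize an individualized insertion plan (optIns)
#'
#' @param profile a `curling_profile`.
#' @param contour a `cochlea_contour`.
#' @param config an [optimization_config()].
#' @param strategy_config overrides for [strategy_default_config()] (initial
#'   pose via `dx0`).
#' @return an `optimization_result`: `plan`, `objective_value`,
#'   `iterations`, `dominated_baseline` (the autoAOS objective on the same
#'   inputs), and `objective_trace` (non-increasing across iterations).
#' @export
optimize_insertion <- function(profile, contour,
                               config = optimization_config(),
                               strategy_config = list()) {
  scfg <- utils::modifyList(strategy_default_config(), strategy_config)
  s <- profile$s
  n <- length(s)
  ds <- c(0, diff(s))
  cap <- config$rate_caps
  dx_full <- profile$insertable_length
  dx_final <- config$terminal$dx_final
  slack <- if (is.null(config$terminal$slack)) 0 else config$terminal$slack
  free_terminal <- is.null(dx_final) || is.na(dx_final)
  if (free_terminal) dx_final <- dx_full

  # infeasibility: terminal feed unreachable under the dx rate cap
  max_reach <- dx_final
  min_start <- dx_final - sum(ds + cap["dx"])
  if (min_start > scfg$dx0 + cap["dx"]) {
    stop(errorCondition(
      sprintf(paste0("terminal feed %.2f mm unreachable from initial feed ",
                     "%.2f mm under the dx rate cap %.2f mm/step"),
              dx_final, scfg$dx0, cap["dx"]),
      class = c("cochsim_infeasible", "error"), violated = "dx"))
  }

  outlines <- lapply(profile$states, build_outline)
  pose_cost <- function(i, dx, dy, dphi) {
    pl <- place_electrode(outlines[[i]], insertion_pose(dx, dy, dphi),
                          contour$cochleostomy)
    step_cost(compute_overlap(pl, contour), config$weights)
  }
  plan_objective <- function(dx, dy, dphi) {
    sum(vapply(seq_len(n), function(i) pose_cost(i, dx[i], dy[i], dphi[i]),
               numeric(1)))
  }

  warm <- plan_autoAOS(profile, contour, config = scfg)
  baseline <- plan_objective(warm$steps$dx, warm$steps$dy, warm$steps$dphi)

  grid1 <- function(lo, hi, k = 5) seq(lo, hi, length.out = k)

  # per-step coordinate descent over (dphi, dy, dx) inside a corridor; the
  # clamped preferred feed (1:1 coupling) is always a candidate and wins
  # ties, so contact-free stretches follow the plain AOS coupling
  descend <- function(i, prev, cor, dx_pref) {
    pref <- min(max(dx_pref, cor[1]), cor[2])
    cur <- list(dx = pref, dy = prev$dy, dphi = prev$dphi)
    for (pass in 1:2) {
      gp <- grid1(prev$dphi - cap["dphi"], prev$dphi + cap["dphi"])
      cc <- vapply(gp, function(a) pose_cost(i, cur$dx, cur$dy, a),
                   numeric(1))
      cur$dphi <- argmin_near(gp, cc, cur$dphi)
      gy <- grid1(prev$dy - cap["dy"], prev$dy + cap["dy"])
      cc <- vapply(gy, function(a) pose_cost(i, cur$dx, a, cur$dphi),
                   numeric(1))
      cur$dy <- argmin_near(gy, cc, cur$dy)
      gx <- sort(unique(c(grid1(cor[1], cor[2]), pref)))
      cc <- vapply(gx, function(a) pose_cost(i, a, cur$dy, cur$dphi),
                   numeric(1))
      cur$dx <- argmin_near(gx, cc, pref)
    }
    cur
  }

  # greedy forward sweep: feed coupled where possible, pose adapted locally
  forward_sweep <- function() {
    dx <- numeric(n); dy <- numeric(n); dphi <- numeric(n)
    prev <- list(dx = scfg$dx0 - ds[1], dy = 0, dphi = 0)
    for (i in seq_len(n)) {
      cor <- if (i == 1) {
        c(max(0, dx_final - sum(ds[-1] + cap["dx"])), dx0_hi)
      } else {
        dx_corridor(i, prev$dx, ds, dx_final, cap["dx"])
      }
      cur <- descend(i, prev, cor, prev$dx + ds[i])
      if (i == n) cur$dx <- dx_final
      dx[i] <- cur$dx; dy[i] <- cur$dy; dphi[i] <- cur$dphi
      prev <- cur
    }
    list(dx = dx, dy = dy, dphi = dphi)
  }

  # terminal placement of the fully curled array: the pose (and, when the
  # terminal feed is free, the depth within the under-insertion tolerance)
  # that nests the manufactured spiral in the lumen
  select_terminal <- function() {
    gdx <- if (free_terminal && slack > 0) {
      seq(max(0, dx_full - slack), dx_full, by = 0.25)
    } else {
      dx_final
    }
    gy <- seq(-2, 2, by = 0.5)
    gp <- seq(-40, 40, by = 10)
    best <- list(cost = Inf, dx = dx_final, dy = 0, dphi = 0)
    for (dxx in gdx) {
      cg <- outer(gy, gp, Vectorize(function(a, b) pose_cost(n, dxx, a, b)))
      ij <- arrayInd(which.min(cg), dim(cg))
      if (cg[ij] < best$cost - 1e-12) {
        best <- list(cost = cg[ij], dx = dxx, dy = gy[ij[1]],
                     dphi = gp[ij[2]])
      }
    }
    gy2 <- seq(best$dy - 0.25, best$dy + 0.25, by = 0.25)
    gp2 <- seq(best$dphi - 5, best$dphi + 5, by = 5)
    cg <- outer(gy2, gp2, Vectorize(function(a, b)
      pose_cost(n, best$dx, a, b)))
    ij <- arrayInd(which.min(cg), dim(cg))
    if (cg[ij] < best$cost - 1e-12) {
      best$cost <- cg[ij]; best$dy <- gy2[ij[1]]; best$dphi <- gp2[ij[2]]
    }
    for (rep_ in 1:2) {   # local refinement
      gy2 <- seq(best$dy - 0.25, best$dy + 0.25, by = 0.05)
      cc <- vapply(gy2, function(a) pose_cost(n, best$dx, a, best$dphi),
                   numeric(1))
      best$dy <- argmin_near(gy2, cc, best$dy)
      gp2 <- seq(best$dphi - 5, best$dphi + 5, by = 1)
      cc <- vapply(gp2, function(a) pose_cost(n, best$dx, best$dy, a),
                   numeric(1))
      best$dphi <- argmin_near(gp2, cc, best$dphi)
    }
    best
  }

  # anchored backward sweep: start from the terminal placement and walk
  # backward under the same rate caps
  backward_sweep <- function(term) {
    dx <- numeric(n); dy <- numeric(n); dphi <- numeric(n)
    dx[n] <- dx_final; dy[n] <- term$dy; dphi[n] <- term$dphi
    nxt <- list(dx = dx[n], dy = dy[n], dphi = dphi[n])
    fwd_reach <- dx0_hi + c(0, cumsum(ds[-1] + cap["dx"]))
    for (i in (n - 1):1) {
      cor <- c(max(0, nxt$dx - ds[i + 1] - cap["dx"]),
               min(nxt$dx - max(0, ds[i + 1] - cap["dx"]), fwd_reach[i]))
      if (i == 1) cor[2] <- min(cor[2], dx0_hi)
      if (cor[1] > cor[2]) cor[1] <- cor[2]
      cur <- descend(i, nxt, cor, nxt$dx - ds[i + 1])
      dx[i] <- cur$dx; dy[i] <- cur$dy; dphi[i] <- cur$dphi
      nxt <- cur
    }
    list(dx = dx, dy = dy, dphi = dphi)
  }

  term <- select_terminal()
  if (free_terminal) dx_final <- term$dx
  dx0_hi <- min(scfg$dx0, dx_final)
  fw <- forward_sweep()
  bw <- backward_sweep(term)
  obj_fw <- plan_objective(fw$dx, fw$dy, fw$dphi)
  obj_bw <- plan_objective(bw$dx, bw$dy, bw$dphi)
  if (obj_bw < obj_fw) {
    dx <- bw$dx; dy <- bw$dy; dphi <- bw$dphi; obj <- obj_bw
  } else {
    dx <- fw$dx; dy <- fw$dy; dphi <- fw$dphi; obj <- obj_fw
  }
  obj_trace <- obj
  iterations <- 1L

  if (config$solver == "coordinate-descent" && config$max_iterations > 0) {
    for (pass in seq_len(config$max_iterations)) {
      improved <- FALSE
      for (i in seq_len(n)) {
        lo_dx <- max(if (i > 1) dx[i - 1] + max(0, ds[i] - cap["dx"]) else 0,
                     if (i < n) dx[i + 1] - ds[i + 1] - cap["dx"] else
                       dx_final)
        hi_dx <- min(if (i > 1) dx[i - 1] + ds[i] + cap["dx"] else dx_final,
                     if (i < n) dx[i + 1] - max(0, ds[i + 1] - cap["dx"])
                     else dx_final)
        if (i == n) { lo_dx <- dx_final; hi_dx <- dx_final }
        lo_dy <- max(if (i > 1) dy[i - 1] - cap["dy"] else -Inf,
                     if (i < n) dy[i + 1] - cap["dy"] else -Inf)
        hi_dy <- min(if (i > 1) dy[i - 1] + cap["dy"] else Inf,
                     if (i < n) dy[i + 1] + cap["dy"] else Inf)
        lo_ph <- max(if (i > 1) dphi[i - 1] - cap["dphi"] else -Inf,
                     if (i < n) dphi[i + 1] - cap["dphi"] else -Inf)
        hi_ph <- min(if (i > 1) dphi[i - 1] + cap["dphi"] else Inf,
                     if (i < n) dphi[i + 1] + cap["dphi"] else Inf)
        if (lo_dx > hi_dx + 1e-9 || lo_dy > hi_dy || lo_ph > hi_ph) next
        base_c <- pose_cost(i, dx[i], dy[i], dphi[i])
        best <- list(c = base_c, dx = dx[i], dy = dy[i], dphi = dphi[i])
        for (a in grid1(lo_ph, hi_ph)) {
          cc <- pose_cost(i, best$dx, best$dy, a)
          if (cc < best$c - 1e-12) { best$c <- cc; best$dphi <- a }
        }
        for (a in grid1(lo_dy, hi_dy)) {
          cc <- pose_cost(i, best$dx, a, best$dphi)
          if (cc < best$c - 1e-12) { best$c <- cc; best$dy <- a }
        }
        for (a in grid1(max(lo_dx, hi_dx - 2), hi_dx)) {
          cc <- pose_cost(i, a, best$dy, best$dphi)
          if (cc < best$c - 1e-12) { best$c <- cc; best$dx <- a }
        }
        if (best$c < base_c - 1e-12) {
          dx[i] <- best$dx; dy[i] <- best$dy; dphi[i] <- best$dphi
          improved <- TRUE
        }
      }
      obj_new <- plan_objective(dx, dy, dphi)
      obj_trace <- c(obj_trace, min(obj_new, obj))
      obj <- min(obj_new, obj)
      iterations <- iterations + 1L
      if (!improved) break
    }
  }

  # the warm start is itself a feasible plan only when the coupled feed ends
  # at dx_final; fall back to it if it is feasible and better
  if (baseline < obj &&
      abs(warm$steps$dx[n] - dx_final) < 1e-9) {
    dx <- warm$steps$dx; dy <- warm$steps$dy; dphi <- warm$steps$dphi
    obj <- baseline
  }

  plan <- new_insertion_plan(
    "optIns", s, dx, dy, dphi,
    constraints = list(
      rate_caps = cap, dx_monotone = TRUE,
      terminal = list(s_max = s[n], dx_final = dx_final),
      solver = config$solver, seed = config$seed))
  structure(list(
    plan = plan, objective_value = obj, iterations = iterations,
    dominated_baseline = baseline, objective_trace = obj_trace),
    class = "optimization_result")
}

#' Independent constraint check of an insertion plan
#'
#' @param plan an `insertion_plan`.
#' @param rate_caps caps as in [optimization_config()].
#' @param terminal optional list (s_max, dx_final) that the last step must
#'   meet.
#' @return invisibly TRUE; a character vector of violations as attribute
#'   `violations` when any were found (and the return value is FALSE).
#' @export
check_plan <- function(plan, rate_caps = c(dx = 0.5, dy = 0.2, dphi = 5),
                       terminal = NULL) {
  st <- plan$steps
  v <- character(0)
  tol <- 1e-6
  if (any(diff(st$s) <= 0)) v <- c(v, "s not strictly increasing")
  if (any(diff(st$dx) < -tol)) v <- c(v, "dx not monotone")
  ds <- diff(st$s)
  if (any(abs(diff(st$dx) - ds) > rate_caps["dx"] + tol)) {
    v <- c(v, "dx rate cap violated")
  }
  if (any(abs(diff(st$dy)) > rate_caps["dy"] + tol)) {
    v <- c(v, "dy rate cap violated")
  }
  if (any(abs(diff(st$dphi)) > rate_caps["dphi"] + tol)) {
    v <- c(v, "dphi rate cap violated")
  }
  if (!is.null(terminal)) {
    n <- nrow(st)
    if (abs(st$s[n] - terminal$s_max) > tol) v <- c(v, "terminal s_max")
    if (!is.null(terminal$dx_final) && !is.na(terminal$dx_final) &&
        abs(st$dx[n] - terminal$dx_final) > tol) {
      v <- c(v, "terminal dx_final")
    }
  }
  ok <- length(v) == 0
  structure(ok, violations = v)
}

#' Compare the three insertion strategies on one electrode/cochlea pair
#'
#' Runs autoAOS, manAOS and optIns on the same inputs and collects the
#' normalized grade histograms, mean grades and summed overlap costs.
#'
#' @param profile a `curling_profile`.
#' @param contour a `cochlea_contour`.
#' @param config list; optional `optimizer` ([optimization_config()]) and
#'   `strategy` (see [strategy_default_config()]) entries.
#' @return a `strategy_comparison`: named list of `simulation_trace`s plus a
#'   `summary` data frame.
#' @export
compare_strategies <- function(profile, contour, config = list()) {
  ocfg <- if (!is.null(config$optimizer)) config$optimizer else
    optimization_config()
  scfg <- if (!is.null(config$strategy)) config$strategy else list()
  sim_cfg <- utils::modifyList(list(weights = ocfg$weights), scfg)
  traces <- list(
    autoAOS = simulate_insertion(plan_autoAOS(profile, contour,
                                              config = scfg),
                                 profile, contour, sim_cfg),
    manAOS = simulate_insertion(plan_manAOS(profile, contour,
                                            config = scfg),
                                profile, contour, sim_cfg),
    optIns = simulate_insertion(
      optimize_insertion(profile, contour, ocfg, scfg)$plan,
      profile, contour, sim_cfg))
  summ <- do.call(rbind, lapply(names(traces), function(nm) {
    tr <- traces[[nm]]
    data.frame(strategy = nm, mean_grade = tr$mean_grade,
               total_cost = tr$total_cost,
               total_overlap_area = tr$total_overlap_area,
               t(tr$histogram), check.names = FALSE)
  }))
  structure(list(traces = traces, summary = summ),
            class = "strategy_comparison")
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat("<strategy_comparison>\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
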