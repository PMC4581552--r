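# Shared fixtures, memoized so expensive objects are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

fx_profile <- function(archetype = "moderate", step = 0.25) {
  memo(paste0("profile_", archetype, "_", step),
       synthesize_curling_profile(archetype, config = list(step = step)))
}

fx_cochlea <- function(size = "CM") {
  memo(paste0("cochlea_", size), synthesize_cochlea(size))
}

# straight lumen band: walls at y = +/- width/2, centerline along x
fx_straight_band <- function(width = 4, half_len = 30) {
  band_contour(cbind(seq(-half_len, half_len, length.out = 121), 0), width)
}

# straight electrode shape state at lateral offset y0
fx_straight_state <- function(y0 = 0, len = 10, n = 120) {
  list(path = cbind(seq(-len, 0, length.out = n), y0), curl_sign = -1)
}

# canonical logarithmic-spiral landmark set (23 points, base to tip)
fx_spiral_points <- function(a = 1, b = 0.15, theta = seq(1, 8,
                                                          length.out = 23),
                             center = c(2, -1)) {
  log_spiral_points(theta, a, b, center)
}

# Monte-Carlo overlap-area oracle: stratified (jittered-grid)
# point-in-polygon sampling via pracma::inpolygon, independent of the
# package's band-integration engine
mc_overlap_area <- function(outline, contour, n = 1e5, seed = 42) {
  set.seed(seed)
  poly <- outline$polygon
  bb <- apply(poly, 2, range)
  wx <- bb[2, 1] - bb[1, 1]; wy <- bb[2, 2] - bb[1, 2]
  nx <- max(1, round(sqrt(n * wx / wy)))
  ny <- max(1, ceiling(n / nx))
  gx <- (rep(seq_len(nx), times = ny) - 1 + stats::runif(nx * ny)) / nx
  gy <- (rep(seq_len(ny), each = nx) - 1 + stats::runif(nx * ny)) / ny
  px <- bb[1, 1] + gx * wx
  py <- bb[1, 2] + gy * wy
  inpoly <- pracma::inpolygon(px, py, poly[, 1], poly[, 2])
  lum <- contour$lumen_polygon
  inlum <- pracma::inpolygon(px, py, lum[, 1], lum[, 2])
  gated <- px > contour$gate_x & py < contour$gate_y
  mean(inpoly & !inlum & !gated) *
    (bb[2, 1] - bb[1, 1]) * (bb[2, 2] - bb[1, 2])
}

# full packaged-fixture batch (4 arrays x 3 cochleae x 3 strategies),
# computed once and shared by the acceptance tests
acceptance_batch <- function() {
  memo("acceptance_batch", {
    d <- file.path(tempdir(), "fixtures-acceptance")
    if (!dir.exists(d)) make_fixtures(seed = 1, dir = d)
    run_batch(run_config(d, seed = 1, log_level = "quiet"))
  })
}

# reduced-instance exhaustive oracle: dynamic program over an absolute pose
# lattice (dx x dy x dphi), enumerating every feasible lattice path exactly
lattice_vs_solver <- function() {
  memo("lattice_vs_solver", {
    prof <- synthesize_curling_profile("moderate",
                                       config = list(step = 0.25,
                                                     s_max = 1.5))
    cont <- fx_cochlea("CS")
    caps <- c(dx = 0.5, dy = 0.2, dphi = 5)
    dx_final <- 7.6 + 1.5 + 1.0
    cfg <- optimization_config(rate_caps = caps,
                               terminal = list(s_max = 1.5,
                                               dx_final = dx_final))
    res <- optimize_insertion(prof, cont, cfg)

    s <- prof$s
    n <- length(s)
    ds <- c(0, diff(s))
    outls <- lapply(prof$states, build_outline)
    pose_cost <- function(i, dx, dy, dphi) {
      pl <- place_electrode(outls[[i]], insertion_pose(dx, dy, dphi),
                            cont$cochleostomy)
      cochsim:::step_cost(compute_overlap(pl, cont), cfg$weights)
    }
    dx_grid <- seq(7.6, dx_final, by = 0.25)
    dy_grid <- seq(-0.4, 0.4, by = 0.2)
    ph_grid <- seq(-10, 10, by = 5)
    nodes <- expand.grid(dx = dx_grid, dy = dy_grid, dphi = ph_grid)
    cost_at <- function(i) {
      vapply(seq_len(nrow(nodes)), function(j) {
        pose_cost(i, nodes$dx[j], nodes$dy[j], nodes$dphi[j])
      }, numeric(1))
    }
    best <- cost_at(1)
    best[nodes$dx > 7.6] <- Inf              # start at the marker depth
    for (i in 2:n) {
      ci <- cost_at(i)
      newbest <- rep(Inf, nrow(nodes))
      for (j in seq_len(nrow(nodes))) {
        dd <- nodes$dx[j] - nodes$dx
        ok <- dd >= -1e-9 & abs(dd - ds[i]) <= caps["dx"] + 1e-9 &
          abs(nodes$dy[j] - nodes$dy) <= caps["dy"] + 1e-9 &
          abs(nodes$dphi[j] - nodes$dphi) <= caps["dphi"] + 1e-9
        if (any(ok)) newbest[j] <- min(best[ok]) + ci[j]
      }
      best <- newbest
    }
    lattice_opt <- min(best[abs(nodes$dx - dx_final) < 1e-9])
    list(solver = res$objective_value, lattice = lattice_opt)
  })
}
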