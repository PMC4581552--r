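# Synthesis of curling profiles: release-from-tip kinematics, arc-length
# conservation, and the sigmoidal tip trajectory.

test_that("the s = 0 state is the banana start configuration", {
  prof <- fx_profile("moderate")
  st0 <- prof$states[[1]]
  k <- cochsim:::polyline_curvature(st0$path)
  k0 <- 8 * prof$config$start_sagitta / prof$L^2
  expect_lt(max(abs(abs(k[5:350]) - k0)), 1e-4)
  expect_equal(unname(st0$tip), c(0, 0), tolerance = 1e-9)
  expect_equal(st0$marker_arclen, 7.6)
})

test_that("full extraction reproduces the manufactured spiral closed form", {
  skip_if_not_installed("vegan")
  # landmarks live on the delivered polyline, so matching the continuous
  # spiral at 1e-6 mm needs vertex spacing with sub-1e-6 chord sagitta
  prof <- synthesize_curling_profile(
    "flat", config = list(step = 0.25, s_max = 18, n_fine = 28800,
                          n_vertices = 4801))
  st <- prof$states[[length(prof$states)]]
  # canonical spiral points at the contacts' arc distances behind the tip
  b <- prof$params$b; r_tip <- prof$params$r_tip
  mm <- b / sqrt(1 + b^2)
  u <- prof$config$tip_offset + prof$config$contact_pitch * (21:0)
  r <- r_tip + mm * u
  th <- log(r / r_tip) / b
  canon <- cbind(r * cos(th), r * sin(th))
  pr <- vegan::procrustes(st$contacts, canon, scale = FALSE,
                          symmetric = FALSE)
  expect_lt(max(stats::residuals(pr)), 1e-6)
})

test_that("arc length is conserved across all extraction states", {
  for (arch in c("flat", "moderate", "pronounced")) {
    prof <- fx_profile(arch)
    len <- vapply(prof$states, function(st) max(st$arc), numeric(1))
    expect_lt(max(abs(len - len[1])), 1e-3)
  }
})

test_that("the unreleased portion is rigid between consecutive states", {
  prof <- fx_profile("moderate")
  cfg <- prof$config
  for (i in c(1, 20, 50)) {
    s_next <- prof$s[i + 1]
    t_vertex <- seq(0, cfg$L, length.out = cfg$n_vertices)
    unrel <- t_vertex < cfg$L - s_next - 1e-9
    dev <- abs(prof$states[[i]]$path[unrel, ] -
                 prof$states[[i + 1]]$path[unrel, ])
    expect_lt(max(dev), 1e-6)
  }
})

test_that("released arc takes the final shape progressively (monotone release)", {
  prof <- fx_profile("moderate")
  final <- prof$states[[length(prof$states)]]
  # curvature of the released distal region matches the final state
  st <- prof$states[[40]]
  cfg <- prof$config
  t_vertex <- seq(0, cfg$L, length.out = cfg$n_vertices)
  rel <- which(t_vertex > cfg$L - st$s + 0.2)
  k_rel <- cochsim:::polyline_curvature(st$path)[rel]
  k_fin <- cochsim:::polyline_curvature(final$path)[rel]
  expect_lt(max(abs(k_rel - k_fin)), 1e-4)
})

test_that("tip trajectories are sigmoidal and ordered by archetype", {
  defl <- vapply(c("flat", "moderate", "pronounced"),
                 function(a) curling_deflection(fx_profile(a)), numeric(1))
  expect_true(defl[["flat"]] < defl[["moderate"]])
  expect_true(defl[["moderate"]] < defl[["pronounced"]])
  for (arch in c("flat", "moderate", "pronounced")) {
    tr <- curling_profile_curve(fx_profile(arch))
    k <- cochsim:::polyline_curvature(tr)
    k <- k[abs(k) > 1e-3]
    expect_gte(sum(diff(sign(k)) != 0), 1)
  }
})

test_that("contacts lie on the central path and respect the marker arc", {
  prof <- fx_profile("pronounced")
  st <- prof$states[[30]]
  d <- cochsim:::points_polyline_distance(st$contacts[, 1],
                                          st$contacts[, 2], st$path)
  expect_lt(max(d), 1e-6)
  expect_equal(st$marker_arclen, 7.6)
})

test_that("states interpolate linearly between stored extraction steps", {
  prof <- fx_profile("moderate")
  mid <- profile_state_at(prof, prof$s[10] + 0.125)
  expected <- (prof$states[[10]]$path + prof$states[[11]]$path) / 2
  expect_equal(mid$path, expected, tolerance = 1e-12)
  expect_error(profile_state_at(prof, prof$s_max + 1),
               class = "cochsim_invalid_plan")
})

test_that("configuration bounds are enforced", {
  expect_error(synthesize_curling_profile("flat",
                                          config = list(s_max = 30)),
               class = "cochsim_invalid_config")
  expect_error(synthesize_curling_profile("flat",
                                          config = list(step = 0.05)),
               class = "cochsim_invalid_config")
})

test_that("curling_profile_curve boundary behaviour", {
  prof <- fx_profile("moderate")
  few <- prof
  few$states <- prof$states[1:2]
  expect_error(curling_profile_curve(few), class = "cochsim_invalid_input")
  const <- structure(list(states = vector("list", 3),
                          tip_trajectory = matrix(c(1, 2), 3, 2,
                                                  byrow = TRUE)),
                     class = "curling_profile")
  cur <- curling_profile_curve(const)
  expect_equal(unique(cur), matrix(c(1, 2), 1))
})

test_that("variability seeds perturb reproducibly", {
  p1 <- synthesize_curling_profile("moderate", variability_seed = 7,
                                   config = list(step = 0.25))
  p2 <- synthesize_curling_profile("moderate", variability_seed = 7,
                                   config = list(step = 0.25))
  p3 <- synthesize_curling_profile("moderate", variability_seed = 8,
                                   config = list(step = 0.25))
  expect_identical(p1$params, p2$params)
  expect_false(identical(p1$params, p3$params))
})
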