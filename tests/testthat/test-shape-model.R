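# Fitting the continuous shape model (logarithmic spiral + straight
# segments) through digitized landmark points.

test_that("spiral parameters are recovered from exact spiral samples", {
  pts <- fx_spiral_points(a = 1.0, b = 0.15)
  m <- fit_shape_model(pts)
  expect_identical(m$n_segments, 0L)
  expect_lt(abs(m$spiral$a - 1.0), 0.01)
  expect_lt(abs(m$spiral$b - 0.15) / 0.15, 0.01)
  expect_lt(m$rms, 1e-6)
})

test_that("collinear points degenerate to a straight-segment-only model", {
  t <- seq(0, 10, length.out = 23)
  pts <- cbind(t, 0.5 * t + 2)
  m <- fit_shape_model(pts)
  expect_true(m$degenerate)
  expect_null(m$spiral)
  expect_identical(m$n_segments, 1L)
  expect_lt(m$rms, 1e-9)
})

test_that("a tangent straight segment is recovered jointly with the spiral", {
  a <- 1; b <- 0.15; th0 <- 2.5
  p0 <- drop(log_spiral_points(th0, a, b))
  # unit tangent of the spiral at th0
  tg <- c(b * cos(th0) - sin(th0), b * sin(th0) + cos(th0))
  tg <- tg / sqrt(sum(tg^2))
  seg_len <- 3
  seg_t <- seq(seg_len, 0.3, length.out = 5)
  seg_pts <- cbind(p0[1] - tg[1] * seg_t, p0[2] - tg[2] * seg_t)
  sp_pts <- log_spiral_points(seq(th0, 8, length.out = 18), a, b)
  pts <- rbind(seg_pts, sp_pts)

  m <- fit_shape_model(pts)
  expect_gte(m$n_segments, 1L)
  fit_len <- sum(vapply(m$segments, `[[`, numeric(1), "length"))
  expect_lt(abs(fit_len - seg_len) / seg_len, 0.05)

  # brute-force oracle: grid over the basal/spiral split point. The first
  # spiral sample is the tangency point itself (it lies on the line), so
  # splits after 5 or 6 points are equivalent zero-residual optima.
  oracle <- vapply(3:10, function(mm) {
    lf <- cochsim:::fit_line_orth(pts[1:mm, , drop = FALSE])
    sf <- cochsim:::fit_spiral(pts[(mm + 1):23, , drop = FALSE],
                               polish = FALSE)
    lf$rss + sf$rss
  }, numeric(1))
  expect_true((which.min(oracle) + 2L) %in% c(5L, 6L))
  expect_lt(min(oracle), 1e-10)
})

test_that("degenerate inputs raise classed errors", {
  expect_error(fit_shape_model(fx_spiral_points()[1:4, ]),
               class = "cochsim_invalid_input")
  expect_error(fit_shape_model(cbind(1:10)), class = "cochsim_invalid_input")
})

test_that("fit round-trip on a synthesized final state recovers the spiral", {
  prof <- fx_profile("moderate")
  st <- prof$states[[length(prof$states)]]
  m <- fit_shape_model(st$contacts)
  expect_lt(abs(m$spiral$b - prof$params$b) / prof$params$b, 0.01)
  # the radius at the tip-most contact must match the construction
  r_fit <- sqrt(sum((st$contacts[22, ] - m$spiral$center)^2))
  mm <- prof$params$b / sqrt(1 + prof$params$b^2)
  u <- prof$config$tip_offset  # arc distance of c22 behind the tip
  r_true <- prof$params$r_tip + mm * u
  expect_lt(abs(r_fit - r_true) / r_true, 0.01)
})

test_that("shape_model_curve evaluates a continuous base-to-tip polyline", {
  pts <- fx_spiral_points()
  m <- fit_shape_model(pts)
  cur <- shape_model_curve(m, n = 300)
  expect_equal(nrow(cur), 300)
  # every input point lies close to the evaluated curve
  d <- cochsim:::points_polyline_distance(pts[, 1], pts[, 2], cur)
  expect_lt(max(d), 1e-3)
})
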