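# Synthetic cochlear contours, the distance-A size metric, and the
# mesh-to-contour projection pipeline.

test_that("synthesized cochleae hit their distance-A target", {
  cm <- synthesize_cochlea(9.0)
  expect_lt(abs(measure_distance_A(cm) - 9.0), 0.05)
  sizes <- vapply(c("CS", "CM", "CL"),
                  function(s) fx_cochlea(s)$distance_A, numeric(1))
  expect_true(all(diff(sizes) > 0))
})

test_that("lumen width is positive everywhere and contours do not cross", {
  for (s in c("CS", "CM", "CL")) {
    ct <- fx_cochlea(s)
    expect_true(all(ct$width > 0))
    gap <- sqrt(rowSums((ct$outer - ct$inner)^2))
    expect_true(all(gap > 0))
  }
})

test_that("measurement is scale-equivariant and handles the annulus case", {
  cm <- fx_cochlea("CM")
  scaled <- cm
  for (f in c("inner", "outer", "centerline")) scaled[[f]] <- cm[[f]] * 1.1
  expect_equal(measure_distance_A(scaled), 1.1 * measure_distance_A(cm),
               tolerance = 1e-9)
  # circle annulus: A equals the outer diameter (centerline traversed
  # clockwise, the package's curl convention, so the left normal points
  # outward)
  th <- seq(0, -2.02 * pi, length.out = 200)
  ring <- band_contour(cbind(3 * cos(th), 3 * sin(th)), 1)
  expect_equal(measure_distance_A(ring), 2 * 3.5, tolerance = 1e-3)
})

test_that("insufficient coverage and bad configs are rejected", {
  half <- band_contour(cbind(cos(seq(0, pi, length.out = 50)),
                             sin(seq(0, pi, length.out = 50))), 0.3)
  expect_error(measure_distance_A(half),
               class = "cochsim_insufficient_coverage")
  expect_error(synthesize_cochlea(turns = 1.0),
               class = "cochsim_invalid_config")
  expect_error(synthesize_cochlea(12.5), class = "cochsim_invalid_config")
})

test_that("narrow lumina raise the contact-forced warning flag", {
  tight <- synthesize_cochlea("CS", config = list(width_scale = 0.3))
  expect_true(tight$narrow_warning)
  expect_false(fx_cochlea("CM")$narrow_warning)
})

make_samples_from_contour <- function(ct, embed = NULL) {
  n <- nrow(ct$inner)
  lapply(seq_len(n), function(i) {
    i3 <- c(ct$inner[i, ], 0)
    o3 <- c(ct$outer[i, ], 0)
    if (!is.null(embed)) { i3 <- embed(i3); o3 <- embed(o3) }
    structure(list(plane_angle = (i - 1) * 5, inner_point = i3,
                   outer_point = o3), class = "cross_section_sample")
  })
}

test_that("ODR plane projection recovers coplanar samples exactly", {
  cm <- fx_cochlea("CM")
  smp <- make_samples_from_contour(cm)
  proj <- project_to_plane(smp)
  expect_lt(attr(proj, "plane")$max_residual, 1e-9)
  expect_equal(proj$centerline, cm$centerline, tolerance = 1e-6)
  # idempotence: projecting the projected contour again is the identity
  proj2 <- project_to_plane(make_samples_from_contour(proj))
  expect_equal(proj2$centerline, proj$centerline, tolerance = 1e-9)
})

test_that("plane normal is recovered within 2 degrees under noise", {
  cm <- fx_cochlea("CM")
  ax <- c(0.3, -0.2, 0.93); ax <- ax / sqrt(sum(ax^2))
  b1 <- c(1, 0, 0) - ax[1] * ax; b1 <- b1 / sqrt(sum(b1^2))
  b2 <- c(ax[2] * b1[3] - ax[3] * b1[2],
          ax[3] * b1[1] - ax[1] * b1[3],
          ax[1] * b1[2] - ax[2] * b1[1])
  set.seed(5)
  embed <- function(p) p[1] * b1 + p[2] * b2 + c(10, -4, 2) +
    stats::rnorm(3, 0, 0.05)
  smp <- make_samples_from_contour(cm, embed)
  proj <- project_to_plane(smp)
  nrm <- attr(proj, "plane")$normal
  ang <- acos(min(abs(sum(nrm * ax)), 1)) * 180 / pi
  expect_lt(ang, 2)
  # SVD oracle on the same point cloud
  pts <- do.call(rbind, lapply(smp, function(s) rbind(s$inner_point,
                                                      s$outer_point)))
  sv <- svd(sweep(pts, 2, colMeans(pts)))
  expect_lt(acos(min(abs(sum(nrm * sv$v[, 3])), 1)) * 180 / pi, 1e-6)
})

test_that("degenerate sample sets are rejected", {
  line_smp <- lapply(1:7, function(i) {
    structure(list(plane_angle = i * 5,
                   inner_point = c(i, 0, 0) * 1.0,
                   outer_point = c(i + 0.0, 0, 0)),
              class = "cross_section_sample")
  })
  expect_error(project_to_plane(line_smp),
               class = "cochsim_degenerate_plane")
  expect_error(project_to_plane(line_smp[1:5]),
               class = "cochsim_invalid_input")
})

helix_mesh <- function(turns = 2, radius = 4, tube_r = 0.5, pitch = 2,
                       n = 400) {
  th <- seq(0, 2 * pi * turns, length.out = n)
  ctl <- cbind(radius * cos(th), radius * sin(th), pitch * th / (2 * pi))
  synthesize_tube_mesh(ctl, tube_r, n_circ = 28)
}

test_that("cross sections of a helical tube recover the tube diameter", {
  mesh <- helix_mesh(turns = 2)
  ax <- modiolar_axis(c(0, 0, 0), c(0, 0, 1))
  smp <- sample_cross_sections(mesh, ax, step_deg = 5, angle_range = 720)
  expect_length(smp, 144)   # 720 / 5
  d <- vapply(smp, function(s) {
    sqrt(sum((s$outer_point - s$inner_point)^2))
  }, numeric(1))
  expect_lt(max(abs(d - 1.0)) / 1.0, 0.05)
})

test_that("axis reversal yields the same samples up to ordering", {
  mesh <- helix_mesh(turns = 1, pitch = 0.5, n = 250)
  s1 <- sample_cross_sections(mesh, modiolar_axis(c(0, 0, 0), c(0, 0, 1)),
                              step_deg = 15, angle_range = 360)
  s2 <- sample_cross_sections(mesh, modiolar_axis(c(0, 0, 0), c(0, 0, -1)),
                              step_deg = 15, angle_range = 360)
  p1 <- do.call(rbind, lapply(s1, `[[`, "outer_point"))
  p2 <- do.call(rbind, lapply(s2, `[[`, "outer_point"))
  for (i in seq_len(nrow(p1))) {
    expect_lt(min(sqrt(rowSums(sweep(p2, 2, p1[i, ])^2))), 0.2)
  }
})

test_that("STL files round-trip through both encodings", {
  mesh <- helix_mesh(turns = 1, n = 40)
  f <- tempfile(fileext = ".stl")
  write_stl(mesh, f)
  back <- read_stl(f)
  expect_equal(back$v1, mesh$v1, tolerance = 1e-6)
  expect_equal(back$v3, mesh$v3, tolerance = 1e-6)
  # binary STL crafted independently of the package writer
  fb <- tempfile(fileext = ".stl")
  con <- file(fb, "wb")
  writeBin(raw(80), con)
  writeBin(2L, con, size = 4, endian = "little")
  tri <- rbind(c(0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1, 0),
               c(0, 0, 1, 1, 0, 0, 1, 1, 0, 0, 1, 0))
  for (i in 1:2) {
    writeBin(as.numeric(tri[i, ]), con, size = 4, endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
  close(con)
  bm <- read_stl(fb)
  expect_equal(nrow(bm$v1), 2)
  expect_equal(bm$v1[1, ], c(0, 0, 0), tolerance = 1e-7)
  expect_equal(bm$v2[1, ], c(1, 0, 0), tolerance = 1e-7)
  expect_equal(bm$v2[2, ], c(1, 1, 0), tolerance = 1e-7)
})
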