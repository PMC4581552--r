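# Penetration scoring and the trauma-risk grade cascade.

test_that("an outline strictly inside the lumen reports zero everywhere", {
  rep0 <- compute_overlap(build_outline(fx_straight_state(y0 = 0)),
                          fx_straight_band(width = 6))
  expect_equal(rep0$total_overlap_area, 0)
  expect_equal(rep0$body_penetration_fraction, 0)
  expect_equal(rep0$tip_overlap_fraction, 0)
  expect_identical(rep0$contact_regions, 0L)
  expect_identical(as.integer(grade(rep0)), 0L)
})

test_that("a rectangle crossing a straight wall by half its width scores 0.5", {
  # walls at y = +-2; basal outer face at 1.75 + 0.65 pokes out by 0.4
  # = half the basal width 0.8
  rep1 <- compute_overlap(build_outline(fx_straight_state(y0 = 1.75)),
                          fx_straight_band(width = 4))
  expect_equal(rep1$body_penetration_fraction, 0.5, tolerance = 1e-6)
})

test_that("inner-near-tip plus outer-near-base penetration sets restraint", {
  # thin upper face (0.15 offset) pokes the outer wall near the base, the
  # thick lower face (0.65 -> 0.45) pokes the inner wall near the tip
  st <- list(path = cbind(seq(0, -2, length.out = 60),
                          seq(0.45, -0.1, length.out = 60)),
             curl_sign = -1)
  rep2 <- compute_overlap(build_outline(st), fx_straight_band(width = 1))
  expect_true(rep2$restraint_flag)
  expect_gte(rep2$contact_regions, 2L)
})

test_that("degenerate outlines are rejected", {
  o <- build_outline(fx_straight_state())
  o$area <- 0
  expect_error(compute_overlap(o, fx_straight_band()),
               class = "cochsim_invalid_input")
})

test_that("overlap areas agree with the Monte-Carlo oracle within 1%", {
  set.seed(11)
  checked <- 0
  for (k in 1:40) {
    width <- stats::runif(1, 1.2, 3)
    y0 <- stats::runif(1, 0.2, width)         # varying penetration depth
    # gentle lumen curvature; radii keep the outline well inside the
    # band's angular extent (the open band ends are not part of the check)
    R <- stats::runif(1, 24, 40)
    th <- seq(-0.6, 0.6, length.out = 121)
    band <- band_contour(cbind(R * sin(th), R * (1 - cos(th)) - width / 2),
                         width)
    len <- stats::runif(1, 6, 12)
    ang <- stats::runif(1, -0.15, 0.15)
    st <- list(path = cbind(seq(-len, 0, length.out = 120) * cos(ang),
                            y0 + seq(-len, 0, length.out = 120) * sin(ang)),
               curl_sign = -1)
    o <- build_outline(st)
    impl <- compute_overlap(o, band)$total_overlap_area
    if (impl < 0.4) next                      # need a meaningful overlap
    oracle <- mc_overlap_area(o, band, n = 1e5, seed = 1000 + k)
    expect_lt(abs(impl - oracle) / oracle, 0.01)
    checked <- checked + 1
    if (checked >= 20) break
  }
  expect_gte(checked, 20)
})

test_that("grade cascade reproduces the rating-scale anchors", {
  expect_identical(as.integer(grade(overlap_report())), 0L)
  expect_identical(as.integer(grade(overlap_report(
    body_penetration_fraction = 0.20, contact_regions = 1L,
    total_overlap_area = 0.1))), 1L)
  expect_identical(as.integer(grade(overlap_report(
    tip_overlap_fraction = 0.6, contact_regions = 1L))), 2L)
  expect_identical(as.integer(grade(overlap_report(
    body_penetration_fraction = 0.3, contact_regions = 1L))), 2L)
  expect_identical(as.integer(grade(overlap_report(
    tip_outside_whole = TRUE, tip_overlap_fraction = 1))), 3L)
  expect_identical(as.integer(grade(overlap_report(
    body_penetration_fraction = 1.0))), 3L)
  expect_identical(as.integer(grade(overlap_report(
    restraint_flag = TRUE, contact_regions = 2L))), 3L)
  expect_identical(as.integer(grade(overlap_report(
    restraint_flag = TRUE, contact_regions = 3L))), 4L)
  expect_identical(as.integer(grade(overlap_report(
    far_outside_flag = TRUE, contact_regions = 1L))), 4L)
  # head-on tip incidence upgrades a slight tip contact
  expect_identical(as.integer(grade(overlap_report(
    tip_overlap_fraction = 0.1, tip_incidence_deg = 20,
    contact_regions = 1L))), 2L)
})

test_that("the grade I to II transition sits exactly at a quarter", {
  g_of <- function(f) as.integer(grade(overlap_report(
    body_penetration_fraction = f)))
  lo <- 0; hi <- 0.5
  while (hi - lo > 1e-9) {
    mid <- (lo + hi) / 2
    if (g_of(mid) >= 2L) hi <- mid else lo <- mid
  }
  expect_equal(hi, 0.25, tolerance = 1e-6)
})

test_that("grade is monotone in the penetration fractions", {
  set.seed(3)
  for (k in 1:50) {
    base <- overlap_report(
      contact_regions = sample(0:3, 1),
      restraint_flag = stats::runif(1) < 0.3,
      tip_overlap_fraction = stats::runif(1))
    gb <- vapply(seq(0, 1, by = 0.05), function(f) {
      as.integer(grade(utils::modifyList(base, list(
        body_penetration_fraction = f))))
    }, integer(1))
    expect_true(all(diff(gb) >= 0))
    gt <- vapply(seq(0, 1, by = 0.05), function(f) {
      as.integer(grade(utils::modifyList(base, list(
        tip_overlap_fraction = f))))
    }, integer(1))
    expect_true(all(diff(gt) >= 0))
  }
})

test_that("grade distributions normalize and aggregate linearly", {
  expect_equal(unname(grade_distribution(c(0, 0, 1, 2))),
               c(0.5, 0.25, 0.25, 0, 0))
  expect_equal(unname(grade_distribution(rep(4, 6))), c(0, 0, 0, 0, 1))
  g1 <- c(0, 1, 1, 2); g2 <- c(3, 3)
  combined <- grade_distribution(c(g1, g2))
  weighted <- (length(g1) * grade_distribution(g1) +
                 length(g2) * grade_distribution(g2)) /
    (length(g1) + length(g2))
  expect_equal(combined, weighted, tolerance = 1e-12)
  expect_equal(sum(combined), 1, tolerance = 1e-12)
  expect_error(grade_distribution(integer(0)),
               class = "cochsim_invalid_input")
})
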