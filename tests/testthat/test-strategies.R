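# Insertion planning (autoAOS, manAOS) and the simulation loop.

test_that("autoAOS couples feed 1:1 to extraction and freezes dy, dphi", {
  prof <- synthesize_curling_profile("moderate",
                                     config = list(step = 0.2,
                                                   s_max = 0.4))
  plan <- plan_autoAOS(prof, fx_cochlea("CM"), config = list(dx0 = 2))
  expect_equal(plan$steps$dx, c(2.0, 2.2, 2.4))
  expect_equal(length(unique(plan$steps$dy)), 1L)
  expect_equal(length(unique(plan$steps$dphi)), 1L)
  expect_equal(nrow(plan$steps), length(prof$s))
  expect_true(plan$constraints_record$dy_locked)
  expect_length(plan$constraints_record$canal_lines$y, 2)
})

test_that("autoAOS plans are deterministic", {
  prof <- fx_profile("moderate")
  p1 <- plan_autoAOS(prof, fx_cochlea("CM"))
  p2 <- plan_autoAOS(prof, fx_cochlea("CM"))
  expect_identical(p1, p2)
})

test_that("manAOS keeps zero rotation for a straight start in a wide lumen", {
  prof <- synthesize_curling_profile(
    "flat", config = list(step = 0.25, s_max = 2, start_sagitta = 1e-9))
  wide <- fx_straight_band(width = 40, half_len = 60)
  plan <- plan_manAOS(prof, wide)
  expect_equal(max(abs(plan$steps$dphi)), 0)
})

test_that("manAOS compensates a banana start and dominates autoAOS per step", {
  prof <- fx_profile("moderate")
  cont <- fx_cochlea("CM")
  pm <- plan_manAOS(prof, cont)
  expect_gt(abs(pm$steps$dphi[1]), 0)
  # brute-force grid oracle at step 0
  o <- build_outline(prof$states[[1]])
  grid <- seq(-5, 5, by = 0.25)
  costs <- vapply(grid, function(a) {
    pl <- place_electrode(o, insertion_pose(7.6, 0, a), cont$cochleostomy)
    cochsim:::step_cost(compute_overlap(pl, cont), c(1, 0.5, 0))
  }, numeric(1))
  expect_gt(abs(grid[which.min(costs)]), 0)
  expect_lt(abs(pm$steps$dphi[1] - grid[which.min(costs)]), 1.3)

  pa <- plan_autoAOS(prof, cont)
  ta <- simulate_insertion(pa, prof, cont)
  tm <- simulate_insertion(pm, prof, cont)
  wc <- c(1, 0.5, 0)
  ca <- vapply(ta$reports, cochsim:::step_cost, numeric(1), weights = wc)
  cm_ <- vapply(tm$reports, cochsim:::step_cost, numeric(1), weights = wc)
  expect_true(all(cm_ <= ca + 1e-9))
  # rotation-rate cap honoured
  expect_true(all(abs(diff(pm$steps$dphi)) <= 5 + 1e-9))
})

test_that("simulation in an oversized lumen is contact-free throughout", {
  prof <- fx_profile("moderate")
  huge <- fx_straight_band(width = 60, half_len = 80)
  tr <- simulate_insertion(plan_autoAOS(prof, huge), prof, huge)
  expect_true(all(tr$steps$grade == 0))
  expect_equal(unname(tr$histogram[1]), 1)
  expect_equal(sum(tr$histogram), 1, tolerance = 1e-12)
})

test_that("simulation traces carry one record per step and normalize", {
  prof <- fx_profile("moderate")
  cont <- fx_cochlea("CS")
  plan <- plan_autoAOS(prof, cont)
  tr <- simulate_insertion(plan, prof, cont)
  expect_equal(nrow(tr$steps), nrow(plan$steps))
  expect_equal(sum(tr$histogram), 1, tolerance = 1e-12)
  expect_length(tr$reports, nrow(plan$steps))
})

test_that("plans outside the profile extraction range are rejected", {
  prof <- fx_profile("moderate")
  plan <- plan_autoAOS(prof, fx_cochlea("CM"))
  plan$steps$s[nrow(plan$steps)] <- prof$s_max + 2
  expect_error(simulate_insertion(plan, prof, fx_cochlea("CM")),
               class = "cochsim_invalid_plan")
})

test_that("feed monotonicity holds for every emitted plan", {
  prof <- fx_profile("pronounced")
  cont <- fx_cochlea("CS")
  plans <- list(plan_autoAOS(prof, cont), plan_manAOS(prof, cont),
                memo("opt_pronounced_CS",
                     optimize_insertion(prof, cont))$plan)
  for (p in plans) {
    expect_true(all(diff(p$steps$dx) >= -1e-9), label = p$strategy)
    expect_true(all(diff(p$steps$s) > 0))
  }
})
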