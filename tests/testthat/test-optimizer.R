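# Constrained insertion optimization (optIns).

test_that("a zero-overlap warm start is returned unchanged", {
  prof <- fx_profile("moderate")
  huge <- fx_straight_band(width = 60, half_len = 80)
  cfg <- optimization_config(
    terminal = list(s_max = prof$s_max, dx_final = 7.6 + prof$s_max))
  res <- optimize_insertion(prof, huge, cfg)
  warm <- plan_autoAOS(prof, huge)
  expect_equal(res$plan$steps$dx, warm$steps$dx, tolerance = 1e-9)
  expect_equal(res$plan$steps$dy, warm$steps$dy, tolerance = 1e-9)
  expect_equal(res$plan$steps$dphi, warm$steps$dphi, tolerance = 1e-9)
  expect_equal(res$objective_value, 0)
})

test_that("optimization beats the autoAOS baseline on a tight fixture", {
  prof <- fx_profile("pronounced")
  cont <- fx_cochlea("CS")
  res <- memo("opt_pronounced_CS", optimize_insertion(prof, cont))
  expect_lt(res$objective_value, res$dominated_baseline)
  expect_true(all(diff(res$plan$steps$dx) >= -1e-9))
  n <- nrow(res$plan$steps)
  dx_term <- res$plan$constraints_record$terminal$dx_final
  expect_equal(res$plan$steps$dx[n], dx_term, tolerance = 1e-9)
  # terminal feed within the under-insertion tolerance of full insertion
  expect_lte(dx_term, prof$insertable_length + 1e-9)
  expect_gte(dx_term, prof$insertable_length - 2 - 1e-9)
})

test_that("emitted plans pass the independent constraint checker", {
  prof <- fx_profile("pronounced")
  cont <- fx_cochlea("CS")
  res <- memo("opt_pronounced_CS", optimize_insertion(prof, cont))
  ok <- check_plan(res$plan,
                   terminal = res$plan$constraints_record$terminal)
  expect_true(ok)
  expect_length(attr(ok, "violations"), 0)
  # the checker itself detects violations
  bad <- res$plan
  bad$steps$dy[5] <- bad$steps$dy[4] + 1
  expect_false(check_plan(bad))
})

test_that("the objective is non-increasing across solver iterations", {
  prof <- fx_profile("pronounced")
  cont <- fx_cochlea("CS")
  res <- memo("opt_pronounced_CS", optimize_insertion(prof, cont))
  expect_true(all(diff(res$objective_trace) <= 1e-9))
  expect_gte(res$iterations, 1L)
})

test_that("unreachable terminal feeds raise an infeasibility error", {
  prof <- fx_profile("moderate")
  cont <- fx_cochlea("CM")
  err <- tryCatch(
    optimize_insertion(prof, cont,
                       optimization_config(
                         terminal = list(s_max = prof$s_max,
                                         dx_final = 100))),
    error = function(e) e)
  expect_s3_class(err, "cochsim_infeasible")
  expect_match(conditionMessage(err), "dx rate cap")
})

test_that("solver matches the exhaustive lattice optimum within 5%", {
  # 6-step reduced instance; the oracle dynamic program enumerates every
  # feasible lattice path exactly (see helper-fixtures.R)
  lv <- lattice_vs_solver()
  expect_true(is.finite(lv$lattice))
  expect_lte(lv$solver, 1.05 * lv$lattice)
})

test_that("strategy comparison produces three normalized histograms", {
  prof <- fx_profile("moderate")
  cont <- fx_cochlea("CM")
  cmp <- memo("cmp_moderate_CM", compare_strategies(prof, cont))
  expect_named(cmp$traces, c("autoAOS", "manAOS", "optIns"))
  for (tr in cmp$traces) {
    expect_equal(sum(tr$histogram), 1, tolerance = 1e-12)
  }
  mg <- cmp$summary$mean_grade
  names(mg) <- cmp$summary$strategy
  expect_lte(mg[["optIns"]], mg[["manAOS"]])
  expect_lte(mg[["manAOS"]], mg[["autoAOS"]])
})

test_that("optimization configuration validates its invariants", {
  expect_error(optimization_config(weights = c(0, 0, 0)))
  expect_error(optimization_config(rate_caps = c(dx = 0, dy = 0.1,
                                                 dphi = 1)))
})
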