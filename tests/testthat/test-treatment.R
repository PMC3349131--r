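test_that("trajectories satisfy their defining geometry", {
  # sequential: first two points 2 mm apart in the same (top) row
  tr <- make_trajectory("sequential")
  expect_equal(nrow(tr), 56)
  expect_equal(tr[2, ] - tr[1, ], c(2e-3, 0))
  expect_equal(tr[1, 2], max(tr[, 2]))     # starts in the top row
  expect_equal(tr[1, 1], min(tr[, 1]))     # ... at its left end

  # random: every consecutive pair >= 8 mm apart, deterministic per seed
  r1 <- make_trajectory("random", seed = 42)
  r2 <- make_trajectory("random", seed = 42)
  expect_identical(r1, r2)
  expect_false(identical(r1, make_trajectory("random", seed = 43)))
  d <- sqrt(rowSums((r1[-1, ] - r1[-nrow(r1), ])^2))
  expect_true(all(d >= 8e-3 - 1e-12))
  expect_setequal(apply(r1, 1, paste, collapse = ","),
                  apply(make_trajectory("sequential"), 1, paste,
                        collapse = ","))
  expect_error(make_trajectory("random", seed = 1, min_sep = 1,
                               max_retries = 10L), "separation")

  # spiral: starts at the centre, radius non-decreasing, ~2 mm steps
  sp <- make_trajectory("spiral", centre = c(1e-3, -2e-3))
  expect_equal(sp[1, ], c(1e-3, -2e-3))
  r <- sqrt(rowSums(sweep(sp, 2, c(1e-3, -2e-3))^2))
  expect_true(!is.unsorted(r))
  step <- sqrt(rowSums((sp[-1, ] - sp[-nrow(sp), ])^2))
  expect_true(all(abs(step[-1] - 2e-3) < 0.3e-3))
})

test_that("plan arithmetic: 56 events, 20 s on / 5 s cool, 1395 s total", {
  plan <- sonication_plan(make_trajectory("sequential"))
  expect_equal(plan$n, 56)
  expect_equal(plan$total_time, 56 * 20 + 55 * 5)
  expect_equal(plan$total_time, 1395)
})

test_that("a zero-power plan deposits no dose and a short treatment logs", {
  f <- tiny_vessel_fields(h = 0.5 * mm)
  ctr <- f$scenario$domain_size[1:2] / 2
  foci <- make_trajectory("sequential", pitch = 1e-3, n_points = 4,
                          centre = ctr)
  plan <- sonication_plan(foci, on = 1, cool = 0.5, p0 = 1e-6, kind = "seq")
  tx <- run_treatment(f, plan, config = solver_config(dt = 0.1))
  expect_equal(nrow(tx$log), 4)
  expect_equal(tx$state$time, 4 * 1 + 3 * 0.5)
  expect_lt(max(tx$state$dose), 1e-9)
})

test_that("treatments are deterministic given the seed", {
  f <- tiny_vessel_fields(h = 0.5 * mm)
  ctr <- f$scenario$domain_size[1:2] / 2
  mk <- function() {
    foci <- make_trajectory("random", pitch = 1e-3, n_points = 4, seed = 5,
                            centre = ctr, min_sep = 1e-3)
    plan <- sonication_plan(foci, on = 1, cool = 0.5, p0 = 20e6,
                            kind = "random", seed = 5)
    run_treatment(f, plan, config = solver_config(dt = 0.1),
                  source_template = fus_source(20e6, 2 * mm, 6 * mm,
                                               focus = c(0, 0, 0)))
  }
  a <- mk()
  b <- mk()
  expect_identical(a$state$T, b$state$T)
  expect_identical(a$log, b$log)
})

test_that("dose increases monotonically with event power", {
  f <- tiny_vessel_fields(h = 0.5 * mm)
  src <- fus_source(1, 2 * mm, 6 * mm, focus = c(4, 4, 8) * mm)
  pw <- power_field(src, f$grid, warn = FALSE)
  cfg <- solver_config(dt = 0.1)
  doses <- vapply(c(10, 15, 20, 30) * 1e6, function(p) {
    out <- simulate_heating(f, p * pw, 5, cfg, warn_focus = FALSE)
    max(out$dose)
  }, numeric(1))
  expect_true(all(diff(doses) > 0))
})

test_that("control_power obeys monotonicity and the band", {
  ctrl <- power_controller()
  # synthetic monotone response: log-linear dose in power
  dose_fn <- function(p) exp(log(500) + (p - 20e6) / 8e6)
  res <- control_power(ctrl, 20e6, dose_fn)      # 500 above band -> lower P0
  expect_lt(res$p0, 20e6)
  expect_true(res$dose >= 230 && res$dose <= 250)
  res2 <- control_power(ctrl, res$p0, dose_fn)   # inside band -> unchanged
  expect_identical(res2$iterations, 0L)
  expect_equal(res2$p0, res$p0)
  low_fn <- function(p) 100 * p / 20e6           # below band -> raise P0
  res3 <- control_power(ctrl, 20e6, low_fn)
  expect_gt(res3$p0, 20e6)
})

test_that("the controller caps per-event incremental dose in a treatment", {
  f <- acc_s6_fields()
  ctr <- f$scenario$domain_size[1:2] / 2
  foci <- make_trajectory("random", centre = ctr, seed = 11)[1:3, ]
  plan <- sonication_plan(foci, p0 = 16.5e6, kind = "random", seed = 11)
  tx <- run_treatment(f, plan, config = acc_cfg(),
                      controller = power_controller())
  expect_true(all(tx$log$peak_inc_dose >= 225 & tx$log$peak_inc_dose <= 255))
  expect_true(all(tx$log$p0 > 0))
})
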