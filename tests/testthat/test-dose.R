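test_that("constant-temperature doses match the closed forms", {
  # 43 C for 240 min -> 240 eq-min (rate 1); 44 C for 120 min -> 240
  # (rate 1/0.5 = 2); 42 C for 60 min -> 15 (rate 0.25)
  expect_equal(accumulate_dose(0, 43, 240 * 60), 240)
  expect_equal(accumulate_dose(0, 44, 120 * 60), 240)
  expect_equal(accumulate_dose(0, 42, 60 * 60), 15)
  expect_equal(normalize_dose(240), 1)
})

test_that("dose is monotone, additive over time and increasing in T", {
  expect_true(all(diff(cem43_rate_r(seq(38, 48, by = 0.1))) > 0))
  # additivity over partitions
  one <- accumulate_dose(0, 43.7, 600)
  two <- accumulate_dose(accumulate_dose(0, 43.7, 200), 43.7, 400)
  expect_equal(one, two)
  # non-decreasing under any temperature history
  set.seed(1)
  d <- 0
  for (Tk in runif(50, 36, 45)) {
    d2 <- accumulate_dose(d, Tk, 5)
    expect_gte(d2, d)
    d <- d2
  }
})

test_that("rectangle-rule quadrature tracks a fine-step oracle on ramps", {
  # linear ramp 37 -> 45 C over 60 s; oracle: 1000x finer rectangle rule
  t_end <- 60
  ramp <- function(t) 37 + 8 * t / t_end
  coarse_dt <- 0.05  # default solver cadence
  tc <- seq(coarse_dt, t_end, by = coarse_dt)
  coarse <- sum(coarse_dt / 60 * cem43_rate_r(ramp(tc)))
  fine_dt <- coarse_dt / 1000
  tf <- seq(fine_dt, t_end, by = fine_dt)
  fine <- sum(fine_dt / 60 * cem43_rate_r(ramp(tf)))
  expect_equal(coarse, fine, tolerance = 0.005)
})

test_that("solver-integrated dose matches the pure R accumulation", {
  f <- tiny_tissue_fields()
  src <- fus_source(40, 3 * mm, 8 * mm, focus = c(4, 4, 8) * mm,
                    units = "W/cm3")
  cfg <- solver_config(dt = 0.1, dose_cutoff = 0)
  eng <- fusbioheat:::bh_engine(f, cfg)
  st <- thermal_state(f, cfg)
  dose_ref <- st$dose
  for (i in 1:30) {
    st <- fusbioheat:::engine_advance(
      eng, st, 40e6 * power_field(fusbioheat:::with_p0(src, 1), f$grid,
                                  warn = FALSE), 1L, dose_on = TRUE)
    dose_ref <- accumulate_dose(dose_ref, st$T, cfg$dt)
  }
  expect_equal(st$dose, dose_ref, tolerance = 1e-10)
})

test_that("midplane extraction picks the central transverse plane", {
  g <- sim_grid(1e-3, c(4, 4, 7) * 1e-3)
  x <- array(seq_len(prod(g$dims)), g$dims)
  expect_equal(midplane(x, g), x[, , 4])
})
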