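test_that("uniform 37 C with zero power is an equilibrium", {
  f <- tiny_vessel_fields()
  out <- simulate_heating(f, NULL, 5, solver_config(dt = 0.1))
  expect_lt(max(abs(out$T - 37)), 1e-6)
})

test_that("diffusion matches the analytic heat kernel (1-D and 3-D)", {
  alpha <- 1.8 / (1000 * 4000)
  cfg <- solver_config(dt = 0.05)
  A <- 100
  t_end <- 5

  # 1-D bar, impulse release at the centre
  f1 <- rasterize(make_scenario(c(16, 0.2, 0.2) * mm, list(), d = 0.02),
                  sim_grid(0.2 * mm, c(16, 0.2, 0.2) * mm))
  eng <- fusbioheat:::bh_engine(f1, cfg)
  st <- thermal_state(f1, cfg)
  ic <- st$grid$dims[1] / 2
  st$T[ic, 1, 1] <- 37 + A
  out <- fusbioheat:::engine_advance(eng, st, NULL, 100L, dose_on = FALSE)
  x <- grid_axes(st$grid)[[1]]
  exact <- 37 + A * st$grid$h[1] / sqrt(4 * pi * alpha * t_end) *
    exp(-(x - x[ic])^2 / (4 * alpha * t_end))
  err1 <- sqrt(sum((out$T[, 1, 1] - exact)^2) / sum((exact - 37)^2))
  expect_lt(err1, 0.02)

  # 3-D point release
  f3 <- rasterize(make_scenario(c(12, 12, 12) * mm, list(), d = 0.02),
                  sim_grid(0.2 * mm, c(12, 12, 12) * mm))
  eng3 <- fusbioheat:::bh_engine(f3, cfg)
  st3 <- thermal_state(f3, cfg)
  ic3 <- st3$grid$dims / 2
  st3$T[ic3[1], ic3[2], ic3[3]] <- 37 + A
  out3 <- fusbioheat:::engine_advance(eng3, st3, NULL, 100L, dose_on = FALSE)
  ax <- grid_axes(st3$grid)
  d <- st3$grid$dims
  r2 <- outer(outer((ax[[1]] - ax[[1]][ic3[1]])^2,
                    (ax[[2]] - ax[[2]][ic3[2]])^2, `+`),
              (ax[[3]] - ax[[3]][ic3[3]])^2, `+`)
  exact3 <- 37 + A * prod(st3$grid$h) / (4 * pi * alpha * t_end)^(3 / 2) *
    exp(-r2 / (4 * alpha * t_end))
  err3 <- sqrt(sum((out3$T - exact3)^2) / sum((exact3 - 37)^2))
  expect_lt(err3, 0.02)
})

test_that("lumen advection translates a pulse at the parabolic axis speed", {
  # single-column lumen: a warm slug moves with the local w, heat content
  # conserved while the slug stays interior (method-of-characteristics)
  v_mean <- 0.05
  size <- c(0.2, 0.2, 40) * mm
  # hair-thin vessel capturing exactly the single on-axis node column
  ves <- vessel_spec(0.09 * mm, size[3], v_mean, origin = size / 2)
  sc <- make_scenario(size, list(ves), d = 0.02)
  f <- rasterize(sc, sim_grid(c(0.2 * mm, 0.2 * mm, 0.2 * mm), size),
                 allow_unresolved = TRUE)
  w_axis <- f$w3[1, 1, 1]
  expect_equal(w_axis, 2 * v_mean, tolerance = 1e-6)
  cfg <- solver_config(dt = 2e-3)
  eng <- fusbioheat:::bh_engine(f, cfg)
  st <- thermal_state(f, cfg)
  kz <- 40:60
  st$T[1, 1, kz] <- 47
  z <- grid_axes(st$grid)[[3]]
  com0 <- sum((st$T[1, 1, ] - 37) * z) / sum(st$T[1, 1, ] - 37)
  e0 <- sum(st$T[1, 1, ] - 37)
  nst <- 50L
  out <- fusbioheat:::engine_advance(eng, st, NULL, nst, dose_on = FALSE)
  prof <- out$T[1, 1, ] - 37
  com1 <- sum(prof * z) / sum(prof)
  # centre of mass advances by w * t (upwind smears but transports exactly)
  expect_equal(com1 - com0, w_axis * nst * cfg$dt, tolerance = 0.02)
  # heat content conserved up to boundary/advective outflow (slug interior)
  expect_equal(sum(prof), e0, tolerance = 0.02)
})

test_that("discrete maximum principle holds without a source", {
  f <- tiny_vessel_fields(v_mean = 0.05)
  cfg <- solver_config(dt = 0.1)
  eng <- fusbioheat:::bh_engine(f, cfg)
  st <- thermal_state(f, cfg)
  set.seed(7)
  st$T[] <- 37 + runif(length(st$T), 0, 10)
  lo <- min(st$T)
  hi <- max(st$T)
  for (i in 1:10) {
    st <- fusbioheat:::engine_advance(eng, st, NULL, 5L, dose_on = FALSE)
    expect_gte(min(st$T), min(lo, 37) - 1e-9)
    expect_lte(max(st$T), hi + 1e-9)
  }
})

test_that("implicit compiled stepper agrees with the explicit reference", {
  f <- tiny_vessel_fields(v_mean = 0.02)
  src <- fus_source(15, 3 * mm, 8 * mm, focus = c(4, 4, 8) * mm,
                    units = "W/cm3")
  ti <- simulate_heating(f, src, 2, solver_config(dt = 2e-3),
                         warn_focus = FALSE)
  te <- simulate_heating(f, src, 2, solver_config(dt = 2e-3,
                                                  scheme = "explicit"),
                         warn_focus = FALSE)
  expect_lt(max(abs(ti$T - te$T)) / (max(ti$T) - 37), 0.01)
  # explicit scheme enforces its stability bound
  expect_error(simulate_heating(f, src, 1,
                                solver_config(dt = 0.5, scheme = "explicit"),
                                warn_focus = FALSE),
               "unstable")
})

test_that("energy is balanced to round-off every implicit step", {
  f <- tiny_vessel_fields(v_mean = 0.05)
  cfg <- solver_config(dt = 0.05)
  eng <- fusbioheat:::bh_engine(f, cfg)
  model <- eng$model
  pw <- power_field(fus_source(10, 3 * mm, 8 * mm, focus = c(4, 4, 8) * mm,
                               units = "W/cm3"), f$grid, warn = FALSE)
  src_dT <- cfg$dt * pw * model$V / model$cap
  T_arr <- array(37, f$grid$dims)
  for (i in 1:20) {
    res <- fusbioheat:::bh_step_energy(model, eng$fac, T_arr, src_dT)
    imbalance <- abs(res$dE - res$E_src - res$Q_bound - res$Q_adv)
    expect_lt(imbalance, 0.01 * max(abs(res$E_src), abs(res$dE)))
    T_arr <- res$T
  }
  # and the diagnostic step reproduces the compiled stepper exactly
  st <- thermal_state(f, cfg)
  out <- fusbioheat:::engine_advance(eng, st, pw, 20L, dose_on = FALSE)
  expect_equal(T_arr, out$T, tolerance = 1e-12)
})

test_that("grid refinement changes the focal peak by < 3%", {
  sc <- make_scenario(c(12, 12, 16) * mm, list(), d = 0.02)
  src <- fus_source(15, 3 * mm, 8 * mm, focus = c(6, 6, 8) * mm,
                    units = "W/cm3")
  peak <- vapply(c(0.5, 0.25) * mm, function(h) {
    f <- rasterize(sc, sim_grid(h, sc$domain_size))
    max(simulate_heating(f, src, 10, solver_config(dt = 0.05),
                         warn_focus = FALSE, dose = FALSE)$T) - 37
  }, numeric(1))
  expect_lt(abs(peak[2] - peak[1]) / peak[2], 0.03)
})

test_that("axisymmetric and 3-D solutions agree on a centred artery", {
  mat <- material_properties()
  ves <- vessel_spec(1.5 * mm, 40 * mm, 0.13, origin = c(15, 15, 20) * mm)
  sc <- make_scenario(c(30, 30, 40) * mm, list(ves), mat)
  src <- fus_source(15, 4 * mm, 30 * mm, focus = c(15, 15, 20) * mm,
                    units = "W/cm3")
  f3 <- rasterize(sc, sim_grid(c(0.25 * mm, 0.25 * mm, 1 * mm),
                               sc$domain_size))
  o3 <- simulate_heating(f3, src, 20, solver_config(dt = 0.1),
                         warn_focus = FALSE, dose = FALSE)
  fa <- rasterize(sc, sim_grid(c(0.25 * mm, 1 * mm), c(15, 40) * mm,
                               mode = "axisym"))
  srca <- fus_source(15, 4 * mm, 30 * mm, focus = c(0, 20 * mm),
                     units = "W/cm3")
  oa <- simulate_heating(fa, srca, 20, solver_config(dt = 0.1),
                         warn_focus = FALSE, dose = FALSE)
  expect_equal(max(o3$T) - 37, max(oa$T) - 37, tolerance = 0.05)
})

test_that("a vanishing vessel recovers the no-vessel solution", {
  size <- c(8, 8, 16) * mm
  src <- fus_source(15, 3 * mm, 8 * mm, focus = size / 2, units = "W/cm3")
  cfg <- solver_config(dt = 0.1)
  f0 <- tiny_tissue_fields(size = size)
  base <- simulate_heating(f0, src, 5, cfg, warn_focus = FALSE, dose = FALSE)
  sc <- make_scenario(size, list(vessel_spec(0.1 * mm, 16 * mm, 0.05,
                                             origin = size / 2)), d = 0.02)
  fv <- rasterize(sc, sim_grid(0.5 * mm, size), allow_unresolved = TRUE)
  withv <- simulate_heating(fv, src, 5, cfg, warn_focus = FALSE,
                            dose = FALSE)
  expect_identical(sum(fv$vessel_id > 0), 0L)
  expect_equal(withv$T, base$T, tolerance = 1e-12)
})

test_that("probe series are recorded by trilinear interpolation", {
  f <- tiny_tissue_fields()
  src <- fus_source(15, 3 * mm, 8 * mm, focus = c(4, 4, 8) * mm,
                    units = "W/cm3")
  probes <- rbind(c(4, 4, 8) * mm, c(2, 4, 8) * mm)
  out <- simulate_heating(f, src, 1, solver_config(dt = 0.1),
                          probes = probes, warn_focus = FALSE)
  expect_s3_class(out$probe_series, "data.frame")
  expect_equal(nrow(out$probe_series), 2 * 10)
  last <- subset(out$probe_series, t == max(t))
  expect_gt(last$T[1], last$T[2])  # focus hotter than off-focus probe
  expect_gt(last$T[2], 37)
})
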