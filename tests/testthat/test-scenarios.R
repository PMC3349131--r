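test_that("material defaults and validation", {
  m <- material_properties()
  expect_equal(m$rho_t, 1000)
  expect_equal(m$c_pt, 4000)
  expect_equal(m$k_eff, 1.8)
  expect_equal(m$rho_b, 1060)
  expect_equal(m$c_pb, 3840)
  expect_equal(m$k_b, 0.6)
  expect_equal(m$T_core, 37)
  expect_error(material_properties(k_eff = -1), "positive")
})

test_that("scenario presets carry the canonical geometries", {
  s1 <- preset_scenario("large_artery")
  expect_length(s1$vessels, 1)
  expect_equal(s1$vessels[[1]]$radius, 1.5e-3)
  expect_equal(s1$vessels[[1]]$length, 0.2)
  expect_equal(s1$vessels[[1]]$v_mean, 0.13)
  expect_equal(s1$vessels[[1]]$direction, c(0, 0, 1))

  s3 <- preset_scenario("secondary_artery")
  expect_equal(s3$vessels[[1]]$radius, 0.3e-3)
  expect_equal(s3$vessels[[1]]$length, 0.04)
  expect_equal(s3$vessels[[1]]$v_mean, 0.08)

  s5 <- preset_scenario("counterflow_pair")
  expect_length(s5$vessels, 2)
  # focus 1 mm from each wall: centres at +-2.5 mm, antiparallel flow
  xs <- vapply(s5$vessels, function(v) v$origin[1], numeric(1))
  expect_equal(sort(xs - s5$domain_size[1] / 2), c(-2.5e-3, 2.5e-3))
  expect_equal(sum(vapply(s5$vessels, `[[`, integer(1), "flow_sign")), 0L)

  s6 <- preset_scenario("multi_pair")
  expect_length(s6$vessels, 18)
  expect_equal(s6$domain_size, c(21, 21, 26) * 1e-3)
  radii <- vapply(s6$vessels, `[[`, numeric(1), "radius")
  expect_equal(sum(radii == 0.5e-3), 6)
  expect_equal(sum(radii == 0.4e-3), 12)
  # artery-vein wall-to-wall gaps: 0.8 mm (large) and 0.6 mm (small)
  org <- t(vapply(s6$vessels, `[[`, numeric(3), "origin"))
  sep_large <- diff(sort(org[radii == 0.5e-3 & org[, 1] == 10.5e-3, 2]))
  expect_equal(sep_large, 1.8e-3, tolerance = 1e-12)

  expect_error(preset_scenario("nope"), "arg")
})

test_that("vessels outside the domain are rejected", {
  expect_error(
    make_scenario(c(10, 10, 20) * 1e-3,
                  list(vessel_spec(2e-3, 20e-3, 0.1,
                                   origin = c(1e-3, 5e-3, 10e-3)))),
    "outside the domain")
  # angled vessel poking through a lateral face
  expect_error(
    make_scenario(c(10, 10, 10) * 1e-3,
                  list(vessel_spec(1e-3, 30e-3, 0.1,
                                   origin = c(5, 5, 5) * 1e-3,
                                   direction = c(1, 0, 1)))),
    "outside the domain")
})

test_that("rasterization reproduces the parabolic profile", {
  f <- tiny_vessel_fields(R = 1e-3, v_mean = 0.05, h = 0.25e-3)
  lum <- f$vessel_id > 0
  expect_true(any(lum))
  # velocity extremes: ~2*Vm at the node nearest the axis (cell centres sit
  # up to h/sqrt(2) off-axis), >= 0 in the lumen, 0 in tissue
  expect_equal(max(f$w3), 2 * 0.05, tolerance = 0.04)
  expect_true(all(f$w3[!lum] == 0))
  expect_true(all(f$w3[lum] >= -1e-12))
  expect_true(all(f$w3 <= 2 * 0.05 + 1e-12))
})

test_that("lumen cross-section node count matches the area oracle", {
  # brute-force point-in-cylinder count vs rasterized mask, R=1.5mm / 0.25mm
  sc <- preset_scenario("large_artery")
  g <- sim_grid(c(0.25e-3, 0.25e-3, 5e-3), sc$domain_size)
  f <- rasterize(sc, g)
  ax <- grid_axes(g)
  ctr <- sc$domain_size[1:2] / 2
  oracle <- sum(outer(ax[[1]] - ctr[1], ax[[2]] - ctr[2],
                      function(x, y) x^2 + y^2) <= (1.5e-3)^2)
  counted <- sum(f$vessel_id[, , 3] > 0)
  expect_equal(counted, oracle)
  expect_equal(counted, pi * 6^2, tolerance = 0.1)  # ~113 +-10%
})

test_that("rasterized lumen volume converges to pi R^2 L", {
  sc <- make_scenario(c(8, 8, 10) * 1e-3,
                      list(vessel_spec(1.2e-3, 10e-3, 0.05,
                                       origin = c(4, 4, 5) * 1e-3)))
  exact <- pi * (1.2e-3)^2 * 10e-3
  err <- vapply(c(0.4, 0.2, 0.1) * 1e-3, function(h) {
    g <- sim_grid(h, sc$domain_size)
    f <- rasterize(sc, g)
    abs(sum(f$vessel_id > 0) * prod(g$h) - exact) / exact
  }, numeric(1))
  expect_lt(err[3], err[1])
  expect_lt(err[3], 0.05)
})

test_that("mean lumen velocity approaches V_m with refinement", {
  v_mean <- 0.08
  sc <- make_scenario(c(8, 8, 6) * 1e-3,
                      list(vessel_spec(1.5e-3, 6e-3, v_mean,
                                       origin = c(4, 4, 3) * 1e-3)))
  g <- sim_grid(c(0.1e-3, 0.1e-3, 2e-3), sc$domain_size)
  f <- rasterize(sc, g)
  expect_equal(mean(f$w3[f$vessel_id > 0]), v_mean, tolerance = 0.03)
})

test_that("builders are pure and rasterization is resolution-guarded", {
  a <- preset_scenario("multi_pair")
  b <- preset_scenario("multi_pair")
  expect_identical(a, b)
  g <- sim_grid(0.5e-3, c(8, 8, 16) * 1e-3)
  sc <- make_scenario(c(8, 8, 16) * 1e-3,
                      list(vessel_spec(0.3e-3, 16e-3, 0.05,
                                       origin = c(4, 4, 8) * 1e-3)))
  expect_error(rasterize(sc, g), "unresolved")
  expect_silent(f <- rasterize(sc, g, allow_unresolved = TRUE))
  sc2 <- make_scenario(c(8, 8, 16) * 1e-3,
                       list(vessel_spec(0.7e-3, 16e-3, 0.05,
                                        origin = c(4, 4, 8) * 1e-3)))
  expect_warning(rasterize(sc2, g), "marginally")
})
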