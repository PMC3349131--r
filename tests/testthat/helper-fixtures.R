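# Shared fixtures. Heavy simulations used by several acceptance checks are
# memoised in `acc` so each is computed once per test run.

mm <- 1e-3

# small 3-D block with one axial vessel, cheap enough for property tests
tiny_vessel_fields <- function(R = 1 * mm, v_mean = 0.02,
                               size = c(8, 8, 16) * mm, h = 0.5 * mm) {
  ves <- vessel_spec(R, size[3], v_mean, origin = size / 2)
  sc <- make_scenario(size, list(ves), d = 0.02)
  rasterize(sc, sim_grid(h, size))
}

tiny_tissue_fields <- function(size = c(8, 8, 16) * mm, h = 0.5 * mm) {
  rasterize(make_scenario(size, list(), d = 0.02), sim_grid(h, size))
}

# -- acceptance-scale shared runs ------------------------------------------

acc <- new.env(parent = emptyenv())

acc_get <- function(key, fun) {
  if (!exists(key, envir = acc, inherits = FALSE))
    assign(key, fun(), envir = acc)
  get(key, envir = acc, inherits = FALSE)
}

acc_s6_fields <- function() acc_get("s6_fields", function() {
  sc <- preset_scenario("multi_pair")
  rasterize(sc, sim_grid(c(0.2 * mm, 0.2 * mm, 2 * mm), sc$domain_size))
})

acc_cfg <- function() solver_config(dt = 0.1)

acc_plan <- function(kind, seed = NULL, p0 = 16.5e6) {
  f <- acc_s6_fields()
  ctr <- f$scenario$domain_size[1:2] / 2
  foci <- make_trajectory(kind, centre = ctr, seed = seed)
  sonication_plan(foci, p0 = p0, kind = kind, seed = seed)
}

acc_fixed_tx <- function(kind, seed = NULL, p0 = 16.5e6) {
  key <- sprintf("fixed_%s_%s_%g", kind, seed %||% 0, p0)
  acc_get(key, function()
    run_treatment(acc_s6_fields(), acc_plan(kind, seed, p0),
                  config = acc_cfg()))
}

acc_var_tx <- function(kind, seed = NULL) {
  key <- sprintf("var_%s_%s", kind, seed %||% 0)
  acc_get(key, function()
    run_treatment(acc_s6_fields(), acc_plan(kind, seed), config = acc_cfg(),
                  controller = power_controller()))
}

acc_mid_stats <- function(tx)
  dose_stats(normalize_dose(midplane(tx$state$dose, tx$grid)))

`%||%` <- function(a, b) if (is.null(a)) b else a

# paired vessel/no-vessel 60 s runs for the peak-reduction checks
acc_s5_runs <- function() acc_get("s5", function() {
  sc <- preset_scenario("counterflow_pair")
  sc0 <- make_scenario(sc$domain_size, list(), d = sc$d)
  g <- sim_grid(c(0.3 * mm, 0.3 * mm, 1 * mm), sc$domain_size)
  src <- fus_source(15, 4 * mm, 30 * mm, focus = sc$domain_size / 2,
                    units = "W/cm3")
  cfg <- solver_config(dt = 0.1)
  list(grid = g, focal_z = sc$domain_size[3] / 2,
       vessel = simulate_heating(rasterize(sc, g), src, 60, cfg,
                                 warn_focus = FALSE, dose = FALSE),
       novessel = simulate_heating(rasterize(sc0, g), src, 60, cfg,
                                   warn_focus = FALSE, dose = FALSE))
})
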