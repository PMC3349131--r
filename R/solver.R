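#' Solver configuration
#'
#' @param dt time step (s). The default implicit scheme is unconditionally
#'   stable; dt controls temporal accuracy only.
#' @param scheme `"implicit"` (backward-Euler locally-one-dimensional
#'   diffusion with upwind advection folded into each axis sweep; compiled)
#'   or `"explicit"` (forward-Euler reference stepper in R, subject to a
#'   stability bound that is checked).
#' @param T_init initial temperature (degrees C); also the core temperature
#'   default is taken from the scenario materials
#' @param dose_cutoff temperature (degrees C) below which per-step CEM43
#'   accumulation is skipped in the compiled stepper. At the default 38 C the
#'   neglected rate is at most `0.25^5` equivalent minutes per minute, i.e.
#'   < 1e-4 normalized dose over a 23-minute treatment.
#' @return an object of class `bh_solver_config`
#' @export
solver_config <- function(dt = 0.05, scheme = c("implicit", "explicit"),
                          T_init = 37, dose_cutoff = 38) {
  scheme <- match.arg(scheme)
  if (dt <= 0) stop("dt must be > 0")
  structure(list(dt = dt, scheme = scheme, T_init = T_init,
                 dose_cutoff = dose_cutoff),
            class = "bh_solver_config")
}

#' Create a fresh thermal state
#'
#' @param fields a [rasterize()] field map
#' @param config a [solver_config()]
#' @return an object of class `bh_state` with uniform initial temperature,
#'   zero dose and time 0
#' @export
thermal_state <- function(fields, config = solver_config()) {
  dims <- fields$grid$dims
  structure(list(time = 0,
                 T = array(config$T_init, dims),
                 dose = array(0, dims),
                 grid = fields$grid),
            class = "bh_state")
}

#' @export
print.bh_state <- function(x, ...) {
  cat(sprintf("<bh_state> t=%.2f s, T in [%.2f, %.2f] C, peak dose %.3g eq-min\n",
              x$time, min(x$T), max(x$T), max(x$dose)))
  invisible(x)
}

# Engine: model + factors cached for repeated stepping on one (fields, dt).
bh_engine <- function(fields, config) {
  model <- build_model(fields, config)
  fac <- if (config$scheme == "implicit") build_factors(model, config$dt)
         else NULL
  list(fields = fields, config = config, model = model, fac = fac)
}

# Advance `state` by nsteps of engine$config$dt with a fixed power field.
# power: array (W/m^3) or NULL. Probes: list(idx, w) or NULL. Modifies and
# returns a new state (arrays are copied once here, then updated in place by
# the compiled core).
engine_advance <- function(engine, state, power, nsteps,
                           probes = NULL, record_plane = 0L,
                           dose_on = TRUE) {
  cfg <- engine$config
  model <- engine$model
  src_dT <- if (is.null(power)) NULL else cfg$dt * power * model$V / model$cap
  T_new <- state$T + 0         # force copy; modified in place by C++
  dose_new <- state$dose + 0
  if (cfg$scheme == "explicit") {
    out <- explicit_advance(engine, T_new, dose_new, src_dT, nsteps,
                            probes, record_plane, dose_on)
    T_new <- out$T
    dose_new <- out$dose
    aux <- out
  } else {
    aux <- bh_run_core(T_new, dose_new, engine$fac, src_dT,
                       as.integer(nsteps), cfg$dt,
                       list(dose_on = isTRUE(dose_on),
                            dose_cutoff = cfg$dose_cutoff,
                            t0 = state$time,
                            record_plane = as.integer(record_plane),
                            probe_idx = if (is.null(probes)) NULL else probes$idx,
                            probe_w = if (is.null(probes)) NULL else probes$w))
  }
  st <- state
  st$time <- state$time + nsteps * cfg$dt
  st$T <- T_new
  st$dose <- dose_new
  st$plane_hist <- aux$plane_hist
  st$probe_hist <- aux$probe_hist
  st
}

# Forward-Euler reference stepper built from the same finite-volume model
# arrays. Checks its stability bound and errors on violation.
explicit_advance <- function(engine, T_arr, dose, src_dT, nsteps,
                             probes = NULL, record_plane = 0L,
                             dose_on = TRUE) {
  model <- engine$model
  cfg <- engine$config
  dims <- model$dims
  dt <- cfg$dt
  Tc <- model$T_core

  shift <- function(x, a, by) {
    idx <- rep(list(quote(expr = )), 3)
    m <- dims[a]
    if (by == 1L) idx[[a]] <- c(2:m, m) else idx[[a]] <- c(1L, 1:(m - 1))
    array(do.call(`[`, c(list(x), idx, list(drop = FALSE))), dims)
  }
  edge_mask <- function(a, end) {
    e <- array(0, dims)
    idx <- rep(list(quote(expr = )), 3)
    idx[[a]] <- if (end == "lo") 1L else dims[a]
    do.call(`[<-`, c(list(e), idx, list(1)))
  }

  # stability: dt <= cap / (sum of all outgoing coefficients)
  coef_sum <- array(0, dims)
  for (a in 1:3) {
    if (is.null(model$G[[a]])) next
    Gm1 <- shift(model$G[[a]], a, -1L) * (1 - edge_mask(a, "lo"))
    coef_sum <- coef_sum + model$G[[a]] + Gm1
    if (!is.null(model$advlo[[a]]))
      coef_sum <- coef_sum + model$advlo[[a]] + model$advhi[[a]]
    bl <- edge_mask(a, "lo")
    bl[bl == 1] <- as.numeric(model$blo[[a]])
    bh <- edge_mask(a, "hi")
    bh[bh == 1] <- as.numeric(model$bhi[[a]])
    coef_sum <- coef_sum + bl + bh
  }
  dt_max <- min(model$cap / coef_sum)
  if (dt > dt_max)
    stop(sprintf("explicit scheme unstable: dt = %g s exceeds bound %.4g s",
                 dt, dt_max))

  np <- if (is.null(probes)) 0L else ncol(probes$idx)
  probe_hist <- if (np > 0) matrix(NA_real_, np, nsteps) else NULL
  plane_hist <- if (record_plane > 0)
    matrix(NA_real_, dims[1] * dims[2], nsteps) else NULL

  for (s in seq_len(nsteps)) {
    flux <- array(0, dims)
    for (a in 1:3) {
      if (is.null(model$G[[a]])) next
      lo <- edge_mask(a, "lo")
      hi <- edge_mask(a, "hi")
      Tp1 <- shift(T_arr, a, 1L)
      Tm1 <- shift(T_arr, a, -1L)
      flux <- flux + model$G[[a]] * (Tp1 - T_arr) * (1 - hi)
      Gm1 <- shift(model$G[[a]], a, -1L)
      flux <- flux + Gm1 * (Tm1 - T_arr) * (1 - lo)
      if (!is.null(model$advlo[[a]])) {
        ghost_lo <- Tm1 * (1 - lo) + Tc * lo
        ghost_hi <- Tp1 * (1 - hi) + Tc * hi
        flux <- flux + model$advlo[[a]] * (ghost_lo - T_arr) +
          model$advhi[[a]] * (ghost_hi - T_arr)
      }
      bl <- lo
      bl[lo == 1] <- as.numeric(model$blo[[a]])
      bh <- hi
      bh[hi == 1] <- as.numeric(model$bhi[[a]])
      flux <- flux + (bl + bh) * (Tc - T_arr)
    }
    T_arr <- T_arr + dt * flux / model$cap
    if (!is.null(src_dT)) T_arr <- T_arr + src_dT
    if (isTRUE(dose_on))
      dose <- dose + (dt / 60) * cem43_rate_r(T_arr)
    if (np > 0)
      for (p in seq_len(np))
        probe_hist[p, s] <- sum(probes$w[, p] * T_arr[probes$idx[, p]])
    if (record_plane > 0)
      plane_hist[, s] <- T_arr[, , record_plane]
  }
  list(T = T_arr, dose = dose, probe_hist = probe_hist,
       plane_hist = plane_hist)
}

#' Simulate a heating (or cooling) interval
#'
#' Advances the coupled tissue/vessel temperature field for `duration`
#' seconds under a fixed source, accumulating CEM43 dose throughout.
#'
#' @param fields a [rasterize()] field map
#' @param source a [fus_source()] object, a power-density array matching the
#'   grid (W/m^3), or NULL for zero power
#' @param duration simulated time (s)
#' @param config a [solver_config()]
#' @param state optional starting [thermal_state()] (default: fresh state)
#' @param probes optional matrix of probe points (n x 3, m; or n x 2 `(r, z)`
#'   on axisymmetric grids) whose temperature is recorded every step by
#'   trilinear interpolation
#' @param record_midplane record the transverse midplane temperature every
#'   step (needed by the treatment power controller)
#' @param dose accumulate thermal dose (default TRUE)
#' @param warn_focus warn when the source focus sits close to a boundary
#' @return a `bh_state` with fields `T`, `dose`, `time`, and (when requested)
#'   `probe_series` (data.frame: t, probe, T) and `plane_hist`
#' @export
simulate_heating <- function(fields, source, duration,
                             config = solver_config(), state = NULL,
                             probes = NULL, record_midplane = FALSE,
                             dose = TRUE, warn_focus = TRUE) {
  stopifnot(inherits(fields, "bh_fields"))
  if (duration <= 0) stop("duration must be > 0")
  engine <- bh_engine(fields, config)
  if (is.null(state)) state <- thermal_state(fields, config)
  power <- resolve_power(source, fields$grid, warn_focus)
  nsteps <- max(1L, as.integer(round(duration / config$dt)))
  if (abs(nsteps * config$dt - duration) > 1e-6 * max(1, duration))
    warning(sprintf("duration rounded to %d steps of dt = %g s",
                    nsteps, config$dt))
  pr <- if (is.null(probes)) NULL else probe_weights(fields$grid, probes)
  if (record_midplane && fields$grid$mode == "axisym")
    stop("record_midplane requires a full 3-D grid")
  k_mid <- if (record_midplane) midplane_index(fields$grid) else 0L
  out <- engine_advance(engine, state, power, nsteps, probes = pr,
                        record_plane = k_mid, dose_on = dose)
  if (!is.null(out$probe_hist)) {
    np <- nrow(out$probe_hist)
    out$probe_series <- data.frame(
      t = rep(state$time + seq_len(nsteps) * config$dt, each = np),
      probe = rep(seq_len(np), nsteps),
      T = as.numeric(out$probe_hist))
  }
  out
}

resolve_power <- function(source, grid, warn_focus = TRUE) {
  if (is.null(source)) return(NULL)
  if (inherits(source, "bh_source"))
    return(power_field(source, grid, warn = warn_focus))
  if (is.numeric(source)) {
    if (length(source) != prod(grid$dims))
      stop("power array does not match the grid")
    return(array(source, grid$dims))
  }
  stop("source must be a bh_source, a power array, or NULL")
}

# index along axis 3 (z) of the transverse midplane (axisym: along z = axis 2)
midplane_index <- function(grid) {
  a <- if (grid$mode == "axisym") 2L else 3L
  as.integer(ceiling(grid$dims[a] / 2))
}

# trilinear interpolation stencils for probe points
probe_weights <- function(grid, points) {
  nd <- if (grid$mode == "axisym") 2L else 3L
  points <- matrix(as.numeric(points), ncol = nd)
  dims <- grid$dims
  np <- nrow(points)
  idx <- matrix(1L, 8, np)
  w <- matrix(0, 8, np)
  for (p in seq_len(np)) {
    i0 <- integer(3)
    fr <- numeric(3)
    for (a in 1:3) {
      if (dims[a] == 1L) {
        i0[a] <- 1L
        fr[a] <- 0
        next
      }
      u <- points[p, a] / grid$h[a] - 0.5
      u <- min(max(u, 0), dims[a] - 1 - 1e-9)
      i0[a] <- as.integer(floor(u)) + 1L
      fr[a] <- u - floor(u)
    }
    c8 <- 1L
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      ii <- pmin(dims, i0 + c(dx, dy, dz))
      idx[c8, p] <- ii[1] + (ii[2] - 1L) * dims[1] +
        (ii[3] - 1L) * dims[1] * dims[2]
      w[c8, p] <- prod(ifelse(c(dx, dy, dz) == 1,
                              fr, 1 - fr)[seq_len(3)])
      c8 <- c8 + 1L
    }
  }
  list(idx = idx, w = w)
}
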