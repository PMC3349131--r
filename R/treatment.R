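#' Dose-capping power controller
#'
#' Emulates per-insonation feedback: before each event is committed, the
#' peak incremental CEM43 dose that the event would deposit on the midplane
#' is evaluated as a function of the event power P0, and P0 is adjusted until
#' that peak falls inside the target band (default 230-250 equivalent
#' minutes, just below the 240 eq-min necrosis threshold).
#'
#' @param band target band for the per-event peak incremental dose
#'   (equivalent minutes at 43 C)
#' @param max_iter iteration cap of the per-event search
#' @param p_range admissible P0 range (W/m^3)
#' @return an object of class `bh_controller`
#' @export
power_controller <- function(band = c(230, 250), max_iter = 8L,
                             p_range = c(1e5, 1e8)) {
  if (band[1] >= band[2]) stop("band must be (low, high) with low < high")
  structure(list(band = band, max_iter = max_iter, p_range = p_range),
            class = "bh_controller")
}

#' Adjust the event power to cap the peak incremental dose
#'
#' Secant search on log(dose) as a function of P0, exploiting the strict
#' monotonicity of thermal dose in deposited power. `dose_fn(p0)` must
#' return the peak incremental dose (equivalent minutes) the event would
#' deposit at power `p0`; during a treatment this is evaluated cheaply by
#' linear superposition of a zero-power and a reference-power simulation of
#' the event. If the iteration cap is reached the nearest power found is
#' accepted with a warning.
#'
#' @param ctrl a [power_controller()]
#' @param p0 current power (W/m^3); first trial
#' @param dose_fn function(p0) -> peak incremental dose (eq-min)
#' @return list with `p0` (accepted power), `dose` (its peak incremental
#'   dose), `iterations`, `converged`
#' @export
control_power <- function(ctrl, p0, dose_fn) {
  band <- ctrl$band
  target <- mean(band)
  clamp <- function(p) min(max(p, ctrl$p_range[1]), ctrl$p_range[2])
  p_a <- clamp(p0)
  d_a <- dose_fn(p_a)
  if (d_a >= band[1] && d_a <= band[2])
    return(list(p0 = p_a, dose = d_a, iterations = 0L, converged = TRUE))
  best <- list(p0 = p_a, dose = d_a)
  # second point: multiplicative nudge toward the band
  p_b <- clamp(if (d_a > target) p_a * 0.8 else p_a * 1.25)
  for (it in seq_len(ctrl$max_iter)) {
    d_b <- dose_fn(p_b)
    if (abs(d_b - target) < abs(best$dose - target))
      best <- list(p0 = p_b, dose = d_b)
    if (d_b >= band[1] && d_b <= band[2])
      return(list(p0 = p_b, dose = d_b, iterations = it, converged = TRUE))
    # secant on log-dose vs power (log dose is close to affine in P0)
    if (d_a <= 0 || d_b <= 0) {
      p_next <- clamp(p_b * if (max(d_a, d_b) < target) 2 else 0.5)
    } else {
      slope <- (log(d_b) - log(d_a)) / (p_b - p_a)
      p_next <- if (!is.finite(slope) || slope <= 0)
        clamp(p_b * if (d_b < target) 1.5 else 0.67)
      else clamp(p_b + (log(target) - log(d_b)) / slope)
    }
    p_a <- p_b
    d_a <- d_b
    p_b <- p_next
  }
  warning(sprintf(
    "power controller hit the iteration cap; accepting P0 = %.3g W/cm^3 (peak dose %.0f eq-min)",
    best$p0 / 1e6, best$dose))
  list(p0 = best$p0, dose = best$dose, iterations = ctrl$max_iter,
       converged = FALSE)
}

#' Execute a multi-insonation treatment
#'
#' Steps the focus through the plan's trajectory: each event deposits power
#' for `plan$on` seconds at its focus, followed by `plan$cool` seconds of
#' cooling (none after the last event). Thermal dose accumulates at every
#' solver step, including cooling periods. With a [power_controller()] the
#' event power is chosen per event by [control_power()]: the event is
#' pre-simulated once with zero power and once at a reference power from the
#' checkpointed state, the midplane temperature history for any P0 follows
#' by superposition (the governing equations are linear in the deposited
#' power), and the accepted P0 is then committed.
#'
#' @param fields a [rasterize()] field map (full 3-D grid)
#' @param plan a [sonication_plan()]
#' @param source_template a [fus_source()] supplying beam widths (its focus
#'   and p0 are overridden per event); default 3.2 mm / 24 mm half-power
#'   widths
#' @param config a [solver_config()]
#' @param controller optional [power_controller()] for variable-power
#'   delivery; NULL = fixed power
#' @param progress print per-event progress
#' @return an object of class `bh_treatment`: list with the final `state`
#'   (temperature + dose), `log` (one row per event: focus, P0, peak
#'   incremental midplane dose, peak midplane temperature at the end of the
#'   insonation), `plan`, `config`
#' @export
run_treatment <- function(fields, plan, source_template = NULL,
                          config = solver_config(dt = 0.25),
                          controller = NULL, progress = FALSE) {
  stopifnot(inherits(fields, "bh_fields"), inherits(plan, "bh_plan"))
  grid <- fields$grid
  if (grid$mode != "xyz") stop("treatments require a full 3-D grid")
  z_mid <- (midplane_index(grid) - 0.5) * grid$h[3]
  foci <- plan$foci
  if (ncol(foci) == 2L) foci <- cbind(foci, z_mid)
  if (any(foci < 0) || any(foci > matrix(grid$size, nrow(foci), 3,
                                         byrow = TRUE)))
    stop("plan foci fall outside the domain")
  if (is.null(source_template))
    source_template <- fus_source(plan$p0, 3.2e-3, 24e-3,
                                  focus = c(0, 0, z_mid))

  engine <- bh_engine(fields, config)
  state <- thermal_state(fields, config)
  k_mid <- midplane_index(grid)
  on_steps <- as.integer(round(plan$on / config$dt))
  cool_steps <- as.integer(round(plan$cool / config$dt))
  dtmin <- config$dt / 60
  n <- plan$n
  log <- data.frame(event = seq_len(n), x = foci[, 1], y = foci[, 2],
                    z = foci[, 3], p0 = NA_real_,
                    peak_inc_dose = NA_real_, peak_T_on = NA_real_,
                    peak_T_end = NA_real_, ctrl_iter = NA_integer_)
  p_cur <- plan$p0

  for (e in seq_len(n)) {
    src <- source_template
    src$focus <- foci[e, ]
    pw_unit <- power_field(with_p0(src, 1), grid, warn = FALSE)
    steps_e <- on_steps + if (e < n) cool_steps else 0L
    mid_before <- state$dose[, , k_mid]

    if (!is.null(controller)) {
      # event pre-simulation: zero-power decay + reference-power response,
      # both mirroring the event structure (power on, then cooling)
      dec <- engine_advance(engine, state, NULL, steps_e,
                            record_plane = k_mid, dose_on = FALSE)
      p_ref <- p_cur
      ref_on <- engine_advance(engine, state, p_ref * pw_unit, on_steps,
                               record_plane = k_mid, dose_on = FALSE)
      ref_hist <- ref_on$plane_hist
      if (steps_e > on_steps) {
        ref_cool <- engine_advance(engine, ref_on, NULL, steps_e - on_steps,
                                   record_plane = k_mid, dose_on = FALSE)
        ref_hist <- cbind(ref_hist, ref_cool$plane_hist)
      }
      D_hist <- dec$plane_hist
      S_hist <- (ref_hist - D_hist) / p_ref
      # only nodes that could plausibly accrue dose matter for the peak
      hot <- which(apply(D_hist + controller$p_range[2] * S_hist, 1, max) > 40)
      if (!length(hot)) hot <- seq_len(nrow(D_hist))
      Dh <- D_hist[hot, , drop = FALSE]
      Sh <- S_hist[hot, , drop = FALSE]
      dose_fn <- function(p) {
        max(rowSums(dtmin * cem43_rate_r(Dh + p * Sh)))
      }
      res <- control_power(controller, p_cur, dose_fn)
      p_cur <- res$p0
      log$ctrl_iter[e] <- res$iterations
    }

    st_on <- engine_advance(engine, state, p_cur * pw_unit, on_steps)
    log$peak_T_on[e] <- max(st_on$T[, , k_mid])
    state <- if (e < n && cool_steps > 0L)
      engine_advance(engine, st_on, NULL, cool_steps) else st_on
    log$p0[e] <- p_cur
    log$peak_inc_dose[e] <- max(state$dose[, , k_mid] - mid_before)
    log$peak_T_end[e] <- max(state$T[, , k_mid])
    if (progress)
      message(sprintf(
        "event %2d/%d  t=%6.0f s  P0=%5.1f W/cm^3  peak dT=%5.2f C  peak inc dose=%6.0f eq-min",
        e, n, state$time, p_cur / 1e6, log$peak_T_on[e] - 37,
        log$peak_inc_dose[e]))
  }

  structure(list(state = state, log = log, plan = plan, config = config,
                 grid = grid),
            class = "bh_treatment")
}

with_p0 <- function(src, p0) {
  src$p0 <- p0
  src
}

#' @export
print.bh_treatment <- function(x, ...) {
  nd <- normalize_dose(midplane(x$state$dose))
  cat(sprintf("<bh_treatment> %s, %d events, %.0f s simulated\n",
              x$plan$kind, x$plan$n, x$state$time))
  cat(sprintf("  midplane normalized dose: peak %.2f\n", max(nd)))
  cat(sprintf("  mean P0 %.1f W/cm^3\n", mean(x$log$p0) / 1e6))
  invisible(x)
}
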