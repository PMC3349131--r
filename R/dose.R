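#' CEM43 thermal dose
#'
#' Thermal dose is measured in cumulative equivalent minutes at the reference
#' temperature of 43 degrees C (Sapareto-Dewey):
#' `TD(t) = integral R^(43 - T(t')) dt'` with the isodose constant
#' `R = 0.5` for `T >= 43` and `R = 0.25` below. Doses are normalized
#' against the 240 equivalent-minute threshold commonly taken as 100%
#' necrosis in muscle, so a normalized dose of 1 marks the necrosis boundary.
#'
#' `cem43_rate_r` returns the instantaneous dose rate `R^(43 - T)` in
#' equivalent minutes per minute.
#'
#' @param T temperature (degrees C), any shape
#' @return dose rate, same shape as `T`
#' @export
cem43_rate_r <- function(T) {
  e <- T - 43
  2^(ifelse(T >= 43, e, 2 * e))
}

#' Accumulate thermal dose over one interval
#'
#' Rectangle-rule quadrature on the supplied (end-of-step) temperature,
#' matching the solver cadence: `dose + dt/60 * R^(43 - T)`.
#'
#' @param dose accumulated dose (equivalent minutes at 43 C), same shape as T
#' @param T temperature field (degrees C)
#' @param dt interval length (s)
#' @return updated dose
#' @export
#' @examples
#' accumulate_dose(0, 43, 240 * 60)  # 240 eq-min
accumulate_dose <- function(dose, T, dt) {
  if (dt <= 0) stop("dt must be > 0")
  dose + (dt / 60) * cem43_rate_r(T)
}

#' Normalize a dose field by the necrosis threshold
#'
#' @param dose dose in equivalent minutes at 43 C
#' @param threshold_min threshold in equivalent minutes (default 240)
#' @return dimensionless normalized dose (1 = necrosis threshold)
#' @export
normalize_dose <- function(dose, threshold_min = 240) dose / threshold_min

#' Extract the transverse midplane of a field
#'
#' The midplane is the x-y plane at the central z index — the plane through
#' which treatment foci are stepped and on which dose statistics are
#' reported.
#'
#' @param x 3-D array on a `bh_grid`
#' @param grid the grid (optional; defaults to central index of dim 3)
#' @return 2-D matrix
#' @export
midplane <- function(x, grid = NULL) {
  k <- if (is.null(grid)) ceiling(dim(x)[3] / 2) else midplane_index(grid)
  x[, , k]
}
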