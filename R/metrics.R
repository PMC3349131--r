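#' Summary statistics of a midplane dose field
#'
#' Reports the peak normalized dose over the whole midplane and the mean and
#' standard deviation over the voxels whose normalized dose exceeds
#' `threshold`. The mask excludes the cool regions inside the vessel lumens
#' (and anything else essentially untreated) so the statistics describe the
#' treated tissue.
#'
#' @param dose_mid midplane normalized dose (matrix or vector)
#' @param threshold mask threshold in normalized dose units (default 0.3)
#' @param sd_type `"population"` (divide by n, default) or `"sample"`
#' @return list of class `bh_dose_stats`: `peak`, `mean`, `sd`, `n_mask`,
#'   `threshold`. With an empty mask, `mean` and `sd` are NA and
#'   `empty_mask` is TRUE.
#' @export
#' @examples
#' dose_stats(c(0.1, 0.4, 0.8))  # mask {0.4, 0.8}: mean 0.6, sd 0.2
dose_stats <- function(dose_mid, threshold = 0.3,
                       sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  x <- as.numeric(dose_mid)
  if (any(!is.finite(x))) stop("dose field contains non-finite values")
  mask <- x > threshold
  out <- list(peak = max(x), threshold = threshold, n_mask = sum(mask),
              empty_mask = !any(mask))
  if (out$empty_mask) {
    warning("no voxels above the dose threshold; masked statistics undefined")
    out$mean <- NA_real_
    out$sd <- NA_real_
  } else {
    xm <- x[mask]
    out$mean <- mean(xm)
    v <- sum((xm - out$mean)^2) /
      if (sd_type == "population") length(xm) else max(1, length(xm) - 1)
    out$sd <- sqrt(v)
  }
  structure(out, class = "bh_dose_stats")
}

#' @export
print.bh_dose_stats <- function(x, ...) {
  cat(sprintf("<bh_dose_stats> peak %.3g; mask >%.2g: n=%d, mean %.3g, sd %.3g\n",
              x$peak, x$threshold, x$n_mask, x$mean, x$sd))
  invisible(x)
}

#' Peak temperature-rise reduction caused by vessels
#'
#' Compares two runs that share grid, source and duration — one with vessels
#' and one without — and reports, for each requested plane, the percentage
#' by which the vessels reduce the plane-wise peak temperature rise:
#' `100 * (dT_novessel - dT_vessel) / dT_novessel`, where the rise is the
#' plane maximum of `T - T_core`.
#'
#' @param state_vessel final `bh_state` of the run with vessels
#' @param state_novessel final `bh_state` of the matched no-vessel run
#' @param grid the shared [sim_grid()]
#' @param focal_z axial position of the focal plane (m)
#' @param offsets axial offsets of the planes to evaluate (m); default the
#'   focal plane itself
#' @param T_core baseline temperature (degrees C)
#' @return numeric vector of percent reductions, one per offset
#' @export
peak_reduction <- function(state_vessel, state_novessel, grid, focal_z,
                           offsets = 0, T_core = 37) {
  stopifnot(identical(dim(state_vessel$T), dim(state_novessel$T)))
  z_axis <- if (grid$mode == "axisym") 2L else 3L
  vapply(offsets, function(off) {
    k <- grid_index(grid, focal_z + off, z_axis)
    pl_v <- if (z_axis == 3L) state_vessel$T[, , k] else state_vessel$T[, k, 1]
    pl_n <- if (z_axis == 3L) state_novessel$T[, , k] else
      state_novessel$T[, k, 1]
    rise_n <- max(pl_n) - T_core
    if (rise_n <= 0) stop("no-vessel baseline shows no temperature rise")
    100 * (rise_n - (max(pl_v) - T_core)) / rise_n
  }, numeric(1))
}
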