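#' Define a focused-ultrasound power-deposition source
#'
#' The deposited power density is modelled as a separable Gaussian around the
#' focus: `P(u) = P0 * prod_u exp(-ln(2) * u^2 / R_u^2)` with beam-frame
#' coordinates u and half-power radii `R_u`. The "half-power width/height"
#' parameters are interpreted as FULL widths at half power, so
#' `R_x = R_y = fwhm_transverse / 2` and `R_z = fwhm_axial / 2`; with this
#' reading the deposited power falls to `P0/2` exactly one half-width from
#' the focus.
#'
#' @param p0 peak power density at the focus
#' @param fwhm_transverse full transverse width at half power (m)
#' @param fwhm_axial full axial length at half power (m)
#' @param focus focus position (m, domain coordinates); length 3, or 2 for
#'   axisymmetric use (r must be 0 on the axis; give `c(0, z)`)
#' @param beam_axis beam propagation direction (default -z, i.e. the beam
#'   enters from the high-z face); only its line matters for the symmetric
#'   Gaussian
#' @param units units of `p0`: `"W/m3"` (default) or `"W/cm3"`
#'   (converted by 1e6)
#' @return an object of class `bh_source`
#' @export
#' @examples
#' fus_source(15, 4e-3, 30e-3, focus = c(30, 30, 100) * 1e-3, units = "W/cm3")
fus_source <- function(p0, fwhm_transverse, fwhm_axial, focus,
                       beam_axis = c(0, 0, -1), units = c("W/m3", "W/cm3")) {
  units <- match.arg(units)
  if (units == "W/cm3") p0 <- p0 * 1e6
  if (p0 < 0) stop("p0 must be >= 0")
  if (fwhm_transverse <= 0 || fwhm_axial <= 0) stop("widths must be > 0")
  nrm <- sqrt(sum(beam_axis^2))
  if (nrm == 0) stop("beam_axis must be non-zero")
  structure(list(p0 = p0,
                 R_t = fwhm_transverse / 2, R_a = fwhm_axial / 2,
                 focus = as.numeric(focus),
                 beam_axis = as.numeric(beam_axis) / nrm),
            class = "bh_source")
}

#' Evaluate the source power density at arbitrary points
#'
#' @param src a [fus_source()]
#' @param points numeric matrix (n x 3) of positions (m)
#' @return numeric vector of power densities (W/m^3)
#' @export
power_at <- function(src, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  d <- sweep(points, 2, src$focus[1:3])
  ua <- d %*% src$beam_axis
  t2 <- pmax(0, rowSums(d^2) - ua^2)
  as.numeric(src$p0 * exp(-log(2) * (t2 / src$R_t^2 + ua^2 / src$R_a^2)))
}

#' Rasterize the source power field onto a grid
#'
#' For a beam along z (the usual case) the separable form is evaluated as an
#' outer product of the three one-dimensional Gaussians; an arbitrarily
#' oriented beam falls back to pointwise evaluation. On an axisymmetric grid
#' the focus must lie on the axis.
#'
#' @param src a [fus_source()]
#' @param grid a [sim_grid()]
#' @param warn warn when the focus is within `2 R_u` of a domain boundary
#' @return array of power densities (W/m^3) with the grid's dimensions
#' @export
power_field <- function(src, grid, warn = TRUE) {
  stopifnot(inherits(src, "bh_source"), inherits(grid, "bh_grid"))
  ax <- grid_axes(grid)
  l2 <- log(2)
  if (grid$mode == "axisym") {
    fz <- src$focus[length(src$focus)]
    if (warn && (fz < 2 * src$R_a || fz > grid$size[2] - 2 * src$R_a))
      warning("focus is within 2*R_u of an axial boundary")
    ar <- exp(-l2 * ax[[1]]^2 / src$R_t^2)
    az <- exp(-l2 * (ax[[2]] - fz)^2 / src$R_a^2)
    return(array(src$p0 * outer(ar, az), grid$dims))
  }
  if (warn) {
    m <- c(src$R_t, src$R_t, src$R_a) * 2
    if (any(src$focus < m) || any(src$focus > grid$size - m))
      warning("focus is within 2*R_u of a domain boundary")
  }
  if (abs(abs(src$beam_axis[3]) - 1) < 1e-12) {
    a1 <- exp(-l2 * (ax[[1]] - src$focus[1])^2 / src$R_t^2)
    a2 <- exp(-l2 * (ax[[2]] - src$focus[2])^2 / src$R_t^2)
    a3 <- exp(-l2 * (ax[[3]] - src$focus[3])^2 / src$R_a^2)
    return(array(src$p0 * outer(a1, outer(a2, a3)), grid$dims))
  }
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  array(power_at(src, pts), grid$dims)
}
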