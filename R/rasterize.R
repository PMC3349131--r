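#' Rasterize a scenario onto a grid
#'
#' Builds the discrete field map: per-node vessel membership and the axial
#' blood-velocity field. A node belongs to a lumen when its centre lies
#' within distance R of the vessel axis (and within the axis segment); its
#' velocity is the parabolic profile
#' `w = flow_sign * 2 * v_mean * (1 - r^2/R^2)` evaluated at the node's
#' perpendicular distance r, directed along the vessel axis. Velocity is
#' zero in tissue.
#'
#' A vessel narrower than one cell across its radius cannot be represented
#' and raises an error (or, with `allow_unresolved = TRUE`, drops out of the
#' discrete model, which is the correct vanishing-vessel limit). Fewer than
#' two nodes across the radius triggers a warning.
#'
#' @param scenario a [make_scenario()] / [preset_scenario()] object
#' @param grid a [sim_grid()] object
#' @param allow_unresolved keep going (without lumen nodes) when a vessel is
#'   below one node across its radius
#' @return an object of class `bh_fields`: list with `grid`, `scenario`,
#'   `vessel_id` (integer array, 0 = tissue), and velocity component arrays
#'   `w1`, `w2`, `w3` (NULL when identically zero; for axisymmetric grids
#'   the axial component is `w2`, along z)
#' @export
rasterize <- function(scenario, grid, allow_unresolved = FALSE) {
  stopifnot(inherits(scenario, "bh_scenario"), inherits(grid, "bh_grid"))
  dims <- grid$dims
  ax <- grid_axes(grid)
  n <- prod(dims)
  vessel_id <- array(0L, dims)
  w <- vector("list", 3L)

  hmin <- min(grid$h[grid$h < 1])
  for (v in scenario$vessels) {
    if (v$radius / hmin < 1) {
      msg <- sprintf(
        "vessel R=%.3g mm unresolved at spacing %.3g mm (<1 node across radius)",
        v$radius * 1e3, hmin * 1e3)
      if (!allow_unresolved) stop(msg)
    } else if (v$radius / hmin < 2) {
      warning(sprintf(
        "vessel R=%.3g mm marginally resolved at spacing %.3g mm (<2 nodes across radius)",
        v$radius * 1e3, hmin * 1e3))
    }
  }

  if (grid$mode == "axisym") {
    if (length(scenario$vessels) > 1L)
      stop("axisymmetric mode supports at most one vessel")
    for (v in scenario$vessels) {
      if (abs(abs(v$direction[3]) - 1) > 1e-9)
        stop("axisymmetric mode requires the vessel to be coaxial with z")
      r <- ax[[1]]
      z <- ax[[2]]
      inr <- r <= v$radius
      z0 <- v$origin[3]
      inz <- abs(z - z0) <= v$length / 2 + 1e-12
      lum <- outer(inr, inz, `&`)
      if (any(lum)) {
        vessel_id <- array(as.integer(lum), dims)
        prof <- v$flow_sign * v$direction[3] * 2 * v$v_mean *
          (1 - (r / v$radius)^2)
        prof[!inr] <- 0
        wz <- array(outer(prof, as.numeric(inz)), dims)
        w[[2]] <- if (is.null(w[[2]])) wz else w[[2]] + wz
      }
    }
  } else {
    X <- array(ax[[1]], dims)
    Y <- array(rep(ax[[2]], each = dims[1]), dims)
    Z <- array(rep(ax[[3]], each = dims[1] * dims[2]), dims)
    for (k in seq_along(scenario$vessels)) {
      v <- scenario$vessels[[k]]
      dx <- X - v$origin[1]; dy <- Y - v$origin[2]; dz <- Z - v$origin[3]
      t_ax <- dx * v$direction[1] + dy * v$direction[2] + dz * v$direction[3]
      r2 <- pmax(0, dx^2 + dy^2 + dz^2 - t_ax^2)
      lum <- r2 <= v$radius^2 & abs(t_ax) <= v$length / 2 + 1e-12
      if (!any(lum)) next
      if (any(vessel_id[lum] != 0L))
        stop("vessel lumens overlap on the grid")
      vessel_id[lum] <- k
      wmag <- v$flow_sign * 2 * v$v_mean * (1 - r2 / v$radius^2)
      for (a in 1:3) {
        if (abs(v$direction[a]) < 1e-12) next
        wa <- array(0, dims)
        wa[lum] <- wmag[lum] * v$direction[a]
        w[[a]] <- if (is.null(w[[a]])) wa else w[[a]] + wa
      }
    }
  }

  structure(list(grid = grid, scenario = scenario, vessel_id = vessel_id,
                 w1 = w[[1]], w2 = w[[2]], w3 = w[[3]]),
            class = "bh_fields")
}

#' @export
print.bh_fields <- function(x, ...) {
  nl <- sum(x$vessel_id > 0L)
  cat(sprintf("<bh_fields> %s grid %s, %d lumen nodes (%.2f%%)\n",
              x$grid$mode, paste(x$grid$dims, collapse = "x"),
              nl, 100 * nl / prod(x$grid$dims)))
  invisible(x)
}
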