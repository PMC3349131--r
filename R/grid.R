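#' Define a computational grid
#'
#' Cell-centred finite-volume grid. Two modes:
#' * `"xyz"`: full 3-D Cartesian grid over a `size[1] x size[2] x size[3]`
#'   block; x and y are transverse, z is the beam axis.
#' * `"axisym"`: axisymmetric (r, z) grid for configurations in which all
#'   vessels are coaxial with z and the focus is on the axis; `size` is
#'   `(r_max, z_length)`. No node sits at r = 0: the first cell centre is at
#'   dr/2, and the zero-area inner face enforces the symmetry condition.
#'
#' The requested spacing is rounded so that an integer number of cells tiles
#' the domain exactly.
#'
#' @param spacing target cell size (m); scalar or per-axis
#' @param size domain extents (m): length 3 for `"xyz"`, length 2 for
#'   `"axisym"`
#' @param mode `"xyz"` or `"axisym"`
#' @return an object of class `bh_grid`
#' @export
#' @examples
#' sim_grid(0.5e-3, c(60, 60, 40) * 1e-3)
sim_grid <- function(spacing, size, mode = c("xyz", "axisym")) {
  mode <- match.arg(mode)
  nd <- if (mode == "xyz") 3L else 2L
  size <- as.numeric(size)
  if (length(size) != nd) stop(sprintf("size must have length %d", nd))
  if (length(spacing) == 1L) spacing <- rep(spacing, nd)
  if (any(spacing <= 0) || any(size <= 0)) stop("spacing and size must be > 0")
  n <- pmax(1L, as.integer(round(size / spacing)))
  h <- size / n
  if (mode == "xyz") {
    dims <- n
  } else {
    dims <- c(n, 1L)
    h <- c(h, 1)
    size <- c(size, 1)
  }
  structure(list(mode = mode, dims = dims, h = h, size = size),
            class = "bh_grid")
}

#' Cell-centre coordinates of a grid
#'
#' @param grid a `bh_grid`
#' @return list of coordinate vectors, one per axis (for `"axisym"`: r then z)
#' @export
grid_axes <- function(grid) {
  lapply(seq_along(grid$dims), function(a) {
    (seq_len(grid$dims[a]) - 0.5) * grid$h[a]
  })
}

#' @export
print.bh_grid <- function(x, ...) {
  cat(sprintf("<bh_grid> mode=%s dims=%s spacing=%s mm (%d cells)\n",
              x$mode, paste(x$dims, collapse = "x"),
              paste(signif(x$h[x$h < 1] * 1e3, 3), collapse = "/"),
              prod(x$dims)))
  invisible(x)
}

# nearest cell index of a physical coordinate along axis a
grid_index <- function(grid, coord, a) {
  pmin(grid$dims[a], pmax(1L, as.integer(round(coord / grid$h[a] + 0.5))))
}
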