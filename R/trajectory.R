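#' Generate a sonication trajectory
#'
#' Builds the ordered list of focus positions through which a treatment
#' steps. Three kinds are supported, all in the transverse midplane:
#'
#' * `"sequential"`: a row-major raster over an `ncol x nrow` rectangular
#'   grid of pitch `pitch`, starting from the top-left point (highest y,
#'   lowest x) and sweeping each row left to right, top to bottom.
#' * `"random"`: a seeded random ordering of the same grid points under the
#'   constraint that consecutive foci are at least `min_sep` apart
#'   (thermal-buildup avoidance). Sampled greedily (uniform among the
#'   admissible unvisited points); if the greedy walk dead-ends the whole
#'   sequence is rejected and resampled, up to `max_retries` times.
#' * `"spiral"`: an outward Archimedean spiral from the centre with `pitch`
#'   between successive turns and `pitch` arc-length between successive
#'   points; the first focus is the centre itself.
#'
#' For `n_points = 56` and the default 2 mm pitch the raster grid is
#' 8 columns x 7 rows (14 x 12 mm footprint).
#'
#' @param kind trajectory kind
#' @param pitch point spacing (m)
#' @param n_points number of insonation points
#' @param seed RNG seed (random kind only; required there)
#' @param centre midplane centre (x, y) the pattern is centred on (m)
#' @param min_sep minimum distance between consecutive random foci (m)
#' @param max_retries random-kind rejection budget
#' @return an `n_points x 2` matrix of (x, y) focus positions (m)
#' @export
make_trajectory <- function(kind = c("sequential", "random", "spiral"),
                            pitch = 2e-3, n_points = 56L, seed = NULL,
                            centre = c(0, 0), min_sep = 8e-3,
                            max_retries = 10000L) {
  kind <- match.arg(kind)
  if (n_points < 1L) stop("n_points must be >= 1")

  if (kind == "spiral") {
    b <- pitch / (2 * pi)
    th <- 0
    r <- 0
    pts <- matrix(0, n_points, 2)
    for (i in seq_len(n_points)[-1]) {
      th <- th + pitch / sqrt(b^2 + r^2)
      r <- b * th
      pts[i, ] <- r * c(cos(th), sin(th))
    }
    return(sweep(pts, 2, centre, "+"))
  }

  # rectangular raster grid shared by sequential and random kinds
  ncols <- as.integer(ceiling(sqrt(n_points)))
  nrows <- as.integer(ceiling(n_points / ncols))
  xs <- (seq_len(ncols) - (ncols + 1) / 2) * pitch
  ys <- (seq_len(nrows) - (nrows + 1) / 2) * pitch
  # row-major from the top-left: highest y first, x increasing within a row
  pts <- cbind(rep(xs, times = nrows),
               rep(rev(ys), each = ncols))[seq_len(n_points), , drop = FALSE]
  pts <- sweep(pts, 2, centre, "+")
  if (kind == "sequential") return(pts)

  if (is.null(seed)) stop("random trajectories require a seed")
  with_local_seed(seed, {
    d2 <- as.matrix(stats::dist(pts))^2
    ok <- d2 >= min_sep^2 - 1e-18
    for (try in seq_len(max_retries)) {
      ord <- integer(n_points)
      ord[1] <- sample.int(n_points, 1L)
      free <- rep(TRUE, n_points)
      free[ord[1]] <- FALSE
      stuck <- FALSE
      for (i in seq_len(n_points)[-1]) {
        cand <- which(free & ok[ord[i - 1L], ])
        if (!length(cand)) {
          stuck <- TRUE
          break
        }
        ord[i] <- if (length(cand) == 1L) cand else sample(cand, 1L)
        free[ord[i]] <- FALSE
      }
      if (!stuck) return(pts[ord, , drop = FALSE])
    }
    stop("could not satisfy the minimum-separation constraint; ",
         "increase max_retries or relax min_sep")
  })
}

#' Assemble a sonication plan
#'
#' An ordered schedule of insonation events: each event switches the source
#' on at one focus for `on` seconds, followed by `cool` seconds of cooling.
#' No cooling period follows the final event, so the total simulated time is
#' `n*on + (n-1)*cool` (1395 s for the default 56 x 20 s + 5 s schedule).
#'
#' @param foci matrix of focus positions: n x 2 (midplane x, y) or n x 3
#' @param on insonation duration (s)
#' @param cool cooling duration between insonations (s)
#' @param p0 peak power density (W/m^3) applied to every event (the starting
#'   power when a controller is used)
#' @param kind trajectory kind label
#' @param seed seed used to generate `foci` (bookkeeping)
#' @return an object of class `bh_plan`
#' @export
sonication_plan <- function(foci, on = 20, cool = 5, p0 = 16.5e6,
                            kind = "custom", seed = NULL) {
  foci <- as.matrix(foci)
  if (!ncol(foci) %in% 2:3) stop("foci must be an n x 2 or n x 3 matrix")
  if (on <= 0 || cool < 0) stop("on must be > 0 and cool >= 0")
  if (p0 <= 0) stop("p0 must be > 0")
  n <- nrow(foci)
  structure(list(foci = foci, on = on, cool = cool, p0 = p0,
                 kind = kind, seed = seed, n = n,
                 total_time = n * on + (n - 1) * cool),
            class = "bh_plan")
}

#' @export
print.bh_plan <- function(x, ...) {
  cat(sprintf("<bh_plan> %s: %d events, %g s on / %g s cool, total %g s, P0 = %.3g W/cm^3\n",
              x$kind, x$n, x$on, x$cool, x$total_time, x$p0 / 1e6))
  invisible(x)
}
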