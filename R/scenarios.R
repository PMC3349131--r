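#' Specify a straight blood vessel
#'
#' A vessel is a straight cylindrical lumen of radius `radius` and length
#' `length`, centred at `origin` and aligned with the unit vector
#' `direction`. Blood moves along `flow_sign * direction` with a parabolic
#' (Poiseuille) profile, `w(r) = 2 * v_mean * (1 - r^2/R^2)`, so the axial
#' velocity peaks at `2 * v_mean` on the axis and vanishes at the wall.
#'
#' @param radius lumen radius R (m)
#' @param length lumen length L (m)
#' @param v_mean mean axial velocity V_m (m/s), >= 0
#' @param origin centre of the vessel axis segment (m, domain coordinates)
#' @param direction axis direction (normalized internally)
#' @param flow_sign +1 for flow along `direction`, -1 for the reverse
#' @return an object of class `bh_vessel`
#' @export
vessel_spec <- function(radius, length, v_mean, origin,
                        direction = c(0, 0, 1), flow_sign = 1L) {
  if (radius <= 0) stop("vessel radius must be > 0")
  if (length <= 0) stop("vessel length must be > 0")
  if (v_mean < 0) stop("v_mean must be >= 0")
  if (!flow_sign %in% c(-1, 1)) stop("flow_sign must be +1 or -1")
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must be a non-zero vector")
  structure(list(radius = radius, length = length, v_mean = v_mean,
                 origin = as.numeric(origin),
                 direction = as.numeric(direction) / nrm,
                 flow_sign = as.integer(flow_sign)),
            class = "bh_vessel")
}

#' Assemble a simulation scenario
#'
#' A scenario is a rectangular tissue block with given materials, a set of
#' straight vessels, and the thickness `d` of the virtual tissue layer that
#' couples the block faces to the body core through the Robin coefficient
#' `h = k_eff / d`.
#'
#' @param domain_size block dimensions (m), length-3 vector
#' @param vessels list of [vessel_spec()] objects (may be empty)
#' @param materials a [material_properties()] object
#' @param d boundary tissue thickness (m) for `h = k_eff/d`
#' @param focus suggested focus position (m); defaults to the block centre
#' @param label free-text label
#' @return an object of class `bh_scenario`
#' @export
make_scenario <- function(domain_size, vessels = list(),
                          materials = material_properties(),
                          d = 0.02, focus = NULL, label = "") {
  domain_size <- as.numeric(domain_size)
  if (length(domain_size) != 3L || any(domain_size <= 0))
    stop("domain_size must be three positive lengths (m)")
  if (d <= 0) stop("boundary thickness d must be > 0")
  if (inherits(vessels, "bh_vessel")) vessels <- list(vessels)
  for (v in vessels) {
    if (!inherits(v, "bh_vessel")) stop("vessels must be bh_vessel objects")
    check_vessel_inside(v, domain_size)
  }
  if (is.null(focus)) focus <- domain_size / 2
  structure(list(domain_size = domain_size, materials = materials,
                 vessels = vessels, d = d, focus = as.numeric(focus),
                 label = label),
            class = "bh_scenario")
}

# Lateral containment: the lumen may only touch the outer faces that its axis
# crosses (inlet/outlet); elsewhere it must stay inside by its perpendicular
# footprint R * sqrt(1 - dir_a^2) along each coordinate axis.
check_vessel_inside <- function(v, domain_size, n_check = 101L) {
  tt <- seq(-v$length / 2, v$length / 2, length.out = n_check)
  for (a in 1:3) {
    half_width <- v$radius * sqrt(max(0, 1 - v$direction[a]^2))
    if (half_width < 1e-12) next  # axis parallel to this coordinate: end faces
    pa <- v$origin[a] + tt * v$direction[a]
    inside <- v$origin[1] + tt * v$direction[1] >= -1e-9 &
      v$origin[1] + tt * v$direction[1] <= domain_size[1] + 1e-9 &
      v$origin[2] + tt * v$direction[2] >= -1e-9 &
      v$origin[2] + tt * v$direction[2] <= domain_size[2] + 1e-9 &
      v$origin[3] + tt * v$direction[3] >= -1e-9 &
      v$origin[3] + tt * v$direction[3] <= domain_size[3] + 1e-9
    bad <- inside & (pa < half_width - 1e-9 |
                       pa > domain_size[a] - half_width + 1e-9)
    if (any(bad))
      stop(sprintf("vessel lumen extends outside the domain along axis %d", a))
  }
  invisible(TRUE)
}

#' Vessel-pair layout of the multi-pair scenario
#'
#' The multi-pair block carries 3 artery-vein pairs of radius 0.5 mm
#' (wall-to-wall gap 0.8 mm) and 6 pairs of radius 0.4 mm (gap 0.6 mm), all
#' running axially (along z). Published descriptions of such blocks leave the
#' in-plane pair positions open, so this fixed, versioned layout is the
#' package's own reproducible choice: the large pairs sit on the midline and
#' the small pairs are interleaved around them. Offsets are relative to the
#' block centre; each pair is split along y (artery at -sep/2 with flow +z,
#' vein at +sep/2 with flow -z).
#'
#' @return data.frame with columns `radius` (m), `x_off`, `y_off` (m),
#'   `sep` (centre-to-centre separation, m)
#' @export
multipair_layout <- function() {
  mm <- 1e-3
  data.frame(
    radius = c(rep(0.5 * mm, 3), rep(0.4 * mm, 6)),
    x_off  = c(-6, 0, 6, -9, -3, 3, 9, -6, 6) * mm,
    y_off  = c(0, 0, 0, 4, -4, 4, -4, -4, 4) * mm,
    sep    = c(rep(1.8 * mm, 3), rep(1.4 * mm, 6))
  )
}

#' Build one of the canonical study scenarios
#'
#' Presets cover the configurations explored in the package's analyses:
#' single straight arteries of three calibres targeted on-axis, an off-axis
#' or angled variant of the large artery, a counterflow artery-vein pair,
#' and a multi-pair block for treatment simulations.
#'
#' * `"large_artery"`: R = 1.5 mm, L = 200 mm, V_m = 13 cm/s, coaxial with z.
#' * `"primary_artery"`: R = 0.5 mm, L = 100 mm, V_m = 8 cm/s.
#' * `"secondary_artery"`: R = 0.3 mm, L = 40 mm, V_m = 8 cm/s.
#' * `"offaxis_or_angled"`: the large artery in a 60 x 60 x 40 mm^3 block;
#'   `focus_offset` moves the suggested focus off the wall (wall distance, m),
#'   `angle` tilts the vessel in the x-z plane (degrees; 90 = transverse).
#' * `"counterflow_pair"`: two large-artery vessels 1 mm either side of the
#'   central focus, antiparallel flow, in a 60 x 60 x 40 mm^3 block.
#' * `"multi_pair"`: 21 x 21 x 26 mm^3 block with the [multipair_layout()]
#'   pairs (18 vessels).
#'
#' Arterial flow runs along +z; the ultrasound beam propagates along -z, so
#' on-axis arterial flow opposes the beam.
#'
#' @param name preset name (see Details)
#' @param v_mean optional mean-velocity override (m/s; applied to all vessels)
#' @param pair_gap optional wall-to-wall gap override for pair presets (m)
#' @param angle vessel tilt in degrees for `"offaxis_or_angled"`
#' @param focus_offset focus-to-wall distance (m) for `"offaxis_or_angled"`;
#'   0 keeps the focus at the vessel centre
#' @param d boundary tissue thickness (m)
#' @param materials a [material_properties()] object
#' @return a `bh_scenario`
#' @export
#' @examples
#' preset_scenario("secondary_artery")
preset_scenario <- function(name = c("large_artery", "primary_artery",
                                     "secondary_artery", "offaxis_or_angled",
                                     "counterflow_pair", "multi_pair"),
                            v_mean = NULL, pair_gap = NULL, angle = 0,
                            focus_offset = 0, d = 0.02,
                            materials = material_properties()) {
  name <- match.arg(name)
  mm <- 1e-3
  vm_or <- function(default) if (is.null(v_mean)) default else v_mean

  if (name %in% c("large_artery", "primary_artery", "secondary_artery")) {
    par <- switch(name,
      large_artery     = list(R = 1.5 * mm, L = 200 * mm, Vm = vm_or(0.13)),
      primary_artery   = list(R = 0.5 * mm, L = 100 * mm, Vm = vm_or(0.08)),
      secondary_artery = list(R = 0.3 * mm, L = 40 * mm,  Vm = vm_or(0.08)))
    size <- c(60 * mm, 60 * mm, par$L)
    ves <- vessel_spec(par$R, par$L, par$Vm, origin = size / 2,
                       direction = c(0, 0, 1), flow_sign = 1L)
    return(make_scenario(size, list(ves), materials, d = d, label = name))
  }

  if (name == "offaxis_or_angled") {
    size <- c(60, 60, 40) * mm
    th <- angle * pi / 180
    dir <- c(sin(th), 0, cos(th))
    ves <- vessel_spec(1.5 * mm, 200 * mm, vm_or(0.13), origin = size / 2,
                       direction = dir, flow_sign = 1L)
    focus <- size / 2
    if (focus_offset > 0) focus[1] <- focus[1] + 1.5 * mm + focus_offset
    sc <- make_scenario(size, list(ves), materials, d = d, focus = focus,
                        label = name)
    return(sc)
  }

  if (name == "counterflow_pair") {
    size <- c(60, 60, 40) * mm
    R <- 1.5 * mm
    gap <- if (is.null(pair_gap)) 1 * mm else pair_gap  # focus-to-wall distance
    offs <- R + gap
    art <- vessel_spec(R, 200 * mm, vm_or(0.13),
                       origin = size / 2 + c(-offs, 0, 0), flow_sign = 1L)
    vein <- vessel_spec(R, 200 * mm, vm_or(0.13),
                        origin = size / 2 + c(offs, 0, 0), flow_sign = -1L)
    return(make_scenario(size, list(art, vein), materials, d = d,
                         label = name))
  }

  # multi_pair
  size <- c(21, 21, 26) * mm
  lay <- multipair_layout()
  centre <- size / 2
  vessels <- list()
  for (i in seq_len(nrow(lay))) {
    sep <- if (is.null(pair_gap)) lay$sep[i] else pair_gap + 2 * lay$radius[i]
    xy <- centre[1:2] + c(lay$x_off[i], lay$y_off[i])
    for (s in c(-1, 1)) {
      vessels[[length(vessels) + 1L]] <- vessel_spec(
        lay$radius[i], size[3], vm_or(0.08),
        origin = c(xy[1], xy[2] + s * sep / 2, centre[3]),
        direction = c(0, 0, 1),
        flow_sign = if (s < 0) 1L else -1L)
    }
  }
  make_scenario(size, vessels, materials, d = d, label = name)
}

#' @export
print.bh_scenario <- function(x, ...) {
  cat(sprintf("<bh_scenario> %s\n", x$label))
  cat(sprintf("  domain: %s mm, d = %g mm, %d vessel(s)\n",
              paste(signif(x$domain_size * 1e3, 4), collapse = " x "),
              x$d * 1e3, length(x$vessels)))
  for (v in x$vessels)
    cat(sprintf("   - R=%.2f mm L=%.0f mm Vm=%.0f cm/s dir=(%.2g,%.2g,%.2g) flow=%+d\n",
                v$radius * 1e3, v$length * 1e3, v$v_mean * 1e2,
                v$direction[1], v$direction[2], v$direction[3], v$flow_sign))
  invisible(x)
}
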