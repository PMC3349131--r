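#' Thermal material properties of tissue and blood
#'
#' Container for the thermal constants of the two-domain bioheat model:
#' a muscle-like tissue block with an *enhanced* (effective) conductivity
#' `k_eff` that lumps the mixing effect of vessels too small to resolve
#' individually, and blood inside discretely modelled vessel lumens.
#'
#' Defaults are generic muscle/blood values commonly used in thermal-therapy
#' modelling.
#'
#' @param rho_t tissue mass density (kg/m^3)
#' @param c_pt tissue specific heat (J kg^-1 K^-1)
#' @param k_eff effective tissue conductivity (W m^-1 K^-1)
#' @param rho_b blood mass density (kg/m^3)
#' @param c_pb blood specific heat (J kg^-1 K^-1)
#' @param k_b blood conductivity (W m^-1 K^-1)
#' @param T_core core / arterial temperature (degrees C)
#' @return an object of class `bh_materials`
#' @export
#' @examples
#' material_properties()
material_properties <- function(rho_t = 1000, c_pt = 4000, k_eff = 1.8,
                                rho_b = 1060, c_pb = 3840, k_b = 0.6,
                                T_core = 37) {
  vals <- c(rho_t = rho_t, c_pt = c_pt, k_eff = k_eff,
            rho_b = rho_b, c_pb = c_pb, k_b = k_b)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all material properties must be finite and strictly positive")
  if (!is.finite(T_core)) stop("T_core must be finite")
  structure(as.list(c(vals, T_core = T_core)), class = "bh_materials")
}

#' @export
print.bh_materials <- function(x, ...) {
  cat("<bh_materials>\n")
  cat(sprintf("  tissue: rho=%g kg/m^3, c_p=%g J/kg/K, k_eff=%g W/m/K\n",
              x$rho_t, x$c_pt, x$k_eff))
  cat(sprintf("  blood : rho=%g kg/m^3, c_p=%g J/kg/K, k_b=%g W/m/K\n",
              x$rho_b, x$c_pb, x$k_b))
  cat(sprintf("  core temperature: %g C\n", x$T_core))
  invisible(x)
}
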