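#' Air properties for drag calculations
#'
#' Bundles the physical constants of the air jet used by every drag formula:
#' the air density \eqn{\rho} and the dimensionless drag (air-resistance)
#' coefficient \eqn{C_d}. Leaves are treated as plane obstacles perpendicular
#' to the jet, for which \eqn{C_d = 1}.
#'
#' @param rho Air density in kg/m^3. Default 1.29.
#' @param c_d Air resistance coefficient, dimensionless. Default 1.0.
#' @return An object of class `air_properties`.
#' @examples
#' air_properties()
#' air_properties(rho = 1.205)
#' @export
air_properties <- function(rho = 1.29, c_d = 1.0) {
  stop_unless_positive(rho, "rho")
  stop_unless_positive(c_d, "c_d")
  structure(list(rho = rho, c_d = c_d), class = "air_properties")
}

#' Geometry of the air-assisted jet footprint
#'
#' The fan jet hits the canopy surface over a circular "air-assisted area"
#' of radius `R`; all drag integrals run over the cylinder this circle sweeps
#' through the canopy.
#'
#' @param R Radius of the circular air-assisted area on the canopy surface, m.
#'   Default 0.16.
#' @return An object of class `jet_geometry`.
#' @export
jet_geometry <- function(R = 0.16) {
  stop_unless_positive(R, "R")
  structure(list(R = R), class = "jet_geometry")
}

#' Canopy slab descriptor
#'
#' Geometry and foliage descriptors of a canopy slab that parameterize its
#' aerodynamic resistance: leaf area density, static windward leaf area
#' inside the air-assisted area, traversed depth `D`, and the thickness
#' `D_prime` of the branch-leaf section used to normalise windward area per
#' unit volume.
#'
#' @param leaf_area_density One-sided leaf area per unit canopy volume,
#'   m^2/m^3.
#' @param s0 Static (windless) windward area of canopy leaves inside the
#'   air-assisted area, m^2.
#' @param D Depth of canopy traversed by the airflow, m.
#' @param D_prime Thickness of the branch-leaf section used for the windward
#'   area per unit volume, m.
#' @return An object of class `canopy_layer`.
#' @examples
#' canopy_layer(leaf_area_density = 4.15, s0 = 0.057, D = 0.9, D_prime = 0.3)
#' @export
canopy_layer <- function(leaf_area_density, s0, D, D_prime) {
  stop_unless_positive(leaf_area_density, "leaf_area_density")
  stop_unless_positive(s0, "s0")
  stop_unless_positive(D, "D")
  stop_unless_positive(D_prime, "D_prime")
  structure(list(leaf_area_density = leaf_area_density, s0 = s0,
                 D = D, D_prime = D_prime),
            class = "canopy_layer")
}

#' Incoming-flow condition
#'
#' The incoming velocity `v_star` is the airflow speed at the instant the jet
#' reaches the windward canopy surface; it anchors the exponential profile.
#'
#' @param v_star Incoming flow velocity at the canopy surface, m/s
#'   (non-negative).
#' @return An object of class `flow_condition`.
#' @export
flow_condition <- function(v_star) {
  if (!is.numeric(v_star) || length(v_star) != 1L || !is.finite(v_star) ||
      v_star < 0) {
    stop("`v_star` must be a single finite non-negative number", call. = FALSE)
  }
  structure(list(v_star = v_star), class = "flow_condition")
}

# Accept either a flow_condition or a bare number everywhere a condition is
# expected; keeps call sites terse without losing validation.
as_flow_condition <- function(cond) {
  if (inherits(cond, "flow_condition")) return(cond)
  flow_condition(cond)
}

#' Two-layer canopy for the corrected outer-layer model
#'
#' Splits the canopy at `boundary` (default 0.3 m) into an outer slab whose
#' windward area deforms with the jet (dynamic `s*`) and an inner slab that
#' keeps the static windless area `s0`.
#'
#' @param outer A [canopy_layer()] restricted to the outer slab; its `D` must
#'   equal `boundary`.
#' @param inner A [canopy_layer()] for the canopy beyond the boundary.
#' @param boundary Depth of the outer/inner interface, m. Default 0.3.
#' @return An object of class `two_layer_canopy`.
#' @export
two_layer_canopy <- function(outer, inner, boundary = 0.3) {
  stopifnot(inherits(outer, "canopy_layer"), inherits(inner, "canopy_layer"))
  stop_unless_positive(boundary, "boundary")
  if (abs(outer$D - boundary) > 1e-12) {
    stop("`outer$D` must equal `boundary` (outer slab spans 0..boundary)",
         call. = FALSE)
  }
  structure(list(outer = outer, inner = inner, boundary = boundary),
            class = "two_layer_canopy")
}

#' @export
print.air_properties <- function(x, ...) {
  cat(sprintf("<air_properties> rho = %g kg/m^3, C_d = %g\n", x$rho, x$c_d))
  invisible(x)
}

#' @export
print.canopy_layer <- function(x, ...) {
  cat(sprintf(
    "<canopy_layer> Lr = %g m^2/m^3, s0 = %g m^2, D = %g m, D' = %g m\n",
    x$leaf_area_density, x$s0, x$D, x$D_prime))
  invisible(x)
}

#' @export
print.attenuation_fit <- function(x, ...) {
  cat(sprintf(
    "<attenuation_fit> k = %.4f 1/m at v* = %g m/s (residual %.3g N)\n",
    x$k, x$v_star, x$residual))
  invisible(x)
}

stop_unless_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single finite positive number", name),
         call. = FALSE)
  }
  invisible(TRUE)
}

stop_unless_nonnegative <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("`%s` must be finite and non-negative", name), call. = FALSE)
  }
  invisible(TRUE)
}
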