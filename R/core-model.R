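#' In-canopy airflow velocity at depth y
#'
#' The jet decelerates inside the canopy because foliage drag removes
#' momentum in proportion to the local velocity, `dv = -k v dy`, giving the
#' exponential profile
#' \deqn{v(y) = v^* e^{-k y}}
#' where `v_star` is the incoming velocity at the canopy surface, `k` the
#' velocity attenuation factor (1/m) and `y` the depth from the windward
#' canopy surface (m).
#'
#' @param cond A [flow_condition()] or a bare non-negative velocity, m/s.
#' @param k Velocity attenuation factor, 1/m (non-negative).
#' @param y Depth(s) from the canopy surface, m (non-negative).
#' @return Velocity in m/s, vectorised over `y`.
#' @examples
#' velocity_at(4, k = 0.746, y = 0.3)
#' @export
velocity_at <- function(cond, k, y) {
  cond <- as_flow_condition(cond)
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k < 0) {
    stop("`k` must be a single finite non-negative number", call. = FALSE)
  }
  stop_unless_nonnegative(y, "y")
  cond$v_star * exp(-k * y)
}

#' In-canopy velocity profile on a depth grid
#'
#' Evaluates [velocity_at()] on a strictly increasing grid of non-negative
#' depths. For `k > 0` the profile is strictly decreasing.
#'
#' @inheritParams velocity_at
#' @param depths Strictly increasing, non-negative depths, m.
#' @return A `velocity_profile`: data frame with columns `depth` (m) and
#'   `velocity` (m/s).
#' @export
velocity_profile <- function(cond, k, depths) {
  check_depth_grid(depths)
  v <- velocity_at(cond, k, depths)
  new_velocity_profile(depths, v)
}

new_velocity_profile <- function(depths, velocities) {
  structure(data.frame(depth = depths, velocity = velocities),
            class = c("velocity_profile", "data.frame"))
}

check_depth_grid <- function(depths) {
  if (!is.numeric(depths) || length(depths) == 0L || any(!is.finite(depths))) {
    stop("`depths` must be a non-empty finite numeric vector", call. = FALSE)
  }
  if (any(depths < 0)) stop("`depths` must be non-negative", call. = FALSE)
  if (is.unsorted(depths, strictly = TRUE)) {
    stop("`depths` must be strictly increasing", call. = FALSE)
  }
  invisible(TRUE)
}

#' Stagnation dynamic pressure of the jet
#'
#' When the jet is brought to rest against an impermeable obstacle the static
#' pressure rises by the dynamic pressure \eqn{P - P_0 = \rho v^2 / 2}.
#'
#' @param air An [air_properties()] object.
#' @param v Airflow velocity, m/s (non-negative).
#' @return A list with `p0` (reference, 0), `p` (stagnation) and
#'   `dp = p - p0` in Pa.
#' @export
dynamic_pressure <- function(air, v) {
  stopifnot(inherits(air, "air_properties"))
  stop_unless_nonnegative(v, "v")
  dp <- 0.5 * air$rho * v^2
  list(p0 = 0, p = dp, dp = dp)
}

#' Aerodynamic drag on a windward area
#'
#' Classical drag law \eqn{F = C_d \rho v^2 S_0 / 2} for an obstacle of
#' windward area `S_0` perpendicular to the flow.
#'
#' @inheritParams dynamic_pressure
#' @param s_windward Windward area S_0, m^2 (non-negative).
#' @return Drag force in N.
#' @examples
#' drag_force(air_properties(), v = 4, s_windward = 0.057)
#' @export
drag_force <- function(air, v, s_windward) {
  stopifnot(inherits(air, "air_properties"))
  stop_unless_nonnegative(v, "v")
  stop_unless_nonnegative(s_windward, "s_windward")
  0.5 * air$c_d * air$rho * v^2 * s_windward
}

#' Windward leaf area per unit canopy volume
#'
#' Normalises the windward leaf area `s` measured inside the air-assisted
#' circle by the volume of the branch-leaf section it was projected from:
#' \deqn{T = s / (\pi R^2 D')}
#'
#' @param s Windward leaf area inside the air-assisted area, m^2.
#' @param jet A [jet_geometry()] object (radius R of the air-assisted area).
#' @param d_prime Thickness of the branch-leaf section, m.
#' @return T in m^2/m^3.
#' @examples
#' windward_area_per_volume(0.057, jet_geometry(0.16), d_prime = 0.3)
#' @export
windward_area_per_volume <- function(s, jet, d_prime) {
  stopifnot(inherits(jet, "jet_geometry"))
  stop_unless_positive(s, "s")
  stop_unless_positive(d_prime, "d_prime")
  s / (pi * jet$R^2 * d_prime)
}

#' Canopy drag predicted from the attenuation factor
#'
#' Integrating the local drag of the exponential profile over the
#' air-assisted cylinder gives the closed-form canopy resistance
#' \deqn{F(k) = \frac{s \rho v^{*2}}{4 k D'} (1 - e^{-2 k D})}
#' which is strictly decreasing in `k` with supremum
#' \eqn{s \rho v^{*2} D / (2 D')} as \eqn{k \to 0^+}.
#'
#' @param k Velocity attenuation factor, 1/m; must be strictly positive
#'   (use [resistance_k_limit()] for the k = 0 limit).
#' @param layer A [canopy_layer()]; its `s0`, `D` and `D_prime` enter the
#'   formula.
#' @param cond A [flow_condition()] or bare velocity, m/s.
#' @param air An [air_properties()] object (only `rho` enters; the drag
#'   coefficient is absorbed into the windward-area calibration).
#' @return Drag force in N.
#' @seealso [solve_k()] for the inverse problem, [resistance_from_T()] for the
#'   equivalent parameterisation through T.
#' @export
resistance_from_k <- function(k, layer, cond, air = air_properties()) {
  stopifnot(inherits(layer, "canopy_layer"), inherits(air, "air_properties"))
  cond <- as_flow_condition(cond)
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0) {
    stop("`k` must be strictly positive; use resistance_k_limit() for k = 0",
         call. = FALSE)
  }
  layer$s0 * air$rho * cond$v_star^2 * (1 - exp(-2 * k * layer$D)) /
    (4 * k * layer$D_prime)
}

#' Zero-attenuation limit of the canopy resistance
#'
#' Closed-form limit of [resistance_from_k()] as k tends to 0:
#' \eqn{s \rho v^{*2} D / (2 D')}. Evaluated directly, never through the
#' 0/0 form.
#'
#' @inheritParams resistance_from_k
#' @return Force in N.
#' @export
resistance_k_limit <- function(layer, cond, air = air_properties()) {
  stopifnot(inherits(layer, "canopy_layer"), inherits(air, "air_properties"))
  cond <- as_flow_condition(cond)
  layer$s0 * air$rho * cond$v_star^2 * layer$D / (2 * layer$D_prime)
}

#' Canopy drag parameterised by windward area per unit volume
#'
#' The same resistance as [resistance_from_k()] written through
#' \eqn{T = s/(\pi R^2 D')}:
#' \deqn{F(k) = \frac{\pi R^2 T \rho v^{*2}}{4 k} (1 - e^{-2 k D})}
#' The two forms agree exactly when `T` comes from
#' [windward_area_per_volume()].
#'
#' @inheritParams resistance_from_k
#' @param T_value Windward area per unit canopy volume, m^2/m^3.
#' @param jet A [jet_geometry()] object.
#' @param d Canopy depth D traversed by the airflow, m.
#' @return Drag force in N.
#' @export
resistance_from_T <- function(k, T_value, jet, d, cond,
                              air = air_properties()) {
  stopifnot(inherits(jet, "jet_geometry"), inherits(air, "air_properties"))
  cond <- as_flow_condition(cond)
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0) {
    stop("`k` must be strictly positive", call. = FALSE)
  }
  stop_unless_positive(T_value, "T_value")
  stop_unless_positive(d, "d")
  pi * jet$R^2 * T_value * air$rho * cond$v_star^2 *
    (1 - exp(-2 * k * d)) / (4 * k)
}

#' Estimate the velocity attenuation factor from a drag measurement
#'
#' Inverts the resistance equation: finds the unique `k > 0` at which the
#' model drag [resistance_from_k()] equals the measured drag. The residual
#' `F(k)` is strictly decreasing, so a sign-changing bracket grown
#' geometrically from `[1e-9, 1]` followed by bisection (with Newton
#' polishing) converges to the unique root.
#'
#' @param f_measured Measured canopy drag, N. Must lie strictly between 0 and
#'   the k -> 0 supremum [resistance_k_limit()]; otherwise the measurement is
#'   infeasible under the model and an error reporting the supremum is
#'   raised.
#' @inheritParams resistance_from_k
#' @param tol Relative tolerance on the recovered force, default 1e-10.
#' @param max_iter Maximum bisection iterations, default 200.
#' @return An `attenuation_fit`: list with `k` (1/m), `v_star`, `layer`,
#'   and `residual` = |F_model(k) - f_measured| in N.
#' @examples
#' layer <- canopy_layer(4.15, s0 = 0.057, D = 0.9, D_prime = 0.3)
#' solve_k(0.97, layer, cond = 4)
#' @export
solve_k <- function(f_measured, layer, cond, air = air_properties(),
                    tol = 1e-10, max_iter = 200L) {
  stopifnot(inherits(layer, "canopy_layer"), inherits(air, "air_properties"))
  cond <- as_flow_condition(cond)
  stop_unless_positive(f_measured, "f_measured")
  sup <- resistance_k_limit(layer, cond, air)
  if (f_measured >= sup) {
    stop(sprintf(
      paste0("infeasible measurement: F = %g N is not below the zero-",
             "attenuation supremum %g N for this layer/condition"),
      f_measured, sup), call. = FALSE)
  }

  g <- function(k) resistance_from_k(k, layer, cond, air) - f_measured
  lo <- 1e-9
  hi <- 1
  # grow the upper bracket until the decreasing residual changes sign
  while (g(hi) > 0) {
    hi <- hi * 2
    if (hi > 1e9) stop("failed to bracket the root", call. = FALSE)
  }

  for (i in seq_len(max_iter)) {
    mid <- 0.5 * (lo + hi)
    if (g(mid) > 0) lo <- mid else hi <- mid
    if ((hi - lo) / hi < 1e-13) break
  }
  k <- 0.5 * (lo + hi)

  # Newton polish to machine precision; F'(k) is available in closed form
  a <- layer$s0 * air$rho * cond$v_star^2 / (4 * layer$D_prime)
  D <- layer$D
  for (i in 1:4) {
    fk <- a * (1 - exp(-2 * k * D)) / k - f_measured
    dfk <- a * (2 * D * exp(-2 * k * D) * k - (1 - exp(-2 * k * D))) / k^2
    step <- fk / dfk
    if (!is.finite(step)) break
    k_new <- k - step
    if (k_new <= 0) break
    k <- k_new
  }

  residual <- abs(resistance_from_k(k, layer, cond, air) - f_measured)
  if (residual / f_measured > tol) {
    stop("root finder did not converge to the requested tolerance",
         call. = FALSE)
  }
  structure(list(k = k, v_star = cond$v_star, layer = layer,
                 residual = residual),
            class = "attenuation_fit")
}
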