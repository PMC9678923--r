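#' Fit the dynamic windward-area model
#'
#' At high incoming velocities the outer-canopy leaves are pressed together
#' by the jet, shrinking the windward area from its windless value `s0` to a
#' velocity-dependent `s*(v)`. Beyond a density-specific saturation velocity
#' the elastic deformation is exhausted and `s*` stabilises at `s_min`.
#' The fitted model is the weakest shape consistent with those observations:
#' a monotone piecewise-linear interpolant through the calibration anchors,
#' clamped to `s0` below the smallest anchor velocity and to `s_min` at and
#' beyond the saturation velocity.
#'
#' Saturation is detected as the smallest anchor velocity from which every
#' later successive relative decrease in `s*` stays below 1%; a
#' `v_sat_hint` overrides the detection.
#'
#' @param pairs Data frame with columns `v_star` (m/s) and `s_star` (m^2):
#'   at least two anchors with distinct velocities, all areas in (0, s0].
#' @param s0 Static (windless) windward area, m^2.
#' @param v_sat_hint Optional known saturation velocity, m/s.
#' @return A `dynamic_windward_model` with elements `s0`, `anchor_points`,
#'   `v_sat` and `s_min`.
#' @examples
#' anchors <- data.frame(v_star = c(6, 8, 10, 12, 14, 15),
#'                       s_star = c(0.056, 0.053, 0.050, 0.048, 0.047, 0.047))
#' fit_dynamic_windward(anchors, s0 = 0.057)
#' @export
fit_dynamic_windward <- function(pairs, s0, v_sat_hint = NULL) {
  stop_unless_positive(s0, "s0")
  if (!is.data.frame(pairs) || !all(c("v_star", "s_star") %in% names(pairs))) {
    stop("`pairs` must be a data frame with columns v_star and s_star",
         call. = FALSE)
  }
  pairs <- pairs[order(pairs$v_star), c("v_star", "s_star")]
  if (nrow(pairs) < 2L || anyDuplicated(pairs$v_star)) {
    stop("need at least 2 anchors with distinct v_star", call. = FALSE)
  }
  if (any(pairs$s_star <= 0) || any(pairs$s_star > s0 * (1 + 1e-12))) {
    stop("all s_star must lie in (0, s0]", call. = FALSE)
  }
  rel_change <- diff(pairs$s_star) / pairs$s_star[-nrow(pairs)]
  if (any(rel_change > 0.01)) {
    stop("anchors are not monotone: s_star increases with v_star beyond 1%",
         call. = FALSE)
  }

  if (is.null(v_sat_hint)) {
    # first anchor after which s* never again drops by >= 1% relative
    decreasing <- -rel_change >= 0.01
    last_drop <- if (any(decreasing)) max(which(decreasing)) else 0L
    v_sat <- pairs$v_star[last_drop + 1L]
  } else {
    stop_unless_positive(v_sat_hint, "v_sat_hint")
    v_sat <- v_sat_hint
  }
  s_min <- min(pairs$s_star[pairs$v_star >= v_sat], pairs$s_star[nrow(pairs)])

  structure(list(s0 = s0, anchor_points = pairs, v_sat = v_sat,
                 s_min = s_min),
            class = "dynamic_windward_model")
}

#' Evaluate the dynamic windward area at a given incoming velocity
#'
#' Clamped monotone evaluation of the fitted model: `s0` in the windless
#' condition and below the smallest calibration velocity, linear
#' interpolation between anchors, and `s_min` at and beyond the saturation
#' velocity.
#'
#' @param model A `dynamic_windward_model` from [fit_dynamic_windward()].
#' @param v_star Incoming velocity, m/s (non-negative, vectorised).
#' @return Windward area s* in m^2.
#' @export
s_star_at <- function(model, v_star) {
  stopifnot(inherits(model, "dynamic_windward_model"))
  stop_unless_nonnegative(v_star, "v_star")
  anchors <- model$anchor_points
  s <- stats::approx(anchors$v_star, anchors$s_star, xout = v_star,
                     rule = 2)$y
  s[v_star == 0] <- model$s0
  s[v_star < anchors$v_star[1L] & v_star > 0] <- model$s0
  s[v_star >= model$v_sat] <- model$s_min
  pmin(pmax(s, model$s_min), model$s0)
}

#' Attenuation-factor estimate with the outer-layer windward correction
#'
#' Identical to [solve_k()] except that for the outer slab (depth not
#' exceeding the two-layer boundary, 0.3 m by default) the static windward
#' area `s0` is replaced by the dynamic `s*(v_star)` from the fitted
#' deformation model. The inner slab keeps `s0`.
#'
#' @param f_measured Measured canopy drag, N.
#' @param two_layer A [two_layer_canopy()].
#' @param cond A [flow_condition()] or bare velocity, m/s.
#' @param air An [air_properties()] object.
#' @param model A `dynamic_windward_model` from [fit_dynamic_windward()].
#' @param which_layer `"outer"` (default; applies the s* branch) or
#'   `"inner"` (static branch).
#' @param ... Passed on to [solve_k()] (`tol`, `max_iter`).
#' @return An `attenuation_fit`.
#' @export
corrected_solve_k <- function(f_measured, two_layer, cond,
                              air = air_properties(), model,
                              which_layer = c("outer", "inner"), ...) {
  stopifnot(inherits(two_layer, "two_layer_canopy"),
            inherits(model, "dynamic_windward_model"))
  which_layer <- match.arg(which_layer)
  cond <- as_flow_condition(cond)
  layer <- if (which_layer == "outer") two_layer$outer else two_layer$inner
  if (which_layer == "outer") {
    s_dyn <- s_star_at(model, cond$v_star)
    layer <- canopy_layer(layer$leaf_area_density, s_dyn, layer$D,
                          layer$D_prime)
  }
  solve_k(f_measured, layer, cond, air, ...)
}

#' Two-layer in-canopy velocity profile
#'
#' The exponential attenuation law is memoryless in depth, so attenuation
#' composes multiplicatively across layers. With a rapid-attenuation outer
#' slab (0..`boundary`) of factor `k_outer` and an inner slab of factor
#' `k_inner`:
#' \deqn{v(y) = v^* e^{-k_{outer} y} \quad (y \le b), \qquad
#'       v(y) = v^* e^{-k_{outer} b} e^{-k_{inner} (y - b)} \quad (y > b)}
#' The profile is continuous at the boundary and reduces to the single-layer
#' law when the two factors are equal.
#'
#' @param cond A [flow_condition()] or bare velocity, m/s.
#' @param k_outer Attenuation factor of the outer slab, 1/m.
#' @param k_inner Attenuation factor of the inner slab, 1/m.
#' @param depths Strictly increasing non-negative depths, m.
#' @param boundary Outer/inner interface depth, m. Default 0.3.
#' @return A `velocity_profile` data frame.
#' @examples
#' two_layer_profile(12, k_outer = 1.682, k_inner = 1.159,
#'                   depths = c(0.15, 0.3, 0.6, 0.9))
#' @export
two_layer_profile <- function(cond, k_outer, k_inner, depths,
                              boundary = 0.3) {
  cond <- as_flow_condition(cond)
  stop_unless_nonnegative(k_outer, "k_outer")
  stop_unless_nonnegative(k_inner, "k_inner")
  stop_unless_positive(boundary, "boundary")
  check_depth_grid(depths)
  v_boundary_log <- -k_outer * boundary
  logv <- ifelse(depths <= boundary,
                 -k_outer * depths,
                 v_boundary_log - k_inner * (depths - boundary))
  new_velocity_profile(depths, cond$v_star * exp(logv))
}
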