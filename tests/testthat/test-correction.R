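make_anchors <- function(v, s) data.frame(v_star = v, s_star = s)

test_that("fit_dynamic_windward detects the saturation velocity", {
  # sparse-canopy style calibration: decreasing until 14 m/s, flat after
  anchors <- make_anchors(c(6, 8, 10, 12, 14, 15),
                          c(0.0560, 0.0535, 0.0510, 0.0490, 0.0478, 0.0478))
  model <- fit_dynamic_windward(anchors, s0 = 0.057)
  expect_equal(model$v_sat, 14)
  expect_equal(model$s_min, 0.0478)

  # constant-area input: saturated from the first anchor
  flat <- make_anchors(c(4, 8, 12), rep(0.057, 3))
  m2 <- fit_dynamic_windward(flat, s0 = 0.057)
  expect_equal(m2$v_sat, 4)
  expect_equal(s_star_at(m2, c(0, 2, 6, 20)), rep(0.057, 4))

  # hint overrides detection
  m3 <- fit_dynamic_windward(anchors, s0 = 0.057, v_sat_hint = 12)
  expect_equal(m3$v_sat, 12)
})

test_that("fit_dynamic_windward validates its anchors", {
  expect_error(fit_dynamic_windward(make_anchors(6, 0.05), s0 = 0.057),
               "at least 2")
  expect_error(fit_dynamic_windward(
    make_anchors(c(6, 8), c(0.050, 0.056)), s0 = 0.057), "monotone")
  expect_error(fit_dynamic_windward(
    make_anchors(c(6, 8), c(0.06, 0.05)), s0 = 0.057), "\\(0, s0\\]")
})

test_that("s_star_at interpolates, clamps, and honours the windless limit", {
  anchors <- make_anchors(seq(6, 15), 0.057 - 0.001 * seq(6, 15))
  model <- fit_dynamic_windward(anchors, s0 = 0.057)
  # interpolant reproduces every anchor exactly
  expect_equal(s_star_at(model, anchors$v_star), anchors$s_star)
  # midway between anchors: linear interpolation
  expect_equal(s_star_at(model, 7.5), (0.050 + 0.049) / 2)
  # clamps
  expect_equal(s_star_at(model, 0), 0.057)
  expect_equal(s_star_at(model, model$v_sat + 5), model$s_min)
  expect_error(s_star_at(model, -1), "non-negative")
  # non-increasing over a dense grid
  grid <- s_star_at(model, seq(0, 20, by = 0.1))
  expect_true(all(diff(grid) <= 1e-15))
  expect_true(all(grid >= model$s_min & grid <= model$s0))
})

two_layer_fixture <- function(s0 = 0.057) {
  outer <- canopy_layer(4.15, s0, 0.3, 0.3)
  inner <- canopy_layer(4.15, s0, 0.6, 0.3)
  two_layer_canopy(outer, inner, boundary = 0.3)
}

test_that("corrected_solve_k reduces to solve_k when s* = s0", {
  tl <- two_layer_fixture()
  flat <- fit_dynamic_windward(make_anchors(c(4, 12), rep(0.057, 2)),
                               s0 = 0.057)
  f <- resistance_from_k(1.5, tl$outer, 10, default_air)
  fit_plain <- solve_k(f, tl$outer, 10, default_air)
  fit_corr <- corrected_solve_k(f, tl, 10, default_air, flat)
  expect_identical(fit_corr$k, fit_plain$k)
})

test_that("smaller s* at fixed drag yields smaller k (drag scales with area)", {
  # F = s * A(k) with A strictly decreasing in k, so at fixed measured F a
  # smaller windward area forces a smaller attenuation factor: sustaining
  # the same total drag with less leaf area requires the flow to stay fast
  # deeper into the canopy.
  tl <- two_layer_fixture()
  shrunk <- fit_dynamic_windward(
    make_anchors(c(6, 10, 11), c(0.050, 0.044, 0.044)), s0 = 0.057)
  f <- resistance_from_k(1.5, tl$outer, 10, default_air)
  fit_static <- solve_k(f, tl$outer, 10, default_air)
  fit_dyn <- corrected_solve_k(f, tl, 10, default_air, shrunk)
  expect_lt(fit_dyn$k, fit_static$k)
  # and at the same true k the shrunken canopy produces less drag
  expect_lt(resistance_from_k(1.5, canopy_layer(4.15, 0.044, 0.3, 0.3), 10,
                              default_air),
            f)
})

test_that("corrected fits recover a known outer-layer k under force noise", {
  # stated world: 0.5% relative force noise, deformation model known
  tl <- two_layer_fixture()
  model <- fit_dynamic_windward(
    make_anchors(c(6, 8, 10, 12, 14, 15),
                 c(0.0560, 0.0535, 0.0510, 0.0490, 0.0478, 0.0478)),
    s0 = 0.057)
  set.seed(11)
  k_true <- 1.9
  v <- 10
  s_dyn <- s_star_at(model, v)
  layer_true <- canopy_layer(4.15, s_dyn, 0.3, 0.3)
  for (rep in 1:20) {
    f_obs <- resistance_from_k(k_true, layer_true, v, default_air) *
      (1 + rnorm(1, 0, 0.005))
    fit <- corrected_solve_k(f_obs, tl, v, default_air, model)
    expect_lt(abs(fit$k - k_true) / k_true, 0.02)
  }
})

test_that("two-layer profile is continuous and composes the two slabs", {
  depths <- c(0.1, 0.3 - 1e-12, 0.3, 0.3 + 1e-12, 0.6, 0.9)
  prof <- two_layer_profile(12, k_outer = 1.682, k_inner = 1.159,
                            depths = depths)
  # continuity at the boundary (one-sided limits coincide)
  expect_lt(abs(prof$velocity[2] - prof$velocity[4]) / prof$velocity[3],
            1e-10)
  expect_equal(prof$velocity[3], 12 * exp(-1.682 * 0.3), tolerance = 1e-12)
  # frozen from 12 * exp(-1.682*0.3) * exp(-1.159*0.3)
  expect_equal(prof$velocity[5], 5.117196087, tolerance = 1e-8)
  expect_true(all(diff(prof$velocity) < 0))

  # degenerate composition: equal k collapses to the single-layer law
  d2 <- seq(0.1, 0.9, by = 0.1)
  expect_equal(two_layer_profile(8, 1.3, 1.3, d2)$velocity,
               velocity_profile(8, 1.3, d2)$velocity, tolerance = 1e-14)
})

test_that("k_outer > k_inner gives rapid-then-slow attenuation", {
  # per-0.1 m fractional velocity loss larger in the outer slab
  d <- (0:9) / 10  # exact decimals; cumulative seq() drifts past 0.3
  prof <- two_layer_profile(12, 2.0, 1.1, d)
  frac_loss <- -diff(prof$velocity) / prof$velocity[-length(d)]
  outer_steps <- frac_loss[d[-1] < 0.35]
  inner_steps <- frac_loss[d[-1] > 0.35]
  expect_gt(min(outer_steps), max(inner_steps))
})
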