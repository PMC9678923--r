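test_that("velocity_at follows the exponential law and its edge cases", {
  expect_identical(velocity_at(4, k = 0.746, y = 0), 4)
  expect_identical(velocity_at(7, k = 0, y = 0.5), 7)
  # frozen from direct evaluation of 4 * exp(-0.746 * 0.3)
  expect_equal(velocity_at(4, k = 0.746, y = 0.3), 3.197900054,
               tolerance = 1e-9)
  expect_error(velocity_at(4, k = -1, y = 0.1), "k")
  expect_error(velocity_at(4, k = 1, y = -0.1), "non-negative")
})

test_that("velocity_profile is element-wise and strictly decreasing", {
  depths <- seq(0.15, 0.9, by = 0.15)
  prof <- velocity_profile(4, 0.746, depths)
  expect_equal(prof$velocity,
               vapply(depths, function(y) velocity_at(4, 0.746, y),
                      numeric(1)))
  expect_true(all(diff(prof$velocity) < 0))
  expect_true(all(prof$velocity < 4 & prof$velocity > 0))

  expect_equal(velocity_profile(0, 1.2, depths)$velocity, rep(0, 6))

  # monotone in k at every positive depth
  p_lo <- velocity_profile(8, 1.159, depths)
  p_hi <- velocity_profile(8, 1.682, depths)
  expect_true(all(p_lo$velocity > p_hi$velocity))

  expect_error(velocity_profile(4, 1, c(0.3, 0.15)), "increasing")
  expect_error(velocity_profile(4, 1, c(-0.1, 0.2)), "non-negative")
})

test_that("dynamic pressure and drag force are the Bernoulli/drag laws", {
  expect_equal(dynamic_pressure(default_air, 4)$dp, 10.32)
  expect_equal(dynamic_pressure(default_air, 0)$dp, 0)
  v <- c(0.7, 1.3, 5.2)
  for (vi in v) {
    expect_equal(dynamic_pressure(default_air, 2 * vi)$dp,
                 4 * dynamic_pressure(default_air, vi)$dp)
  }
  expect_error(dynamic_pressure(default_air, -1), "non-negative")

  expect_equal(drag_force(default_air, 4, 1), 10.32)
  expect_equal(drag_force(default_air, 4, 0.057), 0.58824)
  expect_equal(drag_force(default_air, 4, 0), 0)
  expect_error(drag_force(default_air, 4, -0.1), "non-negative")
})

test_that("windward area per unit volume matches the bench T values", {
  jet <- jet_geometry(0.16)
  ref <- unique(bench_reference()[c("leaf_area_density", "T_m2_per_m3")])
  s_by_density <- c("4.15" = 0.057, "4.79" = 0.060, "5.65" = 0.065)
  for (i in seq_len(nrow(ref))) {
    s <- s_by_density[[as.character(ref$leaf_area_density[i])]]
    T_est <- windward_area_per_volume(s, jet, d_prime = 0.3)
    expect_lt(abs(T_est - ref$T_m2_per_m3[i]) / ref$T_m2_per_m3[i], 0.015)
  }
  # normalization: s equal to the cylinder-section volume gives T = 1
  expect_equal(windward_area_per_volume(pi * 0.16^2 * 0.3, jet, 0.3), 1)
  expect_error(windward_area_per_volume(0, jet, 0.3), "positive")
})

test_that("resistance_from_k evaluates the closed form and its k->0 limit", {
  layer <- canopy_layer(4.15, 0.057, 0.9, 0.3)
  # frozen from direct evaluation at the bench condition
  expect_equal(resistance_from_k(0.746, layer, 4, default_air),
               0.971051339, tolerance = 1e-8)
  lim <- resistance_k_limit(layer, 4, default_air)
  expect_equal(lim, 1.76472)
  expect_equal(resistance_from_k(1e-9, layer, 4, default_air), lim,
               tolerance = 1e-6)
  expect_error(resistance_from_k(0, layer, 4, default_air), "positive")
  expect_error(resistance_from_k(-1, layer, 4, default_air), "positive")
})

test_that("the T- and s-parameterised resistances are algebraically equal", {
  set.seed(42)
  jet <- jet_geometry(0.16)
  for (i in 1:25) {
    s <- runif(1, 0.02, 0.12)
    d_prime <- runif(1, 0.1, 0.6)
    d <- runif(1, 0.3, 1.5)
    k <- runif(1, 0.05, 5)
    v <- runif(1, 1, 15)
    layer <- canopy_layer(4, s, d, d_prime)
    T_val <- windward_area_per_volume(s, jet, d_prime)
    f1 <- resistance_from_k(k, layer, v, default_air)
    f2 <- resistance_from_T(k, T_val, jet, d, v, default_air)
    expect_lt(abs(f1 - f2) / f1, 1e-12)
  }
})

test_that("resistance_from_T forward-evaluates at the printed T", {
  # rounding of the printed T explains the small gap to the measured 2.96 N
  f <- resistance_from_T(1.159, 2.353, jet_geometry(0.16), d = 0.9,
                         cond = 8, air = default_air)
  expect_equal(f, 2.951642597, tolerance = 1e-8)
  # quadratic scaling in v*
  f4 <- resistance_from_T(1.159, 2.353, jet_geometry(0.16), 0.9, 4,
                          default_air)
  expect_equal(f / f4, 4, tolerance = 1e-12)
})

test_that("closed-form resistance agrees with the volume-integral oracle", {
  set.seed(7)
  jet <- jet_geometry(0.16)
  for (i in 1:10) {
    k <- runif(1, 0.05, 4)
    T_val <- runif(1, 1, 4)
    d <- runif(1, 0.3, 1.2)
    v <- runif(1, 2, 14)
    f_closed <- resistance_from_T(k, T_val, jet, d, v, default_air)
    f_quad <- quadrature_resistance(k, T_val, jet$R, d, v, 1.29)
    expect_lt(abs(f_closed - f_quad) / f_closed, 1e-8)
  }
})

test_that("solve_k inverts the resistance equation (roundtrip property)", {
  layer <- canopy_layer(4.79, 0.060, 0.9, 0.3)
  for (k_true in c(0.05, 0.2, 0.746, 1.5, 3, 10)) {
    f <- resistance_from_k(k_true, layer, 9, default_air)
    fit <- solve_k(f, layer, 9, default_air)
    expect_lt(abs(fit$k - k_true) / k_true, 1e-8)
    expect_lt(fit$residual, 1e-10 * f)
  }
})

test_that("solve_k reproduces the bench calibration table within 2%", {
  campaign <- bench_campaign()
  ref <- bench_reference()
  for (i in seq_len(nrow(campaign))) {
    fit <- solve_k(campaign$force_N[i], layer_for_row(campaign[i, ]),
                   campaign$v_star[i], default_air)
    expect_lt(abs(fit$k - ref$k[i]) / ref$k[i], 0.02)
  }
})

test_that("solve_k rejects infeasible drags with the supremum reported", {
  layer <- canopy_layer(4.15, 0.057, 0.9, 0.3)
  sup <- resistance_k_limit(layer, 4, default_air)
  expect_error(solve_k(sup * 1.01, layer, 4, default_air),
               "infeasible measurement")
  expect_error(solve_k(sup, layer, 4, default_air), "supremum")
  expect_error(solve_k(0, layer, 4, default_air), "positive")
  # just-feasible drag still converges
  fit <- solve_k(sup * 0.999, layer, 4, default_air)
  expect_true(fit$k > 0 && fit$k < 0.01)
})
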