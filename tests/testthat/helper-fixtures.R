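# Shared fixtures: the bundled bench campaign (drag table) and the published
# calibration k/T values it was reduced to, plus an independent quadrature
# oracle for the closed-form resistance.

bench_campaign <- function() {
  read_campaign_csv(system.file("extdata", "pear_campaign.csv",
                                package = "canopyair"))
}

bench_reference <- function() {
  utils::read.csv(system.file("extdata", "pear_k_reference.csv",
                              package = "canopyair"))
}

default_air <- air_properties(rho = 1.29, c_d = 1.0)

layer_for_row <- function(row) {
  canopy_layer(row$leaf_area_density, row$s_m2, row$D_m, row$D_prime_m)
}

# Independent oracle: numerical quadrature of the local-drag volume integral
# over the air-assisted cylinder (radius R, depth D), with v(x,y,z) =
# v* e^(-k y) and windward area density T. Fubini: the integrand only
# depends on y, so the x/z part is the numerically-integrated circle area.
quadrature_resistance <- function(k, T_value, R, D, v_star, rho) {
  area <- stats::integrate(function(x) 2 * sqrt(pmax(R^2 - x^2, 0)),
                           -R, R, rel.tol = 1e-12)$value
  depth <- stats::integrate(function(y) 0.5 * rho * T_value * v_star^2 *
                              exp(-2 * k * y),
                            0, D, rel.tol = 1e-12)$value
  area * depth
}
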