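# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so generators stay pure functions of (spec, seed).
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic drag-measurement campaign
#'
#' Describes the measurement campaign to emulate: the grid of canopy leaf
#' area densities and incoming velocities, the true attenuation factor in
#' each cell, the shared geometry, and the instrument noise. Defaults follow
#' the bench campaign shipped with the package: densities 4.15/4.79/5.65
#' m^2/m^3 with static windward areas 0.057/0.060/0.065 m^2, velocities
#' 4/8/12 m/s, jet radius 0.16 m, canopy depth 0.9 m, branch-leaf section
#' 0.3 m, a force gauge with 0.5% relative error and an anemometer with
#' 0.025 m/s error (both interpreted as 1-sd Gaussian).
#'
#' @param densities Leaf area densities Lr, m^2/m^3.
#' @param v_stars Incoming velocities, m/s.
#' @param true_k Matrix of true attenuation factors, `length(densities)` rows
#'   by `length(v_stars)` columns, all > 0.
#' @param s0 Static windward areas per density, m^2.
#' @param jet A [jet_geometry()].
#' @param D,D_prime Canopy depth and branch-leaf section thickness, m.
#' @param force_noise_rel Relative sd of the force gauge. Default 0.005.
#' @param anemometer_sd Sd of anemometer readings, m/s. Default 0.025.
#' @param seed Integer RNG seed.
#' @return An object of class `campaign_spec`.
#' @export
campaign_spec <- function(densities = c(4.15, 4.79, 5.65),
                          v_stars = c(4, 8, 12),
                          true_k = reference_k_matrix(),
                          s0 = c(0.057, 0.060, 0.065),
                          jet = jet_geometry(0.16),
                          D = 0.9, D_prime = 0.3,
                          force_noise_rel = 0.005,
                          anemometer_sd = 0.025,
                          seed = 1L) {
  if (length(densities) == 0L || length(v_stars) == 0L) {
    stop("`densities` and `v_stars` must be non-empty", call. = FALSE)
  }
  true_k <- as.matrix(true_k)
  if (!all(dim(true_k) == c(length(densities), length(v_stars)))) {
    stop("`true_k` must be a densities x v_stars matrix", call. = FALSE)
  }
  if (any(true_k <= 0)) stop("all true_k must be > 0", call. = FALSE)
  if (length(s0) != length(densities) || any(s0 <= 0)) {
    stop("`s0` must give one positive area per density", call. = FALSE)
  }
  if (force_noise_rel < 0 || anemometer_sd < 0) {
    stop("noise parameters must be non-negative", call. = FALSE)
  }
  stopifnot(inherits(jet, "jet_geometry"))
  structure(list(densities = densities, v_stars = v_stars, true_k = true_k,
                 s0 = s0, jet = jet, D = D, D_prime = D_prime,
                 force_noise_rel = force_noise_rel,
                 anemometer_sd = anemometer_sd, seed = as.integer(seed)),
            class = "campaign_spec")
}

#' Attenuation factors of the bench calibration campaign
#'
#' The 3 x 3 grid of attenuation factors (1/m) obtained on the bench for
#' sparse/medium/compact pear canopies (Lr = 4.15, 4.79, 5.65 m^2/m^3) at
#' incoming velocities 4, 8 and 12 m/s; used as the default ground truth for
#' synthetic campaigns.
#'
#' @return A 3 x 3 numeric matrix (rows = densities, cols = velocities).
#' @export
reference_k_matrix <- function() {
  matrix(c(0.746, 1.159, 1.682,
           0.874, 1.457, 2.014,
           1.087, 1.824, 2.401),
         nrow = 3, byrow = FALSE,
         dimnames = list(Lr = c("4.15", "4.79", "5.65"),
                         v_star = c("4", "8", "12")))
}

#' Generate a synthetic drag-measurement campaign
#'
#' Emulates a bench campaign: for every (density, velocity) cell the
#' noiseless drag is the closed-form [resistance_from_k()] at the true
#' attenuation factor, and the observed drag is truth times
#' `(1 + N(0, force_noise_rel))`, resampled while non-positive. The hidden
#' truth is kept alongside the observations so recovery tests never have to
#' re-derive it.
#'
#' @param spec A [campaign_spec()].
#' @param air An [air_properties()] object.
#' @return A `synthetic_campaign`: list with `campaign` (data frame in the
#'   campaign CSV dialect: leaf_area_density, v_star, force_N, s_m2, R_m,
#'   D_m, D_prime_m), `truth` (data frame with true_k and force_true_N) and
#'   `seed`.
#' @export
generate_campaign <- function(spec, air = air_properties()) {
  stopifnot(inherits(spec, "campaign_spec"))
  grid <- expand.grid(i = seq_along(spec$densities),
                      j = seq_along(spec$v_stars))
  rows <- with_seed(spec$seed, {
    lapply(seq_len(nrow(grid)), function(r) {
      i <- grid$i[r]; j <- grid$j[r]
      layer <- canopy_layer(spec$densities[i], spec$s0[i], spec$D,
                            spec$D_prime)
      f_true <- resistance_from_k(spec$true_k[i, j], layer,
                                  spec$v_stars[j], air)
      f_obs <- f_true * (1 + stats::rnorm(1, 0, spec$force_noise_rel))
      while (f_obs <= 0) {
        f_obs <- f_true * (1 + stats::rnorm(1, 0, spec$force_noise_rel))
      }
      data.frame(leaf_area_density = spec$densities[i],
                 v_star = spec$v_stars[j], force_N = f_obs,
                 s_m2 = spec$s0[i], R_m = spec$jet$R, D_m = spec$D,
                 D_prime_m = spec$D_prime,
                 true_k = spec$true_k[i, j], force_true_N = f_true)
    })
  })
  all <- do.call(rbind, rows)
  obs_cols <- c("leaf_area_density", "v_star", "force_N", "s_m2", "R_m",
                "D_m", "D_prime_m")
  structure(list(campaign = all[obs_cols],
                 truth = all[c("leaf_area_density", "v_star", "true_k",
                               "force_true_N")],
                 seed = spec$seed),
            class = "synthetic_campaign")
}

#' Generate noisy anemometer readings of an exponential profile
#'
#' Exponential-law truth plus Gaussian anemometer noise per depth, floored
#' at zero (an anemometer cannot read a negative speed).
#'
#' @param k True attenuation factor, 1/m.
#' @param cond A [flow_condition()] or bare velocity, m/s.
#' @param depths Strictly increasing non-negative depths, m.
#' @param sd Anemometer noise sd, m/s. Default 0.025.
#' @param seed Integer RNG seed.
#' @return A list with `observed` (a `velocity_profile` with noise) and
#'   `truth` (the noiseless profile).
#' @export
generate_velocity_measurements <- function(k, cond, depths, sd = 0.025,
                                           seed = 1L) {
  if (sd < 0) stop("`sd` must be non-negative", call. = FALSE)
  truth <- velocity_profile(cond, k, depths)
  observed <- with_seed(seed, {
    noisy <- pmax(truth$velocity + stats::rnorm(length(depths), 0, sd), 0)
    new_velocity_profile(depths, noisy)
  })
  list(observed = observed, truth = truth)
}

#' Generate a synthetic canopy projection image
#'
#' Emulates a white-background canopy photograph: a bright background with
#' mild texture, dark leaf-like ellipses placed at random inside the marked
#' circular air-assisted region until the covered fraction of the ROI is
#' within 0.5% absolute of the target (single dark pixels fill the last
#' gap). Overlapping ellipses project to single coverage, as leaves do.
#' The achieved coverage is returned as the ground truth.
#'
#' @param leaf_fraction_target Target fraction of ROI covered by leaf, in
#'   \[0, 1).
#' @param roi_radius_px ROI radius in pixels. Default 60.
#' @param image_size `(rows, cols)` of the image. Default 160 x 160.
#' @param scale Metres per pixel; defaults to 0.16 / roi_radius_px so the
#'   ROI matches the 0.16 m jet radius.
#' @param seed Integer RNG seed.
#' @return A list with `image` (a [projection_image()]) and `truth_fraction`.
#' @export
generate_canopy_image <- function(leaf_fraction_target, roi_radius_px = 60,
                                  image_size = c(160, 160),
                                  scale = 0.16 / roi_radius_px, seed = 1L) {
  if (!is.numeric(leaf_fraction_target) || leaf_fraction_target < 0 ||
      leaf_fraction_target >= 1) {
    stop("`leaf_fraction_target` must lie in [0, 1)", call. = FALSE)
  }
  nr <- image_size[1]; nc <- image_size[2]
  center <- c((nr + 1) / 2, (nc + 1) / 2)
  with_seed(seed, {
    # textured white-cloth background, clipped to a bright band
    px <- matrix(pmin(pmax(stats::rnorm(nr * nc, 0.92, 0.02), 0.8), 1),
                 nr, nc)
    rr <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    in_roi <- (rr - center[1])^2 + (cc - center[2])^2 < roi_radius_px^2
    n_roi <- sum(in_roi)
    covered <- matrix(FALSE, nr, nc)

    frac <- function() sum(covered & in_roi) / n_roi
    tol <- 0.005
    max_ax <- max(4, roi_radius_px / 4)
    while (frac() < leaf_fraction_target - tol) {
      gap <- leaf_fraction_target - frac()
      # shrink candidate ellipses as the gap closes so we never overshoot far
      a <- stats::runif(1, 2, max(2.5, min(max_ax, sqrt(gap * n_roi / pi))))
      b <- a * stats::runif(1, 0.4, 1)
      theta <- stats::runif(1, 0, pi)
      r0 <- center[1] + stats::runif(1, -1, 1) * roi_radius_px * 0.9
      c0 <- center[2] + stats::runif(1, -1, 1) * roi_radius_px * 0.9
      dr <- rr - r0; dc <- cc - c0
      u <- dr * cos(theta) + dc * sin(theta)
      w <- -dr * sin(theta) + dc * cos(theta)
      ell <- (u / a)^2 + (w / b)^2 <= 1
      cand <- covered | (ell & in_roi)
      if (sum(cand & in_roi) / n_roi <= leaf_fraction_target + tol) {
        covered <- cand
      }
    }
    # top up with single pixels if ellipses stalled just below the band
    if (frac() < leaf_fraction_target - tol / 2) {
      free <- which(in_roi & !covered)
      need <- round((leaf_fraction_target - frac()) * n_roi)
      covered[sample(free, min(need, length(free)))] <- TRUE
    }
    # leaf pixels: dark with texture
    n_cov <- sum(covered)
    px[covered] <- pmin(pmax(stats::rnorm(n_cov, 0.15, 0.05), 0), 0.4)
    truth <- frac()
    list(image = projection_image(px, scale, center, roi_radius_px),
         truth_fraction = truth)
  })
}
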