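#' Canopy projection image with a marked air-assisted region
#'
#' A grayscale canopy photograph taken along the jet axis against a white
#' background, together with the marked circular region of interest (the
#' air-assisted area) and the metric scale of the image.
#'
#' @param pixels Numeric matrix of grayscale intensities in \[0, 1\]
#'   (0 = black, 1 = white); rows index image rows.
#' @param scale Metres per pixel (> 0).
#' @param roi_center Numeric length-2 vector `(row, col)` of the circle
#'   centre, in pixels.
#' @param roi_radius_px Circle radius in pixels (> 0). The circle must lie
#'   fully inside the image.
#' @return An object of class `projection_image`.
#' @export
projection_image <- function(pixels, scale, roi_center, roi_radius_px) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0L) {
    stop("`pixels` must be a non-empty numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(pixels)) || any(pixels < 0) || any(pixels > 1)) {
    stop("intensities must be finite and within [0, 1]", call. = FALSE)
  }
  stop_unless_positive(scale, "scale")
  stop_unless_positive(roi_radius_px, "roi_radius_px")
  if (length(roi_center) != 2L || any(!is.finite(roi_center))) {
    stop("`roi_center` must be (row, col)", call. = FALSE)
  }
  if (roi_center[1] - roi_radius_px < 1 ||
      roi_center[1] + roi_radius_px > nrow(pixels) ||
      roi_center[2] - roi_radius_px < 1 ||
      roi_center[2] + roi_radius_px > ncol(pixels)) {
    stop("ROI circle extends outside the image bounds", call. = FALSE)
  }
  structure(list(pixels = pixels, scale = scale,
                 roi_center = as.numeric(roi_center),
                 roi_radius_px = roi_radius_px),
            class = "projection_image")
}

# logical mask of pixels strictly inside the ROI circle
roi_mask <- function(img) {
  nr <- nrow(img$pixels); nc <- ncol(img$pixels)
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (rr - img$roi_center[1])^2 + (cc - img$roi_center[2])^2 <
    img$roi_radius_px^2
}

# Otsu's threshold: maximise between-class variance of a 256-bin histogram.
otsu_threshold <- function(intensities, n_bins = 256L) {
  h <- tabulate(pmin(floor(intensities * n_bins) + 1L, n_bins), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b2 <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  mids[which.max(sigma_b2)] + 0.5 / n_bins  # upper edge of the best bin
}

#' Estimate windward leaf area from a canopy projection image
#'
#' Pixels strictly inside the marked air-assisted circle darker than the
#' threshold are classified as leaf (the protocol guarantees a bright,
#' white-cloth background). When no threshold is supplied a global
#' histogram-based (Otsu) threshold is computed from the ROI intensities;
#' on a degenerate (uniform) ROI the threshold falls back to the midpoint
#' intensity 0.5 and the estimate is flagged low-confidence. The windward
#' area follows from the leaf pixel fraction and the metric ROI area:
#' \deqn{s = \mathrm{leaf\ fraction} \times \pi (r_{px} \cdot
#'       \mathrm{scale})^2}
#'
#' @param img A [projection_image()].
#' @param threshold Optional intensity threshold in (0, 1); leaf = strictly
#'   below.
#' @return A `windward_area_estimate`: list with `leaf_fraction`, `s` (m^2),
#'   `threshold_used`, `roi_radius_m`, and `low_confidence`.
#' @export
estimate_windward_area <- function(img, threshold = NULL) {
  stopifnot(inherits(img, "projection_image"))
  vals <- img$pixels[roi_mask(img)]
  low_confidence <- FALSE
  if (is.null(threshold)) {
    if (diff(range(vals)) < 1e-9) {
      threshold <- 0.5
      low_confidence <- TRUE
    } else {
      threshold <- otsu_threshold(vals)
    }
  } else {
    stop_unless_positive(threshold, "threshold")
  }
  leaf_fraction <- mean(vals < threshold)
  roi_radius_m <- img$roi_radius_px * img$scale
  structure(list(leaf_fraction = leaf_fraction,
                 s = leaf_fraction * pi * roi_radius_m^2,
                 threshold_used = threshold,
                 roi_radius_m = roi_radius_m,
                 low_confidence = low_confidence),
            class = "windward_area_estimate")
}

#' @export
print.windward_area_estimate <- function(x, ...) {
  cat(sprintf(
    "<windward_area_estimate> leaf fraction %.3f | s = %.4g m^2 | thr %.3f%s\n",
    x$leaf_fraction, x$s, x$threshold_used,
    if (x$low_confidence) " (low confidence)" else ""))
  invisible(x)
}

#' Windward area per unit volume from an image-based estimate
#'
#' Converts a [estimate_windward_area()] result to T = s / (pi R^2 D'),
#' after checking that the metric ROI radius agrees with the jet geometry
#' within 1% — a mismatch indicates a mis-calibrated image scale.
#'
#' @param est A `windward_area_estimate`.
#' @param jet A [jet_geometry()].
#' @param d_prime Branch-leaf section thickness, m.
#' @return T in m^2/m^3 (0 when no leaf pixels were found).
#' @export
area_to_T <- function(est, jet, d_prime) {
  stopifnot(inherits(est, "windward_area_estimate"),
            inherits(jet, "jet_geometry"))
  if (abs(est$roi_radius_m - jet$R) / jet$R > 0.01) {
    stop(sprintf(
      "calibration error: image ROI radius %.4g m vs jet radius %.4g m",
      est$roi_radius_m, jet$R), call. = FALSE)
  }
  if (est$s == 0) return(0)
  windward_area_per_volume(est$s, jet, d_prime)
}

#' Read a portable graymap (ASCII PGM, "P2") image
#'
#' Minimal reader for the plain-text PGM dialect used for the package's
#' fixtures and CLI; intensities are normalised to \[0, 1\] by the file's
#' maxval.
#'
#' @param path Path to a P2 PGM file.
#' @return Numeric intensity matrix in \[0, 1\].
#' @export
read_pgm <- function(path) {
  tokens <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (length(tokens) < 4L || tokens[1] != "P2") {
    stop("not an ASCII (P2) PGM file: ", path, call. = FALSE)
  }
  nc <- as.integer(tokens[2]); nr <- as.integer(tokens[3])
  maxval <- as.numeric(tokens[4])
  vals <- as.numeric(tokens[-(1:4)])
  if (length(vals) != nr * nc) {
    stop("PGM pixel count does not match header dimensions", call. = FALSE)
  }
  matrix(vals, nrow = nr, ncol = nc, byrow = TRUE) / maxval
}

#' Write a matrix as an ASCII PGM (P2) image
#'
#' @param pixels Numeric matrix of intensities in \[0, 1\].
#' @param path Output path.
#' @param maxval Maximum gray value, default 255.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(pixels, path, maxval = 255L) {
  stopifnot(is.matrix(pixels), all(pixels >= 0), all(pixels <= 1))
  q <- round(t(pixels) * maxval)  # PGM is row-major
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(pixels), nrow(pixels)),
               as.character(maxval)), con)
  write(q, con, ncolumns = 16L)
  invisible(path)
}
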