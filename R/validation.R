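#' Score a single theoretical/experimental velocity pair
#'
#' Absolute error and per-point model accuracy:
#' \deqn{v_w = |v_2 - v_1|, \qquad I = (1 - v_w / v_1) \times 100\%}
#' where `v1` is the theoretical and `v2` the experimental velocity. The
#' accuracy divides by the theoretical value and is reported as computed —
#' it goes negative when the error exceeds `v1` (no clamping).
#'
#' @param v1 Theoretical velocity, m/s (strictly positive).
#' @param v2 Experimental velocity, m/s (non-negative).
#' @param y Optional depth the pair belongs to, m.
#' @return A one-row data frame with columns `y`, `v1`, `v2`, `v_w` and
#'   `accuracy_I` (percent).
#' @examples
#' score_point(v1 = 2.0, v2 = 1.5)
#' @export
score_point <- function(v1, v2, y = NA_real_) {
  if (!is.numeric(v1) || length(v1) != 1L || !is.finite(v1) || v1 <= 0) {
    stop("`v1` must be strictly positive (accuracy is undefined at v1 <= 0)",
         call. = FALSE)
  }
  stop_unless_nonnegative(v2, "v2")
  v_w <- abs(v2 - v1)
  data.frame(y = y, v1 = v1, v2 = v2, v_w = v_w,
             accuracy_I = (1 - v_w / v1) * 100)
}

#' Score a theoretical against an experimental velocity profile
#'
#' Computes per-depth error records, their mean accuracy, the error range,
#' the squared Pearson correlation between the two series, and the mean
#' relative error. Both profiles must share an identical depth grid.
#'
#' @param theoretical,experimental `velocity_profile` objects (or data
#'   frames with columns `depth` and `velocity`) on the same depth grid.
#' @return A `validation_report`: list with `records` (data frame),
#'   `mean_accuracy` (%), `error_range` (min/max of v_w, m/s), `r_squared`,
#'   and `mean_relative_error` (%).
#' @export
score_profiles <- function(theoretical, experimental) {
  th <- as.data.frame(theoretical)
  ex <- as.data.frame(experimental)
  if (!all(c("depth", "velocity") %in% names(th)) ||
      !all(c("depth", "velocity") %in% names(ex))) {
    stop("profiles need columns `depth` and `velocity`", call. = FALSE)
  }
  if (nrow(th) != nrow(ex) ||
      any(abs(th$depth - ex$depth) > 1e-9)) {
    stop("depth grids of the two profiles do not align", call. = FALSE)
  }
  records <- do.call(rbind, Map(score_point, th$velocity, ex$velocity,
                                th$depth))
  r2 <- if (nrow(records) >= 2L &&
            stats::sd(th$velocity) > 0 && stats::sd(ex$velocity) > 0) {
    stats::cor(th$velocity, ex$velocity)^2
  } else if (all(records$v_w == 0)) 1 else NA_real_
  structure(list(
    records = records,
    mean_accuracy = mean(records$accuracy_I),
    error_range = c(min = min(records$v_w), max = max(records$v_w)),
    r_squared = r2,
    mean_relative_error = mean_relative_error(th$velocity, ex$velocity)
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    paste0("<validation_report> %d points | mean accuracy %.1f%% | ",
           "error range %.3f-%.3f m/s | R^2 %s\n"),
    nrow(x$records), x$mean_accuracy, x$error_range[["min"]],
    x$error_range[["max"]],
    if (is.na(x$r_squared)) "NA" else sprintf("%.3f", x$r_squared)))
  invisible(x)
}

#' Mean relative error between two velocity series
#'
#' Mean of `|a - b| / a * 100` over positions, with `series_a` as the
#' (strictly positive) reference.
#'
#' @param series_a Reference velocities, m/s (strictly positive).
#' @param series_b Comparison velocities, m/s.
#' @return Mean relative error in percent.
#' @export
mean_relative_error <- function(series_a, series_b) {
  if (length(series_a) != length(series_b)) {
    stop("series must have equal length", call. = FALSE)
  }
  if (any(!is.finite(series_a)) || any(series_a <= 0)) {
    stop("reference series must be strictly positive", call. = FALSE)
  }
  mean(abs(series_a - series_b) / series_a) * 100
}

#' Aggregate several validation reports
#'
#' Two aggregation conventions for a mean accuracy over multiple measurement
#' conditions: `"pooled"` averages every record of every report with equal
#' weight; `"by_condition"` first averages within each report, then averages
#' the per-report means.
#'
#' @param reports List of `validation_report` objects.
#' @param mode `"pooled"` or `"by_condition"`.
#' @return Mean accuracy in percent.
#' @export
aggregate_accuracy <- function(reports, mode = c("pooled", "by_condition")) {
  mode <- match.arg(mode)
  stopifnot(length(reports) > 0L,
            all(vapply(reports, inherits, TRUE, "validation_report")))
  if (mode == "pooled") {
    mean(unlist(lapply(reports, function(r) r$records$accuracy_I)))
  } else {
    mean(vapply(reports, function(r) r$mean_accuracy, numeric(1)))
  }
}
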