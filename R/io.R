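campaign_columns <- c("leaf_area_density", "v_star", "force_N", "s_m2",
                      "R_m", "D_m", "D_prime_m")

#' Read a drag-measurement campaign CSV
#'
#' Comma-separated, dot decimal, UTF-8, header required. Expected columns:
#' `leaf_area_density`, `v_star`, `force_N`, `s_m2`, `R_m`, `D_m`,
#' `D_prime_m` — one row per (density, velocity) condition. Parse errors
#' name the offending row and column.
#'
#' @param path Path to the CSV file.
#' @return Data frame with the campaign columns.
#' @examples
#' path <- system.file("extdata", "pear_campaign.csv", package = "canopyair")
#' head(read_campaign_csv(path))
#' @export
read_campaign_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  missing <- setdiff(campaign_columns, names(df))
  if (length(missing) > 0L) {
    stop("campaign CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) stop("campaign CSV has no rows", call. = FALSE)
  for (col in campaign_columns) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric value in column `%s`, row %d", col, bad[1]),
           call. = FALSE)
    }
    df[[col]] <- v
  }
  df[campaign_columns]
}

#' Write a campaign data frame to CSV
#'
#' @param campaign Data frame with the campaign columns (see
#'   [read_campaign_csv()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_campaign_csv <- function(campaign, path) {
  stopifnot(all(campaign_columns %in% names(campaign)))
  utils::write.csv(campaign[campaign_columns], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Fit the attenuation factor for every row of a campaign
#'
#' Runs [solve_k()] on each (density, velocity, drag) row. Rows whose
#' measured drag is infeasible under the model (at or above the
#' zero-attenuation supremum) are reported rather than fitted.
#'
#' @param campaign Campaign data frame (see [read_campaign_csv()]).
#' @param air An [air_properties()] object.
#' @param tol Relative force tolerance passed to [solve_k()].
#' @return A `campaign_fit`: list with `fits` (data frame adding `k` and
#'   `residual` to the campaign columns) and `infeasible` (data frame with
#'   the offending rows and messages; zero rows when all fits succeed).
#' @export
fit_campaign <- function(campaign, air = air_properties(), tol = 1e-10) {
  stopifnot(is.data.frame(campaign),
            all(campaign_columns %in% names(campaign)))
  fits <- campaign
  fits$k <- NA_real_
  fits$residual <- NA_real_
  bad <- list()
  for (i in seq_len(nrow(campaign))) {
    row <- campaign[i, ]
    layer <- canopy_layer(row$leaf_area_density, row$s_m2, row$D_m,
                          row$D_prime_m)
    fit <- tryCatch(
      solve_k(row$force_N, layer, row$v_star, air, tol = tol),
      error = function(e) e)
    if (inherits(fit, "error")) {
      bad[[length(bad) + 1L]] <- data.frame(
        row = i, leaf_area_density = row$leaf_area_density,
        v_star = row$v_star, force_N = row$force_N,
        message = conditionMessage(fit))
    } else {
      fits$k[i] <- fit$k
      fits$residual[i] <- fit$residual
    }
  }
  infeasible <- if (length(bad) > 0L) do.call(rbind, bad) else
    data.frame(row = integer(), leaf_area_density = numeric(),
               v_star = numeric(), force_N = numeric(),
               message = character())
  structure(list(fits = fits, infeasible = infeasible),
            class = "campaign_fit")
}

#' Serialise a campaign fit (plus optional deformation model) to JSON
#'
#' @param fit A `campaign_fit` from [fit_campaign()].
#' @param path Output path.
#' @param air The [air_properties()] used for the fits.
#' @param windward_model Optional `dynamic_windward_model` to embed.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(fit, path, air = air_properties(),
                             windward_model = NULL) {
  stopifnot(inherits(fit, "campaign_fit"))
  obj <- list(
    air = list(rho = air$rho, c_d = air$c_d),
    geometry = list(R = fit$fits$R_m[1], D = fit$fits$D_m[1],
                    D_prime = fit$fits$D_prime_m[1]),
    fits = fit$fits[c("leaf_area_density", "v_star", "s_m2", "force_N",
                      "k", "residual")]
  )
  if (!is.null(windward_model)) {
    obj$windward_model <- list(
      s0 = windward_model$s0,
      v_sat = windward_model$v_sat,
      s_min = windward_model$s_min,
      anchor_points = windward_model$anchor_points)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read a fitted-model JSON written by [write_model_json()]
#'
#' @param path Path to the JSON file.
#' @return A list with `air`, `geometry`, `fits` (data frame) and, when
#'   present, the reconstructed `windward_model`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$windward_model)) {
    wm <- obj$windward_model
    obj$windward_model <- fit_dynamic_windward(
      as.data.frame(wm$anchor_points), s0 = wm$s0, v_sat_hint = wm$v_sat)
  }
  obj
}

#' Write a validation report to JSON and/or flat CSV
#'
#' @param report A `validation_report` from [score_profiles()].
#' @param json_path,csv_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, the list of paths written.
#' @export
write_validation_report <- function(report, json_path = NULL,
                                    csv_path = NULL) {
  stopifnot(inherits(report, "validation_report"))
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      mean_accuracy = report$mean_accuracy,
      error_range = as.list(report$error_range),
      r_squared = report$r_squared,
      mean_relative_error = report$mean_relative_error,
      records = report$records
    ), json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  if (!is.null(csv_path)) {
    utils::write.csv(report$records, csv_path, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(list(json = json_path, csv = csv_path))
}
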