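#' Read the pit-count and colony CSV tables
#'
#' Schema-validated readers for the two pipeline inputs.  Violations are
#' reported with row numbers.
#'
#' @param path CSV file path.
#' @return Validated data.frame.
#' @export
read_pit_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("dilution", "field_id", "count")
  if (!all(need %in% names(df)))
    stop("pit table must have columns: ", paste(need, collapse = ", "))
  bad <- which(!is.finite(df$count) | df$count < 0 |
                 df$count != round(df$count))
  if (length(bad))
    stop("pit table: non-negative integer `count` required at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!is.finite(df$dilution) | df$dilution < 0 | df$dilution > 1)
  if (length(bad))
    stop("pit table: `dilution` outside [0, 1] at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  df
}

#' @rdname read_pit_table
#' @export
read_colony_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("dilution", "plated", "colonies")
  if (!all(need %in% names(df)))
    stop("colony table must have columns: ", paste(need, collapse = ", "))
  bad <- which(!is.finite(df$plated) | df$plated <= 0)
  if (length(bad))
    stop("colony table: positive `plated` required at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!is.finite(df$colonies) | df$colonies < 0 |
                 df$colonies > df$plated)
  if (length(bad))
    stop("colony table: `colonies` outside [0, plated] at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  df
}

#' End-to-end dilution-series analysis
#'
#' Ties the stages together the way the bench analysis proceeds:
#' (1) origin-constrained linear calibration of per-field pit counts
#' against dilution; (2) conversion of the fitted pit density into mean
#' detected pits per nucleus (pit areal density times nucleus area);
#' (3) Monte-Carlo pit-to-hit and pit-to-dose conversion per dilution;
#' (4) plating efficiency from the sham (dilution 0) limb of the colony
#' table (or as supplied); (5) surviving fractions per dilution from
#' pooled colony counts; (6) origin-constrained exponential survival fit
#' on the dose axis, yielding the slope `k`, `D0 = 1/k`, and the average
#' dose rate of the exposure.
#'
#' @param pit_table data.frame (`dilution`, `field_id`, `count`).
#' @param colony_table data.frame (`dilution`, `plated`, `colonies`).
#' @param conversion a [dose_per_detected_pit()] conversion.
#' @param nucleus_area nucleus footprint area, um^2.
#' @param field_area observation-field area, um^2.
#' @param exposure_min exposure duration in minutes (default 24 h).
#' @param plating_efficiency control plating efficiency; required when
#'   the colony table has no dilution-0 rows.
#' @return Object of class `pipeline_report`.
#' @export
run_full_pipeline <- function(pit_table, colony_table, conversion,
                              nucleus_area = 280, field_area = 98826,
                              exposure_min = 1440,
                              plating_efficiency = NULL) {
  stopifnot(inherits(conversion, "dose_conversion"))
  exposed <- pit_table[pit_table$dilution > 0, , drop = FALSE]
  calib <- fit_linear_calibration(
    data.frame(dilution = exposed$dilution, response = exposed$count),
    through_origin = TRUE, field_area = field_area)
  if (calib$slope <= 0)
    stop("calibration slope is not positive; ",
         "pit counts carry no dilution signal to convert")

  if (is.null(plating_efficiency)) {
    sham <- colony_table[colony_table$dilution == 0, , drop = FALSE]
    if (nrow(sham) == 0L)
      stop("no sham (dilution 0) colony rows; supply `plating_efficiency`")
    plating_efficiency <- sum(sham$colonies) / sum(sham$plated)
  }

  dils <- sort(unique(colony_table$dilution[colony_table$dilution > 0]),
               decreasing = TRUE)
  per <- lapply(dils, function(d) {
    pits_nuc <- predict_calibration(calib, d) / field_area * nucleus_area
    hd <- pits_to_hits_and_dose(pits_nuc, conversion)
    rows <- colony_table[colony_table$dilution == d, , drop = FALSE]
    sf <- colony_survival(sum(rows$plated), sum(rows$colonies),
                          plating_efficiency)
    data.frame(dilution = d, pits_per_nucleus = pits_nuc,
               hits_per_nucleus = hd$hits, hits_sd = hd$hits_sd,
               dose_Gy = hd$dose_Gy, dose_sd = hd$dose_sd,
               dose_rate_Gy_min = hd$dose_Gy / exposure_min,
               sf = sf$sf, sf_se = sf$sf_se)
  })
  per <- do.call(rbind, per)
  fit <- fit_exponential_survival(
    data.frame(dose = per$dose_Gy, sf = per$sf, sd = per$sf_se))
  per$sf_predicted <- predict_sf(fit, per$dose_Gy)

  structure(list(calibration = calib, conversion = conversion,
                 plating_efficiency = plating_efficiency,
                 per_dilution = per, survival_fit = fit,
                 k = fit$k, D0_Gy = fit$D0,
                 nucleus_area = nucleus_area, field_area = field_area,
                 exposure_min = exposure_min),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  calibration slope %.4g pits/field per unit dilution (r2 = %.3f)\n",
              x$calibration$slope, x$calibration$r2))
  cat(sprintf("  plating efficiency %.3f\n", x$plating_efficiency))
  print(x$per_dilution, row.names = FALSE, digits = 4)
  cat(sprintf("  SF = exp(-%.3f D): D0 = %.3g Gy (r2 = %.2f on log scale)\n",
              x$k, x$D0_Gy, x$survival_fit$r2))
  invisible(x)
}

#' Write a pipeline report as JSON (plus fitted-curve CSV)
#'
#' @param report a `pipeline_report`.
#' @param path output JSON path; a sibling `<path>_curve.csv` with the
#'   fitted survival curve is written alongside.
#' @return `path`, invisibly.
#' @export
write_pipeline_report <- function(report, path) {
  stopifnot(inherits(report, "pipeline_report"))
  fit <- report$survival_fit
  out <- list(
    calibration = list(slope = report$calibration$slope,
                       slope_se = report$calibration$slope_se,
                       intercept = report$calibration$intercept,
                       r2 = report$calibration$r2),
    conversion = list(dose_per_pit_Gy = report$conversion$dose_per_pit_Gy,
                      dose_per_pit_se = report$conversion$dose_per_pit_se,
                      hits_per_pit = report$conversion$hits_per_pit,
                      hits_per_pit_se = report$conversion$hits_per_pit_se),
    plating_efficiency = report$plating_efficiency,
    per_dilution = report$per_dilution,
    survival = list(k_per_Gy = fit$k, k_se = fit$k_se,
                    k_ci95 = fit$k_ci, D0_Gy = fit$D0,
                    D0_ci95 = fit$D0_ci, r2_log = fit$r2),
    package_version = as.character(utils::packageVersion("alphadosim")))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  dmax <- max(report$per_dilution$dose_Gy)
  curve <- data.frame(dose_Gy = seq(0, dmax * 1.05, length.out = 101))
  curve$sf <- predict_sf(fit, curve$dose_Gy)
  utils::write.csv(curve, sub("\\.json$", "_curve.csv", path),
                   row.names = FALSE)
  invisible(path)
}
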