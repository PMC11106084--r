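#' Linear dilution calibration
#'
#' Least-squares fit of a response (etch pits per field, mean gammaH2AX
#' foci per nucleus, percent positive cells, ...) against the daughter
#' medium dilution factor.  The default is origin-constrained (zero
#' activity implies zero excess response, matching the sham-source
#' result); `r2` is reported as the squared Pearson correlation between
#' observed and fitted responses, which lies in \[0, 1\] for either form.
#'
#' @param pairs data.frame with columns `dilution` (in (0, 1\]) and
#'   `response`; replicate rows per dilution are welcome.
#' @param through_origin constrain the intercept to zero (default TRUE).
#' @param field_area observation-field area, um^2, carried as metadata
#'   for pit-count calibrations (default 98826).
#' @return Object of class `dilution_calibration` with `slope`,
#'   `intercept`, `r2`, `n`, and the underlying `lm` fit.
#' @export
fit_linear_calibration <- function(pairs, through_origin = TRUE,
                                   field_area = 98826) {
  stopifnot(is.data.frame(pairs),
            all(c("dilution", "response") %in% names(pairs)))
  if (any(pairs$dilution <= 0 | pairs$dilution > 1))
    stop("dilutions must lie in (0, 1]")
  if (length(unique(pairs$dilution)) < 3L)
    stop("need at least 3 distinct dilutions")
  if (stats::var(pairs$dilution) == 0)
    stop("zero variance in dilutions")
  fit <- if (through_origin) stats::lm(response ~ 0 + dilution, data = pairs)
         else stats::lm(response ~ dilution, data = pairs)
  co <- stats::coef(fit)
  slope <- unname(co[["dilution"]])
  intercept <- if (through_origin) 0 else unname(co[["(Intercept)"]])
  fitted <- stats::fitted(fit)
  r2 <- if (stats::sd(fitted) == 0 || stats::sd(pairs$response) == 0) NA_real_
        else stats::cor(pairs$response, fitted)^2
  # noiseless inputs give a zero-residual fit; the SE is then just 0
  slope_se <- suppressWarnings(
    unname(sqrt(diag(stats::vcov(fit)))[["dilution"]]))
  structure(list(slope = slope, slope_se = slope_se,
                 intercept = intercept, r2 = r2,
                 n = nrow(pairs), through_origin = through_origin,
                 field_area = field_area, fit = fit),
            class = "dilution_calibration")
}

#' @export
print.dilution_calibration <- function(x, ...) {
  cat(sprintf(
    "<dilution_calibration> slope %.4g +/- %.2g, intercept %.4g, r2 = %.3f (n = %d)\n",
    x$slope, x$slope_se, x$intercept, x$r2, x$n))
  invisible(x)
}

#' Predicted response of a dilution calibration
#'
#' @param calib a `dilution_calibration`.
#' @param dilution dilution factor(s).
#' @return Predicted response(s) from the fitted line.
#' @export
predict_calibration <- function(calib, dilution) {
  stopifnot(inherits(calib, "dilution_calibration"))
  calib$intercept + calib$slope * dilution
}

#' Convert detected pits per nucleus into hits and dose
#'
#' Scales a measured mean etch-pit count per nucleus by the Monte-Carlo
#' hit-to-pit ratio and dose-per-pit conversion; relative errors combine
#' in quadrature (first-order delta method).
#'
#' @param mean_pits mean detected pits per nucleus (`>= 0`).
#' @param conv a [dose_per_detected_pit()] conversion.
#' @param pits_sd optional SD of the measured mean (default 0).
#' @return data.frame with `hits`, `hits_sd`, `dose_Gy`, `dose_sd`.
#' @export
pits_to_hits_and_dose <- function(mean_pits, conv, pits_sd = 0) {
  stopifnot(inherits(conv, "dose_conversion"))
  if (any(mean_pits < 0)) stop("mean pit count must be >= 0")
  rel_p <- ifelse(mean_pits > 0, pits_sd / mean_pits, 0)
  hits <- mean_pits * conv$hits_per_pit
  hits_sd <- hits * sqrt(rel_p^2 +
                           (conv$hits_per_pit_se / conv$hits_per_pit)^2)
  dose <- mean_pits * conv$dose_per_pit_Gy
  dose_sd <- dose * sqrt(rel_p^2 +
                           (conv$dose_per_pit_se / conv$dose_per_pit_Gy)^2)
  data.frame(hits = hits, hits_sd = hits_sd,
             dose_Gy = dose, dose_sd = dose_sd)
}

#' Exponential (shoulderless) clonogenic survival fit
#'
#' Regression of `ln SF` on dose, constrained through `SF(0) = 1`: the
#' one-parameter pure-exponential survival curve `SF = exp(-k D)` typical
#' of high-LET alpha exposures.  `D0 = 1/k` is the mean lethal dose (the
#' dose reducing survival to 1/e).  The fit is unweighted by default; a
#' weighted variant (inverse delta-method variances of ln SF from the
#' supplied SDs) is available behind a flag.
#'
#' @param points data.frame with columns `dose` (Gy) and `sf` in (0, 1\];
#'   optional `sd` column (SD of `sf`) used when `weighted = TRUE`.
#' @param weighted use weights `(sf/sd)^2` on the log scale.
#' @return Object of class `survival_fit` with `k` (1/Gy), `k_se`,
#'   `k_ci` (95%), `D0` (Gy), `D0_ci`, and `r2` on the log scale.
#' @export
fit_exponential_survival <- function(points, weighted = FALSE) {
  stopifnot(is.data.frame(points),
            all(c("dose", "sf") %in% names(points)))
  if (any(points$sf <= 0)) stop("all surviving fractions must be > 0")
  if (any(points$sf > 1 + 1e-12)) stop("surviving fractions must be <= 1")
  if (any(points$dose < 0)) stop("doses must be >= 0")
  if (nrow(points) < 3L) stop("need at least 3 survival points")
  if (stats::var(points$dose) == 0) stop("all doses identical")
  df <- data.frame(dose = points$dose, lsf = log(points$sf))
  w <- NULL
  if (weighted) {
    if (is.null(points$sd)) stop("weighted fit needs an `sd` column")
    w <- (points$sf / points$sd)^2
  }
  fit <- stats::lm(lsf ~ 0 + dose, data = df, weights = w)
  k <- -unname(stats::coef(fit)[["dose"]])
  if (k <= 0)
    warning("fitted survival slope is non-positive; D0 undefined")
  k_se <- suppressWarnings(unname(sqrt(diag(stats::vcov(fit)))[["dose"]]))
  ci <- suppressWarnings(-rev(unname(stats::confint(fit)["dose", ])))
  r2 <- stats::cor(df$lsf, df$dose)^2
  structure(list(k = k, k_se = k_se, k_ci = ci,
                 D0 = 1 / k, D0_ci = rev(1 / ci), r2 = r2,
                 n = nrow(points), weighted = weighted, fit = fit),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf(
    "<survival_fit> SF = exp(-%.3f D); D0 = %.3g Gy (95%% CI %.3g-%.3g), r2 = %.2f\n",
    x$k, x$D0, x$D0_ci[1], x$D0_ci[2], x$r2))
  invisible(x)
}

#' Predicted surviving fraction
#'
#' @param fit a `survival_fit`, or directly a numeric slope `k` (1/Gy).
#' @param dose dose(s) in Gy, `>= 0`.
#' @return `exp(-k * dose)`.
#' @export
predict_sf <- function(fit, dose) {
  k <- if (inherits(fit, "survival_fit")) fit$k else fit
  stopifnot(is.numeric(k), length(k) == 1L)
  if (any(dose < 0)) stop("dose must be >= 0")
  exp(-k * dose)
}

#' Average dose rate of an exposure
#'
#' @param total_dose_Gy total absorbed dose, Gy.
#' @param duration_min exposure duration, minutes (> 0).
#' @return Average dose rate, Gy/min.
#' @export
average_dose_rate <- function(total_dose_Gy, duration_min) {
  if (any(duration_min <= 0)) stop("duration must be positive")
  total_dose_Gy / duration_min
}

#' Surviving fraction from a colony-formation assay
#'
#' `SF = (colonies / plated) / plating_efficiency`, with a binomial
#' standard error attached.  Vectorized over dishes.
#'
#' @param plated cells plated per dish (> 0).
#' @param colonies colonies scored (`<= plated`).
#' @param plating_efficiency control plating efficiency in (0, 1\].
#' @return data.frame with `sf` and `sf_se`.
#' @export
colony_survival <- function(plated, colonies, plating_efficiency) {
  if (any(plated <= 0)) stop("zero cells plated")
  if (any(plating_efficiency <= 0 | plating_efficiency > 1))
    stop("plating efficiency must lie in (0, 1]")
  if (any(colonies < 0) || any(colonies > plated))
    stop("colonies must lie in [0, plated]")
  p <- colonies / plated
  data.frame(sf = p / plating_efficiency,
             sf_se = sqrt(p * (1 - p) / plated) / plating_efficiency)
}
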