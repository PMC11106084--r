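#' Truth parameters for a synthetic daughter-medium experiment
#'
#' Bundles the generative parameters of a synthetic experiment: the
#' (unknown in reality, known here) alpha-decay density of the undiluted
#' medium over the exposure window, the dilution series, nucleus-area
#' distribution, the per-hit focus yield, the dose conversion, the true
#' mean lethal dose, and the assay sizes.
#'
#' @param dm_1x_alpha_density alpha decays per cm^3 delivered by the 1x
#'   medium over the exposure.
#' @param dilutions dilution factors in (0, 1].
#' @param nucleus_area_mean,nucleus_area_sd nucleus footprint area, um^2.
#' @param foci_per_hit gammaH2AX foci induced per nucleus hit.
#' @param hit_to_pit_ratio true hits per detected pit.
#' @param dose_per_pit_Gy true absorbed dose per detected pit, Gy.
#' @param D0_true true mean lethal dose, Gy.
#' @param plating_efficiency control plating efficiency in (0, 1].
#' @param pit_rate_um effective registered-pit yield per unit decay
#'   density per unit area: pit areal density = density * pit_rate_um
#'   (units um; equals mean alpha range x registered fraction / 4 for a
#'   thick uniform slab).
#' @param field_area observation-field area, um^2.
#' @param n_fields,n_nuclei,n_dishes replicates per dilution.
#' @param include_sham add a dilution-0 (sham) limb.
#' @param foci_dispersion optional negative-binomial size parameter for
#'   over-dispersed focus counts; `NULL` gives Poisson counts.
#' @param seed default seed used by [generate_experiment()].
#' @return Object of class `truth_params`.
#' @export
truth_params <- function(dm_1x_alpha_density,
                         dilutions = c(1, 1/2, 1/4, 1/8),
                         nucleus_area_mean = 280, nucleus_area_sd = 39,
                         foci_per_hit = 3.0, hit_to_pit_ratio = 47.2 / (3 * 4.7),
                         dose_per_pit_Gy = 1.10 / 4.7,
                         D0_true = 1 / 5.09,
                         plating_efficiency = 0.7,
                         pit_rate_um = NULL,
                         field_area = 98826,
                         n_fields = 5, n_nuclei = 50, n_dishes = 3,
                         include_sham = TRUE, foci_dispersion = NULL,
                         seed = 1L) {
  if (is.null(pit_rate_um)) pit_rate_um <- .default_pit_rate_um()
  vals <- c(dm_1x_alpha_density, nucleus_area_mean, nucleus_area_sd,
            foci_per_hit, hit_to_pit_ratio, dose_per_pit_Gy, D0_true,
            plating_efficiency, pit_rate_um, field_area,
            n_fields, n_nuclei, n_dishes)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all truth parameters must be positive and finite")
  if (any(dilutions <= 0 | dilutions > 1))
    stop("dilutions must lie in (0, 1]")
  if (plating_efficiency > 1) stop("plating efficiency must be <= 1")
  structure(list(dm_1x_alpha_density = dm_1x_alpha_density,
                 dilutions = sort(dilutions, decreasing = TRUE),
                 nucleus_area_mean = nucleus_area_mean,
                 nucleus_area_sd = nucleus_area_sd,
                 foci_per_hit = foci_per_hit,
                 hit_to_pit_ratio = hit_to_pit_ratio,
                 dose_per_pit_Gy = dose_per_pit_Gy,
                 D0_true = D0_true,
                 plating_efficiency = plating_efficiency,
                 pit_rate_um = pit_rate_um,
                 field_area = field_area,
                 n_fields = n_fields, n_nuclei = n_nuclei,
                 n_dishes = n_dishes,
                 include_sham = isTRUE(include_sham),
                 foci_dispersion = foci_dispersion,
                 seed = seed),
            class = "truth_params")
}

# Registered-pit yield per unit decay density and unit area for a thick
# uniform slab under the default registration model: mean range x
# registered fraction / 4 (one-sided plane crossings are density x
# mean-range / 4 per area).
.default_pit_rate_um <- function(model = registration_model()) {
  inv <- dm_alpha_inventory(1, 1, 1)   # only the spectrum is used
  rbar <- sum(range_in_water(inv$spectrum$energy_MeV) *
                inv$spectrum$fraction)
  f_reg <- 1 - sin(model$critical_dip_angle * pi / 180)^2
  rbar * f_reg / 4
}

#' Reference-condition truth parameters
#'
#' Truth parameters anchored to the reference 24-h exposure conditions:
#' the 1x decay density is set so the 1/2x limb yields a mean of 4.7
#' detected pits per nucleus (of mean area 280 um^2), the focus yield is
#' set so the same limb yields a mean of 47.2 foci per nucleus (about
#' 10 foci per detected pit), and the dose conversion and D0 match the
#' fitted survival curve `SF = exp(-5.09 D)`.
#'
#' @param ... overrides passed on to [truth_params()].
#' @return A `truth_params` object.
#' @export
paper_like_defaults <- function(...) {
  pit_rate <- .default_pit_rate_um()
  # 1/2x limb: 0.5 * n_v * pit_rate * area = 4.7 pits/nucleus
  n_v_um3 <- 4.7 / (0.5 * pit_rate * 280)
  truth_params(dm_1x_alpha_density = n_v_um3 * 1e12, ...)
}

#' Generate a synthetic daughter-medium experiment
#'
#' Emulates the statistical structure of the dilution-series experiment:
#' per-field etch-pit counts are Poisson with mean linear in dilution;
#' per-nucleus focus counts are Poisson (or negative-binomial when
#' over-dispersion is requested) with mean proportional to the nucleus
#' hits; colony counts are binomial under a pure-exponential survival
#' curve with the stated plating efficiency.  A sham (dilution 0) limb
#' carries zero-mean pit counts and survival equal to the plating
#' efficiency.  Deterministic under a fixed seed.
#'
#' @param truth a [truth_params] object.
#' @param seed integer seed (defaults to `truth$seed`).
#' @return Object of class `synthetic_experiment` with `pit_table`
#'   (`dilution`, `field_id`, `count`), `foci_table` (`dilution`,
#'   `nucleus_id`, `focus_count`, `nucleus_area`), `colony_table`
#'   (`dilution`, `dish_id`, `plated`, `colonies`) and the `truth` echo.
#' @export
generate_experiment <- function(truth, seed = truth$seed) {
  stopifnot(inherits(truth, "truth_params"))
  set.seed(seed)
  n_v <- truth$dm_1x_alpha_density * 1e-12    # decays per um^3
  dils <- truth$dilutions
  if (truth$include_sham) dils <- c(dils, 0)

  pit_rows <- list(); foci_rows <- list(); col_rows <- list()
  for (d in dils) {
    dens <- d * n_v
    # per-field pit counts over the observation field
    mu_field <- dens * truth$pit_rate_um * truth$field_area
    pit_rows[[length(pit_rows) + 1L]] <- data.frame(
      dilution = d, field_id = seq_len(truth$n_fields),
      count = stats::rpois(truth$n_fields, mu_field))
    # per-nucleus focus counts; nucleus areas vary
    area <- stats::rnorm(truth$n_nuclei, truth$nucleus_area_mean,
                         truth$nucleus_area_sd)
    area <- pmax(area, truth$nucleus_area_mean / 4)
    pits_nuc <- dens * truth$pit_rate_um * area
    mu_foci <- pits_nuc * truth$hit_to_pit_ratio * truth$foci_per_hit
    foci <- if (is.null(truth$foci_dispersion))
      stats::rpois(truth$n_nuclei, mu_foci)
    else
      stats::rnbinom(truth$n_nuclei, mu = mu_foci,
                     size = truth$foci_dispersion)
    foci_rows[[length(foci_rows) + 1L]] <- data.frame(
      dilution = d, nucleus_id = seq_len(truth$n_nuclei),
      focus_count = foci, nucleus_area = round(area, 2))
    # colony assay: dose through the pit -> dose conversion at mean area
    dose <- dens * truth$pit_rate_um * truth$nucleus_area_mean *
      truth$dose_per_pit_Gy
    p_col <- truth$plating_efficiency * exp(-dose / truth$D0_true)
    plated <- min(2e6, max(200, ceiling(300 / p_col)))
    col_rows[[length(col_rows) + 1L]] <- data.frame(
      dilution = d, dish_id = seq_len(truth$n_dishes),
      plated = plated,
      colonies = stats::rbinom(truth$n_dishes, plated, p_col))
  }
  structure(list(pit_table = do.call(rbind, pit_rows),
                 foci_table = do.call(rbind, foci_rows),
                 colony_table = do.call(rbind, col_rows),
                 truth = truth, seed = seed),
            class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat("<synthetic_experiment> seed", x$seed, "\n")
  agg <- stats::aggregate(count ~ dilution, x$pit_table, mean)
  cat("  mean pits/field by dilution:\n")
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Write / read a synthetic dataset as CSV tables plus a truth sidecar
#'
#' Writes `pit_table.csv`, `foci_table.csv`, `colony_table.csv` (the
#' exact schemas the pipeline readers expect) and `truth.json`.
#'
#' @param x a `synthetic_experiment`.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_synthetic_dataset <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(x$pit_table, file.path(dir, "pit_table.csv"),
                   row.names = FALSE)
  utils::write.csv(x$foci_table, file.path(dir, "foci_table.csv"),
                   row.names = FALSE)
  utils::write.csv(x$colony_table, file.path(dir, "colony_table.csv"),
                   row.names = FALSE)
  truth <- x$truth
  class(truth) <- NULL
  truth$foci_dispersion <- truth$foci_dispersion %||% NA
  jsonlite::write_json(c(truth, list(seed_used = x$seed)),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
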