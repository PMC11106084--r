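#' Monolayer / CR-39 slab geometry
#'
#' The model geometry: a water-equivalent medium slab occupying
#' `0 <= z <= medium_depth`, the CR-39 detector at the plane `z = 0`, and
#' the cell nucleus modeled as a right circular cylinder of footprint
#' area `nucleus_area` and height `nucleus_thickness`, with its base at
#' `z = nucleus_z_offset` (0 = resting on the detector plane, the
#' monolayer case) and axis at `x = y = 0`.  The lateral extent of the
#' medium is effectively infinite (emitters are sampled over a box wide
#' enough that no track from outside can reach the nucleus).
#'
#' @param medium_depth slab depth, um (default 2000; a warning is issued
#'   at simulation time if it does not exceed the maximum alpha range).
#' @param nucleus_area nucleus footprint area, um^2 (default 280).
#' @param nucleus_thickness nucleus height, um.  The default (5.25) is a
#'   model calibration: it is the one free knob of the geometry and is
#'   set so that the simulated hit-to-pit ratio and absorbed dose at the
#'   measured pit count reproduce the reference analysis (see the
#'   methods vignette).
#' @param nucleus_z_offset height of the nucleus base above the detector
#'   plane, um (default 0).
#' @param lateral_margin extra half-width added to the lateral sampling
#'   box beyond `nucleus_radius + max_range`, um.
#' @return Object of class `geometry_config`.
#' @export
geometry_config <- function(medium_depth = 2000, nucleus_area = 280,
                            nucleus_thickness = 5.25, nucleus_z_offset = 0,
                            lateral_margin = 1) {
  stopifnot(medium_depth > 0, nucleus_area > 0, nucleus_thickness > 0,
            nucleus_z_offset >= 0, lateral_margin >= 0)
  if (nucleus_z_offset + nucleus_thickness > medium_depth)
    stop("nucleus does not fit inside the medium slab")
  structure(list(medium_depth = medium_depth,
                 nucleus_area = nucleus_area,
                 nucleus_radius = sqrt(nucleus_area / pi),
                 nucleus_thickness = nucleus_thickness,
                 nucleus_z_offset = nucleus_z_offset,
                 lateral_margin = lateral_margin),
            class = "geometry_config")
}

#' CR-39 etch-pit registration model
#'
#' The simplest solid-state nuclear track detector criterion: an alpha
#' arriving at the detector plane leaves a countable etch pit iff its dip
#' angle (the angle between the track and the detector surface) is at
#' least `critical_dip_angle`, optionally restricted to an arrival-energy
#' window.  For a thick uniform emitter slab, plane-crossing tracks have
#' `sin(dip)` distributed with density `2u` on \[0, 1\], so the expected
#' registered fraction is `1 - sin^2(critical_dip_angle)`.  The default
#' of 40 degrees puts that fraction at 0.59, inside the 50-60% efficiency
#' band reported for etched CR-39 (see the methods vignette for how this
#' default was fixed).
#'
#' @param critical_dip_angle degrees above the detector surface,
#'   `0 <= angle < 90`.
#' @param energy_window optional `c(E_min, E_max)` MeV at arrival.
#' @return Object of class `registration_model`.
#' @export
registration_model <- function(critical_dip_angle = 40,
                               energy_window = NULL) {
  stopifnot(critical_dip_angle >= 0, critical_dip_angle < 90)
  if (!is.null(energy_window)) {
    stopifnot(length(energy_window) == 2L,
              energy_window[1] >= 0, energy_window[2] > energy_window[1])
  }
  structure(list(critical_dip_angle = critical_dip_angle,
                 energy_window = energy_window),
            class = "registration_model")
}

# Relevant z-sampling intervals: decays above max_range of both the
# detector plane and the nucleus can neither register a pit nor hit the
# nucleus, so sampling is restricted to the union of the two relevant
# bands and all tallies are rescaled by the sampled length.  Returns a
# 2-column matrix of merged [lo, hi) intervals.
.relevant_z_intervals <- function(geom, max_range) {
  d <- geom$medium_depth
  iv <- rbind(
    c(0, min(d, max_range + 1)),
    c(max(0, geom$nucleus_z_offset - max_range - 1),
      min(d, geom$nucleus_z_offset + geom$nucleus_thickness + max_range + 1)))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  merged <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    k <- nrow(merged)
    if (iv[i, 1] <= merged[k, 2]) {
      merged[k, 2] <- max(merged[k, 2], iv[i, 2])
    } else merged <- rbind(merged, iv[i, , drop = FALSE])
  }
  merged
}

#' Sample alpha-decay events in the medium slab
#'
#' Decay positions are uniform in the slab volume (including the nucleus
#' interior -- emitters diffuse into the cell), emission directions are
#' isotropic on the sphere, and energies are drawn from the inventory
#' spectrum.  Reproducible under a fixed seed.
#'
#' @param inventory an `alpha_inventory` (only its `spectrum` is used).
#' @param geom a [geometry_config].
#' @param n number of decays to sample.
#' @param seed optional integer seed.
#' @param z_intervals optional 2-column matrix of `z` bands to restrict
#'   sampling to (importance device used internally by [run_microdose()];
#'   the default samples the full slab depth).
#' @return data.frame with origin (`x`, `y`, `z`, um), unit direction
#'   (`ux`, `uy`, `uz`), energy `E0` (MeV) and CSDA `range_um`.
#' @export
sample_decay_events <- function(inventory, geom, n, seed = NULL,
                                z_intervals = NULL) {
  stopifnot(inherits(geom, "geometry_config"), n > 0)
  sp <- inventory$spectrum
  if (is.null(sp) || nrow(sp) == 0L) stop("empty emission spectrum")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(z_intervals))
    z_intervals <- matrix(c(0, geom$medium_depth), nrow = 1)
  lens <- z_intervals[, 2] - z_intervals[, 1]
  band <- if (nrow(z_intervals) == 1L) rep(1L, n) else
    sample.int(nrow(z_intervals), n, replace = TRUE, prob = lens)
  z <- z_intervals[band, 1] + stats::runif(n) * lens[band]
  max_range <- max(range_in_water(sp$energy_MeV))
  L <- geom$nucleus_radius + max_range + geom$lateral_margin
  x <- stats::runif(n, -L, L)
  y <- stats::runif(n, -L, L)
  uz <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  rho <- sqrt(pmax(1 - uz^2, 0))
  ei <- sample.int(nrow(sp), n, replace = TRUE, prob = sp$fraction)
  E0 <- sp$energy_MeV[ei]
  data.frame(x = x, y = y, z = z,
             ux = rho * cos(phi), uy = rho * sin(phi), uz = uz,
             E0 = E0, range_um = range_in_water(E0))
}

#' Chord of a track through the nucleus cylinder
#'
#' Ray-cylinder intersection clipped to the track's residual range:
#' returns, per track, the entry and exit arc lengths of the nucleus
#' chord along the direction of flight, clipped to `[0, range]`.  A track
#' originating inside the nucleus has `s_entry = 0`; a "hit" is a clipped
#' interval of positive length.
#'
#' @param tracks data.frame as produced by [sample_decay_events()].
#' @param geom a [geometry_config].
#' @return data.frame with `s_entry`, `s_exit` (um) and logical `hit`.
#' @export
chord_through_nucleus <- function(tracks, geom) {
  stopifnot(inherits(geom, "geometry_config"))
  n <- nrow(tracks)
  r <- geom$nucleus_radius
  z0 <- geom$nucleus_z_offset
  z1 <- z0 + geom$nucleus_thickness
  big <- 1e12

  # lateral (infinite cylinder) interval: |(x,y) + s*(ux,uy)| <= r
  a <- tracks$ux^2 + tracks$uy^2
  b <- 2 * (tracks$x * tracks$ux + tracks$y * tracks$uy)
  cc <- tracks$x^2 + tracks$y^2 - r^2
  lat_lo <- rep(-big, n); lat_hi <- rep(big, n)
  vert <- a < 1e-14
  lat_lo[vert & cc > 0] <- big   # vertical ray outside footprint: empty
  lat_hi[vert & cc > 0] <- -big
  nv <- !vert
  disc <- b[nv]^2 - 4 * a[nv] * cc[nv]
  hitlat <- disc > 0
  sq <- sqrt(pmax(disc, 0))
  lo <- (-b[nv] - sq) / (2 * a[nv])
  hi <- (-b[nv] + sq) / (2 * a[nv])
  lat_lo[nv] <- ifelse(hitlat, lo, big)
  lat_hi[nv] <- ifelse(hitlat, hi, -big)

  # axial (slab z0..z1) interval
  ax_lo <- rep(-big, n); ax_hi <- rep(big, n)
  horiz <- abs(tracks$uz) < 1e-14
  inside_z <- tracks$z >= z0 & tracks$z <= z1
  ax_lo[horiz & !inside_z] <- big
  ax_hi[horiz & !inside_z] <- -big
  nh <- !horiz
  t1 <- (z0 - tracks$z[nh]) / tracks$uz[nh]
  t2 <- (z1 - tracks$z[nh]) / tracks$uz[nh]
  ax_lo[nh] <- pmin(t1, t2)
  ax_hi[nh] <- pmax(t1, t2)

  s_entry <- pmax(pmax(lat_lo, ax_lo), 0)
  s_exit <- pmin(pmin(lat_hi, ax_hi), tracks$range_um)
  hit <- s_exit > s_entry
  s_entry[!hit] <- NA_real_
  s_exit[!hit] <- NA_real_
  data.frame(s_entry = s_entry, s_exit = s_exit, hit = hit)
}

#' CR-39 registration decision for tracks reaching the detector
#'
#' A track reaches the detector if it moves downward (`uz < 0`) and its
#' residual range exceeds the path length to the plane `z = 0`.  Among
#' reaching tracks, it registers iff its dip angle is at least the model's
#' critical dip angle and (when set) its arrival energy lies inside the
#' energy window.  For tracks that never reach the plane the registration
#' decision is undefined (`NA`).
#'
#' @param tracks data.frame as produced by [sample_decay_events()].
#' @param model a [registration_model].
#' @return data.frame with logicals `reaches`, `registers`, and
#'   `arrival_energy_MeV`, `dip_deg` (NA for non-reaching tracks).
#' @export
cr39_registers <- function(tracks, model) {
  stopifnot(inherits(model, "registration_model"))
  s_det <- ifelse(tracks$uz < 0, -tracks$z / tracks$uz, Inf)
  reaches <- tracks$uz < 0 & s_det < tracks$range_um
  n <- nrow(tracks)
  arrival <- rep(NA_real_, n)
  dip <- rep(NA_real_, n)
  registers <- rep(NA, n)
  if (any(reaches)) {
    arrival[reaches] <- energy_after_pathlength(tracks$E0[reaches],
                                                s_det[reaches])
    dip[reaches] <- asin(pmin(-tracks$uz[reaches], 1)) * 180 / pi
    reg <- dip[reaches] >= model$critical_dip_angle
    if (!is.null(model$energy_window)) {
      reg <- reg & arrival[reaches] >= model$energy_window[1] &
        arrival[reaches] <= model$energy_window[2]
    }
    registers[reaches] <- reg
  }
  data.frame(reaches = reaches, registers = registers,
             arrival_energy_MeV = arrival, dip_deg = dip,
             s_det = ifelse(reaches, s_det, NA_real_))
}

#' Monte-Carlo microdosimetry of the monolayer exposure
#'
#' Transports `n_decays` straight-line alpha tracks from uniformly
#' distributed emitters through the slab geometry and tallies, per
#' nucleus and per unit decay density: (a) nucleus hits, including tracks
#' that stop inside the nucleus and upward-moving tracks; (b) detected
#' CR-39 pits, as pit areal density times the nucleus footprint area
#' (matching the merge of separately acquired pit and nucleus images),
#' with the direct within-footprint pit count as a cross-check; (c)
#' energy deposited in the nucleus per hit (entry energy minus exit
#' energy) and the absorbed dose at the stated decay density.
#'
#' Sampling is restricted to the `z` bands within one alpha range of the
#' detector plane or the nucleus (no other decay can contribute to any
#' tally) and all extensive tallies are rescaled accordingly, so results
#' are unbiased for the full slab.
#'
#' @param inventory an `alpha_inventory` (spectrum; `per_volume` supplies
#'   the default decay density).
#' @param geom a [geometry_config].
#' @param model a [registration_model].
#' @param n_decays number of sampled decays (>= 1e4 for meaningful
#'   standard errors; default 1e6).
#' @param seed optional integer seed; identical (config, seed) give
#'   identical tallies.
#' @param decay_density alpha decays per cm^3 of medium over the exposure
#'   (defaults to `inventory$per_volume`).
#' @param chunk_size decays per vectorized chunk.
#' @param keep_hits keep per-hit specific energies (default TRUE).
#' @return Object of class `microdose_tally`; see
#'   [dose_per_detected_pit()] for the derived pit-to-dose conversion.
#' @export
run_microdose <- function(inventory, geom = geometry_config(),
                          model = registration_model(),
                          n_decays = 1e6, seed = NULL,
                          decay_density = NULL, chunk_size = 1e6,
                          keep_hits = TRUE) {
  stopifnot(inherits(geom, "geometry_config"),
            inherits(model, "registration_model"), n_decays >= 1)
  if (is.null(decay_density)) decay_density <- inventory$per_volume
  if (is.null(decay_density) || !is.finite(decay_density) ||
      decay_density < 0)
    stop("`decay_density` (decays/cm^3) must be supplied")
  sp <- inventory$spectrum
  if (is.null(sp) || nrow(sp) == 0L) stop("empty emission spectrum")
  max_range <- max(range_in_water(sp$energy_MeV))
  if (geom$medium_depth <= max_range)
    warning("medium depth (", geom$medium_depth,
            " um) does not exceed the maximum alpha range (",
            round(max_range, 1), " um); the slab is not thick")
  if (!is.null(seed)) set.seed(seed)

  ziv <- .relevant_z_intervals(geom, max_range)
  L_z <- sum(ziv[, 2] - ziv[, 1])
  L <- geom$nucleus_radius + max_range + geom$lateral_margin
  A_box <- (2 * L)^2                     # um^2
  V_samp <- A_box * L_z                  # um^3
  n_v <- decay_density * 1e-12           # decays per um^3
  r2 <- geom$nucleus_radius^2

  n_hit <- 0; n_reach <- 0; n_reg <- 0; n_fp <- 0; n_hit_and_reg <- 0
  sum_edep <- 0; sum_edep2 <- 0
  edep_hits <- numeric(0)
  n_decays <- as.integer(round(n_decays))
  done <- 0L
  while (done < n_decays) {
    m <- min(chunk_size, n_decays - done)
    ev <- sample_decay_events(inventory, geom, m, z_intervals = ziv)
    ch <- chord_through_nucleus(ev, geom)
    hit <- ch$hit
    edep <- numeric(m)
    if (any(hit)) {
      e_in <- energy_after_pathlength(ev$E0[hit], ch$s_entry[hit])
      e_out <- energy_after_pathlength(ev$E0[hit], ch$s_exit[hit])
      edep[hit] <- e_in - e_out
    }
    rg <- cr39_registers(ev, model)
    reg <- !is.na(rg$registers) & rg$registers
    fp <- reg
    if (any(reg)) {
      xi <- ev$x[reg] + ev$ux[reg] * rg$s_det[reg]
      yi <- ev$y[reg] + ev$uy[reg] * rg$s_det[reg]
      fp[reg] <- xi^2 + yi^2 <= r2
    }
    n_hit <- n_hit + sum(hit)
    n_reach <- n_reach + sum(rg$reaches)
    n_reg <- n_reg + sum(reg)
    n_fp <- n_fp + sum(fp)
    n_hit_and_reg <- n_hit_and_reg + sum(hit & reg)
    sum_edep <- sum_edep + sum(edep)
    sum_edep2 <- sum_edep2 + sum(edep^2)
    if (keep_hits) edep_hits <- c(edep_hits, edep[hit])
    done <- done + m
  }
  n <- n_decays

  # scale factors: expected true decays represented by the sample
  scale_nuc <- n_v * V_samp / n          # per-nucleus extensive tallies
  p_hit <- n_hit / n
  p_reg <- n_reg / n
  hits_mean <- n_hit * scale_nuc
  hits_se <- sqrt(n_hit * (1 - p_hit)) * scale_nuc
  pit_density <- n_v * L_z * p_reg       # pits per um^2
  pits_mean <- pit_density * geom$nucleus_area
  pits_se <- sqrt(n_reg * (1 - p_reg)) / n * n_v * L_z * geom$nucleus_area
  pits_fp_mean <- n_fp * scale_nuc
  energy_mean <- sum_edep * scale_nuc    # MeV per nucleus
  energy_se <- sqrt(max(sum_edep2 - sum_edep^2 / n, 0)) * scale_nuc
  V_nuc <- geom$nucleus_area * geom$nucleus_thickness   # um^3
  mev_to_gy <- 1.602176634e-13 / (V_nuc * 1e-15)  # Gy per MeV in nucleus
  dose <- energy_mean * mev_to_gy
  dose_se <- energy_se * mev_to_gy

  ratio <- if (n_reg > 0) hits_mean / pits_mean else NA_real_
  ratio_se <- NA_real_
  if (n_reg > 0 && n_hit > 0) {
    cov_hr <- n_hit_and_reg / n - p_hit * p_reg
    relvar <- (p_hit * (1 - p_hit) / p_hit^2 +
               p_reg * (1 - p_reg) / p_reg^2 -
               2 * cov_hr / (p_hit * p_reg)) / n
    ratio_se <- ratio * sqrt(max(relvar, 0))
  }

  # per-exposure hit histogram by multinomial partition of the decay pool
  hist_hits <- NULL
  n_per_exposure <- n_v * V_samp
  if (keep_hits && n_per_exposure > 0 && n / n_per_exposure >= 10) {
    K <- floor(n / n_per_exposure)
    ids <- sample.int(K, n_hit, replace = TRUE)
    hist_hits <- tabulate(ids, nbins = K)
  }

  structure(list(
    n_decays = n, decay_density = decay_density,
    sampled_volume_um3 = V_samp, sampled_depth_um = L_z,
    hits_per_nucleus = list(mean = hits_mean, se = hits_se,
                            var = hits_mean,   # Poisson process of hits
                            histogram = hist_hits),
    pits_per_nucleus = list(mean = pits_mean, se = pits_se,
                            within_footprint = pits_fp_mean),
    pit_areal_density_um2 = pit_density,
    hit_to_pit_ratio = ratio, hit_to_pit_ratio_se = ratio_se,
    energy_per_nucleus_MeV = energy_mean,
    energy_per_nucleus_se = energy_se,
    dose_Gy = dose, dose_se = dose_se,
    specific_energy_per_hit_Gy = if (keep_hits) edep_hits * mev_to_gy,
    registration_efficiency = if (n_reach > 0) n_reg / n_reach else NA_real_,
    registration_efficiency_se = if (n_reach > 0)
      sqrt((n_reg / n_reach) * (1 - n_reg / n_reach) / n_reach)
      else NA_real_,
    counts = list(hit = n_hit, reach = n_reach, registered = n_reg,
                  footprint_pits = n_fp),
    geom = geom, model = model, spectrum = sp),
    class = "microdose_tally")
}

#' @export
print.microdose_tally <- function(x, ...) {
  cat("<microdose_tally> ", format(x$n_decays, big.mark = ","),
      " decays at ", format(x$decay_density, digits = 4),
      " decays/cm^3\n", sep = "")
  cat(sprintf("  hits/nucleus        %.4g +/- %.2g\n",
              x$hits_per_nucleus$mean, x$hits_per_nucleus$se))
  cat(sprintf("  pits/nucleus        %.4g +/- %.2g (footprint tally %.4g)\n",
              x$pits_per_nucleus$mean, x$pits_per_nucleus$se,
              x$pits_per_nucleus$within_footprint))
  cat(sprintf("  hit-to-pit ratio    %.3f +/- %.3f\n",
              x$hit_to_pit_ratio, x$hit_to_pit_ratio_se))
  cat(sprintf("  dose                %.4g +/- %.2g Gy\n",
              x$dose_Gy, x$dose_se))
  cat(sprintf("  registration eff.   %.3f\n", x$registration_efficiency))
  invisible(x)
}

#' Pit-to-dose and pit-to-hit conversion from a tally
#'
#' The bridge between the measurable (detected etch pits per nucleus) and
#' the quantities of interest: absorbed dose per detected pit and total
#' nucleus hits per detected pit, with standard errors propagated by the
#' delta method for ratios of Monte-Carlo means.
#'
#' @param tally a `microdose_tally` with a positive pit tally.
#' @return Object of class `dose_conversion` with `dose_per_pit_Gy`,
#'   `hits_per_pit` and their standard errors.
#' @export
dose_per_detected_pit <- function(tally) {
  stopifnot(inherits(tally, "microdose_tally"))
  p <- tally$pits_per_nucleus$mean
  if (!is.finite(p) || p <= 0) stop("zero pit tally: no conversion")
  rel_p <- tally$pits_per_nucleus$se / p
  dpp <- tally$dose_Gy / p
  dpp_se <- dpp * sqrt((tally$dose_se / tally$dose_Gy)^2 + rel_p^2)
  structure(list(dose_per_pit_Gy = dpp, dose_per_pit_se = dpp_se,
                 hits_per_pit = tally$hit_to_pit_ratio,
                 hits_per_pit_se = tally$hit_to_pit_ratio_se,
                 source = "microdose_tally"),
            class = "dose_conversion")
}

#' @export
print.dose_conversion <- function(x, ...) {
  cat(sprintf("<dose_conversion> %.4g +/- %.2g Gy/pit, %.3f +/- %.3f hits/pit\n",
              x$dose_per_pit_Gy, x$dose_per_pit_se,
              x$hits_per_pit, x$hits_per_pit_se))
  invisible(x)
}
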