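test_that("decay sampling is uniform in depth, isotropic, and spectrum-faithful", {
  inv <- half_dm_inventory()
  geom <- geometry_config()
  ev <- sample_decay_events(inv, geom, 1e5, seed = 1)
  n <- nrow(ev)
  # uniform depth: mean z = depth/2 within 3 SE
  se_z <- (geom$medium_depth / sqrt(12)) / sqrt(n)
  expect_lt(abs(mean(ev$z) - geom$medium_depth / 2), 3 * se_z)
  # isotropy: mean polar cosine 0 within 3 SE
  expect_lt(abs(mean(ev$uz)), 3 / (sqrt(3) * sqrt(n)))
  expect_equal(ev$ux^2 + ev$uy^2 + ev$uz^2, rep(1, n), tolerance = 1e-9)
  # branch split 0.6406 / 0.3594 within 3 SE
  f <- mean(ev$E0 == 8.785)
  expect_lt(abs(f - 0.6406), 3 * sqrt(0.6406 * 0.3594 / n))
  expect_error(sample_decay_events(list(spectrum = NULL), geom, 10),
               "spectrum")
})

test_that("ray-cylinder chords agree with a brute-force ray-marching oracle", {
  geom <- geometry_config()
  set.seed(99)
  n <- 1000
  uz <- runif(n, -1, 1); phi <- runif(n, 0, 2 * pi)
  rho <- sqrt(1 - uz^2)
  E0 <- sample(c(8.785, 6.05), n, replace = TRUE)
  tracks <- data.frame(
    x = runif(n, -20, 20), y = runif(n, -20, 20), z = runif(n, 0, 15),
    ux = rho * cos(phi), uy = rho * sin(phi), uz = uz,
    E0 = E0, range_um = range_in_water(E0))
  ch <- chord_through_nucleus(tracks, geom)
  r2 <- geom$nucleus_radius^2
  z1 <- geom$nucleus_thickness
  step <- 0.01
  for (i in seq_len(n)) {
    s <- seq(0, tracks$range_um[i], by = step)
    px <- tracks$x[i] + tracks$ux[i] * s
    py <- tracks$y[i] + tracks$uy[i] * s
    pz <- tracks$z[i] + tracks$uz[i] * s
    inside <- px^2 + py^2 <= r2 & pz >= 0 & pz <= z1
    if (ch$hit[i] && (ch$s_exit[i] - ch$s_entry[i]) > 0.05) {
      expect_true(any(inside), label = paste("track", i))
      expect_lt(abs(min(s[inside]) - ch$s_entry[i]), 0.05)
      expect_lt(abs(max(s[inside]) - ch$s_exit[i]), 0.05)
    } else if (!ch$hit[i]) {
      expect_false(any(inside), label = paste("track", i))
    }
  }
})

test_that("tracks born inside the nucleus enter at zero path length", {
  geom <- geometry_config()
  tracks <- data.frame(x = 0, y = 0, z = 2, ux = 0, uy = 0, uz = 1,
                       E0 = 8.785, range_um = range_in_water(8.785))
  ch <- chord_through_nucleus(tracks, geom)
  expect_true(ch$hit)
  expect_equal(ch$s_entry, 0)
  expect_equal(ch$s_exit, geom$nucleus_thickness - 2)
  # vertical track above the footprint: chord equals the thickness
  tr2 <- data.frame(x = 0, y = 0, z = 50, ux = 0, uy = 0, uz = -1,
                    E0 = 8.785, range_um = range_in_water(8.785))
  ch2 <- chord_through_nucleus(tr2, geom)
  expect_equal(ch2$s_exit - ch2$s_entry, geom$nucleus_thickness,
               tolerance = 1e-9)
  # lateral miss
  tr3 <- data.frame(x = 50, y = 0, z = 2, ux = 0, uy = 1, uz = 0,
                    E0 = 8.785, range_um = range_in_water(8.785))
  expect_false(chord_through_nucleus(tr3, geom)$hit)
})

test_that("CR-39 registration follows the critical-dip-angle criterion", {
  model <- registration_model()
  mk <- function(z, uz, E0 = 8.785) {
    u <- sqrt(1 - uz^2)
    data.frame(x = 0, y = 0, z = z, ux = u, uy = 0, uz = uz,
               E0 = E0, range_um = range_in_water(E0))
  }
  # normal incidence registers
  expect_true(cr39_registers(mk(10, -1), model)$registers)
  # dip below the critical angle does not
  shallow <- cr39_registers(mk(1, -sin(10 * pi / 180)), model)
  expect_true(shallow$reaches)
  expect_false(shallow$registers)
  # upward track never reaches; decision undefined
  up <- cr39_registers(mk(10, 0.5), model)
  expect_false(up$reaches)
  expect_true(is.na(up$registers))
  # out of range: reaches FALSE
  far <- cr39_registers(mk(100, -1), model)
  expect_false(far$reaches)
  # energy window excludes an arrival energy outside it
  win <- registration_model(energy_window = c(1, 4))
  deep <- cr39_registers(mk(10, -1), win)   # arrives ~8.2 MeV
  expect_false(deep$registers)
})

test_that("zero decay density yields all-zero tallies", {
  tl <- run_microdose(half_dm_inventory(), geometry_config(),
                      registration_model(), n_decays = 2e4, seed = 3,
                      decay_density = 0)
  expect_equal(tl$hits_per_nucleus$mean, 0)
  expect_equal(tl$pits_per_nucleus$mean, 0)
  expect_equal(tl$dose_Gy, 0)
})

test_that("extensive tallies scale linearly with decay density; ratios are invariant", {
  inv <- half_dm_inventory()
  t1 <- run_microdose(inv, n_decays = 5e4, seed = 5, decay_density = 1e9)
  t2 <- run_microdose(inv, n_decays = 5e4, seed = 5, decay_density = 2e9)
  expect_equal(t2$hits_per_nucleus$mean, 2 * t1$hits_per_nucleus$mean,
               tolerance = 1e-12)
  expect_equal(t2$pits_per_nucleus$mean, 2 * t1$pits_per_nucleus$mean,
               tolerance = 1e-12)
  expect_equal(t2$dose_Gy, 2 * t1$dose_Gy, tolerance = 1e-12)
  expect_equal(t2$hit_to_pit_ratio, t1$hit_to_pit_ratio, tolerance = 1e-12)
  c1 <- dose_per_detected_pit(t1); c2 <- dose_per_detected_pit(t2)
  expect_equal(c2$dose_per_pit_Gy, c1$dose_per_pit_Gy, tolerance = 1e-12)
})

test_that("identical configuration and seed reproduce the tally exactly", {
  inv <- half_dm_inventory()
  a <- run_microdose(inv, n_decays = 5e4, seed = 11, decay_density = 1e9)
  b <- run_microdose(inv, n_decays = 5e4, seed = 11, decay_density = 1e9)
  expect_identical(a$counts, b$counts)
  expect_identical(a$energy_per_nucleus_MeV, b$energy_per_nucleus_MeV)
})

test_that("a medium shallower than the alpha range triggers the geometry warning", {
  expect_warning(
    run_microdose(half_dm_inventory(), geometry_config(medium_depth = 50),
                  n_decays = 1e4, seed = 1, decay_density = 1e9),
    "not thick")
})

test_that("footprint pit tally cross-checks the areal-density pit estimate", {
  tl <- default_tally()
  expect_equal(tl$pits_per_nucleus$within_footprint,
               tl$pits_per_nucleus$mean,
               tolerance = 0.1)
  expect_gte(tl$hit_to_pit_ratio, 1)
  # dose follows from the energy tally and the nucleus mass at rho = 1
  v_kg <- tl$geom$nucleus_area * tl$geom$nucleus_thickness * 1e-15
  expect_equal(tl$dose_Gy,
               tl$energy_per_nucleus_MeV * 1.602176634e-13 / v_kg,
               tolerance = 1e-12)
})

test_that("pit-to-dose conversion propagates errors and rejects empty tallies", {
  conv <- default_conversion()
  tl <- default_tally()
  expect_equal(conv$dose_per_pit_Gy, tl$dose_Gy / tl$pits_per_nucleus$mean)
  expect_equal(conv$hits_per_pit, tl$hit_to_pit_ratio)
  expect_gt(conv$dose_per_pit_se, 0)
  empty <- tl
  empty$pits_per_nucleus$mean <- 0
  expect_error(dose_per_detected_pit(empty), "zero pit tally")
})
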