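test_that("single-nuclide decay halves activity over one half-life", {
  inv <- chain_inventory(c("Ra-224" = 1e6))
  a0 <- inv$activities[["Ra-224"]]
  out <- bateman_activities(inv, 3.63 * 86400)
  expect_equal(out$activities[["Ra-224"]], a0 / 2, tolerance = 1e-12)
  expect_equal(out$atoms[["Ra-224"]], 5e5, tolerance = 1e-12)
})

test_that("short-lived daughter reaches secular equilibrium with its parent", {
  lam <- decay_constants(ra224_chain())
  inv <- chain_inventory(c("Ra-224" = 1e9))
  out <- bateman_activities(inv, 10 * 55.6)   # ten Rn-220 half-lives
  ratio <- out$activities[["Rn-220"]] / out$activities[["Ra-224"]]
  expected <- lam[["Rn-220"]] / (lam[["Rn-220"]] - lam[["Ra-224"]])
  expect_equal(ratio, expected, tolerance = 1e-3)
  expect_equal(expected, 1, tolerance = 1e-3)
})

test_that("Pb-212 -> Bi-212 -> Po-212 activities match a stiff ODE oracle", {
  skip_if_not_installed("deSolve")
  tab <- ra224_chain()
  t_eval <- 2 * 3600
  sol <- ode_chain_atoms(tab, c("Pb-212" = 1e8), c(0, t_eval))
  lam <- decay_constants(tab)
  out <- bateman_activities(chain_inventory(c("Pb-212" = 1e8)), t_eval)
  for (nm in c("Pb-212", "Bi-212", "Po-212", "Tl-208")) {
    expect_equal(out$activities[[nm]], unname(lam[[nm]] * sol[2, nm]),
                 tolerance = 1e-4, label = paste("activity of", nm))
  }
})

test_that("full chain from Ra-224 matches the ODE oracle and conserves atoms", {
  skip_if_not_installed("deSolve")
  tab <- ra224_chain()
  n0 <- 1e9
  times <- c(0, 600, 3600, 6 * 3600, 86400, 5 * 86400)
  sol <- ode_chain_atoms(tab, c("Ra-224" = n0), times)
  inv <- chain_inventory(c("Ra-224" = n0))
  for (i in seq_along(times)[-1]) {
    out <- bateman_activities(inv, times[i])
    # atoms destined for stable Pb-208 are conserved in a closed system
    expect_equal(sum(out$atoms), n0, tolerance = 1e-9)
    for (nm in tab$nuclides$name) {
      ref <- unname(sol[i, nm])
      if (ref > 1e-6 * n0)  # compare the populated members
        expect_equal(out$atoms[[nm]], ref, tolerance = 5e-5,
                     label = paste0(nm, " atoms at t=", times[i]))
    }
  }
})

test_that("confluent Bateman form handles (near-)equal decay constants", {
  # two-member chain with identical half-lives: N2 = N0 * lambda * t * exp(-lambda t)
  nuclides <- data.frame(name = c("A", "B", "C"),
                         half_life_s = c(100, 100, Inf))
  modes <- data.frame(parent = c("A", "B"), mode = c("beta", "beta"),
                      branching = c(1, 1), daughter = c("B", "C"),
                      alpha_energy_MeV = c(NA, NA))
  tab <- nuclide_table(nuclides, modes)
  lam <- log(2) / 100
  out <- bateman_activities(chain_inventory(c(A = 1e6), table = tab), 150)
  expect_equal(out$atoms[["B"]], 1e6 * lam * 150 * exp(-lam * 150),
               tolerance = 1e-10)
  # near-degenerate (1e-12 apart) must agree with the exactly-degenerate form
  nuclides2 <- nuclides
  nuclides2$half_life_s[2] <- 100 * (1 + 1e-12)
  tab2 <- nuclide_table(nuclides2, modes)
  out2 <- bateman_activities(chain_inventory(c(A = 1e6), table = tab2), 150)
  expect_equal(out2$atoms[["B"]], out$atoms[["B"]], tolerance = 1e-9)
})

test_that("activities decay monotonically once the chain empties its head", {
  inv <- chain_inventory(c("Ra-224" = 1e9))
  # after transients, every activity decreases between consecutive times
  times <- 86400 * seq(2, 20, by = 2)
  acts <- sapply(times, function(t) bateman_activities(inv, t)$activities)
  for (nm in rownames(acts)) {
    a <- acts[nm, ]
    if (all(a > 0)) expect_true(all(diff(a) < 0), label = nm)
  }
})

test_that("Pb-212 buildup under constant feed is monotone with known milestones", {
  expect_equal(pb212_buildup_fraction(0), 0)
  expect_equal(pb212_buildup_fraction(10.64 * 3600), 0.5, tolerance = 1e-12)
  expect_equal(pb212_buildup_fraction(Inf), 1)
  # stabilizes near its asymptote about one day in
  expect_equal(pb212_buildup_fraction(24 * 3600), 1 - 2^(-24 / 10.64),
               tolerance = 1e-12)
  expect_equal(pb212_buildup_fraction(24 * 3600), 0.79, tolerance = 0.005)
  tt <- seq(0, 3 * 86400, by = 3600)
  f <- pb212_buildup_fraction(tt)
  expect_true(all(diff(f) > 0) && all(f <= 1))
  expect_error(pb212_buildup_fraction(-1), "incubation")
})

test_that("DM alpha inventory integrates the decaying Pb-212 activity", {
  lam <- decay_constants(ra224_chain())[["Pb-212"]]
  a0 <- 1234; vol <- 2; dil <- 0.5
  inf_total <- dil * a0 * vol / lam
  expect_equal(dm_alpha_inventory(a0, 1e12, vol, dil)$total_alpha_decays,
               inf_total, tolerance = 1e-6)
  expect_equal(dm_alpha_inventory(a0, 10.64 * 3600, vol, dil)$total_alpha_decays,
               inf_total / 2, tolerance = 1e-12)
  # quadrature oracle: integral of the decaying activity over the window
  quad <- stats::integrate(function(t) dil * a0 * vol * exp(-lam * t),
                           0, 24 * 3600, rel.tol = 1e-10)$value
  got <- dm_alpha_inventory(a0, 24 * 3600, vol, dil)$total_alpha_decays
  expect_equal(got, quad, tolerance = 1e-8)
  expect_equal(got / inf_total, 0.7905, tolerance = 1e-3)
})

test_that("exactly one alpha is emitted per Pb-212 decay regardless of branching", {
  inv <- dm_alpha_inventory(1000, 24 * 3600, 2, 1)
  expect_equal(sum(inv$spectrum$fraction), 1, tolerance = 1e-12)
  # perturb the branch split; the alpha yield per decay must stay 1
  tab <- ra224_chain()
  bi <- tab$modes$parent == "Bi-212"
  tab$modes$branching[bi] <- c(0.25, 0.75)
  inv2 <- dm_alpha_inventory(1000, 24 * 3600, 2, 1, table = tab)
  expect_equal(sum(inv2$spectrum$fraction), 1, tolerance = 1e-12)
  expect_equal(inv2$total_alpha_decays, inv$total_alpha_decays)
})

test_that("activity decay-correction follows the Ra-224 half-life in both directions", {
  expect_equal(decay_correct_activity(7.4e4, 0), 7.4e4)
  expect_equal(decay_correct_activity(7.4e4, 3.63 * 86400), 3.7e4)
  expect_equal(decay_correct_activity(7.4e4, -3.63 * 86400), 1.48e5)
  expect_error(decay_correct_activity(NA_real_, 0), "non-finite")
})

test_that("invalid decay-chain inputs are rejected", {
  expect_error(bateman_activities(chain_inventory(c("Ra-224" = 1)), -5),
               ">= 0")
  expect_error(chain_inventory(c("Xx-999" = 1)), "unknown nuclide")
  expect_error(dm_alpha_inventory(100, 3600, 2, dilution = 1.5), "dilution")
  expect_error(dm_alpha_inventory(100, 3600, 2, dilution = 0), "dilution")
  expect_error(dm_alpha_inventory(100, -1, 2, 1), "duration")
  expect_error(dm_alpha_inventory(100, 3600, -2, 1), "volume")
})

test_that("nuclide tables round-trip through the editable CSV format", {
  tab <- ra224_chain()
  path <- withr::local_tempfile(fileext = ".csv")
  write_nuclide_table(tab, path)
  back <- read_nuclide_table(path)
  expect_equal(back$nuclides$half_life_s, tab$nuclides$half_life_s,
               tolerance = 1e-12)
  expect_equal(back$modes$branching, tab$modes$branching)
  expect_equal(back$modes$alpha_energy_MeV, tab$modes$alpha_energy_MeV)
})

test_that("chain time series exports the long CSV schema", {
  ts <- chain_time_series(chain_inventory(c("Ra-224" = 1e6)),
                          c(0, 3600, 86400))
  expect_named(ts, c("time_s", "nuclide", "atoms", "activity_Bq"))
  expect_equal(nrow(ts), 3 * 8)
  expect_true(all(ts$atoms >= 0) && all(ts$activity_Bq >= 0))
})
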