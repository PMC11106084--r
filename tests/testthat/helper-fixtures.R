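# Shared fixtures.  The default-geometry Monte-Carlo tally is the most
# expensive object several files need; it is computed once per test run
# and memoized here.

.fixture_env <- new.env()

half_dm_inventory <- function() {
  dm_alpha_inventory(a0_pb212 = 1000, duration = 24 * 3600, volume = 2,
                     dilution = 0.5)
}

# decay density used for absolute tallies in tests (decays/cm^3); the
# pit->hit and pit->dose conversions do not depend on it
test_decay_density <- 1.7e9

default_tally <- function() {
  if (is.null(.fixture_env$tally)) {
    .fixture_env$tally <- run_microdose(
      half_dm_inventory(), geometry_config(), registration_model(),
      n_decays = 1e6, seed = 424242, decay_density = test_decay_density)
  }
  .fixture_env$tally
}

default_conversion <- function() dose_per_detected_pit(default_tally())

# Right-hand side of the decay-chain rate equations for the deSolve
# oracle: dN/dt = -lambda*N + sum over parents of branching*lambda_p*N_p.
chain_ode_rhs <- function(table) {
  lam <- decay_constants(table)
  nm <- names(lam)
  function(t, y, parms) {
    dy <- -lam * y
    for (i in seq_len(nrow(table$modes))) {
      p <- table$modes$parent[i]
      d <- table$modes$daughter[i]
      dy[d] <- dy[d] + table$modes$branching[i] * lam[p] * y[p]
    }
    list(dy)
  }
}

ode_chain_atoms <- function(table, atoms0, times) {
  nm <- table$nuclides$name
  y0 <- stats::setNames(numeric(length(nm)), nm)
  y0[names(atoms0)] <- atoms0
  deSolve::lsoda(y0, times, chain_ode_rhs(table), parms = NULL,
                 rtol = 1e-10, atol = 1e-12, maxsteps = 50000)
}
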