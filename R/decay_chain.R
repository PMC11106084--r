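#' Chain inventory: atom counts and activities at a point in time
#'
#' @param atoms named numeric vector of atom counts (nuclides absent from
#'   the vector are taken as zero).
#' @param time time since the reference instant, seconds.
#' @param table a [nuclide_table]; defaults to [ra224_chain()].
#' @return Object of class `chain_inventory` with elements `time`,
#'   `atoms`, `activities` (Bq; `activity = ln2/T_half * atoms`, zero for
#'   stable nuclides) and the `table` it was built against.
#' @export
chain_inventory <- function(atoms, time = 0, table = ra224_chain()) {
  stopifnot(inherits(table, "nuclide_table"), is.numeric(atoms))
  if (is.null(names(atoms)) || any(names(atoms) == ""))
    stop("`atoms` must be a named vector of nuclide counts")
  unknown <- setdiff(names(atoms), table$nuclides$name)
  if (length(unknown))
    stop("unknown nuclide name(s): ", paste(unknown, collapse = ", "))
  if (any(atoms < 0)) stop("atom counts must be >= 0")
  full <- stats::setNames(numeric(nrow(table$nuclides)), table$nuclides$name)
  full[names(atoms)] <- atoms
  lam <- decay_constants(table)
  structure(list(time = time, atoms = full, activities = lam * full,
                 table = table),
            class = "chain_inventory")
}

#' @export
print.chain_inventory <- function(x, ...) {
  cat("<chain_inventory> at t =", x$time, "s\n")
  df <- data.frame(nuclide = names(x$atoms), atoms = x$atoms,
                   activity_Bq = x$activities, row.names = NULL)
  print(df[df$atoms > 0 | df$activities > 0, ], ...)
  invisible(x)
}

#' @export
as.data.frame.chain_inventory <- function(x, ...) {
  data.frame(time_s = x$time, nuclide = names(x$atoms),
             atoms = unname(x$atoms),
             activity_Bq = unname(x$activities), row.names = NULL)
}

# Generalized (confluent) divided difference of f(x) = exp(-x * t) over the
# nodes `lam`.  For distinct nodes this is the classic Newton divided
# difference; nodes equal within `rtol` (relative) use the derivative form
# f^(m)(x)/m! = (-t)^m exp(-x t)/m!, which is the confluent limit of the
# Bateman coefficients for (near-)degenerate decay constants.
.dd_exp <- function(lam, t, rtol = 1e-9) {
  n <- length(lam)
  x <- sort(lam)
  d <- exp(-x * t)
  if (n == 1L) return(d)
  for (m in seq_len(n - 1L)) {
    i <- seq_len(n - m)
    dx <- x[i + m] - x[i]
    conf <- dx <= rtol * pmax(abs(x[i]), abs(x[i + m]))
    nd <- numeric(n - m)
    nd[!conf] <- (d[i[!conf] + 1L] - d[i[!conf]]) / dx[!conf]
    if (any(conf))
      nd[conf] <- (-t)^m * exp(-x[i[conf]] * t) / factorial(m)
    d <- nd
  }
  d
}

# All decay paths from `from` through the chain (including the length-1
# path).  Returns a list of lists: names (path member names) and bprod
# (product of branching fractions along the path edges).
.chain_paths <- function(table, from) {
  out <- list()
  recurse <- function(names, bprod) {
    out[[length(out) + 1L]] <<- list(names = names, bprod = bprod)
    tip <- names[length(names)]
    mm <- table$modes[table$modes$parent == tip, , drop = FALSE]
    for (j in seq_len(nrow(mm)))
      recurse(c(names, mm$daughter[j]), bprod * mm$branching[j])
  }
  recurse(from, 1)
  out
}

#' Bateman solution for a branching decay chain
#'
#' Propagates a [chain_inventory] forward in time using the closed-form
#' Bateman solution for a linear chain with branching.  The per-path atom
#' count is evaluated through a generalized divided difference of
#' `exp(-lambda t)`, which reduces to the classic Bateman sum for distinct
#' decay constants and to the confluent limiting form when decay constants
#' coincide to within 1e-9 relative, so near-degenerate chains stay
#' numerically stable.  Stable end members (lambda = 0) are handled as an
#' ordinary node at zero.
#'
#' @param initial a [chain_inventory] describing the state at `initial$time`.
#' @param t elapsed time in seconds (scalar, `>= 0`).
#' @return A new [chain_inventory] at `initial$time + t`.
#' @export
bateman_activities <- function(initial, t) {
  stopifnot(inherits(initial, "chain_inventory"))
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t))
    stop("`t` must be a finite numeric scalar")
  if (t < 0) stop("`t` must be >= 0")
  table <- initial$table
  lam <- decay_constants(table)
  atoms <- stats::setNames(numeric(length(lam)), names(lam))
  src <- names(initial$atoms)[initial$atoms > 0]
  for (s in src) {
    n0 <- initial$atoms[[s]]
    for (p in .chain_paths(table, s)) {
      nm <- p$names
      k <- length(nm)
      l <- lam[nm]
      # N_k(t) = N0 * prod(b_i lambda_i, i<k) * (-1)^(k-1) * dd[l_1..l_k] e^{-xt}
      coef <- if (k == 1L) 1 else prod(l[-k]) * p$bprod
      val <- n0 * coef * (-1)^(k - 1) * .dd_exp(unname(l), t)
      # tiny negative round-off is clipped
      atoms[nm[k]] <- atoms[nm[k]] + max(val, 0)
    }
  }
  chain_inventory(atoms, time = initial$time + t, table = table)
}

#' Time series of a decaying chain
#'
#' Convenience wrapper evaluating [bateman_activities()] on a grid of
#' times, in the long format used for CSV export (columns `time_s`,
#' `nuclide`, `atoms`, `activity_Bq`).
#'
#' @param initial a [chain_inventory].
#' @param times numeric vector of elapsed times (s), all `>= 0`.
#' @return data.frame in long format.
#' @export
chain_time_series <- function(initial, times) {
  stopifnot(is.numeric(times), all(times >= 0))
  do.call(rbind, lapply(times, function(t)
    as.data.frame(bateman_activities(initial, t))))
}

#' Pb-212 activity buildup under constant feed
#'
#' In a medium fed at a constant rate with Rn-220 (whose sub-minute
#' progeny reach Pb-212 essentially instantly), the Pb-212 activity
#' approaches its asymptote as `1 - exp(-lambda_Pb * t)`; it stabilizes at
#' its asymptotic level roughly one day after the source is introduced.
#'
#' @param t_incubation incubation time, seconds (vectorized, `>= 0`).
#' @param half_life_s Pb-212 half-life in seconds.
#' @return Fraction of the asymptotic Pb-212 activity, in \[0, 1\].
#' @export
pb212_buildup_fraction <- function(t_incubation,
                                   half_life_s = 10.64 * 3600) {
  if (any(!is.finite(t_incubation) & !is.infinite(t_incubation)))
    stop("non-finite incubation time")
  if (any(t_incubation < 0)) stop("incubation time must be >= 0")
  1 - 2^(-t_incubation / half_life_s)
}

#' Alpha-emission inventory of a daughter medium exposure
#'
#' Total alpha decays delivered by a daughter medium (DM) during an
#' exposure window, assuming Bi-212/Po-212 in secular equilibrium with
#' Pb-212 at the start of the exposure and no resupply: each Pb-212 decay
#' is followed by exactly one alpha, either the Bi-212 alpha (6.05 MeV)
#' or, through the beta branch, the Po-212 alpha (8.785 MeV).
#'
#' @param a0_pb212 Pb-212 activity concentration of the undiluted (1x)
#'   medium at exposure start, Bq/mL.
#' @param duration exposure duration, seconds.
#' @param volume medium volume, mL.
#' @param dilution dilution factor in (0, 1\].
#' @param table a [nuclide_table] supplying branch fractions and alpha
#'   energies.
#' @return Object of class `alpha_inventory` with `total_alpha_decays`,
#'   `spectrum` (data.frame `energy_MeV`, `fraction`, `emitter`), and
#'   `per_volume` (decays per cm^3 over the window).
#' @export
dm_alpha_inventory <- function(a0_pb212, duration, volume = 2,
                               dilution = 1, table = ra224_chain()) {
  if (!is.numeric(dilution) || dilution <= 0 || dilution > 1)
    stop("`dilution` must lie in (0, 1]")
  if (volume <= 0) stop("`volume` must be positive")
  if (duration <= 0) stop("`duration` must be positive")
  lam_pb <- decay_constants(table)[["Pb-212"]]
  total <- dilution * a0_pb212 * volume / lam_pb *
    (1 - exp(-lam_pb * duration))
  mm <- table$modes[table$modes$parent == "Bi-212", , drop = FALSE]
  b_alpha <- mm$branching[mm$mode == "alpha"]
  b_beta <- mm$branching[mm$mode == "beta"]
  e_bi <- mm$alpha_energy_MeV[mm$mode == "alpha"]
  po <- table$modes[table$modes$parent == "Po-212" &
                      table$modes$mode == "alpha", , drop = FALSE]
  spectrum <- data.frame(
    energy_MeV = c(po$alpha_energy_MeV, e_bi),
    fraction = c(b_beta, b_alpha),
    emitter = c("Po-212", "Bi-212"),
    stringsAsFactors = FALSE)
  structure(list(total_alpha_decays = total, spectrum = spectrum,
                 per_volume = total / volume,
                 a0_pb212 = a0_pb212, duration = duration,
                 volume = volume, dilution = dilution),
            class = "alpha_inventory")
}

#' @export
print.alpha_inventory <- function(x, ...) {
  cat("<alpha_inventory>\n",
      " total alpha decays: ", format(x$total_alpha_decays, digits = 4),
      " (", format(x$per_volume, digits = 4), " per cm^3)\n", sep = "")
  print(x$spectrum)
  invisible(x)
}

#' Mean alpha energy of an emission inventory
#'
#' @param inventory an `alpha_inventory` (or any list with a `spectrum`
#'   data.frame of `energy_MeV` and `fraction`).
#' @return Fraction-weighted mean alpha energy, MeV.
#' @export
mean_alpha_energy <- function(inventory) {
  sp <- inventory$spectrum
  sum(sp$energy_MeV * sp$fraction) / sum(sp$fraction)
}

#' Decay-correct an activity to a reference instant
#'
#' Source activities are corrected to the start of the source incubation
#' according to the Ra-224 half-life: `a_ref * 2^(-dt / T_half)`.  A
#' positive `dt` decays the activity forward in time; a negative `dt`
#' back-corrects it.
#'
#' @param a_ref reference activity, Bq.
#' @param dt signed time offset, seconds.
#' @param half_life_s half-life used for the correction (default Ra-224,
#'   3.63 d).
#' @return Corrected activity, Bq.
#' @export
decay_correct_activity <- function(a_ref, dt, half_life_s = 3.63 * 86400) {
  if (any(!is.finite(a_ref)) || any(!is.finite(dt)))
    stop("non-finite input")
  a_ref * 2^(-dt / half_life_s)
}
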