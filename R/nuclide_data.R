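#' Nuclide decay-scheme table
#'
#' A `nuclide_table` holds the decay scheme of a (branching, acyclic) chain:
#' one row per nuclide with its half-life, and one row per decay mode with
#' its branching fraction, daughter, and alpha energy for alpha modes.
#' Stable nuclides carry an infinite half-life and no modes.
#'
#' @param nuclides data.frame with columns `name` (character) and
#'   `half_life_s` (numeric, seconds; `Inf` for stable nuclides).
#' @param modes data.frame with columns `parent`, `mode` (`"alpha"` or
#'   `"beta"`), `branching` (fraction in \[0,1\]), `daughter`, and
#'   `alpha_energy_MeV` (`NA` for beta modes).
#' @return An object of class `nuclide_table`.
#' @export
nuclide_table <- function(nuclides, modes) {
  stopifnot(is.data.frame(nuclides), is.data.frame(modes))
  need_n <- c("name", "half_life_s")
  need_m <- c("parent", "mode", "branching", "daughter", "alpha_energy_MeV")
  if (!all(need_n %in% names(nuclides)))
    stop("`nuclides` must have columns: ", paste(need_n, collapse = ", "))
  if (!all(need_m %in% names(modes)))
    stop("`modes` must have columns: ", paste(need_m, collapse = ", "))
  if (anyDuplicated(nuclides$name))
    stop("duplicated nuclide names")
  if (any(nuclides$half_life_s <= 0))
    stop("half-lives must be positive")
  if (!all(modes$parent %in% nuclides$name))
    stop("unknown parent nuclide in modes table")
  if (!all(modes$daughter %in% nuclides$name))
    stop("unknown daughter nuclide in modes table")
  if (!all(modes$mode %in% c("alpha", "beta")))
    stop("decay modes must be 'alpha' or 'beta'")
  bad_e <- modes$mode == "alpha" &
    (!is.finite(modes$alpha_energy_MeV) | modes$alpha_energy_MeV <= 0)
  if (any(bad_e))
    stop("alpha modes must carry a positive alpha energy")
  # branching fractions of each unstable nuclide must sum to 1
  for (nm in nuclides$name[is.finite(nuclides$half_life_s)]) {
    b <- modes$branching[modes$parent == nm]
    if (length(b) == 0L)
      stop("unstable nuclide ", nm, " has no decay modes")
    if (abs(sum(b) - 1) > 1e-12)
      stop("branching fractions of ", nm, " sum to ", sum(b), ", not 1")
  }
  # acyclicity: daughters must appear strictly after parents in some
  # topological order; detect cycles by repeated stripping
  remaining <- nuclides$name
  repeat {
    has_parent <- remaining %in% modes$daughter[modes$parent %in% remaining]
    roots <- remaining[!has_parent]
    if (length(roots) == 0L) {
      if (length(remaining) > 0L) stop("decay scheme contains a cycle")
      break
    }
    remaining <- setdiff(remaining, roots)
    if (length(remaining) == 0L) break
  }
  structure(list(nuclides = nuclides, modes = modes), class = "nuclide_table")
}

#' @export
print.nuclide_table <- function(x, ...) {
  cat("<nuclide_table> ", nrow(x$nuclides), " nuclides, ",
      nrow(x$modes), " decay modes\n", sep = "")
  hl <- x$nuclides$half_life_s
  lab <- ifelse(is.finite(hl), paste0(signif(hl, 4), " s"), "stable")
  cat(paste0("  ", format(x$nuclides$name, width = 8), " T1/2 = ", lab),
      sep = "\n")
  invisible(x)
}

#' The Ra-224 decay chain
#'
#' Decay scheme of Ra-224 and its progeny down to stable Pb-208, with
#' half-lives, branching fractions, and alpha energies keyed to the NuDat3
#' evaluated data.  Bi-212 branches: alpha (36%) to Tl-208 with its
#' 6.05/6.09 MeV doublet collapsed to a single 6.05 MeV line, and beta
#' (64%) to Po-212, which emits the 8.785 MeV alpha.  The 0.145 s member
#' of the chain is Po-216 (the alpha daughter of Rn-220).
#'
#' @return A [nuclide_table] for the chain
#'   Ra-224 -> Rn-220 -> Po-216 -> Pb-212 -> Bi-212 -> (Tl-208 | Po-212) -> Pb-208.
#' @export
ra224_chain <- function() {
  nuclides <- data.frame(
    name        = c("Ra-224", "Rn-220", "Po-216", "Pb-212",
                    "Bi-212", "Po-212", "Tl-208", "Pb-208"),
    half_life_s = c(3.63 * 86400, 55.6, 0.145, 10.64 * 3600,
                    60.55 * 60, 2.99e-7, 3.053 * 60, Inf),
    stringsAsFactors = FALSE)
  modes <- data.frame(
    parent    = c("Ra-224", "Rn-220", "Po-216", "Pb-212",
                  "Bi-212", "Bi-212", "Po-212", "Tl-208"),
    mode      = c("alpha", "alpha", "alpha", "beta",
                  "alpha", "beta", "alpha", "beta"),
    branching = c(1, 1, 1, 1, 0.3594, 0.6406, 1, 1),
    daughter  = c("Rn-220", "Po-216", "Pb-212", "Bi-212",
                  "Tl-208", "Po-212", "Pb-208", "Pb-208"),
    alpha_energy_MeV = c(5.685, 6.288, 6.778, NA, 6.05, NA, 8.785, NA),
    stringsAsFactors = FALSE)
  nuclide_table(nuclides, modes)
}

#' Decay constants of a nuclide table
#'
#' @param table a [nuclide_table].
#' @return Named numeric vector of decay constants (1/s); 0 for stable
#'   nuclides.
#' @export
decay_constants <- function(table) {
  stopifnot(inherits(table, "nuclide_table"))
  hl <- table$nuclides$half_life_s
  lam <- ifelse(is.finite(hl), log(2) / hl, 0)
  stats::setNames(lam, table$nuclides$name)
}

#' Read / write a nuclide table as an editable CSV file
#'
#' The on-disk format is one row per decay mode (stable nuclides get a
#' single row with mode `"stable"`), with the half-life given as a value
#' plus unit (`s`, `min`, `h`, `d`).
#'
#' @param path file path.
#' @return `read_nuclide_table` returns a [nuclide_table];
#'   `write_nuclide_table` returns `path` invisibly.
#' @export
read_nuclide_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "half_life", "half_life_unit", "mode", "branching",
            "daughter", "alpha_energy_MeV")
  if (!all(need %in% names(df)))
    stop("nuclide file must have columns: ", paste(need, collapse = ", "))
  mult <- c(s = 1, min = 60, h = 3600, d = 86400)
  if (!all(df$half_life_unit %in% c(names(mult), "")))
    stop("unknown half-life unit; use s, min, h or d")
  hl <- ifelse(df$mode == "stable", Inf,
               df$half_life * mult[df$half_life_unit])
  first <- !duplicated(df$name)
  nuclides <- data.frame(name = df$name[first], half_life_s = hl[first],
                         stringsAsFactors = FALSE)
  mm <- df[df$mode != "stable", , drop = FALSE]
  modes <- data.frame(parent = mm$name, mode = mm$mode,
                      branching = mm$branching, daughter = mm$daughter,
                      alpha_energy_MeV = mm$alpha_energy_MeV,
                      stringsAsFactors = FALSE)
  nuclide_table(nuclides, modes)
}

#' @rdname read_nuclide_table
#' @param table a [nuclide_table] to write.
#' @export
write_nuclide_table <- function(table, path) {
  stopifnot(inherits(table, "nuclide_table"))
  rows <- list()
  for (i in seq_len(nrow(table$nuclides))) {
    nm <- table$nuclides$name[i]
    hl <- table$nuclides$half_life_s[i]
    if (!is.finite(hl)) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = nm, half_life = NA_real_, half_life_unit = "",
        mode = "stable", branching = NA_real_, daughter = "",
        alpha_energy_MeV = NA_real_, stringsAsFactors = FALSE)
      next
    }
    unit <- if (hl >= 86400) c("d", 86400) else if (hl >= 3600) c("h", 3600)
            else if (hl >= 60) c("min", 60) else c("s", 1)
    mm <- table$modes[table$modes$parent == nm, , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      name = nm, half_life = hl / as.numeric(unit[2]),
      half_life_unit = unit[1], mode = mm$mode, branching = mm$branching,
      daughter = mm$daughter, alpha_energy_MeV = mm$alpha_energy_MeV,
      stringsAsFactors = FALSE)
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}
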