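#' Read and validate a structured run configuration
#'
#' Run configurations are YAML files with the parameter blocks of a
#' simulation or pipeline run.  Unknown keys (at the top level or inside
#' a block) are rejected, so typos fail loudly rather than silently
#' falling back to defaults.
#'
#' Recognised blocks and keys:
#' \describe{
#'   \item{geometry}{`medium_depth`, `nucleus_area`, `nucleus_thickness`,
#'     `nucleus_z_offset`, `lateral_margin` — see [geometry_config()].}
#'   \item{registration}{`critical_dip_angle`, `energy_window` — see
#'     [registration_model()].}
#'   \item{inventory}{`a0_pb212`, `duration`, `volume`, `dilution` — see
#'     [dm_alpha_inventory()].}
#'   \item{mc}{`n_decays`, `decay_density`, `chunk_size`.}
#'   \item{fit}{`weighted`, `exposure_min`, `nucleus_area`, `field_area`,
#'     `plating_efficiency`.}
#'   \item{(top level)}{`seed`, `out`.}
#' }
#'
#' @param path YAML file path.
#' @return A list of validated blocks, of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- list(
    geometry = c("medium_depth", "nucleus_area", "nucleus_thickness",
                 "nucleus_z_offset", "lateral_margin"),
    registration = c("critical_dip_angle", "energy_window"),
    inventory = c("a0_pb212", "duration", "volume", "dilution"),
    mc = c("n_decays", "decay_density", "chunk_size"),
    fit = c("weighted", "exposure_min", "nucleus_area", "field_area",
            "plating_efficiency"))
  scalars <- c("seed", "out")
  unknown_top <- setdiff(names(cfg), c(names(allowed), scalars))
  if (length(unknown_top))
    stop("unknown config key(s): ", paste(unknown_top, collapse = ", "))
  for (blk in intersect(names(cfg), names(allowed))) {
    bad <- setdiff(names(cfg[[blk]]), allowed[[blk]])
    if (length(bad))
      stop("unknown key(s) in `", blk, "`: ", paste(bad, collapse = ", "))
  }
  structure(cfg, class = "run_config")
}

#' Build the model objects named by a run configuration
#'
#' @param cfg a [read_run_config()] result (or plain list with the same
#'   blocks).
#' @return List with `geom`, `model`, and (when an `inventory` block is
#'   present) `inventory`.
#' @export
config_objects <- function(cfg) {
  geom <- do.call(geometry_config, cfg$geometry %||% list())
  model <- do.call(registration_model, cfg$registration %||% list())
  inventory <- NULL
  if (!is.null(cfg$inventory))
    inventory <- do.call(dm_alpha_inventory, cfg$inventory)
  list(geom = geom, model = model, inventory = inventory)
}

#' Provenance block for run reports
#'
#' @param cfg the configuration used (list).
#' @param seed the seed used.
#' @return List echoing the configuration, package version and seed.
#' @export
provenance_block <- function(cfg, seed = NULL) {
  list(config = unclass(cfg), seed = seed,
       package = "alphadosim",
       package_version = as.character(utils::packageVersion("alphadosim")),
       r_version = as.character(getRversion()))
}
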