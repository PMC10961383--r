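# Run configuration: strict YAML parsing against documented defaults.
# Unknown keys are rejected (silent defaulting would corrupt
# parameter-recovery experiments); every field has a default.

#' Default run configuration
#'
#' Nested list of every tunable, with the documented defaults: optics (the
#' off-axis DHM setup), scene geometry, treatment effects (the four EV
#' formulations at their printed mean shrink fractions plus control), noise,
#' reconstruction, morphometry, statistics and flow-gating parameters.
#'
#' @return a named list; see [load_config()] for validation
#' @export
default_config <- function() {
  list(
    seed = 1L,
    output_dir = "holoqpi-out",
    optics = list(wavelength_um = 0.6328, magnification = 20,
                  numerical_aperture = 0.65, camera_pixel_um = 5.2,
                  bit_depth = 8L, carrier_cycles_per_px = c(0.25, 0.25),
                  reference_amplitude_ratio = 3,
                  medium_refractive_index = 1),
    scene = list(field_size_px = c(192L, 192L), object_pixel_um = 0.26,
                 n_cells = 6L, cell_radius_um = c(4, 6),
                 cell_height_um = c(2, 4), cell_refractive_index = 1.385,
                 medium_refractive_index = 1.335, membrane_enabled = FALSE,
                 pore_diameter_um = 0.4, pore_pitch_um = 4,
                 pore_depth_phase_rad = 0.5),
    treatments = list(
      list(label = "si-EV", volume_shrink_fraction = 0.07406,
           cell_loss_count = 0L, shrink_dispersion = 0.05),
      list(label = "fol-si-EV", volume_shrink_fraction = 0.1462,
           cell_loss_count = 0L, shrink_dispersion = 0.05),
      list(label = "DOX-EV", volume_shrink_fraction = 0.2725,
           cell_loss_count = 0L, shrink_dispersion = 0.05),
      list(label = "fol-DOX-EV", volume_shrink_fraction = 0.4854,
           cell_loss_count = 0L, shrink_dispersion = 0.05)),
    noise = list(photon_scale = 1000, read_noise_sigma = 1),
    reconstruction = list(filter_kernel_px = 3L, autofocus = TRUE,
                          autofocus_range_um = c(-20, 20),
                          autofocus_steps = 9L, delta_n = 0.05,
                          background_quantile = 0.5),
    morphometry = list(min_height_um = 0.3, min_area_um2 = 5,
                       smooth_sigma_px = 2, watershed_tolerance_um = 0.3,
                       dilate_px = 4L),
    stats = list(n_fields = 5L, control_quantile = 0.99),
    flow = list(n_events = 10000L,
                fractions = list("fol-si-EV" = 0.7894, "si-EV" = 0.2959,
                                 "fol-DOX-EV" = 0.9881, "DOX-EV" = 0.8779),
                negative = list(meanlog = log(50), sdlog = 0.4),
                positive = list(meanlog = log(5000), sdlog = 0.5))
  )
}

# recursive strict merge: every user key must exist in the defaults
merge_strict <- function(defaults, user, path = character(0)) {
  if (is.null(user)) return(defaults)
  if (!is.list(user) || !is.list(defaults)) return(user)
  if (length(user) == 0) return(defaults)
  extra <- setdiff(names(user), names(defaults))
  # treatments/fractions are open-ended named lists, everything else strict
  open <- length(path) && path[length(path)] %in% c("treatments", "fractions")
  if (length(extra) && !open && !is.null(names(defaults)))
    stop("unknown configuration key: ",
         paste(c(path, extra[1]), collapse = "."))
  if (is.null(names(user))) return(user)  # replace unnamed lists wholesale
  out <- defaults
  for (key in names(user))
    out[[key]] <- merge_strict(defaults[[key]], user[[key]], c(path, key))
  out
}

validate_config <- function(cfg) {
  do.call(optical_config, cfg$optics)          # range checks, named errors
  do.call(scene_params, c(cfg$scene, list(seed = cfg$seed)))
  for (tr in cfg$treatments) do.call(treatment_effect, tr)
  flow_mixture(cfg$flow$negative, cfg$flow$positive)
  if (!is.null(cfg$noise$photon_scale) && cfg$noise$photon_scale <= 0)
    stop("noise.photon_scale must be positive or null")
  if (cfg$stats$n_fields < 1) stop("stats.n_fields must be >= 1")
  if (cfg$stats$control_quantile <= 0.5 || cfg$stats$control_quantile >= 1)
    stop("stats.control_quantile must lie in (0.5, 1)")
  if (cfg$reconstruction$filter_kernel_px %% 2 == 0)
    stop("reconstruction.filter_kernel_px must be odd")
  invisible(cfg)
}

#' Load and validate a run configuration
#'
#' Reads a YAML file, merges it over [default_config()] with strict key
#' checking (a typo'd key raises an error naming it), and validates every
#' value through the type constructors. An empty file yields all defaults.
#'
#' @param path YAML configuration file
#' @return the validated configuration list
#' @export
load_config <- function(path) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_strict(default_config(), user)
  cfg$seed <- as.integer(cfg$seed)
  validate_config(cfg)
  cfg
}

#' Save a configuration as YAML
#'
#' @param cfg configuration list
#' @param path output path
#' @return invisibly, `path`
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
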