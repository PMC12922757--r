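# Layered YAML configuration. Every default equals the value used by the
# owning module; unknown keys are rejected.

#' Default run configuration
#'
#' Nested list of every tunable parameter with its default. The `phenotypes`
#' block maps population names to [phenotype_params()] fields.
#'
#' @return nested list
#' @export
default_config <- function() {
  ph_fields <- function(p) unclass(p)[setdiff(names(unclass(p)), "label")]
  list(
    seed = 1L,
    device = list(chamber_length = 300, chamber_height = 5, chamber_width = 300,
                  constriction_x = 100, pillar_extent = 20, gap_width = 3,
                  cell_length = 25, saturation_x = 250,
                  D_cm2s = 5e-6, t_end_s = 3600, dx_um = 1, dt_s = 0.5,
                  establish_tol = 0.10),
    simulate = list(n_cells = 300L, dt_s = 30, n_frames = 180L),
    phenotypes = list(control = ph_fields(phenotype_presets("control")),
                      knockout = ph_fields(phenotype_presets("knockout")),
                      overexpresser = ph_fields(phenotype_presets("overexpresser"))),
    traces = list(baseline = 100, noise_cv = 0.1, spike_amp = 400,
                  spike_decay_s = 90),
    vesicles = list(dispersion = 5),
    analysis = list(min_final_x = 100, n_boot = 2000L, min_points = 3L,
                    trim_arrest = TRUE, k_mad = 5, min_separation_s = 60,
                    spike_window_factor = 2,
                    classifier = list(orientation = 45, eccentricity = 0.75,
                                      solidity = 0.9),
                    band_width_px = 3L, ne_band_px = 2L),
    render = list(enabled = TRUE, pixel_size = 1, n_frames = 2L,
                  cortical_ratio = 2)
  )
}

.merge_config <- function(base, user, path = "") {
  if (identical(path, "phenotypes")) {
    # a user phenotypes block replaces the preset populations; each
    # population's fields are layered over the control template
    tpl <- default_config()$phenotypes$control
    return(stats::setNames(
      lapply(names(user), function(k)
        .merge_config(tpl, user[[k]], paste0(path, ".", k))),
      names(user)))
  }
  for (k in names(user)) {
    here <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(base)) cta_stop("unknown config key: ", here)
    if (is.list(base[[k]]) && is.list(user[[k]])) {
      base[[k]] <- .merge_config(base[[k]], user[[k]], here)
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Read a YAML run configuration, layered over the defaults
#'
#' @param path YAML file; NULL returns the defaults
#' @return nested config list
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) cta_stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    cfg <- .merge_config(cfg, user)
  }
  cfg
}

#' Write a configuration as YAML
#' @param config nested config list
#' @param path output path
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

.geometry_from_config <- function(cfg) {
  d <- cfg$device
  device_geometry(chamber_length = d$chamber_length,
                  chamber_height = d$chamber_height,
                  chamber_width = d$chamber_width,
                  constriction_x = d$constriction_x,
                  pillar_extent = d$pillar_extent, gap_width = d$gap_width,
                  cell_length = d$cell_length, saturation_x = d$saturation_x)
}

.phenotype_from_config <- function(name, fields) {
  do.call(phenotype_params, c(list(label = name), fields))
}
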