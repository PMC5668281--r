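#' Default run configuration
#'
#' Returns the full nested list of generator, segmentation, feature and
#' analysis parameters. Every tunable of the package lives here; a YAML file
#' with the same structure (see [read_config()]) overrides defaults by key.
#'
#' Generator defaults emulate a 20x sCMOS acquisition of adherent reporter
#' cells at screening density: 768x768 px fields at 0.65 um/px with ~150
#' cells per field (near-confluent monolayer), log-normal per-cell reporter
#' totals (CV 0.25), additive background and mean-dependent camera noise
#' (variance = gain x mean plus Gaussian read noise), quantized to 16-bit
#' counts.
#'
#' @return Nested named list with elements `generator`, `segmentation`,
#'   `features`, `analysis`.
#' @export
#' @examples
#' cfg <- default_config()
#' names(cfg)
default_config <- function() {
  list(
    generator = list(
      field_shape = c(768L, 768L),
      pixel_size_um = 0.65,
      cells_per_field = 150L,
      fields_per_well = 4L,
      cell_body_scale = 1.9,
      channels = c("nuclear_dye", "cyto_dye", "reporter"),
      include_hook = FALSE,
      nuc_dye_mean = 300,
      cyto_dye_mean = 150,
      pyknotic_dye_gain = 1.8,
      hook_punctum_intensity = 2000,
      reporter_cv = 0.25,
      background = 40,
      noise_gain = 1.0,
      read_noise_sd = 3.0,
      noise_enabled = TRUE,
      placement_tolerance_px = 0,
      max_place_attempts = 500L,
      releaser_effect = 0.6,
      loss_effect = 0.7,
      toxic_effect = 0.6
    ),
    segmentation = list(
      smoothing_sigma = 1,
      threshold_method = "otsu",
      fixed_threshold = NA_real_,
      min_nucleus_area = 120,
      max_nucleus_area = 1400,
      split_touching = TRUE,
      cyto_max_radius = 32,
      annulus_fallback_px = 6,
      keep_border_objects = TRUE
    ),
    features = list(
      granularity_radius = 5L,
      pyknosis_alpha = 0.5,
      pyknosis_beta = 1.3,
      min_cells_per_well = 20L,
      ratio_eps = 1e-6
    ),
    analysis = list(
      features = c("mean_nuc_reporter", "mean_cyto_reporter", "mean_ratio",
                   "mean_granularity", "pyknotic_fraction"),
      z_population = "samples_only",
      t_hit = 2.0,
      t_null = 1.0,
      t_tox = 2.0,
      top_k = 20L
    )
  )
}

#' Read a run configuration from YAML
#'
#' Reads a (possibly partial) YAML configuration and merges it over
#' [default_config()]. Unknown keys raise a schema error naming them.
#'
#' @param path Path to a YAML file.
#' @return Full configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  merge_config(default_config(), user)
}

#' Write a configuration to YAML
#'
#' @param config Configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# Recursive merge with key validation: every user key must exist in the
# defaults, so typos surface as schema errors rather than silent no-ops.
merge_config <- function(base, user, prefix = "") {
  bad <- setdiff(names(user), names(base))
  if (length(bad) > 0)
    stop("unknown config key(s): ", paste0(prefix, bad, collapse = ", "))
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]]) && !is.null(names(base[[k]]))) {
      base[[k]] <- merge_config(base[[k]], user[[k]], paste0(prefix, k, "."))
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

validate_config <- function(config) {
  g <- config$generator
  known <- c("nuclear_dye", "cyto_dye", "reporter", "hook")
  bad <- setdiff(g$channels, known)
  if (length(bad) > 0)
    stop("unknown channel name(s) in config: ", paste(bad, collapse = ", "))
  need <- c("nuclear_dye", "cyto_dye", "reporter")
  if (!all(need %in% g$channels))
    stop("config channels must include: ", paste(need, collapse = ", "))
  s <- config$segmentation
  if (!(s$min_nucleus_area > 0 && s$min_nucleus_area < s$max_nucleus_area))
    stop("require 0 < min_nucleus_area < max_nucleus_area")
  if (s$cyto_max_radius <= 0) stop("cyto_max_radius must be > 0")
  invisible(config)
}
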