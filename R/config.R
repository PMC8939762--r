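# Configuration and report I/O.
#
# Interface keys carry explicit unit suffixes (_mm, _um, _hz, _mhz, _s,
# _ms, _m_s, _mm_s, _np_mm, _mpa, _v, _c) to prevent unit confusion;
# dimensionless keys are whitelisted.  Internals are SI-with-mm.

.dimensionless_keys <- c(
  "n_boundaries", "n_planes", "n_cycles", "n_bursts", "harmonic",
  "convention", "z_order", "medium", "seed", "method", "normalize",
  "duty_cycle", "amplitude", "noise_sd", "spots_per_plane", "version")

.unit_suffixes <- c("_mm", "_um", "_hz", "_mhz", "_s", "_ms", "_m_s",
                    "_mm_s", "_np_mm", "_mpa", "_pa", "_v", "_vpp", "_c",
                    "_kg_m3", "_w_cm2", "_min")

.known_keys <- c(
  .dimensionless_keys,
  "focal_length_mm", "frequency_hz", "design_sound_speed_m_s",
  "matching_layer_sound_speed_m_s",
  "skin_mm", "gel_mm", "distances_mm", "calibration_mpa",
  "diameter_mm", "spacing_mm", "z_spacing_mm", "z_start_mm",
  "dwell_s", "speed_mm_s", "focal_diameter_um", "voxel_um",
  "total_diameter_mm", "total_height_mm",
  "prf_hz", "pulse_width_s", "pressure_mpa", "drive_vpp",
  "sample_rate_hz", "thickness_mm", "temp_c", "time_min")

#' Validate a configuration list
#'
#' Checks that every key is known and that numeric keys carry a unit
#' suffix; unknown or suffix-less keys are reported together.
#'
#' @param cfg named list (from [load_config()] or built in code).
#' @return `cfg`, invisibly, or an error naming every offending key.
#' @export
validate_config <- function(cfg) {
  if (is.null(names(cfg)) || any(!nzchar(names(cfg)))) {
    stop("config must be a fully named list", call. = FALSE)
  }
  keys <- names(cfg)
  unknown <- setdiff(keys, .known_keys)
  has_suffix <- vapply(keys, function(k) {
    any(endsWith(k, .unit_suffixes))
  }, logical(1))
  missing_units <- keys[!has_suffix & !(keys %in% .dimensionless_keys) &
                          vapply(cfg, is.numeric, logical(1))]
  problems <- c(
    if (length(unknown)) sprintf("unknown keys: %s",
                                 paste(unknown, collapse = ", ")),
    if (length(missing_units)) sprintf(
      "numeric keys without unit suffix: %s",
      paste(missing_units, collapse = ", ")))
  if (length(problems)) {
    stop(paste(c("invalid config:", problems), collapse = "\n  "),
         call. = FALSE)
  }
  invisible(cfg)
}

#' Load a YAML or JSON configuration file
#'
#' Format chosen by extension (`.yaml`/`.yml` or `.json`); the result is
#' passed through [validate_config()].
#'
#' @param path file path.
#' @return named list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                "yaml" = , "yml" = yaml::read_yaml(path),
                "json" = jsonlite::fromJSON(path, simplifyVector = TRUE),
                stop(sprintf("unsupported config format '.%s'", ext),
                     call. = FALSE))
  validate_config(cfg)
  cfg
}

#' Save a configuration file
#'
#' @param cfg named list (validated first).
#' @param path destination; `.yaml`/`.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  validate_config(cfg)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         "yaml" = , "yml" = yaml::write_yaml(cfg, path),
         "json" = jsonlite::write_json(cfg, path, auto_unbox = TRUE,
                                       digits = NA, pretty = TRUE),
         stop(sprintf("unsupported config format '.%s'", ext),
              call. = FALSE))
  invisible(path)
}

#' Write a result report with a provenance block
#'
#' JSON report carrying the results plus the seed, package version and
#' the MD5 of the originating config file.  Timestamps are omitted so
#' that two runs with the same inputs produce byte-identical reports.
#'
#' @param results named list of results (numbers, vectors, strings).
#' @param path destination `.json` file.
#' @param seed the seed the run used, if any.
#' @param config_path path of the config the run loaded, if any (hashed
#'   into the provenance block).
#' @return `path`, invisibly.
#' @export
save_report <- function(results, path, seed = NULL, config_path = NULL) {
  prov <- list(
    package = "sfat",
    version = as.character(utils::packageVersion("sfat")),
    seed = seed,
    config_md5 = if (!is.null(config_path))
      unname(tools::md5sum(config_path)) else NULL)
  jsonlite::write_json(list(provenance = prov, results = results),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
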