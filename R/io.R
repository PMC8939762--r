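# Machine-readable lens / plan / field / profile files.  Every writer
# has a reader that inverts it.

#' Write and read a lens design as JSON
#'
#' @param lens an [lens_design()].
#' @param path destination `.json`.
#' @return `write_lens_json`: `path` invisibly; `read_lens_json`: an
#'   `sfat_lens`.
#' @export
write_lens_json <- function(lens, path) {
  stopifnot(inherits(lens, "sfat_lens"))
  jsonlite::write_json(
    list(focal_length_mm = lens$focal_length_mm,
         frequency_hz = lens$frequency_hz,
         design_sound_speed_m_s = lens$design_sound_speed_m_s,
         n_boundaries = length(lens$boundary_radii_mm),
         boundary_radii_mm = lens$boundary_radii_mm,
         annuli_mm = lens$annuli_mm,
         matching_layer_mm = lens$matching_layer_mm),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_lens_json
#' @export
read_lens_json <- function(path) {
  j <- jsonlite::fromJSON(path)
  lens <- lens_design(focal_length_mm = j$focal_length_mm,
                      frequency_hz = j$frequency_hz,
                      design_sound_speed_m_s = j$design_sound_speed_m_s,
                      n_boundaries = j$n_boundaries)
  # the stored radii are authoritative (guards against formula drift)
  stopifnot(max(abs(lens$boundary_radii_mm - j$boundary_radii_mm)) < 1e-9)
  lens
}

#' Write and read a scan plan as JSON
#'
#' @param plan an [scan_plan()].
#' @param path destination `.json`.
#' @return `write_plan_json`: `path` invisibly; `read_plan_json`: an
#'   `sfat_scan_plan`.
#' @export
write_plan_json <- function(plan, path) {
  stopifnot(inherits(plan, "sfat_scan_plan"))
  jsonlite::write_json(
    plan[c("diameter_mm", "spacing_mm", "convention", "n_planes",
           "z_spacing_mm", "z_order", "dwell_s", "speed_mm_s",
           "spots_per_plane")],
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_plan_json
#' @export
read_plan_json <- function(path) {
  j <- jsonlite::fromJSON(path)
  scan_plan(diameter_mm = j$diameter_mm, spacing_mm = j$spacing_mm,
            n_planes = j$n_planes, z_spacing_mm = j$z_spacing_mm,
            dwell_s = j$dwell_s, speed_mm_s = j$speed_mm_s,
            convention = j$convention, z_order = j$z_order,
            spots_per_plane = j$spots_per_plane)
}

#' Export a spot table as CSV
#'
#' Columns `x_mm`, `y_mm`, `z_mm`, `order` for every spot of every
#' plane, in execution order.
#'
#' @param plan an [scan_plan()].
#' @param path destination `.csv`.
#' @return `path`, invisibly.
#' @export
write_spot_csv <- function(plan, path) {
  stopifnot(inherits(plan, "sfat_scan_plan"))
  n <- nrow(plan$spots)
  out <- do.call(rbind, lapply(seq_len(plan$n_planes), function(pl) {
    data.frame(x_mm = plan$spots$x_mm, y_mm = plan$spots$y_mm,
               z_mm = plan$z_planes_mm[pl],
               order = (pl - 1) * n + seq_len(n))
  }))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write and read a pressure field as CSV plus JSON metadata
#'
#' Long-format CSV (`r_mm`, `z_mm`, `p_real`, `p_imag`) with a JSON
#' sidecar (`<path>.meta.json`) holding the method, media and
#' calibration.
#'
#' @param field an `sfat_field`.
#' @param path destination `.csv`.
#' @return `write_field_csv`: `path` invisibly; `read_field_csv`: an
#'   `sfat_field`.
#' @export
write_field_csv <- function(field, path) {
  stopifnot(inherits(field, "sfat_field"))
  grid <- expand.grid(r_mm = field$r_mm, z_mm = field$z_mm)
  utils::write.csv(
    data.frame(grid, p_real = as.vector(Re(field$p)),
               p_imag = as.vector(Im(field$p))),
    path, row.names = FALSE)
  meta <- list(method = field$method,
               frequency_hz = field$frequency_hz,
               calibration_scale = field$calibration_scale,
               layer_thickness_mm = field$layer_thickness_mm,
               media = lapply(field$media, unclass))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path) {
  d <- utils::read.csv(path)
  meta <- jsonlite::fromJSON(paste0(path, ".meta.json"),
                             simplifyDataFrame = FALSE)
  r <- sort(unique(d$r_mm))
  z <- sort(unique(d$z_mm))
  p <- matrix(complex(real = d$p_real, imaginary = d$p_imag),
              length(r), length(z))
  structure(
    list(r_mm = r, z_mm = z, p = p, frequency_hz = meta$frequency_hz,
         method = meta$method,
         media = lapply(meta$media, function(m)
           medium(m$name, m$density_kg_m3, m$sound_speed_m_s,
                  m$attenuation_np_mm)),
         layer_thickness_mm = unlist(meta$layer_thickness_mm) %||% numeric(0),
         calibration_scale = meta$calibration_scale %||% NA_real_),
    class = "sfat_field")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export and import normalized beam profiles as CSV
#'
#' Two-column profile (`coordinate`, `amplitude`) with the axis label
#' and units in an `axis` column, matching hydrophone beam-profile
#' exports.  Amplitudes are normalized to a peak of 1 on write.
#'
#' @param coordinate axial (mm) or lateral (um) positions.
#' @param amplitude pressure amplitudes (normalized on write).
#' @param axis `"axial"` or `"lateral"`.
#' @param path destination `.csv`.
#' @return `write_profile_csv`: `path` invisibly; `read_profile_csv`:
#'   data.frame with `coordinate`, `amplitude`, `axis`.
#' @export
write_profile_csv <- function(coordinate, amplitude, axis, path) {
  stopifnot(length(coordinate) == length(amplitude),
            axis %in% c("axial", "lateral"))
  utils::write.csv(
    data.frame(coordinate = coordinate,
               amplitude = amplitude / max(amplitude),
               axis = axis),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
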