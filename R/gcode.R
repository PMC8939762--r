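#' Export a scan plan as G-code
#'
#' Minimal RS-274 subset understood by consumer 3-axis controllers:
#' `G21` (millimetres), `G90` (absolute coordinates), `G1` linear moves
#' at a fixed feedrate (mm/min), `G4 P<ms>` dwell at each treatment
#' spot, and `G1 Z` moves between planes.  Coordinates are written with
#' three decimals; [parse_gcode()] inverts the export exactly at that
#' precision.
#'
#' @param plan an [scan_plan()].
#' @param path optional file to write; when `NULL` the lines are
#'   returned invisibly only.
#' @param comment logical: include a header comment block.
#' @return character vector of G-code lines (invisibly when `path`
#'   given).
#' @export
export_gcode <- function(plan, path = NULL, comment = TRUE) {
  stopifnot(inherits(plan, "sfat_scan_plan"))
  feed <- plan$speed_mm_s * 60
  dwell_ms <- round(plan$dwell_s * 1000)
  num <- function(x) sprintf("%.3f", x)
  lines <- character(0)
  if (comment) {
    lines <- c(lines, sprintf(
      "; raster treatment scan: %d spots/plane x %d planes, dwell %g s",
      nrow(plan$spots), plan$n_planes, plan$dwell_s))
  }
  lines <- c(lines, "G21", "G90", sprintf("G1 F%s", num(feed)))
  for (pl in seq_len(plan$n_planes)) {
    lines <- c(lines, sprintf("G1 Z%s", num(plan$z_planes_mm[pl])))
    lines <- c(lines, unlist(lapply(seq_len(nrow(plan$spots)), function(i) {
      c(sprintf("G1 X%s Y%s", num(plan$spots$x_mm[i]),
        num(plan$spots$y_mm[i])),
        sprintf("G4 P%d", dwell_ms))
    })))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Parse G-code back into a scan-plan description
#'
#' Inverse of [export_gcode()] for the emitted dialect.  Unsupported
#' words are rejected with their line numbers.
#'
#' @param x character vector of G-code lines, or a file path.
#' @return list with `spots` (data.frame `x_mm`, `y_mm` in route order,
#'   from the first plane), `z_planes_mm`, `dwell_s`, `speed_mm_s`,
#'   `n_planes`, `spots_per_plane`.
#' @export
parse_gcode <- function(x) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x) else x
  feed <- NA_real_
  dwell_ms <- NA_real_
  cur_x <- NA_real_; cur_y <- NA_real_; cur_z <- NA_real_
  xs <- numeric(0); ys <- numeric(0); zs <- numeric(0)
  z_planes <- numeric(0)
  bad <- character(0)
  for (i in seq_along(lines)) {
    ln <- trimws(sub(";.*$", "", lines[i]))
    if (!nzchar(ln)) next
    words <- strsplit(ln, "[[:space:]]+")[[1]]
    head_word <- toupper(words[1])
    if (head_word %in% c("G21", "G90", "G0")) {
      next
    } else if (head_word == "G4") {
      p <- grep("^P", toupper(words[-1]), value = TRUE)
      if (!length(p)) {
        bad <- c(bad, sprintf("line %d: G4 without P word", i))
        next
      }
      dwell_ms <- as.numeric(sub("^P", "", p[1]))
      # a dwell marks the current position as a treatment spot
      xs <- c(xs, cur_x); ys <- c(ys, cur_y); zs <- c(zs, cur_z)
    } else if (head_word == "G1") {
      for (w in words[-1]) {
        axis <- toupper(substr(w, 1, 1))
        val <- suppressWarnings(as.numeric(substr(w, 2, nchar(w))))
        if (is.na(val)) {
          bad <- c(bad, sprintf("line %d: malformed word '%s'", i, w))
        } else if (axis == "X") cur_x <- val
        else if (axis == "Y") cur_y <- val
        else if (axis == "Z") {
          cur_z <- val
          z_planes <- c(z_planes, val)
        } else if (axis == "F") feed <- val
        else bad <- c(bad, sprintf("line %d: unsupported axis '%s'", i, axis))
      }
    } else {
      bad <- c(bad, sprintf("line %d: unsupported word '%s'", i, head_word))
    }
  }
  if (length(bad)) {
    stop(paste(c("G-code parse errors:", bad), collapse = "\n  "),
         call. = FALSE)
  }
  n_planes <- length(z_planes)
  spp <- if (n_planes > 0) sum(zs == z_planes[1]) else length(xs)
  first <- if (n_planes > 0) zs == z_planes[1] else rep(TRUE, length(xs))
  list(spots = data.frame(x_mm = xs[first], y_mm = ys[first]),
       z_planes_mm = z_planes,
       dwell_s = dwell_ms / 1000,
       speed_mm_s = feed / 60,
       n_planes = max(1L, n_planes),
       spots_per_plane = spp)
}
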