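#' Arena geometry for the ring-gap climbing disk
#'
#' Describes the circular climbing disk: a bowl-like centre recess from which
#' the flies start, five (by default) concentric water-filled ring-gaps
#' ("grooves") of increasing width, and the land rings between them. All
#' lengths are in millimetres; the coordinate origin is the disk centre.
#'
#' The default geometry is a disk of radius 69 mm with grooves of widths
#' 2.0, 2.5, 3.0, 3.5 and 4.0 mm. Groove radial placement is configurable;
#' by default the recess (radius 10 mm), the five grooves and the rim are
#' separated by six equal land rings, so the outermost groove's outer edge
#' plus one land width ends exactly at the rim.
#'
#' @param disk_radius Disk radius in mm.
#' @param disk_height Disk height in mm (informational).
#' @param recess_radius Radius of the centre recess in mm.
#' @param groove_widths Strictly increasing groove widths in mm.
#' @param groove_inner_radii Inner radius of each groove in mm, or `NULL` to
#'   place the grooves with equal land widths between recess, grooves and rim.
#' @param ceiling_gap Clearance between disk surface and cover glass in mm.
#'
#' @return An object of class `arena_geometry`: a list with the fields above
#'   plus `groove_outer_radii`.
#' @examples
#' geom <- arena_geometry()
#' geom$groove_widths
#' @export
arena_geometry <- function(disk_radius = 69,
                           disk_height = 15,
                           recess_radius = 10,
                           groove_widths = c(2.0, 2.5, 3.0, 3.5, 4.0),
                           groove_inner_radii = NULL,
                           ceiling_gap = 3) {
  if (!is.numeric(disk_radius) || disk_radius <= 0) {
    abort_config("`disk_radius` must be a positive number.")
  }
  if (any(diff(groove_widths) <= 0)) {
    abort_config("`groove_widths` must be strictly increasing.")
  }
  n <- length(groove_widths)
  if (is.null(groove_inner_radii)) {
    land <- (disk_radius - recess_radius - sum(groove_widths)) / (n + 1)
    if (land <= 0) {
      abort_config("Grooves do not fit inside the disk with equal land widths.")
    }
    groove_inner_radii <- recess_radius + land * seq_len(n) +
      cumsum(c(0, groove_widths[-n]))
  }
  outer <- groove_inner_radii + groove_widths
  if (recess_radius >= groove_inner_radii[1]) {
    abort_config("`recess_radius` must be smaller than the innermost groove inner radius.")
  }
  if (any(outer[-n] >= groove_inner_radii[-1])) {
    abort_config("Groove annuli must be pairwise disjoint.")
  }
  if (outer[n] > disk_radius) {
    abort_config("Outermost groove extends beyond the disk rim.")
  }
  structure(
    list(
      disk_radius = disk_radius,
      disk_height = disk_height,
      recess_radius = recess_radius,
      groove_widths = groove_widths,
      groove_inner_radii = groove_inner_radii,
      groove_outer_radii = outer,
      ceiling_gap = ceiling_gap
    ),
    class = "arena_geometry"
  )
}

#' @export
print.arena_geometry <- function(x, ...) {
  cat("<arena_geometry> disk radius", x$disk_radius, "mm,",
      length(x$groove_widths), "grooves (widths",
      paste(x$groove_widths, collapse = ", "), "mm)\n")
  invisible(x)
}

#' Single-gap catwalk setup
#'
#' Describes the linear catwalk with one rectangular gap used for per-approach
#' scoring: a walkway 30 mm long, 10 mm high and 4 mm wide with a gap of
#' 2.0--6.0 mm width and 5 mm depth in the middle. The distal sidewall can be
#' dark plastic (`"dark"`), clear Perspex (`"clear"`, weak contrast) or
#' decorated with vertical black-and-white stripes (`"striped"`, enhanced
#' contrast).
#'
#' @param gap_width Gap width in mm, in \[2, 6\].
#' @param visibility One of `"dark"`, `"clear"`, `"striped"`.
#' @param length,height,width Catwalk dimensions in mm.
#' @param gap_depth Gap depth in mm.
#' @return An object of class `catwalk_setup`.
#' @examples
#' catwalk_setup(4.0, "striped")
#' @export
catwalk_setup <- function(gap_width,
                          visibility = c("dark", "clear", "striped"),
                          length = 30, height = 10, width = 4,
                          gap_depth = 5) {
  visibility <- match.arg(visibility)
  if (!is.numeric(gap_width) || length(gap_width) != 1 || gap_width <= 0) {
    abort_config("`gap_width` must be a single positive number (mm).")
  }
  if (gap_width < 2 || gap_width > 6) {
    abort_config("`gap_width` must lie in [2, 6] mm.")
  }
  structure(
    list(gap_width = gap_width, visibility = visibility,
         length = length, height = height, width = width,
         gap_depth = gap_depth),
    class = "catwalk_setup"
  )
}

# Index of the groove annulus containing radius r, or NA_integer_.
groove_at_radius <- function(r, geometry) {
  hit <- which(r >= geometry$groove_inner_radii & r <= geometry$groove_outer_radii)
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

abort_config <- function(msg) {
  rlang::abort(msg, class = "ringgap_error_config")
}

abort_validation <- function(msg) {
  rlang::abort(msg, class = "ringgap_error_validation")
}
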