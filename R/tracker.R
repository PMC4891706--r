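#' Render a synthetic overhead-camera frame
#'
#' Emulates one 1 Hz frame of the backlit climbing disk: bright disk
#' surface, darker water-filled groove annuli, dark background outside the
#' disk, and one dark elliptical blob (about a body length of 2.6 mm) per
#' fly. Overlapping flies merge into one blob, as they would on camera.
#'
#' @param positions A data frame with `x_mm`, `y_mm` (may have zero rows).
#' @param geometry An [arena_geometry()].
#' @param pixel_pitch Pixel size in mm/px.
#' @param body_length,body_width Blob axes in mm.
#' @return A numeric intensity matrix in \[0, 1\] of class `ringgap_frame`
#'   with attributes `pixel_pitch` and `centre` (px coordinates of the disk
#'   centre). Rows run along -y (image convention), columns along +x.
#' @examples
#' fr <- render_frame(tibble::tibble(x_mm = 0, y_mm = 0), arena_geometry(),
#'                    pixel_pitch = 0.5)
#' dim(fr)
#' @export
render_frame <- function(positions, geometry, pixel_pitch = 0.2,
                         body_length = 2.6, body_width = 1.2) {
  base <- frame_background(geometry, pixel_pitch)
  img <- base$img
  if (nrow(positions) > 0) {
    r <- sqrt(positions$x_mm^2 + positions$y_mm^2)
    if (any(r > geometry$disk_radius + 1e-9)) {
      abort_validation("Fly positions outside the disk cannot be rendered.")
    }
    a <- body_length / 2 / pixel_pitch
    b <- body_width / 2 / pixel_pitch
    half <- ceiling(a) + 1L
    n_px <- nrow(img)
    for (i in seq_len(nrow(positions))) {
      cc <- base$centre[1] + positions$x_mm[i] / pixel_pitch
      rr <- base$centre[2] - positions$y_mm[i] / pixel_pitch
      rows <- max(1L, floor(rr - half)):min(n_px, ceiling(rr + half))
      cols <- max(1L, floor(cc - half)):min(ncol(img), ceiling(cc + half))
      dr <- (rows - rr) / b
      dc <- (cols - cc) / a
      mask <- outer(dr^2, dc^2, `+`) <= 1
      img[rows, cols][mask] <- 0.08
    }
  }
  structure(img, pixel_pitch = pixel_pitch, centre = base$centre,
            class = c("ringgap_frame", "matrix", "array"))
}

# Disk background (bright field, darker grooves, dark exterior), cached per
# geometry/pitch within a session.
frame_background <- function(geometry, pixel_pitch) {
  key <- paste0(signif(geometry$disk_radius, 10), "_",
                paste(signif(geometry$groove_inner_radii, 10), collapse = ","),
                "_", pixel_pitch)
  cached <- .ringgap_cache[[key]]
  if (!is.null(cached)) return(cached)
  pad <- 4L
  n_px <- 2L * (ceiling(geometry$disk_radius / pixel_pitch) + pad) + 1L
  centre <- c((n_px + 1) / 2, (n_px + 1) / 2) # (col, row) of disk centre
  cols <- matrix(seq_len(n_px), n_px, n_px, byrow = TRUE)
  rows <- matrix(seq_len(n_px), n_px, n_px)
  r_mm <- sqrt((cols - centre[1])^2 + (rows - centre[2])^2) * pixel_pitch
  img <- matrix(0.2, n_px, n_px) # outside the disk
  img[r_mm <= geometry$disk_radius] <- 1.0
  for (g in seq_along(geometry$groove_widths)) {
    in_groove <- r_mm >= geometry$groove_inner_radii[g] &
      r_mm <= geometry$groove_outer_radii[g]
    img[in_groove] <- 0.75
  }
  out <- list(img = img, centre = centre)
  .ringgap_cache[[key]] <- out
  out
}

.ringgap_cache <- new.env(parent = emptyenv())

#' Detect fly blobs in a frame
#'
#' Thresholds the frame (by default Otsu's method on the land surface of
#' the disk interior -- the groove annuli are excluded from the threshold
#' estimate so that the split separates fly blobs from the bright land
#' rather than grooves from land, keeping drowned flies inside a groove
#' detectable), labels connected components and keeps those whose area
#' falls inside the size band, returning centroids in mm. Components that
#' escape the band (such as whole groove annuli under a manual threshold)
#' are rejected by area; two flies closer than about a body length merge
#' into a single detection.
#'
#' @param frame A `ringgap_frame` from [render_frame()].
#' @param geometry An [arena_geometry()].
#' @param threshold Intensity threshold; `NULL` for the Otsu default.
#' @param size_band Accepted blob area in mm^2 (`c(min, max)`).
#' @return A tibble with `x_mm`, `y_mm`, `area_px`, `area_mm2`.
#' @export
detect_blobs <- function(frame, geometry, threshold = NULL,
                         size_band = c(0.8, 20)) {
  pitch <- attr(frame, "pixel_pitch")
  centre <- attr(frame, "centre")
  img <- unclass(frame)
  attributes(img) <- list(dim = dim(img))
  if (is.null(threshold)) {
    n_px <- nrow(img)
    cols <- matrix(seq_len(n_px), n_px, n_px, byrow = TRUE)
    rows <- matrix(seq_len(n_px), n_px, n_px)
    r_mm <- sqrt((cols - centre[1])^2 + (rows - centre[2])^2) * pitch
    in_groove <- rep(FALSE, length(r_mm))
    for (g in seq_along(geometry$groove_widths)) {
      in_groove <- in_groove | (r_mm >= geometry$groove_inner_radii[g] &
                                  r_mm <= geometry$groove_outer_radii[g])
    }
    land <- img[r_mm <= geometry$disk_radius & !in_groove]
    threshold <- EBImage::otsu(EBImage::Image(matrix(land, ncol = 1)),
                               range = c(0, 1))
  }
  mask <- img < threshold
  if (!any(mask)) {
    return(tibble::tibble(x_mm = numeric(), y_mm = numeric(),
                          area_px = integer(), area_mm2 = numeric()))
  }
  labels <- EBImage::bwlabel(mask)
  idx <- which(labels > 0)
  lab <- labels[idx]
  row_i <- ((idx - 1L) %% nrow(img)) + 1L
  col_i <- ((idx - 1L) %/% nrow(img)) + 1L
  area <- as.vector(table(lab))
  cen_r <- tapply(row_i, lab, mean)
  cen_c <- tapply(col_i, lab, mean)
  area_mm2 <- area * pitch^2
  keep <- area_mm2 >= size_band[1] & area_mm2 <= size_band[2]
  out <- tibble::tibble(
    x_mm = (cen_c[keep] - centre[1]) * pitch,
    y_mm = (centre[2] - cen_r[keep]) * pitch,
    area_px = as.integer(area[keep]),
    area_mm2 = area_mm2[keep])
  inside <- sqrt(out$x_mm^2 + out$y_mm^2) <= geometry$disk_radius
  out[inside, ]
}

#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbour assignment of detections to the previous
#' frame's track positions within a gating radius (the largest plausible
#' 1 s displacement). Tracks with no detection in a frame (a fly hidden in
#' a merged blob) are carried at their last position and flagged as
#' coasting; when a surplus detection appears while all track slots are
#' taken, it re-captures the nearest coasting track. More detections than
#' `n_flies` in any frame is a validation error.
#'
#' @param detections A list of per-frame detection tibbles (one per second,
#'   frame times 0, 1, 2, ...), as from [detect_blobs()].
#' @param n_flies Number of track slots.
#' @param gate Gating radius in mm.
#' @return A `ring_tracks`-shaped tibble with `t_s`, `fly_id`, `x_mm`,
#'   `y_mm`, `status` (all `"alive"`; apply [annotate_deaths()] to recover
#'   drowned flies) and a logical `coasting` column.
#' @export
link_detections <- function(detections, n_flies = 15, gate = 15) {
  n_frames <- length(detections)
  if (n_frames == 0L) abort_validation("No frames to link.")
  for (f in seq_len(n_frames)) {
    if (nrow(detections[[f]]) > n_flies) {
      abort_validation(paste0("Frame ", f - 1L, " has ",
                              nrow(detections[[f]]),
                              " detections but only ", n_flies,
                              " flies are configured."))
    }
  }
  first <- detections[[1]]
  n_tracks <- nrow(first)
  tx <- first$x_mm
  ty <- first$y_mm
  out <- vector("list", n_frames)
  out[[1]] <- tibble::tibble(t_s = 0L, fly_id = seq_len(n_tracks),
                             x_mm = tx, y_mm = ty, coasting = FALSE)
  for (f in 2:n_frames) {
    det <- detections[[f]]
    matched_track <- rep(FALSE, n_tracks)
    matched_det <- rep(FALSE, nrow(det))
    if (nrow(det) > 0 && n_tracks > 0) {
      dmat <- outer(tx, det$x_mm, `-`)^2 + outer(ty, det$y_mm, `-`)^2
      repeat {
        i <- which.min(replace(dmat, outer(matched_track, matched_det, `|`),
                               Inf))
        if (length(i) == 0L || !is.finite(dmat[i])) break
        ti <- ((i - 1L) %% n_tracks) + 1L
        di <- ((i - 1L) %/% n_tracks) + 1L
        if (dmat[i] > gate^2) break
        tx[ti] <- det$x_mm[di]
        ty[ti] <- det$y_mm[di]
        matched_track[ti] <- TRUE
        matched_det[di] <- TRUE
        if (all(matched_track) || all(matched_det)) break
      }
    }
    for (di in which(!matched_det)) {
      if (n_tracks < n_flies) { # open a new track slot
        n_tracks <- n_tracks + 1L
        tx[n_tracks] <- det$x_mm[di]
        ty[n_tracks] <- det$y_mm[di]
        matched_track[n_tracks] <- TRUE
        # back-fill earlier frames with the first observed position
        for (g in seq_len(f - 1L)) {
          out[[g]] <- dplyr::bind_rows(out[[g]], tibble::tibble(
            t_s = g - 1L, fly_id = n_tracks,
            x_mm = det$x_mm[di], y_mm = det$y_mm[di], coasting = TRUE))
        }
      } else { # re-capture the nearest coasting track, no gate
        free <- which(!matched_track)
        if (length(free) == 0L) break
        d2 <- (tx[free] - det$x_mm[di])^2 + (ty[free] - det$y_mm[di])^2
        ti <- free[which.min(d2)]
        tx[ti] <- det$x_mm[di]
        ty[ti] <- det$y_mm[di]
        matched_track[ti] <- TRUE
      }
    }
    out[[f]] <- tibble::tibble(t_s = f - 1L, fly_id = seq_len(n_tracks),
                               x_mm = tx[seq_len(n_tracks)],
                               y_mm = ty[seq_len(n_tracks)],
                               coasting = !matched_track[seq_len(n_tracks)])
  }
  res <- dplyr::bind_rows(out) %>%
    dplyr::arrange(.data$fly_id, .data$t_s) %>%
    dplyr::mutate(status = "alive", .before = "coasting")
  res
}

#' Annotate drowned flies on a recovered track table
#'
#' Applies the immobility-in-groove rule of [detect_deaths_from_track()] to
#' every fly and rewrites `status` to `"dead"` from the detected drowning
#' time onward.
#'
#' @param tracks A track table (`t_s`, `fly_id`, `x_mm`, `y_mm`).
#' @param geometry An [arena_geometry()].
#' @param eps Immobility tolerance in mm.
#' @return `tracks` with an updated `status` column.
#' @export
annotate_deaths <- function(tracks, geometry, eps = 0.5) {
  tracks %>%
    dplyr::arrange(.data$fly_id, .data$t_s) %>%
    dplyr::group_by(.data$fly_id) %>%
    dplyr::group_modify(function(df, key) {
      d <- detect_deaths_from_track(df, geometry, eps)
      df$status <- "alive"
      if (d$is_dead) df$status[df$t_s >= d$death_time] <- "dead"
      df
    }) %>%
    dplyr::ungroup() %>%
    dplyr::relocate("t_s", "fly_id")
}

#' Track a stack of rendered frames
#'
#' Convenience wrapper: detect blobs in every frame, link them, and
#' annotate deaths, yielding a track table in the same dialect as
#' [simulate_ring_experiment()].
#'
#' @param frames List of `ringgap_frame` matrices (1 Hz).
#' @param geometry An [arena_geometry()].
#' @param n_flies,gate,threshold,size_band,eps See [detect_blobs()] and
#'   [link_detections()].
#' @return A `ring_tracks` tibble.
#' @export
track_frames <- function(frames, geometry, n_flies = 15, gate = 15,
                         threshold = NULL, size_band = c(0.8, 20),
                         eps = 0.5) {
  det <- purrr::map(frames, detect_blobs, geometry = geometry,
                    threshold = threshold, size_band = size_band)
  linked <- link_detections(det, n_flies = n_flies, gate = gate)
  out <- annotate_deaths(linked, geometry, eps = eps)
  new_ring_tracks(dplyr::select(out, "t_s", "fly_id", "x_mm", "y_mm",
                                "status"),
                  geometry = geometry)
}
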