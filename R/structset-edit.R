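# Structure-set defacing: drop eye/lens/cornea ROIs, rebuild the body
# contour, clip other ROIs that protrude into the cropped region, and keep
# PTV and brain contour data untouched.

#' Clip an ROI against the retain-mask
#'
#' Clipping happens in voxel space: the ROI is rasterized, intersected with
#' the kept-voxel set, and polygonized back to planar contours. This handles
#' the non-convex carve-outs that PTV/brain preservation puts into the mask
#' uniformly, at the cost of sub-voxel fidelity. An ROI left with no voxels
#' is returned with an empty polygon list (with a warning) rather than
#' dropped.
#'
#' @param roi A [roi_contour()].
#' @param mask A [build_retain_mask()] result.
#' @param geometry The CT [image_volume()] defining the grid.
#' @return The clipped [roi_contour()] (name, number, role preserved).
#' @export
clip_roi <- function(roi, mask, geometry) {
  m <- rasterize_roi(roi, geometry) & mask$keep
  polys <- polygonize_mask(m, geometry)
  if (length(polys) == 0) {
    warning("ROI '", roi$name, "' lies entirely inside the cropped region; ",
            "kept with no contours", call. = FALSE)
  }
  roi_contour(roi$name, roi$number, polys, role = roi$role)
}

#' Rebuild the body contour after defacing
#'
#' The body outline must follow the defaced image surface: same voxel-space
#' clipping as [clip_roi()], applied to the body ROI.
#'
#' @inheritParams clip_roi
#' @param body The body [roi_contour()].
#' @return The rebuilt body [roi_contour()].
#' @export
rebuild_body <- function(body, mask, geometry) {
  clip_roi(body, mask, geometry)
}

#' Deface a structure set
#'
#' Eye, lens and cornea ROIs are removed outright. PTV and brain ROIs pass
#' through with their polygon data untouched. The body contour is rebuilt to
#' follow the defaced surface. Any other ROI is clipped iff some of its
#' voxels fall in the removed region; otherwise it is returned vertex-for-
#' vertex unchanged. ROI numbers and names of surviving ROIs are preserved.
#'
#' @param ss A [structure_set()] referencing `volume`'s frame of reference.
#' @param mask A [build_retain_mask()] result.
#' @param volume The CT [image_volume()].
#' @return The defaced [structure_set()].
#' @export
deface_structure_set <- function(ss, mask, volume) {
  if (!identical(ss$frame_of_reference, volume$frame_of_reference)) {
    stop_geometry("structure set frame of reference does not match the CT")
  }
  out <- list()
  body_seen <- FALSE
  for (r in ss$rois) {
    if (r$role %in% c("eye", "lens", "cornea")) next
    if (r$role %in% c("ptv", "brain")) {
      out[[length(out) + 1L]] <- r
      next
    }
    if (r$role == "body") {
      body_seen <- TRUE
      out[[length(out) + 1L]] <- rebuild_body(r, mask, volume)
      next
    }
    m <- rasterize_roi(r, volume)
    if (any(m & !mask$keep)) {
      out[[length(out) + 1L]] <- clip_roi(r, mask, volume)
    } else {
      out[[length(out) + 1L]] <- r
    }
  }
  if (!body_seen) {
    warning("no body ROI found; structure set defaced without a body rebuild",
            call. = FALSE)
  }
  structure_set(out, frame_of_reference = ss$frame_of_reference,
                referenced_series = ss$referenced_series,
                referenced_study = ss$referenced_study,
                referenced_instances = ss$referenced_instances,
                label = ss$label)
}
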