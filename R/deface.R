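# Defacing core: eye-derived crop landmarks, retain-mask construction with
# PTV/brain preservation, and mask application to the image.

#' Compute crop landmarks from the contoured eyes
#'
#' The crop region is defined by two scalars derived from the eye contours:
#' `z_inf`, the position of the inferior-most slice containing any eye
#' contour (snapped to the nearest CT slice), and `y_mid`, the
#' anterior-posterior midpoint of the eyes, taken as the unweighted mean over
#' eye ROIs of each ROI's vertex-centroid y coordinate. Voxels on or above
#' `z_inf` and anterior to `y_mid` are candidates for removal.
#'
#' @param ss A [structure_set()] containing at least one ROI with role `eye`.
#' @param volume The [image_volume()] the contours refer to.
#' @return An object of class `crop_landmarks` with fields `z_inf`, `y_mid`,
#'   `source_roi_names`.
#' @export
compute_landmarks <- function(ss, volume) {
  eyes <- rois_with_role(ss, "eye")
  eyes <- Filter(function(r) length(r$polygons) > 0, eyes)
  if (length(eyes) == 0) {
    stop_no_eyes("eyes not contoured: no ROI with role 'eye' has contour data")
  }
  if (length(eyes) == 1) {
    warning("only one eye ROI found ('", eyes[[1]]$name,
            "'); landmarks use that eye alone", call. = FALSE)
  }
  z_min <- min(vapply(eyes, function(r) {
    min(vapply(r$polygons, function(p) p[1, 3], numeric(1)))
  }, numeric(1)))
  k <- which.min(abs(volume$slice_positions - z_min))
  z_inf <- volume$slice_positions[k]

  centroid_y <- vapply(eyes, function(r) {
    ys <- unlist(lapply(r$polygons, function(p) p[, 2]))
    mean(ys)
  }, numeric(1))
  y_mid <- mean(centroid_y)

  g <- geom_axes(volume)
  if (y_mid < min(g$y) || y_mid > max(g$y)) {
    stop_geometry("eye midpoint y=", signif(y_mid, 6), " mm lies outside the image")
  }
  structure(list(z_inf = z_inf, y_mid = y_mid,
                 source_roi_names = vapply(eyes, function(r) r$name, character(1))),
            class = "crop_landmarks")
}

#' @export
print.crop_landmarks <- function(x, ...) {
  cat(sprintf("<crop_landmarks> z_inf = %.2f mm, y_mid = %.2f mm (from %s)\n",
              x$z_inf, x$y_mid, paste(x$source_roi_names, collapse = ", ")))
  invisible(x)
}

#' Build the retain-mask
#'
#' A voxel is kept iff it is inferior to the crop (`z < z_inf`), posterior to
#' the eye midpoint (`y >= y_mid`), or inside the PTV or brain. The
#' inferior-most eye slice itself is part of the cropped region.
#'
#' @param volume The CT [image_volume()].
#' @param landmarks [compute_landmarks()] result.
#' @param ptv_mask,brain_mask Logical masks on the CT grid (all-`FALSE` if
#'   the structure is absent).
#' @return An object of class `retain_mask` with fields `keep` (logical
#'   array), `preserved` (PTV-or-brain membership used for dose resampling),
#'   `landmarks`, and preserved-voxel counts.
#' @export
build_retain_mask <- function(volume, landmarks, ptv_mask = NULL, brain_mask = NULL) {
  g <- geom_axes(volume)
  if (is.null(ptv_mask)) ptv_mask <- array(FALSE, g$dim)
  if (is.null(brain_mask)) brain_mask <- array(FALSE, g$dim)
  stopifnot(identical(dim(ptv_mask), g$dim), identical(dim(brain_mask), g$dim))

  below <- g$z < landmarks$z_inf                 # per-slice
  posterior <- g$y >= landmarks$y_mid            # per-row
  base <- array(rep(posterior, times = g$dim[2] * g$dim[3]), g$dim)
  base[, , below] <- TRUE
  preserved <- ptv_mask | brain_mask
  keep <- base | preserved

  structure(list(
    keep = keep,
    preserved = preserved,
    landmarks = landmarks,
    preserved_ptv_voxels = sum(ptv_mask & !base),
    preserved_brain_voxels = sum(brain_mask & !base)
  ), class = "retain_mask")
}

#' @export
print.retain_mask <- function(x, ...) {
  cat(sprintf("<retain_mask> %d / %d voxels kept (PTV carve-out %d, brain %d)\n",
              sum(x$keep), length(x$keep),
              x$preserved_ptv_voxels, x$preserved_brain_voxels))
  invisible(x)
}

#' Apply the retain-mask to a CT volume
#'
#' Retained voxels keep their stored values bit-for-bit; removed voxels are
#' set to the stored value that maps to `fill_hu` through the volume's
#' rescale mapping (clamped to the representable range). Metadata other than
#' the pixel grid is unchanged.
#'
#' @param volume An [image_volume()] on the mask's grid.
#' @param mask A [build_retain_mask()] result.
#' @param fill_hu HU value written into removed voxels (default -1000, air).
#' @return The defaced [image_volume()].
#' @export
deface_image <- function(volume, mask, fill_hu = -1000) {
  if (!identical(dim(volume$stored_values), dim(mask$keep))) {
    stop_geometry("mask grid does not match the volume")
  }
  fill_stored <- round((fill_hu - volume$rescale_intercept) / volume$rescale_slope)
  lim <- 2^(volume$bits_stored - 1)
  fill_stored <- max(-lim, min(lim - 1, fill_stored))
  out <- volume
  out$stored_values[!mask$keep] <- as.integer(fill_stored)
  out
}

#' Apply the retain-mask to a co-registered volume
#'
#' For images already registered to the planning CT and resampled onto its
#' grid (e.g. a cone-beam CT): same contract as [deface_image()].
#'
#' @param volume2 An [image_volume()] with the mask's exact geometry and the
#'   CT's frame of reference.
#' @param mask A [build_retain_mask()] result (built on the planning CT).
#' @param fill_hu HU fill value for removed voxels.
#' @return The defaced [image_volume()].
#' @export
apply_mask_to_coregistered <- function(volume2, mask, fill_hu = -1000) {
  if (!identical(dim(volume2$stored_values), dim(mask$keep))) {
    stop_geometry("co-registered volume geometry differs from the mask grid; ",
                  "resample it onto the planning-CT grid first")
  }
  deface_image(volume2, mask, fill_hu = fill_hu)
}
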