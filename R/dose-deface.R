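# Dose defacing: evaluate the retain rule on the dose grid's own geometry
# and zero out removed voxels.

#' Resample the retain-mask onto a dose grid
#'
#' The crop rule (`z < z_inf` or `y >= y_mid`) is analytic in patient mm, so
#' it is evaluated directly at each dose voxel centre rather than
#' interpolated. PTV/brain preservation is a binary membership, looked up at
#' the nearest CT voxel (no fractional membership at structure edges). Dose
#' voxels outside the CT extent use the analytic rule alone.
#'
#' @param mask A [build_retain_mask()] result (on the CT grid).
#' @param ct_geometry The CT [image_volume()] the mask was built on.
#' @param dose_geometry A [dose_grid()] sharing the CT frame of reference.
#' @return Logical 3D array on the dose grid.
#' @export
resample_mask_to_dose <- function(mask, ct_geometry, dose_geometry) {
  if (!identical(ct_geometry$frame_of_reference, dose_geometry$frame_of_reference)) {
    stop_geometry("dose frame of reference does not match the CT")
  }
  gd <- geom_axes(dose_geometry)
  gc <- geom_axes(ct_geometry)
  lm <- mask$landmarks

  keep <- array(FALSE, gd$dim)
  below <- gd$z < lm$z_inf
  posterior <- gd$y >= lm$y_mid
  keep[] <- rep(posterior, times = gd$dim[2] * gd$dim[3])
  keep[, , below] <- TRUE

  # nearest CT voxel index along each axis; NA outside the CT extent
  near_idx <- function(coords, axis, step) {
    i <- round((coords - axis[1]) / step) + 1
    i[coords < axis[1] - step / 2 | coords > axis[length(axis)] + step / 2] <- NA
    pmin(pmax(i, 1), length(axis))
  }
  ri <- near_idx(gd$y, gc$y, ct_geometry$pixel_spacing[1])
  ci <- near_idx(gd$x, gc$x, ct_geometry$pixel_spacing[2])
  ki <- near_idx(gd$z, gc$z, slice_gap(ct_geometry))

  inb_r <- !is.na(ri); inb_c <- !is.na(ci); inb_k <- !is.na(ki)
  for (k in which(inb_k)) {
    pres <- mask$preserved[ri[inb_r], ci[inb_c], ki[k], drop = FALSE]
    sub <- keep[inb_r, inb_c, k, drop = FALSE]
    keep[inb_r, inb_c, k] <- sub | pres
  }
  keep
}

#' Apply a resampled retain-mask to a dose grid
#'
#' Removed voxels are set to 0 Gy; retained voxels are unchanged (and the
#' writer re-derives the dose-grid scaling so they round-trip within one
#' quantization step). The grid itself is not cropped, so the object stays
#' valid for downstream DVH tooling.
#'
#' @param dose A [dose_grid()].
#' @param dose_mask Logical array on the dose grid from
#'   [resample_mask_to_dose()].
#' @return The defaced [dose_grid()].
#' @export
deface_dose <- function(dose, dose_mask) {
  if (!identical(dim(dose$values), dim(dose_mask))) {
    stop_geometry("dose mask grid does not match the dose grid")
  }
  out <- dose
  out$values[!dose_mask] <- 0
  out
}
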