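# Writers for CT series, RT Structure Set and RT Dose (Explicit VR LE).

.common_geometry_elements <- function(origin, pixel_spacing, frame_uid) {
  list(
    "0020,0032" = dcm_el("DS", origin),
    "0020,0037" = dcm_el("DS", IDENTITY_ORIENTATION),
    "0020,0052" = dcm_el("UI", frame_uid),
    "0028,0002" = dcm_el("US", 1L),
    "0028,0004" = dcm_el("CS", "MONOCHROME2"),
    "0028,0030" = dcm_el("DS", pixel_spacing)
  )
}

#' Write an image volume as a DICOM CT series
#'
#' One file per axial slice (`CT_0001.dcm`, ...), using the volume's own
#' study/series/instance identifiers.
#'
#' @param volume An [image_volume()].
#' @param path Output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
write_ct_series <- function(volume, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop_io("cannot create CT output directory: ", path)
  d <- dim(volume$stored_values)
  gap <- slice_gap(volume)
  paths <- character(d[3])
  for (k in seq_len(d[3])) {
    z <- volume$slice_positions[k]
    pix <- writeBin(as.integer(t(volume$stored_values[, , k])), raw(),
                    size = 2, endian = "little")
    ds <- c(list(
      "0008,0016" = dcm_el("UI", SOP_CT),
      "0008,0018" = dcm_el("UI", volume$sop_instance_uids[k]),
      "0008,0060" = dcm_el("CS", "CT"),
      "0018,0050" = dcm_el("DS", gap),
      "0020,000D" = dcm_el("UI", volume$study_uid),
      "0020,000E" = dcm_el("UI", volume$series_uid),
      "0020,0013" = dcm_el("IS", k)
    ),
    .common_geometry_elements(c(volume$origin[1], volume$origin[2], z),
                              volume$pixel_spacing, volume$frame_of_reference),
    list(
      "0028,0010" = dcm_el("US", d[1]),
      "0028,0011" = dcm_el("US", d[2]),
      "0028,0100" = dcm_el("US", 16L),
      "0028,0101" = dcm_el("US", volume$bits_stored),
      "0028,0102" = dcm_el("US", 15L),
      "0028,0103" = dcm_el("US", 1L),
      "0028,1052" = dcm_el("DS", volume$rescale_intercept),
      "0028,1053" = dcm_el("DS", volume$rescale_slope),
      "7FE0,0010" = dcm_el("OW", pix)
    ))
    paths[k] <- file.path(path, sprintf("CT_%04d.dcm", k))
    dcm_write_file(paths[k], ds, SOP_CT, volume$sop_instance_uids[k])
  }
  invisible(paths)
}

#' Write a structure set as a DICOM RT Structure Set
#'
#' @param ss A [structure_set()]; its `referenced_*` fields must identify the
#'   CT series the contours refer to.
#' @param path Output file path.
#' @param sop_instance_uid SOP instance UID for the new object.
#' @return `path`, invisibly.
#' @export
write_structure_set <- function(ss, path, sop_instance_uid = new_uid()) {
  contour_image_items <- lapply(ss$referenced_instances, function(uid) {
    list("0008,1150" = dcm_el("UI", SOP_CT), "0008,1155" = dcm_el("UI", uid))
  })
  rfor_item <- list(
    "0020,0052" = dcm_el("UI", ss$frame_of_reference),
    "3006,0012" = dcm_el("SQ", list(list(
      "0008,1150" = dcm_el("UI", SOP_DETACHED_STUDY),
      "0008,1155" = dcm_el("UI", ss$referenced_study %||% new_uid()),
      "3006,0014" = dcm_el("SQ", list(list(
        "0020,000E" = dcm_el("UI", ss$referenced_series),
        "3006,0016" = dcm_el("SQ", contour_image_items)
      )))
    )))
  )

  roi_items <- lapply(ss$rois, function(r) {
    list("3006,0022" = dcm_el("IS", r$number),
         "3006,0024" = dcm_el("UI", ss$frame_of_reference),
         "3006,0026" = dcm_el("LO", r$name),
         "3006,0036" = dcm_el("CS", "AUTOMATIC"))
  })

  contour_items <- lapply(ss$rois, function(r) {
    contours <- lapply(r$polygons, function(p) {
      list("3006,0042" = dcm_el("CS", "CLOSED_PLANAR"),
           "3006,0046" = dcm_el("IS", nrow(p)),
           "3006,0050" = dcm_el("DS", as.numeric(t(p))))
    })
    list("3006,0040" = dcm_el("SQ", contours),
         "3006,0084" = dcm_el("IS", r$number))
  })

  ds <- list(
    "0008,0016" = dcm_el("UI", SOP_RTSTRUCT),
    "0008,0018" = dcm_el("UI", sop_instance_uid),
    "0008,0060" = dcm_el("CS", "RTSTRUCT"),
    "0020,000D" = dcm_el("UI", ss$referenced_study %||% new_uid()),
    "0020,000E" = dcm_el("UI", new_uid()),
    "3006,0002" = dcm_el("SH", ss$label),
    "3006,0010" = dcm_el("SQ", list(rfor_item)),
    "3006,0020" = dcm_el("SQ", roi_items),
    "3006,0039" = dcm_el("SQ", contour_items)
  )
  dcm_write_file(path, ds, SOP_RTSTRUCT, sop_instance_uid)
  invisible(path)
}

#' Write a dose grid as a DICOM RT Dose
#'
#' Dose is quantized to 32-bit unsigned stored values with a freshly derived
#' dose-grid scaling (maximum dose mapped near the top of the range), so
#' retained values round-trip well within 1e-6 Gy.
#'
#' @param dose A [dose_grid()].
#' @param path Output file path.
#' @param study_uid Study the dose belongs to.
#' @param sop_instance_uid SOP instance UID for the new object.
#' @return `path`, invisibly.
#' @export
write_dose <- function(dose, path, study_uid = new_uid(),
                       sop_instance_uid = new_uid()) {
  d <- dim(dose$values)
  maxv <- max(dose$values)
  scaling <- if (maxv > 0) maxv / (2^31 - 1) else 1
  frames <- lapply(seq_len(d[3]), function(k) {
    as.integer(round(t(dose$values[, , k]) / scaling))
  })
  pix <- writeBin(unlist(frames), raw(), size = 4, endian = "little")
  ds <- c(list(
    "0008,0016" = dcm_el("UI", SOP_RTDOSE),
    "0008,0018" = dcm_el("UI", sop_instance_uid),
    "0008,0060" = dcm_el("CS", "RTDOSE"),
    "0020,000D" = dcm_el("UI", study_uid),
    "0020,000E" = dcm_el("UI", new_uid()),
    "0028,0008" = dcm_el("IS", d[3]),
    "0028,0009" = dcm_el("AT", c(0x3004, 0x000C))
  ),
  .common_geometry_elements(dose$origin, dose$pixel_spacing,
                            dose$frame_of_reference),
  list(
    "0028,0010" = dcm_el("US", d[1]),
    "0028,0011" = dcm_el("US", d[2]),
    "0028,0100" = dcm_el("US", 32L),
    "0028,0101" = dcm_el("US", 32L),
    "0028,0102" = dcm_el("US", 31L),
    "0028,0103" = dcm_el("US", 0L),
    "3004,0002" = dcm_el("CS", "GY"),
    "3004,0004" = dcm_el("CS", "PHYSICAL"),
    "3004,000A" = dcm_el("CS", "PLAN"),
    "3004,000C" = dcm_el("DS", dose$slice_positions - dose$origin[3]),
    "3004,000E" = dcm_el("DS", scaling),
    "7FE0,0010" = dcm_el("OW", pix)
  ))
  dcm_write_file(path, ds, SOP_RTDOSE, sop_instance_uid)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a CT / structure set / dose triplet
#'
#' Generates fresh series and SOP instance identifiers for all objects (the
#' frame of reference is preserved), points the structure set's image
#' references at the new CT instances, and writes `ct/` plus `rtstruct.dcm`
#' and (optionally) `rtdose.dcm` under `path`. With [set_uid_seed()] the
#' generated identifiers — and hence the files — are reproducible.
#'
#' @param volume An [image_volume()].
#' @param ss A [structure_set()] sharing the volume's frame of reference.
#' @param dose Optional [dose_grid()] sharing the same frame of reference.
#' @param path Output directory.
#' @return List with elements `ct_dir`, `rtstruct`, `rtdose` (paths; `rtdose`
#'   `NULL` when no dose given), invisibly.
#' @export
write_outputs <- function(volume, ss, dose = NULL, path) {
  if (!identical(volume$frame_of_reference, ss$frame_of_reference)) {
    stop_geometry("structure set frame of reference does not match the CT")
  }
  if (!is.null(dose) && !identical(volume$frame_of_reference, dose$frame_of_reference)) {
    stop_geometry("dose frame of reference does not match the CT")
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop_io("cannot create output directory: ", path)

  volume$series_uid <- new_uid()
  volume$sop_instance_uids <- vapply(seq_along(volume$slice_positions),
                                     function(i) new_uid(), character(1))
  ss$referenced_series <- volume$series_uid
  ss$referenced_study <- volume$study_uid
  ss$referenced_instances <- volume$sop_instance_uids

  ct_dir <- file.path(path, "ct")
  write_ct_series(volume, ct_dir)
  rtstruct <- file.path(path, "rtstruct.dcm")
  write_structure_set(ss, rtstruct)
  rtdose <- NULL
  if (!is.null(dose)) {
    rtdose <- file.path(path, "rtdose.dcm")
    write_dose(dose, rtdose, study_uid = volume$study_uid)
  }
  invisible(list(ct_dir = ct_dir, rtstruct = rtstruct, rtdose = rtdose))
}
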