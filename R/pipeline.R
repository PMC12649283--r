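# End-to-end defacing pipeline over DICOM inputs, and an original-vs-defaced
# evaluation helper. The command-line interface (inst/cli/rtdeface.R) is a
# thin wrapper over these functions.

#' Deface a CT series with its DICOM-RT objects
#'
#' Full workflow: read the CT series, structure set and (optionally) dose;
#' derive crop landmarks from the eye contours; build the retain-mask with
#' PTV/brain preservation; apply it to the image; rebuild the structure set
#' (eyes/lenses/corneas removed, body rebuilt, protruding ROIs clipped, PTV
#' and brain untouched); resample the mask to the dose grid and zero removed
#' dose voxels; write all outputs with fresh identifiers plus a JSON report.
#'
#' @param ct_dir Directory with the CT slice files.
#' @param rtstruct_path RT Structure Set path (must contain contoured eyes).
#' @param rtdose_path Optional RT Dose path.
#' @param out_dir Output directory (`ct/`, `rtstruct.dcm`, `rtdose.dcm`,
#'   `report.json`).
#' @param patterns ROI-role patterns (see [default_role_patterns()]).
#' @param fill_hu HU value written into removed voxels.
#' @param uid_seed Optional integer; when given, freshly generated DICOM
#'   identifiers are deterministic (reproducible outputs).
#' @return The [build_report()] result, invisibly.
#' @export
run_deface <- function(ct_dir, rtstruct_path, rtdose_path = NULL, out_dir,
                       patterns = default_role_patterns(), fill_hu = -1000,
                       uid_seed = NULL) {
  t0 <- proc.time()[["elapsed"]]
  volume <- read_ct_series(ct_dir)
  ss <- read_structure_set(rtstruct_path, patterns)
  if (!identical(ss$frame_of_reference, volume$frame_of_reference)) {
    stop_geometry("structure set frame of reference does not match the CT")
  }
  dose <- if (!is.null(rtdose_path)) read_dose(rtdose_path) else NULL

  landmarks <- compute_landmarks(ss, volume)
  ptv_mask <- rasterize_union(rois_with_role(ss, "ptv"), volume)
  brain_mask <- rasterize_union(rois_with_role(ss, "brain"), volume)
  mask <- build_retain_mask(volume, landmarks, ptv_mask, brain_mask)

  defaced_volume <- deface_image(volume, mask, fill_hu = fill_hu)
  defaced_ss <- deface_structure_set(ss, mask, volume)

  defaced_dose <- NULL
  if (!is.null(dose)) {
    dose_mask <- resample_mask_to_dose(mask, volume, dose)
    defaced_dose <- deface_dose(dose, dose_mask)
  }

  if (!is.null(uid_seed)) set_uid_seed(uid_seed)
  write_outputs(defaced_volume, defaced_ss, defaced_dose, out_dir)

  report <- build_report(volume, defaced_volume, ss, defaced_ss, mask,
                         dose, defaced_dose,
                         runtime_seconds = proc.time()[["elapsed"]] - t0)
  report_to_json(report, file.path(out_dir, "report.json"))
  invisible(report)
}

#' Compare an original and a defaced dataset
#'
#' Reads the CT + structure set from both directories (each laid out as
#' written by [run_deface()]/[write_outputs()]: a `ct/` subdirectory — or the
#' directory itself holding the slices — plus `rtstruct.dcm`), rasterizes
#' same-named ROIs on the original CT grid and reports their Dice overlap.
#'
#' @param original_dir,defaced_dir Dataset directories.
#' @param patterns ROI-role patterns.
#' @return List with per-ROI `name`, `role`, `dice`, plus the landmark values
#'   recomputed from the original structure set.
#' @export
evaluate_pair <- function(original_dir, defaced_dir,
                          patterns = default_role_patterns()) {
  find_ct <- function(dir) {
    if (dir.exists(file.path(dir, "ct"))) file.path(dir, "ct") else dir
  }
  find_ss <- function(dir) {
    p <- file.path(dir, "rtstruct.dcm")
    if (!file.exists(p)) stop_io("no rtstruct.dcm under ", dir)
    p
  }
  vol <- read_ct_series(find_ct(original_dir))
  ss <- read_structure_set(find_ss(original_dir), patterns)
  dss <- read_structure_set(find_ss(defaced_dir), patterns)

  landmarks <- compute_landmarks(ss, vol)
  by_name <- stats::setNames(dss$rois, vapply(dss$rois, function(r) r$name, character(1)))
  rois <- lapply(ss$rois, function(r) {
    a <- rasterize_roi(r, vol)
    dr <- by_name[[r$name]]
    b <- if (is.null(dr)) array(FALSE, dim(a)) else rasterize_roi(dr, vol)
    list(name = r$name, role = r$role,
         present_after = !is.null(dr), dice = dice(a, b))
  })
  list(landmarks = list(z_inf = landmarks$z_inf, y_mid = landmarks$y_mid),
       rois = rois)
}
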