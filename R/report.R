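# Machine-readable summary of one defacing run.

#' Summarize a defacing run
#'
#' Collects landmark values, voxel accounting, per-ROI actions and Dice
#' scores (original versus defaced rasterizations on the CT grid), the PTV
#' location category, retained fractions for the preserved structures, and
#' dose totals into a serializable report.
#'
#' @param volume,defaced_volume CT before and after defacing.
#' @param ss,defaced_ss Structure set before and after defacing.
#' @param mask The [build_retain_mask()] used.
#' @param dose,defaced_dose Optional dose grids before/after.
#' @param runtime_seconds Wall-clock duration of the run.
#' @return A list of class `deface_report`.
#' @export
build_report <- function(volume, defaced_volume, ss, defaced_ss, mask,
                         dose = NULL, defaced_dose = NULL,
                         runtime_seconds = NA_real_) {
  defaced_by_number <- list()
  for (r in defaced_ss$rois) defaced_by_number[[as.character(r$number)]] <- r

  rois <- list()
  ptv_mask <- NULL
  for (r in ss$rois) {
    orig_m <- rasterize_roi(r, volume)
    dr <- defaced_by_number[[as.character(r$number)]]
    action <- if (r$role %in% c("eye", "lens", "cornea")) {
      "removed"
    } else if (r$role %in% c("ptv", "brain")) {
      "kept"
    } else if (r$role == "body") {
      "rebuilt"
    } else if (!is.null(dr) && identical(dr$polygons, r$polygons)) {
      "untouched"
    } else {
      "clipped"
    }
    def_m <- if (is.null(dr)) array(FALSE, dim(orig_m)) else rasterize_roi(dr, volume)
    retained <- if (any(orig_m)) retained_fraction(orig_m, mask) else NA_real_
    rois[[length(rois) + 1L]] <- list(
      name = r$name, number = r$number, role = r$role, action = action,
      voxels = sum(orig_m), dice = dice(orig_m, def_m),
      retained_fraction = retained)
    if (r$role == "ptv") {
      ptv_mask <- if (is.null(ptv_mask)) orig_m else ptv_mask | orig_m
    }
  }

  ptv_category <- if (!is.null(ptv_mask) && any(ptv_mask)) {
    classify_ptv(ptv_mask, mask$landmarks, volume)
  } else NA_character_

  dose_summary <- NULL
  if (!is.null(dose) && !is.null(defaced_dose)) {
    dose_summary <- list(total_gy_before = sum(dose$values),
                         total_gy_after = sum(defaced_dose$values))
  }

  structure(list(
    landmarks = list(z_inf = mask$landmarks$z_inf, y_mid = mask$landmarks$y_mid,
                     source_roi_names = mask$landmarks$source_roi_names),
    voxels_total = length(mask$keep),
    voxels_removed = sum(!mask$keep),
    image_voxels_modified = sum(volume$stored_values != defaced_volume$stored_values),
    preserved_ptv_voxels = mask$preserved_ptv_voxels,
    preserved_brain_voxels = mask$preserved_brain_voxels,
    ptv_category = ptv_category,
    rois = rois,
    dose = dose_summary,
    runtime_seconds = runtime_seconds
  ), class = "deface_report")
}

#' @export
print.deface_report <- function(x, ...) {
  cat(sprintf("<deface_report> z_inf=%.1f mm, y_mid=%.1f mm; %d/%d voxels removed\n",
              x$landmarks$z_inf, x$landmarks$y_mid, x$voxels_removed, x$voxels_total))
  if (!is.na(x$ptv_category %||% NA)) cat("  PTV category:", x$ptv_category, "\n")
  for (r in x$rois) {
    cat(sprintf("  %-16s %-9s Dice %.3f\n", r$name, r$action, r$dice))
  }
  invisible(x)
}

#' Serialize a report to JSON
#' @param report A `deface_report`.
#' @param path Optional output file; when given, the JSON is written there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
report_to_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Deserialize a report from JSON
#' @param path File path or a JSON string.
#' @return A `deface_report`.
#' @export
report_from_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyVector = TRUE)
  x$rois <- lapply(x$rois, function(r) r)
  structure(x, class = "deface_report")
}
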