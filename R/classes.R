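# Domain containers. All geometry is DICOM LPS patient coordinates with an
# axis-aligned identity orientation (head-first-supine): x increases to the
# patient's left, y increases posteriorly (anterior = smaller y), z increases
# superiorly. Arrays are indexed [row, col, slice]; rows run along y, columns
# along x.

IDENTITY_ORIENTATION <- c(1, 0, 0, 0, 1, 0)

#' Construct a CT image volume
#'
#' @param stored_values Integer 3D array (rows x cols x slices) of raw stored
#'   pixel values (HU = `rescale_slope * stored + rescale_intercept`).
#' @param origin Patient-space position (mm, LPS) of the first voxel centre.
#' @param pixel_spacing Numeric length-2: (row spacing = y step, column
#'   spacing = x step) in mm.
#' @param slice_positions Per-slice z coordinate (mm), strictly increasing.
#' @param rescale_slope,rescale_intercept Stored-value to HU linear map.
#' @param frame_of_reference,study_uid,series_uid DICOM identifiers; fresh
#'   UIDs are generated when omitted.
#' @param sop_instance_uids Per-slice SOP instance UIDs (generated if `NULL`).
#' @param bits_stored Bit depth of the stored values (signed), default 16.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(stored_values, origin, pixel_spacing, slice_positions,
                         rescale_slope = 1, rescale_intercept = -1024,
                         frame_of_reference = new_uid(), study_uid = new_uid(),
                         series_uid = new_uid(), sop_instance_uids = NULL,
                         bits_stored = 16L) {
  stopifnot(length(dim(stored_values)) == 3L, length(origin) == 3L,
            length(pixel_spacing) == 2L)
  if (any(pixel_spacing <= 0)) stop_geometry("pixel_spacing must be positive")
  nz <- dim(stored_values)[3]
  if (length(slice_positions) != nz) {
    stop_geometry("slice_positions length must match slice count")
  }
  if (nz > 1 && any(diff(slice_positions) <= 0)) {
    stop_geometry("slice_positions must be strictly increasing")
  }
  if (abs(origin[3] - slice_positions[1]) > 1e-6) {
    stop_geometry("origin z must equal the first slice position")
  }
  lim <- 2^(bits_stored - 1)
  rng <- range(stored_values)
  if (rng[1] < -lim || rng[2] > lim - 1) {
    stop_geometry("stored values exceed the declared bit depth")
  }
  if (is.null(sop_instance_uids)) {
    sop_instance_uids <- vapply(seq_len(nz), function(i) new_uid(), character(1))
  }
  structure(list(
    stored_values = stored_values,
    origin = as.numeric(origin),
    pixel_spacing = as.numeric(pixel_spacing),
    slice_positions = as.numeric(slice_positions),
    rescale_slope = rescale_slope,
    rescale_intercept = rescale_intercept,
    orientation = IDENTITY_ORIENTATION,
    frame_of_reference = frame_of_reference,
    study_uid = study_uid,
    series_uid = series_uid,
    sop_instance_uids = sop_instance_uids,
    bits_stored = as.integer(bits_stored)
  ), class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$stored_values)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$pixel_spacing[1], x$pixel_spacing[2],
              if (d[3] > 1) x$slice_positions[2] - x$slice_positions[1] else NA))
  cat(sprintf("  origin (%.1f, %.1f, %.1f) mm; HU = %g * stored + %g\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$rescale_slope, x$rescale_intercept))
  invisible(x)
}

#' Hounsfield values of a volume
#' @param volume An `image_volume`.
#' @return Numeric array of HU values.
#' @export
hu_values <- function(volume) {
  volume$rescale_slope * volume$stored_values + volume$rescale_intercept
}

#' Construct a single ROI with its planar contours
#'
#' @param name ROI name as it appears in the structure set.
#' @param number Unique integer ROI number.
#' @param polygons List of closed planar polygons; each an (n >= 3) x 3 numeric
#'   matrix of (x, y, z) vertices in patient mm with constant z. The polygon is
#'   implicitly closed (first vertex not repeated).
#' @param role One of eye, lens, cornea, brain, ptv, body, other.
#' @return An object of class `roi_contour`.
#' @export
roi_contour <- function(name, number, polygons = list(), role = "other") {
  role <- match.arg(role, c("eye", "lens", "cornea", "brain", "ptv", "body", "other"))
  for (p in polygons) {
    stopifnot(is.matrix(p), ncol(p) == 3L, nrow(p) >= 3L)
    if (diff(range(p[, 3])) > 1e-6) stop_geometry("contour not planar in z: ", name)
  }
  structure(list(name = name, number = as.integer(number),
                 role = role, polygons = polygons),
            class = "roi_contour")
}

#' Construct a structure set
#'
#' @param rois List of [roi_contour()] objects with unique numbers.
#' @param frame_of_reference Frame-of-reference UID shared with the CT.
#' @param referenced_series Series UID of the CT the contours refer to.
#' @param referenced_study Study UID of the referenced CT.
#' @param referenced_instances SOP instance UIDs of the referenced CT slices.
#' @param label Structure set label.
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(rois, frame_of_reference, referenced_series,
                          referenced_study = NULL, referenced_instances = character(0),
                          label = "rtdeface") {
  nums <- vapply(rois, function(r) r$number, integer(1))
  if (anyDuplicated(nums)) stop_geometry("ROI numbers must be unique")
  structure(list(rois = rois,
                 frame_of_reference = frame_of_reference,
                 referenced_series = referenced_series,
                 referenced_study = referenced_study,
                 referenced_instances = referenced_instances,
                 label = label),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> %d ROIs\n", length(x$rois)))
  for (r in x$rois) {
    cat(sprintf("  [%d] %-16s role=%-7s %d contours\n",
                r$number, r$name, r$role, length(r$polygons)))
  }
  invisible(x)
}

#' Find ROIs by role
#' @param ss A `structure_set`.
#' @param role Role tag to match.
#' @return List of matching `roi_contour` objects (possibly empty).
#' @export
rois_with_role <- function(ss, role) {
  Filter(function(r) identical(r$role, role), ss$rois)
}

#' Construct a dose grid
#'
#' @param values 3D numeric array of dose (Gy), indexed (row, col, frame).
#' @param origin First voxel centre (mm, LPS).
#' @param pixel_spacing (row, col) spacing in mm.
#' @param slice_positions Per-frame z (mm), strictly increasing.
#' @param frame_of_reference Frame-of-reference UID shared with the CT.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(values, origin, pixel_spacing, slice_positions,
                      frame_of_reference) {
  stopifnot(length(dim(values)) == 3L)
  if (any(values < 0)) stop_geometry("dose values must be non-negative")
  if (any(pixel_spacing <= 0)) stop_geometry("pixel_spacing must be positive")
  if (length(slice_positions) != dim(values)[3]) {
    stop_geometry("slice_positions length must match frame count")
  }
  structure(list(values = values,
                 origin = as.numeric(origin),
                 pixel_spacing = as.numeric(pixel_spacing),
                 slice_positions = as.numeric(slice_positions),
                 orientation = IDENTITY_ORIENTATION,
                 frame_of_reference = frame_of_reference),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<dose_grid> %d x %d x %d, max %.2f Gy\n", d[1], d[2], d[3],
              max(x$values)))
  invisible(x)
}

# Shared geometry accessors -----------------------------------------------

# Voxel-centre coordinate axes of an image_volume or dose_grid.
geom_axes <- function(obj) {
  d <- dim(if (inherits(obj, "dose_grid")) obj$values else obj$stored_values)
  list(
    x = obj$origin[1] + (seq_len(d[2]) - 1) * obj$pixel_spacing[2],
    y = obj$origin[2] + (seq_len(d[1]) - 1) * obj$pixel_spacing[1],
    z = obj$slice_positions,
    dim = d
  )
}

same_geometry <- function(a, b, tol = 1e-6) {
  ga <- geom_axes(a); gb <- geom_axes(b)
  identical(ga$dim, gb$dim) &&
    max(abs(ga$x - gb$x)) <= tol &&
    max(abs(ga$y - gb$y)) <= tol &&
    max(abs(ga$z - gb$z)) <= tol
}

slice_gap <- function(obj) {
  z <- obj$slice_positions
  if (length(z) > 1) min(diff(z)) else 1
}
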