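# Readers for CT series, RT Structure Set and RT Dose.

.check_orientation <- function(iop, path) {
  if (is.null(iop) || length(iop) != 6 ||
      max(abs(iop - IDENTITY_ORIENTATION)) > 1e-4) {
    stop_geometry("unsupported image orientation (",
                  paste(signif(iop, 4), collapse = ", "),
                  "); only axis-aligned head-first-supine is handled: ", path)
  }
}

.decode_slice_pixels <- function(ds, path) {
  rows <- dcm_require(ds, "0028,0010", "Rows")
  cols <- dcm_require(ds, "0028,0011", "Columns")
  bits <- dcm_value(ds, "0028,0100", 16L)
  signed <- identical(dcm_value(ds, "0028,0103", 0L), 1L) ||
    identical(dcm_value(ds, "0028,0103", 0L), 1)
  pix <- dcm_require(ds, "7FE0,0010", "PixelData")
  size <- bits %/% 8L
  v <- readBin(pix, "integer", rows * cols, size = size,
               signed = if (size < 4) signed else TRUE, endian = "little")
  if (!signed && size == 4) v <- ifelse(v < 0, as.numeric(v) + 4294967296, v)
  t(matrix(v, nrow = cols, ncol = rows))
}

#' Read a DICOM CT series
#'
#' Reads every DICOM file in a directory, checks that they form a single
#' axial CT series with uniform slice spacing, and assembles the slices
#' inferior-to-superior. Stored pixel values are kept as written; no HU
#' conversion is applied to the grid.
#'
#' @param path Directory containing one CT slice per file.
#' @param gap_tolerance Maximum allowed deviation (mm) between slice gaps.
#' @return An [image_volume()].
#' @export
read_ct_series <- function(path, gap_tolerance = 1e-3) {
  if (!dir.exists(path)) stop_io("CT directory not found: ", path)
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  slices <- list()
  for (f in files) {
    ds <- tryCatch(dcm_read_file(f), rtdeface_io_error = function(e) NULL)
    if (is.null(ds)) next
    if (!identical(dcm_value(ds, "0008,0016"), SOP_CT)) next
    slices[[length(slices) + 1L]] <- list(ds = ds, path = f)
  }
  if (length(slices) < 2) stop_io("insufficient slices: need >= 2 CT slices in ", path)

  series <- unique(vapply(slices, function(s) dcm_require(s$ds, "0020,000E", "SeriesInstanceUID"), character(1)))
  if (length(series) != 1) stop_io("mixed series in ", path, ": ", paste(series, collapse = ", "))

  for (s in slices) .check_orientation(dcm_value(s$ds, "0020,0037"), s$path)

  zs <- vapply(slices, function(s) dcm_require(s$ds, "0020,0032", "ImagePositionPatient")[3], numeric(1))
  ord <- order(zs)
  slices <- slices[ord]
  zs <- zs[ord]
  gaps <- diff(zs)
  if (any(gaps <= 0)) stop_io("duplicate slice positions in ", path)
  if (max(gaps) - min(gaps) > gap_tolerance) {
    stop_io(sprintf("non-uniform slice spacing in %s (gaps %.4f..%.4f mm)",
                    path, min(gaps), max(gaps)))
  }

  first <- slices[[1]]$ds
  ipp <- dcm_require(first, "0020,0032", "ImagePositionPatient")
  spacing <- dcm_require(first, "0028,0030", "PixelSpacing")
  mats <- lapply(slices, function(s) .decode_slice_pixels(s$ds, s$path))
  arr <- array(0L, dim = c(nrow(mats[[1]]), ncol(mats[[1]]), length(mats)))
  for (k in seq_along(mats)) arr[, , k] <- mats[[k]]

  image_volume(
    stored_values = arr,
    origin = c(ipp[1], ipp[2], zs[1]),
    pixel_spacing = spacing,
    slice_positions = zs,
    rescale_slope = dcm_value(first, "0028,1053", 1),
    rescale_intercept = dcm_value(first, "0028,1052", 0),
    frame_of_reference = dcm_require(first, "0020,0052", "FrameOfReferenceUID"),
    study_uid = dcm_require(first, "0020,000D", "StudyInstanceUID"),
    series_uid = series,
    sop_instance_uids = vapply(slices, function(s) dcm_require(s$ds, "0008,0018", "SOPInstanceUID"), character(1)),
    bits_stored = as.integer(dcm_value(first, "0028,0101", 16L))
  )
}

#' Read a DICOM RT Structure Set
#'
#' @param path Path to the RT Structure Set file.
#' @param patterns Role-name patterns, see [default_role_patterns()].
#' @return A [structure_set()] with one role per ROI; ROIs declared without
#'   contour data are kept with empty polygon lists (with a warning).
#' @export
read_structure_set <- function(path, patterns = default_role_patterns()) {
  ds <- dcm_read_file(path)
  if (!identical(dcm_value(ds, "0008,0016"), SOP_RTSTRUCT)) {
    stop_io("not an RT Structure Set: ", path)
  }

  frame_uid <- NULL; ref_series <- NULL; ref_study <- NULL; ref_instances <- character(0)
  rfors <- dcm_value(ds, "3006,0010", list())
  if (length(rfors) >= 1) {
    frame_uid <- dcm_value(rfors[[1]], "0020,0052")
    studies <- dcm_value(rfors[[1]], "3006,0012", list())
    if (length(studies) >= 1) {
      ref_study <- dcm_value(studies[[1]], "0008,1155")
      series <- dcm_value(studies[[1]], "3006,0014", list())
      if (length(series) >= 1) {
        ref_series <- dcm_value(series[[1]], "0020,000E")
        cis <- dcm_value(series[[1]], "3006,0016", list())
        ref_instances <- vapply(cis, function(ci) dcm_value(ci, "0008,1155", ""), character(1))
      }
    }
  }

  roi_defs <- dcm_value(ds, "3006,0020", list())
  contour_items <- dcm_value(ds, "3006,0039", list())
  by_number <- list()
  for (item in contour_items) {
    num <- dcm_value(item, "3006,0084")
    polys <- list()
    for (cs in dcm_value(item, "3006,0040", list())) {
      gtype <- dcm_value(cs, "3006,0042", "CLOSED_PLANAR")
      if (!identical(gtype, "CLOSED_PLANAR")) {
        warning("skipping non-planar contour of type ", gtype, call. = FALSE)
        next
      }
      dat <- dcm_value(cs, "3006,0050")
      if (is.null(dat) || length(dat) < 9) next
      polys[[length(polys) + 1L]] <- matrix(dat, ncol = 3, byrow = TRUE)
    }
    by_number[[as.character(num)]] <- polys
  }

  rois <- list()
  for (rd in roi_defs) {
    num <- dcm_value(rd, "3006,0022")
    name <- dcm_value(rd, "3006,0026", paste0("ROI_", num))
    polys <- by_number[[as.character(num)]]
    if (is.null(polys)) {
      warning("ROI '", name, "' has no contour data; keeping it empty", call. = FALSE)
      polys <- list()
    }
    rois[[length(rois) + 1L]] <- roi_contour(name, num, polys,
                                             role = assign_role(name, patterns))
  }

  structure_set(rois, frame_of_reference = frame_uid,
                referenced_series = ref_series, referenced_study = ref_study,
                referenced_instances = ref_instances,
                label = dcm_value(ds, "3006,0002", "StructureSet"))
}

#' Read a DICOM RT Dose grid
#'
#' @param path Path to the RT Dose file.
#' @return A [dose_grid()] with values in Gy (stored values multiplied by the
#'   dose-grid scaling attribute).
#' @export
read_dose <- function(path) {
  ds <- dcm_read_file(path)
  if (!identical(dcm_value(ds, "0008,0016"), SOP_RTDOSE)) {
    stop_io("not an RT Dose object: ", path)
  }
  scaling <- dcm_value(ds, "3004,000E")
  if (is.null(scaling)) stop_io("missing DoseGridScaling in ", path)
  if (scaling == 0) stop_io("DoseGridScaling is zero in ", path)

  .check_orientation(dcm_value(ds, "0020,0037"), path)
  rows <- dcm_require(ds, "0028,0010", "Rows")
  cols <- dcm_require(ds, "0028,0011", "Columns")
  frames <- as.integer(dcm_require(ds, "0028,0008", "NumberOfFrames"))
  bits <- dcm_value(ds, "0028,0100", 32L)
  size <- bits %/% 8L
  pix <- dcm_require(ds, "7FE0,0010", "PixelData")
  v <- readBin(pix, "integer", rows * cols * frames, size = size,
               signed = if (size < 4) FALSE else TRUE, endian = "little")
  v <- as.numeric(v)
  if (size == 4) v <- ifelse(v < 0, v + 4294967296, v)

  arr <- array(0, dim = c(rows, cols, frames))
  per <- rows * cols
  for (k in seq_len(frames)) {
    arr[, , k] <- t(matrix(v[((k - 1) * per + 1):(k * per)], nrow = cols))
  }

  ipp <- dcm_require(ds, "0020,0032", "ImagePositionPatient")
  gfov <- dcm_require(ds, "3004,000C", "GridFrameOffsetVector")
  dose_grid(
    values = arr * scaling,
    origin = ipp,
    pixel_spacing = dcm_require(ds, "0028,0030", "PixelSpacing"),
    slice_positions = ipp[3] + gfov,
    frame_of_reference = dcm_require(ds, "0020,0052", "FrameOfReferenceUID")
  )
}
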