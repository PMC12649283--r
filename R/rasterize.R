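# Contour <-> voxel-mask conversion. A voxel belongs to an ROI iff its centre
# lies inside an odd number of that slice's polygons (even-odd rule), which is
# deterministic and independent of vertex order and winding.

# Even-odd point-in-polygon, vectorized over query points, half-open ray
# crossing test so shared edges cannot double-count.
points_in_polygon <- function(px, py, poly_x, poly_y) {
  n <- length(poly_x)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    yi <- poly_y[i]; yj <- poly_y[j]
    if (yi != yj) {
      crosses <- ((yi > py) != (yj > py)) &
        (px < (poly_x[j] - poly_x[i]) * (py - yi) / (yj - yi) + poly_x[i])
      inside <- xor(inside, crosses)
    }
    j <- i
  }
  inside
}

.nearest_slice <- function(z, slice_positions, gap) {
  k <- which.min(abs(slice_positions - z))
  if (abs(slice_positions[k] - z) > gap / 2 + 1e-6) return(NA_integer_)
  k
}

#' Rasterize an ROI onto an image grid
#'
#' Each polygon is assigned to the nearest CT slice (within half a slice gap;
#' otherwise it is skipped with a warning). A voxel is set iff its centre is
#' inside an odd number of that slice's polygons.
#'
#' @param roi A [roi_contour()].
#' @param geometry An [image_volume()] or [dose_grid()] supplying the grid.
#' @return Logical 3D array (rows x cols x slices).
#' @export
rasterize_roi <- function(roi, geometry) {
  g <- geom_axes(geometry)
  gap <- slice_gap(geometry)
  mask <- array(FALSE, dim = g$dim)
  for (p in roi$polygons) {
    k <- .nearest_slice(p[1, 3], g$z, gap)
    if (is.na(k)) {
      warning("contour of '", roi$name, "' at z=", signif(p[1, 3], 6),
              " mm matches no slice; skipped", call. = FALSE)
      next
    }
    # limit the point-in-polygon test to the polygon's bounding box
    ci <- which(g$x >= min(p[, 1]) - 1e-9 & g$x <= max(p[, 1]) + 1e-9)
    ri <- which(g$y >= min(p[, 2]) - 1e-9 & g$y <= max(p[, 2]) + 1e-9)
    if (!length(ci) || !length(ri)) next
    px <- rep(g$x[ci], each = length(ri))
    py <- rep(g$y[ri], times = length(ci))
    inside <- points_in_polygon(px, py, p[, 1], p[, 2])
    sub <- matrix(inside, nrow = length(ri))
    mask[ri, ci, k] <- xor(mask[ri, ci, k], sub)
  }
  mask
}

#' Rasterize the union of several ROIs
#' @param rois List of [roi_contour()] objects.
#' @param geometry Grid-defining object.
#' @return Logical 3D array; all-`FALSE` when `rois` is empty.
#' @export
rasterize_union <- function(rois, geometry) {
  g <- geom_axes(geometry)
  mask <- array(FALSE, dim = g$dim)
  for (r in rois) mask <- mask | rasterize_roi(r, geometry)
  mask
}

#' Extract per-slice contours from a binary mask
#'
#' Traces the 0.5-level iso-contours of each axial slice (the mask is padded
#' with zeros so every contour closes) and returns them as closed planar
#' polygons in patient mm. Re-rasterizing the result reproduces the input up
#' to a one-voxel boundary band.
#'
#' @param mask Logical/0-1 3D array on the grid of `geometry`.
#' @param geometry Grid-defining object.
#' @return List of (n x 3) polygon matrices (possibly empty).
#' @export
polygonize_mask <- function(mask, geometry) {
  g <- geom_axes(geometry)
  stopifnot(identical(dim(mask), g$dim))
  dy <- geometry$pixel_spacing[1]; dx <- geometry$pixel_spacing[2]
  ypad <- c(g$y[1] - dy, g$y, g$y[length(g$y)] + dy)
  xpad <- c(g$x[1] - dx, g$x, g$x[length(g$x)] + dx)
  polys <- list()
  for (k in seq_len(g$dim[3])) {
    sl <- mask[, , k]
    if (!any(sl)) next
    padded <- matrix(0, nrow = g$dim[1] + 2, ncol = g$dim[2] + 2)
    padded[2:(g$dim[1] + 1), 2:(g$dim[2] + 1)] <- sl + 0
    # contourLines wants z[i, j] at (x[i], y[j]): feed rows as its x axis
    cls <- grDevices::contourLines(x = ypad, y = xpad, z = padded, levels = 0.5)
    for (cl in cls) {
      yv <- cl$x; xv <- cl$y
      n <- length(xv)
      if (n > 1 && xv[1] == xv[n] && yv[1] == yv[n]) {
        xv <- xv[-n]; yv <- yv[-n]
      }
      if (length(xv) < 3) next
      polys[[length(polys) + 1L]] <- cbind(xv, yv, rep(g$z[k], length(xv)),
                                           deparse.level = 0)
    }
  }
  polys
}
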