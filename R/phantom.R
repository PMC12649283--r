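# Synthetic head-and-neck phantom: an ellipsoidal head on a cylindrical neck,
# spherical eyes/lenses/corneas near the anterior surface, a posterior brain,
# inferior OARs, a PTV in one of three positions relative to the crop region,
# and a Gaussian dose blob on the PTV. Stands in for (non-shareable) patient
# CT-sim data in all tests.

run_with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic head phantom
#'
#' Geometry is in patient mm (LPS, head-first-supine; anterior = smaller y,
#' superior = larger z) and is independent of the voxel grid, so the same
#' anatomy can be sampled at any resolution. The PTV is placed according to
#' `ptv_mode`: entirely inferior to the crop region (`below`), on crop slices
#' but posterior to the eye midpoint (`same_slice`), or protruding into the
#' cropped region (`overlap`), emulating the three clinically observed PTV
#' locations. With `jitter_mm > 0` the whole anatomy is rigidly shifted by a
#' seeded random offset and the eye radii are jittered per eye, which varies
#' the induced landmarks without breaking the declared PTV mode.
#'
#' @param ptv_mode One of `"below"`, `"same_slice"`, `"overlap"`.
#' @param grid_shape CT grid (rows, cols, slices), default 128 x 128 x 80.
#' @param spacing Voxel spacing (dy, dx, dz) mm, default 2 x 2 x 2.
#' @param seed Integer seed for jitter and noise.
#' @param jitter_mm Half-width (mm) of the rigid anatomy shift (0 = off).
#' @param noise_sd Standard deviation (HU) of additive Gaussian image noise
#'   (0 = off, the default, for bit-exact tests).
#' @param dose_amplitude_gy Peak of the Gaussian dose blob (Gy).
#' @param dose_sigma_mm Width of the dose blob (mm).
#' @param dose_shape,dose_spacing Dose grid shape and spacing (its geometry
#'   deliberately differs from the CT grid).
#' @param hu Named per-tissue HU values.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(ptv_mode = c("below", "same_slice", "overlap"),
                         grid_shape = c(128L, 128L, 80L),
                         spacing = c(2, 2, 2),
                         seed = 1L,
                         jitter_mm = 0,
                         noise_sd = 0,
                         dose_amplitude_gy = 70,
                         dose_sigma_mm = 18,
                         dose_shape = c(64L, 64L, 48L),
                         dose_spacing = c(3, 3, 3),
                         hu = c(air = -1000, soft = 40, brain = 30, eye = 20,
                                cornea = 55, lens = 80, bone = 700, ptv = 50)) {
  ptv_mode <- match.arg(ptv_mode)
  ptv_center <- switch(ptv_mode,
    below      = c(0, 20, 50),
    same_slice = c(0, 30, 95),
    overlap    = c(0, -37, 95))
  spec <- list(
    ptv_mode = ptv_mode,
    grid_shape = as.integer(grid_shape),
    spacing = as.numeric(spacing),
    seed = as.integer(seed),
    jitter_mm = jitter_mm,
    noise_sd = noise_sd,
    hu = hu,
    body = list(center = c(0, 10, 100), semi = c(65, 80, 55),
                neck_radius = 40, neck_zmax = 100),
    eyes = list(center_l = c(30, -45, 100), center_r = c(-30, -45, 100),
                radius = c(12, 12)),
    lenses = list(center_l = c(30, -52, 100), center_r = c(-30, -52, 100),
                  radius = 4),
    corneas = list(center_l = c(30, -56, 100), center_r = c(-30, -56, 100),
                   radius = 3),
    brain = list(center = c(0, 15, 120), semi = c(45, 65, 32)),
    oars = list(
      Parotid_L = list(center = c(38, 15, 70), radius = 10, tissue = "soft"),
      Parotid_R = list(center = c(-38, 15, 70), radius = 10, tissue = "soft"),
      Mandible  = list(center = c(0, -35, 68), radius = 9, tissue = "bone")),
    ptv = list(center = ptv_center, radius = switch(ptv_mode, below = 18, 15)),
    dose = list(amplitude = dose_amplitude_gy, sigma = dose_sigma_mm,
                shape = as.integer(dose_shape), spacing = as.numeric(dose_spacing))
  )
  structure(spec, class = "phantom_spec")
}

# Rigid anatomy shift + per-eye radius jitter, deterministic in the seed.
.jitter_spec <- function(spec) {
  if (spec$jitter_mm <= 0) return(spec)
  run_with_seed(spec$seed, {
    shift <- stats::runif(3, -spec$jitter_mm, spec$jitter_mm)
    dr <- stats::runif(2, -spec$jitter_mm / 3, spec$jitter_mm / 3)
    move <- function(p) p + shift
    spec$body$center <- move(spec$body$center)
    spec$body$neck_zmax <- spec$body$neck_zmax + shift[3]
    spec$eyes$center_l <- move(spec$eyes$center_l)
    spec$eyes$center_r <- move(spec$eyes$center_r)
    spec$eyes$radius <- spec$eyes$radius + dr
    spec$lenses$center_l <- move(spec$lenses$center_l)
    spec$lenses$center_r <- move(spec$lenses$center_r)
    spec$corneas$center_l <- move(spec$corneas$center_l)
    spec$corneas$center_r <- move(spec$corneas$center_r)
    spec$brain$center <- move(spec$brain$center)
    for (nm in names(spec$oars)) spec$oars[[nm]]$center <- move(spec$oars[[nm]]$center)
    spec$ptv$center <- move(spec$ptv$center)
    spec
  })
}

# Contours of a sphere: one circle per slice whose slab (thickness = slice
# gap) intersects the sphere, with the radius evaluated at the in-slab point
# nearest the sphere centre. This partial-volume convention contours the
# sphere's full superior-inferior extent, as clinical contours do.
sphere_contours <- function(center, r, geometry, n_vertices = 48) {
  g <- geom_axes(geometry)
  gap <- slice_gap(geometry)
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  polys <- list()
  for (k in seq_along(g$z)) {
    dz <- abs(g$z[k] - center[3])
    if (dz >= r + gap / 2) next
    dz_eff <- max(0, dz - gap / 2)
    rk <- max(sqrt(max(r^2 - dz_eff^2, 0)), 0.25)
    polys[[length(polys) + 1L]] <- cbind(center[1] + rk * cos(th),
                                         center[2] + rk * sin(th),
                                         rep(g$z[k], n_vertices),
                                         deparse.level = 0)
  }
  polys
}

ellipsoid_contours <- function(center, semi, geometry, n_vertices = 72) {
  g <- geom_axes(geometry)
  gap <- slice_gap(geometry)
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  polys <- list()
  for (k in seq_along(g$z)) {
    dz <- abs(g$z[k] - center[3])
    if (dz >= semi[3] + gap / 2) next
    dz_eff <- max(0, dz - gap / 2)
    s <- sqrt(max(1 - (dz_eff / semi[3])^2, 0))
    rx <- max(semi[1] * s, 0.25); ry <- max(semi[2] * s, 0.25)
    polys[[length(polys) + 1L]] <- cbind(center[1] + rx * cos(th),
                                         center[2] + ry * sin(th),
                                         rep(g$z[k], n_vertices),
                                         deparse.level = 0)
  }
  polys
}

# Analytic body membership (head ellipsoid + neck cylinder) at voxel centres.
.body_mask <- function(spec, geometry) {
  g <- geom_axes(geometry)
  b <- spec$body
  xs <- rep(g$x, each = g$dim[1])
  ys <- rep(g$y, times = g$dim[2])
  mask <- array(FALSE, g$dim)
  plane <- ((xs - b$center[1]) / b$semi[1])^2 + ((ys - b$center[2]) / b$semi[2])^2
  neck <- (xs - b$center[1])^2 + (ys - b$center[2])^2 <= b$neck_radius^2
  for (k in seq_along(g$z)) {
    dz <- (g$z[k] - b$center[3]) / b$semi[3]
    in_head <- if (abs(dz) < 1) plane <= 1 - dz^2 else rep(FALSE, length(plane))
    in_neck <- neck & (g$z[k] <= b$neck_zmax)
    mask[, , k] <- matrix(in_head | in_neck, nrow = g$dim[1])
  }
  mask
}

#' Generate a synthetic phantom triplet
#'
#' Builds the CT volume, structure set and dose grid described by a
#' [phantom_spec()]. Tissue HU values are painted by rasterizing the same
#' contours that go into the structure set, so image and contours are exactly
#' consistent. After generation the phantom re-derives the crop landmarks
#' from its own structure set and asserts that the declared `ptv_mode` holds;
#' infeasible geometry is an error.
#'
#' @param spec A [phantom_spec()].
#' @return List of class `rt_phantom` with elements `volume`
#'   ([image_volume()]), `structures` ([structure_set()]), `dose`
#'   ([dose_grid()]), `spec` (the realized, jittered spec) and `landmarks`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  spec <- .jitter_spec(spec)

  # phantom identifiers are a pure function of the spec seed, so the same
  # spec yields a bit-identical triplet
  old_uid_seed <- .rt_env$uid_seed
  old_uid_counter <- .rt_env$uid_counter
  .rt_env$uid_seed <- 70000L + spec$seed
  .rt_env$uid_counter <- 0L
  on.exit({
    .rt_env$uid_seed <- old_uid_seed
    .rt_env$uid_counter <- old_uid_counter
  })

  d <- spec$grid_shape
  sp <- spec$spacing
  origin <- c(-(d[2] - 1) * sp[2] / 2, -(d[1] - 1) * sp[1] / 2, 0)
  zs <- (seq_len(d[3]) - 1) * sp[3]
  frame_uid <- new_uid()
  geom <- list(origin = origin, pixel_spacing = sp[1:2], slice_positions = zs)
  # a lightweight stand-in with just the geometry fields geom_axes needs
  geom$stored_values <- array(0L, d)
  class(geom) <- "image_volume"

  body_mask <- .body_mask(spec, geom)
  body_polys <- polygonize_mask(body_mask, geom)

  rois <- list(
    roi_contour("BODY", 1L, body_polys, role = "body"),
    roi_contour("Eye_L", 2L, sphere_contours(spec$eyes$center_l, spec$eyes$radius[1], geom), role = "eye"),
    roi_contour("Eye_R", 3L, sphere_contours(spec$eyes$center_r, spec$eyes$radius[2], geom), role = "eye"),
    roi_contour("Lens_L", 4L, sphere_contours(spec$lenses$center_l, spec$lenses$radius, geom, 24), role = "lens"),
    roi_contour("Lens_R", 5L, sphere_contours(spec$lenses$center_r, spec$lenses$radius, geom, 24), role = "lens"),
    roi_contour("Cornea_L", 6L, sphere_contours(spec$corneas$center_l, spec$corneas$radius, geom, 24), role = "cornea"),
    roi_contour("Cornea_R", 7L, sphere_contours(spec$corneas$center_r, spec$corneas$radius, geom, 24), role = "cornea"),
    roi_contour("Brain", 8L, ellipsoid_contours(spec$brain$center, spec$brain$semi, geom), role = "brain")
  )
  nxt <- 9L
  for (nm in names(spec$oars)) {
    o <- spec$oars[[nm]]
    rois[[length(rois) + 1L]] <- roi_contour(nm, nxt, sphere_contours(o$center, o$radius, geom), role = "other")
    nxt <- nxt + 1L
  }
  ptv_roi <- roi_contour("PTV70", nxt, sphere_contours(spec$ptv$center, spec$ptv$radius, geom), role = "ptv")
  rois[[length(rois) + 1L]] <- ptv_roi

  # paint tissues (later paints overwrite earlier ones)
  hu_arr <- array(spec$hu[["air"]], d)
  paint <- function(hu_arr, mask, hu) { hu_arr[mask] <- hu; hu_arr }
  hu_arr <- paint(hu_arr, body_mask, spec$hu[["soft"]])
  masks <- lapply(rois, rasterize_roi, geometry = geom)
  names(masks) <- vapply(rois, function(r) r$name, character(1))
  for (nm in names(spec$oars)) {
    hu_arr <- paint(hu_arr, masks[[nm]], spec$hu[[spec$oars[[nm]]$tissue]])
  }
  hu_arr <- paint(hu_arr, masks[["Brain"]], spec$hu[["brain"]])
  hu_arr <- paint(hu_arr, masks[["PTV70"]], spec$hu[["ptv"]])
  hu_arr <- paint(hu_arr, masks[["Eye_L"]] | masks[["Eye_R"]], spec$hu[["eye"]])
  hu_arr <- paint(hu_arr, masks[["Cornea_L"]] | masks[["Cornea_R"]], spec$hu[["cornea"]])
  hu_arr <- paint(hu_arr, masks[["Lens_L"]] | masks[["Lens_R"]], spec$hu[["lens"]])

  stored <- hu_arr + 1024  # slope 1, intercept -1024
  if (spec$noise_sd > 0) {
    stored <- run_with_seed(spec$seed + 1L, {
      stored + round(stats::rnorm(length(stored), sd = spec$noise_sd))
    })
  }
  stored <- pmin(pmax(stored, -32768), 32767)
  storage.mode(stored) <- "integer"
  dim(stored) <- d

  study_uid <- new_uid()
  volume <- image_volume(stored, origin, sp[1:2], zs,
                         rescale_slope = 1, rescale_intercept = -1024,
                         frame_of_reference = frame_uid, study_uid = study_uid)
  ss <- structure_set(rois, frame_of_reference = frame_uid,
                      referenced_series = volume$series_uid,
                      referenced_study = study_uid,
                      referenced_instances = volume$sop_instance_uids,
                      label = paste0("phantom_", spec$ptv_mode))

  # dose: Gaussian blob centred on the PTV, on its own (coarser) grid
  dd <- spec$dose$shape
  dsp <- spec$dose$spacing
  dorigin <- c(-(dd[2] - 1) * dsp[2] / 2, -(dd[1] - 1) * dsp[1] / 2, 6)
  dzs <- dorigin[3] + (seq_len(dd[3]) - 1) * dsp[3]
  dx <- dorigin[1] + (seq_len(dd[2]) - 1) * dsp[2]
  dyy <- dorigin[2] + (seq_len(dd[1]) - 1) * dsp[1]
  c0 <- spec$ptv$center
  r2_plane <- outer((dyy - c0[2])^2, (dx - c0[1])^2, "+")
  dvals <- array(0, dd)
  for (k in seq_len(dd[3])) {
    dvals[, , k] <- spec$dose$amplitude *
      exp(-(r2_plane + (dzs[k] - c0[3])^2) / (2 * spec$dose$sigma^2))
  }
  dose <- dose_grid(dvals, dorigin, dsp[1:2], dzs, frame_of_reference = frame_uid)

  # self-check: the declared PTV mode must hold for the landmarks the
  # phantom's own eye contours induce
  landmarks <- compute_landmarks(ss, volume)
  mode <- classify_ptv(masks[["PTV70"]], landmarks, volume)
  declared <- switch(spec$ptv_mode, below = "below",
                     same_slice = "same_slice_no_overlap", overlap = "overlap")
  if (!identical(mode, declared)) {
    stop_geometry("infeasible phantom geometry: ptv_mode '", spec$ptv_mode,
                  "' but generated PTV classifies as '", mode, "'")
  }

  structure(list(volume = volume, structures = ss, dose = dose,
                 spec = spec, landmarks = landmarks),
            class = "rt_phantom")
}

#' @export
print.rt_phantom <- function(x, ...) {
  cat(sprintf("<rt_phantom> ptv_mode=%s, seed=%d\n", x$spec$ptv_mode, x$spec$seed))
  print(x$landmarks)
  invisible(x)
}
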