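# Shared fixtures, built in code. Tests use a coarse (3 mm) phantom grid so
# the whole anatomy fits while keeping every file fast; the anatomy itself is
# identical to the package defaults.

small_spec <- function(mode = "below", seed = 1L, ...) {
  phantom_spec(mode, grid_shape = c(64L, 64L, 54L), spacing = c(3, 3, 3),
               dose_shape = c(48L, 48L, 32L), dose_spacing = c(4, 4, 4),
               seed = seed, ...)
}

# Cache plain small phantoms (per mode/seed) across tests within a file run.
.phantom_cache <- new.env(parent = emptyenv())
small_phantom <- function(mode = "below", seed = 1L) {
  key <- paste(mode, seed, sep = "_")
  if (is.null(.phantom_cache[[key]])) {
    .phantom_cache[[key]] <- generate_phantom(small_spec(mode, seed))
  }
  .phantom_cache[[key]]
}

# A tiny bare image volume with controllable geometry, for unit tests.
tiny_volume <- function(dim = c(8L, 8L, 4L), spacing = c(1, 1, 1),
                        origin = c(0, 0, 0), stored = NULL) {
  if (is.null(stored)) stored <- array(0L, dim)
  image_volume(stored, origin, spacing[1:2],
               origin[3] + (seq_len(dim[3]) - 1) * spacing[3])
}

# Independent per-voxel evaluation of the retain rule (triple loop; no shared
# code with build_retain_mask).
brute_force_retain <- function(volume, landmarks, ptv_mask, brain_mask) {
  g <- rtdeface:::geom_axes(volume)
  keep <- array(FALSE, g$dim)
  for (k in seq_len(g$dim[3])) {
    for (j in seq_len(g$dim[2])) {
      for (i in seq_len(g$dim[1])) {
        keep[i, j, k] <- g$z[k] < landmarks$z_inf ||
          g$y[i] >= landmarks$y_mid ||
          ptv_mask[i, j, k] || brain_mask[i, j, k]
      }
    }
  }
  keep
}

fake_landmarks <- function(z_inf, y_mid) {
  structure(list(z_inf = z_inf, y_mid = y_mid, source_roi_names = "test"),
            class = "crop_landmarks")
}

# Random connected-ish blob mask: union of random discs per slice.
random_blob_mask <- function(volume, n_discs = 3, min_r = 3, max_r = 8) {
  g <- rtdeface:::geom_axes(volume)
  mask <- array(FALSE, g$dim)
  for (k in seq_len(g$dim[3])) {
    cx0 <- runif(1, min(g$x) + max_r, max(g$x) - max_r)
    cy0 <- runif(1, min(g$y) + max_r, max(g$y) - max_r)
    for (d in seq_len(n_discs)) {
      cx <- cx0 + runif(1, -3, 3)
      cy <- cy0 + runif(1, -3, 3)
      r <- runif(1, min_r, max_r)
      dist2 <- outer((g$y - cy)^2, (g$x - cx)^2, "+")
      mask[, , k] <- mask[, , k] | (dist2 <= r^2)
    }
  }
  mask
}

# Exact plane-intersection circle contours of a sphere (distinct from the
# phantom's slab convention; used where analytic geometry must be exact).
plane_sphere_contours <- function(center, r, volume, n = 72) {
  g <- rtdeface:::geom_axes(volume)
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  polys <- list()
  for (k in seq_along(g$z)) {
    dz <- g$z[k] - center[3]
    if (abs(dz) >= r) next
    rk <- sqrt(r^2 - dz^2)
    polys[[length(polys) + 1L]] <- cbind(center[1] + rk * cos(th),
                                         center[2] + rk * sin(th),
                                         rep(g$z[k], n), deparse.level = 0)
  }
  polys
}

cli_path <- function() {
  p <- system.file("cli", "rtdeface.R", package = "rtdeface")
  stopifnot(nzchar(p))
  p
}

run_cli <- function(args) {
  out <- suppressWarnings(
    system2(file.path(R.home("bin"), "Rscript"), c(cli_path(), args),
            stdout = TRUE, stderr = TRUE))
  list(status = attr(out, "status") %||% 0L, output = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
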