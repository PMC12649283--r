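# DICOM reading/writing: round trips, degenerate inputs, reference
# integrity, and an independent cross-read with pydicom.

test_that("CT series round-trips bit-identically and is insensitive to file order", {
  ph <- small_phantom("below")
  td <- withr::local_tempdir()
  write_ct_series(ph$volume, td)

  vol <- read_ct_series(td)
  expect_identical(vol$stored_values, ph$volume$stored_values)
  expect_equal(vol$origin, ph$volume$origin)
  expect_equal(vol$pixel_spacing, ph$volume$pixel_spacing)
  expect_equal(vol$slice_positions, ph$volume$slice_positions)
  expect_identical(vol$sop_instance_uids, ph$volume$sop_instance_uids)
  expect_equal(vol$rescale_intercept, -1024)

  # scramble file names so on-disk order disagrees with slice order
  shuf <- withr::local_tempdir()
  files <- list.files(td, full.names = TRUE)
  for (i in seq_along(files)) {
    file.copy(files[i], file.path(shuf, sprintf("x%03d.dcm", (i * 37L) %% 101L)))
  }
  vol2 <- read_ct_series(shuf)
  expect_identical(vol2$stored_values, vol$stored_values)
  expect_equal(vol2$slice_positions, vol$slice_positions)
})

test_that("degenerate CT inputs are rejected", {
  ph <- small_phantom("below")
  td <- withr::local_tempdir()
  write_ct_series(ph$volume, td)
  files <- sort(list.files(td, full.names = TRUE))

  one <- withr::local_tempdir()
  file.copy(files[1], one)
  expect_error(read_ct_series(one), "insufficient slices",
               class = "rtdeface_io_error")

  # removing an interior slice leaves a non-uniform gap
  gap <- withr::local_tempdir()
  file.copy(files, gap)
  file.remove(file.path(gap, basename(files[3])))
  expect_error(read_ct_series(gap), "non-uniform", class = "rtdeface_io_error")

  # a slice from a different series poisons the directory
  ph2 <- generate_phantom(small_spec("below", seed = 5L))
  other <- withr::local_tempdir()
  write_ct_series(ph2$volume, other)
  mixed <- withr::local_tempdir()
  file.copy(files, mixed)
  file.copy(list.files(other, full.names = TRUE)[1],
            file.path(mixed, "stray.dcm"))
  expect_error(read_ct_series(mixed), "mixed series", class = "rtdeface_io_error")
})

test_that("structure set round-trips vertices within 1e-3 mm and keeps roles", {
  ph <- small_phantom("overlap")
  td <- withr::local_tempdir()
  f <- file.path(td, "rs.dcm")
  write_structure_set(ph$structures, f)
  ss <- read_structure_set(f)

  expect_identical(vapply(ss$rois, function(r) r$name, character(1)),
                   vapply(ph$structures$rois, function(r) r$name, character(1)))
  expect_identical(vapply(ss$rois, function(r) r$role, character(1)),
                   vapply(ph$structures$rois, function(r) r$role, character(1)))
  expect_identical(ss$frame_of_reference, ph$structures$frame_of_reference)
  for (i in seq_along(ss$rois)) {
    orig <- ph$structures$rois[[i]]$polygons
    got <- ss$rois[[i]]$polygons
    expect_length(got, length(orig))
    for (j in seq_along(orig)) {
      expect_lt(max(abs(got[[j]] - orig[[j]])), 1e-3)
    }
  }
})

test_that("ROI role patterns classify clinical names, including brainstem", {
  expect_identical(assign_role("Eye_L"), "eye")
  expect_identical(assign_role("ORBIT_R"), "eye")
  expect_identical(assign_role("PTV70"), "ptv")
  expect_identical(assign_role("Lens_R"), "lens")
  expect_identical(assign_role("Brain"), "brain")
  expect_identical(assign_role("BrainStem"), "other")
  expect_identical(assign_role("External"), "body")
  expect_identical(assign_role("SpinalCord"), "other")

  conf <- read_role_patterns(system.file("extdata", "roles.conf",
                                         package = "rtdeface"))
  expect_identical(assign_role("BrainStem", conf), "other")
  expect_identical(assign_role("Cornea_L", conf), "cornea")
})

test_that("dose round-trips within 1e-6 Gy; zero scaling and zero dose handled", {
  ph <- small_phantom("overlap")
  td <- withr::local_tempdir()
  f <- file.path(td, "rd.dcm")
  write_dose(ph$dose, f)
  dg <- read_dose(f)
  expect_lt(max(abs(dg$values - ph$dose$values)), 1e-6)
  expect_equal(dg$origin, ph$dose$origin)
  expect_equal(dg$slice_positions, ph$dose$slice_positions)

  zero <- dose_grid(array(0, c(4, 4, 3)), c(0, 0, 0), c(2, 2), c(0, 2, 4),
                    frame_of_reference = ph$dose$frame_of_reference)
  fz <- file.path(td, "zero.dcm")
  write_dose(zero, fz)
  expect_true(all(read_dose(fz)$values == 0))

  # hand-craft a dose file with DoseGridScaling = 0
  ds <- rtdeface:::dcm_read_file(f)
  ds[["3004,000E"]] <- rtdeface:::dcm_el("DS", 0)
  bad <- file.path(td, "bad.dcm")
  rtdeface:::dcm_write_file(bad, ds, rtdeface:::SOP_RTDOSE, "1.2.3")
  expect_error(read_dose(bad), "scaling", ignore.case = TRUE,
               class = "rtdeface_io_error")
})

test_that("write_outputs refreshes identifiers, keeps references resolvable, checks frame of reference", {
  ph <- small_phantom("below")
  td <- withr::local_tempdir()
  set_uid_seed(101)
  paths <- write_outputs(ph$volume, ph$structures, ph$dose, td)
  set_uid_seed(NULL)

  vol <- read_ct_series(paths$ct_dir)
  ss <- read_structure_set(paths$rtstruct)
  dg <- read_dose(paths$rtdose)

  # fresh series, same frame of reference
  expect_false(identical(vol$series_uid, ph$volume$series_uid))
  expect_identical(vol$frame_of_reference, ph$volume$frame_of_reference)
  expect_identical(ss$frame_of_reference, vol$frame_of_reference)
  expect_identical(dg$frame_of_reference, vol$frame_of_reference)

  # structure-set image references resolve against the written CT instances
  expect_identical(ss$referenced_series, vol$series_uid)
  expect_true(all(ss$referenced_instances %in% vol$sop_instance_uids))
  expect_length(ss$referenced_instances, length(vol$sop_instance_uids))

  alien <- ph$dose
  alien$frame_of_reference <- "1.2.3.4"
  expect_error(write_outputs(ph$volume, ph$structures, alien, td),
               class = "rtdeface_geometry_error")
})

test_that("pydicom independently reads files written by the package", {
  ph <- generate_phantom(phantom_spec("below", grid_shape = c(24L, 24L, 12L),
                                      spacing = c(8, 8, 8),
                                      dose_shape = c(12L, 12L, 8L),
                                      dose_spacing = c(12, 12, 12)))
  td <- withr::local_tempdir()
  paths <- write_outputs(ph$volume, ph$structures, ph$dose, td)

  script <- file.path(td, "check.py")
  writeLines(c(
    "import pydicom, glob, json, sys, numpy as np",
    sprintf("fs = sorted(glob.glob(r'%s/*.dcm'))", paths$ct_dir),
    "sls = [pydicom.dcmread(f) for f in fs]",
    "sls.sort(key=lambda d: float(d.ImagePositionPatient[2]))",
    "vol = np.stack([d.pixel_array for d in sls], axis=-1)",
    sprintf("ss = pydicom.dcmread(r'%s')", paths$rtstruct),
    sprintf("rd = pydicom.dcmread(r'%s')", paths$rtdose),
    "cd = ss.ROIContourSequence[1].ContourSequence[0].ContourData",
    "print(json.dumps({",
    " 'sum': int(vol.astype('int64').sum()),",
    " 'corner': [int(vol[0,0,0]), int(vol[5,3,2])],",
    " 'rows': int(sls[0].Rows),",
    " 'names': [str(r.ROIName) for r in ss.StructureSetROISequence],",
    " 'eye0': [float(x) for x in cd[:6]],",
    " 'dosemax': float((rd.pixel_array * rd.DoseGridScaling).max()),",
    "}))"
  ), script)
  out <- system2("python", script, stdout = TRUE, stderr = TRUE)
  expect_null(attr(out, "status"))
  got <- jsonlite::fromJSON(paste(out, collapse = ""))

  expect_equal(got$sum, sum(as.numeric(ph$volume$stored_values)))
  expect_equal(got$corner, c(ph$volume$stored_values[1, 1, 1],
                             ph$volume$stored_values[6, 4, 3]))
  expect_equal(got$rows, dim(ph$volume$stored_values)[1])
  expect_identical(got$names,
                   vapply(ph$structures$rois, function(r) r$name, character(1)))
  eye_poly <- ph$structures$rois[[2]]$polygons[[1]]
  expect_equal(got$eye0, as.numeric(t(eye_poly[1:2, ])), tolerance = 1e-6)
  expect_equal(got$dosemax, max(ph$dose$values), tolerance = 1e-6)
})
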