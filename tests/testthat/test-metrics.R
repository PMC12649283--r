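# Validation metrics: Dice, PTV classification, retained fraction,
# Youden-threshold selection, match rates, and the run report.

test_that("dice handles identical, disjoint, partial and empty masks", {
  m <- function(v) array(v, c(4, 4, 1))
  a <- m(FALSE); a[1:2, 1:2, 1] <- TRUE          # |a| = 4
  b <- m(FALSE); b[2:3, 1:2, 1] <- TRUE          # |b| = 4, overlap 2
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, m(FALSE)), 0)
  expect_equal(dice(m(FALSE), m(FALSE)), 1)
  expect_equal(dice(a, b), 0.5)                  # 2*2 / (4+4)
  d <- m(FALSE); d[3:4, 3:4, 1] <- TRUE
  expect_equal(dice(a, d), 0)
  expect_error(dice(a, array(FALSE, c(5, 4, 1))), class = "rtdeface_geometry_error")

  set.seed(61)
  for (rep in 1:10) {
    x <- array(runif(64) < 0.4, c(4, 4, 4))
    y <- array(runif(64) < 0.4, c(4, 4, 4))
    expect_equal(dice(x, y), dice(y, x))
    expect_gte(dice(x, y), 0)
    expect_lte(dice(x, y), 1)
    if (any(x) && dice(x, y) == 1) expect_identical(x, y)
  }
})

test_that("classify_ptv partitions the three locations and rejects empty PTVs", {
  vol <- tiny_volume(dim = c(10L, 10L, 10L), spacing = c(1, 1, 1))
  lm <- fake_landmarks(z_inf = 5, y_mid = 5)
  below <- array(FALSE, c(10, 10, 10)); below[8, 8, 2] <- TRUE
  same <- array(FALSE, c(10, 10, 10)); same[8, 8, 8] <- TRUE   # y=7 >= 5
  over <- same; over[2, 2, 8] <- TRUE                          # y=1 < 5, z=7 >= 5
  expect_identical(classify_ptv(below, lm, vol), "below")
  expect_identical(classify_ptv(same, lm, vol), "same_slice_no_overlap")
  expect_identical(classify_ptv(over, lm, vol), "overlap")
  expect_error(classify_ptv(array(FALSE, c(10, 10, 10)), lm, vol),
               class = "rtdeface_geometry_error")
})

test_that("retained_fraction matches a brute-force voxel count and rejects empty structures", {
  set.seed(67)
  vol <- tiny_volume(dim = c(12L, 12L, 6L))
  none <- array(FALSE, c(12, 12, 6))
  mask <- build_retain_mask(vol, fake_landmarks(3, 6), none, none)
  for (rep in 1:5) {
    s <- array(runif(12 * 12 * 6) < 0.3, c(12, 12, 6))
    if (!any(s)) next
    want <- sum(s & mask$keep) / sum(s)
    expect_equal(retained_fraction(s, mask), want)
  }
  expect_error(retained_fraction(none, mask), class = "rtdeface_geometry_error")
})

test_that("youden_threshold separates separable lists and degrades to J=0 on identical lists", {
  th <- youden_threshold(c(0.1, 0.2), c(0.5, 0.6))
  expect_equal(th$j, 1)
  expect_equal(th$tpr, 1)
  expect_equal(th$fpr, 0)
  expect_gt(th$threshold, 0.2)
  expect_lt(th$threshold, 0.5)

  same <- c(0.2, 0.3, 0.4)
  expect_equal(youden_threshold(same, same)$j, 0)
  expect_error(youden_threshold(numeric(0), c(1)), class = "rtdeface_io_error")
})

test_that("youden_threshold equals an exhaustive scan (and pROC) on random instances", {
  set.seed(71)
  for (rep in 1:25) {
    ns <- sample(5:40, 1); nd <- sample(5:40, 1)
    same <- round(runif(ns, 0, 1), 2)    # ties across lists on purpose
    different <- round(runif(nd, 0.2, 1.4), 2)
    got <- youden_threshold(same, different)
    # oracle: J is a step function changing only at observed distances
    j_at <- function(t) mean(same <= t) - mean(different <= t)
    grid <- sort(unique(c(same, different)))
    best_j <- max(c(vapply(grid, j_at, numeric(1)), 0))  # 0 = threshold below all
    expect_equal(got$j, best_j)
    expect_equal(j_at(got$threshold), got$j)
  }

  same <- c(0.12, 0.2, 0.33, 0.4, 0.41)
  different <- c(0.3, 0.45, 0.5, 0.8, 0.9, 1.1)
  got <- youden_threshold(same, different)
  r <- pROC::roc(response = c(rep(1, length(same)), rep(0, length(different))),
                 predictor = c(same, different), direction = ">", quiet = TRUE)
  proc_j <- max(r$sensitivities + r$specificities - 1)
  expect_equal(got$j, proc_j)
})

test_that("match_rate counts boundary distances as matches", {
  expect_equal(match_rate(c(0.2, 0.4), 0.331), 0.5)
  expect_equal(match_rate(c(0.5, 0.6), 0.4), 0)
  expect_equal(match_rate(c(0.1, 0.2), 0.4), 1)
  expect_equal(match_rate(c(0.3, 0.5), 0.3), 0.5)  # boundary inclusive
  expect_error(match_rate(numeric(0), 0.3), class = "rtdeface_io_error")
})

test_that("recognition_summary reproduces a defacing-style drop in match rate", {
  set.seed(73)
  same <- pmax(0, rnorm(70, 0.25, 0.05))
  different <- pmin(2, pmax(0, rnorm(200, 0.55, 0.08)))
  defaced <- pmin(2, pmax(0, rnorm(70, 0.6, 0.08)))
  s <- recognition_summary(same, different, defaced)
  expect_gt(s$baseline_match_rate, 0.9)
  expect_lt(s$defaced_match_rate, 0.2)
  expect_lt(s$defaced_match_rate, s$false_positive_rate + 0.1)
})

test_that("distance files parse with and without headers", {
  td <- withr::local_tempdir()
  f1 <- file.path(td, "d1.tsv")
  writeLines(c("pair_id\tdistance", "p1\t0.21", "p2\t0.47"), f1)
  d <- read_distances(f1)
  expect_equal(unname(d), c(0.21, 0.47))
  expect_identical(names(d), c("p1", "p2"))

  f2 <- file.path(td, "d2.csv")
  writeLines(c("p1,0.9", "p2,1.1"), f2)
  expect_equal(unname(read_distances(f2)), c(0.9, 1.1))

  f3 <- file.path(td, "bad.tsv")
  writeLines(c("p1\tnot_a_number"), f3)
  expect_error(read_distances(f3), class = "rtdeface_io_error")
})

test_that("the run report is internally consistent and survives JSON round-trip", {
  ph <- small_phantom("below")
  vol <- ph$volume
  mask <- build_retain_mask(vol, ph$landmarks,
                            rasterize_union(rois_with_role(ph$structures, "ptv"), vol),
                            rasterize_union(rois_with_role(ph$structures, "brain"), vol))
  dvol <- deface_image(vol, mask)
  dss <- suppressWarnings(deface_structure_set(ph$structures, mask, vol))
  rep <- build_report(vol, dvol, ph$structures, dss, mask)

  # two independent accountings of removed voxels agree
  expect_equal(rep$voxels_removed, sum(!mask$keep))
  expect_equal(rep$image_voxels_modified,
               sum(!mask$keep & vol$stored_values != 24L))

  td <- withr::local_tempdir()
  f <- file.path(td, "report.json")
  report_to_json(rep, f)
  back <- report_from_json(f)
  expect_equal(back$voxels_removed, rep$voxels_removed)
  expect_equal(back$landmarks$z_inf, rep$landmarks$z_inf)
  expect_equal(length(back$rois), length(rep$rois))
  expect_identical(back$ptv_category, rep$ptv_category)
  expect_equal(vapply(back$rois, function(r) r$dice, numeric(1)),
               vapply(rep$rois, function(r) r$dice, numeric(1)))
})
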