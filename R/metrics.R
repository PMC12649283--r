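# Validation metrics: Dice overlap, PTV-location classification, retained
# fractions, and recognition-threshold statistics on precomputed
# face-embedding cosine distances. Face detection/embedding itself is out of
# scope; these functions operate on supplied distance lists.

#' Dice overlap coefficient of two binary masks
#'
#' @param a,b Binary masks on the same grid.
#' @return `2|a n b| / (|a| + |b|)` in \[0, 1\]; defined as 1 when both masks
#'   are empty (identical empty structures are not a mismatch) and 0 when
#'   exactly one is empty.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop_geometry("dice: masks are on different grids")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Classify a PTV's location relative to the crop region
#'
#' Evaluated against the initial crop region (before PTV/brain preservation):
#' `overlap` if any PTV voxel lies on a crop slice and anterior to the eye
#' midpoint, otherwise `same_slice_no_overlap` if any PTV voxel lies on a
#' crop slice, otherwise `below`.
#'
#' @param ptv_mask Non-empty logical mask on `geometry`'s grid.
#' @param landmarks A `crop_landmarks` object.
#' @param geometry Grid-defining object ([image_volume()] or [dose_grid()]).
#' @return One of `"below"`, `"same_slice_no_overlap"`, `"overlap"`.
#' @export
classify_ptv <- function(ptv_mask, landmarks, geometry) {
  if (!any(ptv_mask)) stop_geometry("classify_ptv: empty PTV mask")
  g <- geom_axes(geometry)
  stopifnot(identical(dim(ptv_mask), g$dim))
  on_crop_slice <- g$z >= landmarks$z_inf
  anterior <- g$y < landmarks$y_mid
  sub <- ptv_mask[, , on_crop_slice, drop = FALSE]
  if (!any(sub)) return("below")
  if (any(sub[anterior, , , drop = FALSE])) return("overlap")
  "same_slice_no_overlap"
}

#' Fraction of a structure surviving defacing
#'
#' @param structure_mask Non-empty logical mask on the CT grid.
#' @param keep Kept-voxel set: a [build_retain_mask()] result or its `keep`
#'   array.
#' @return `|structure n keep| / |structure|` in \[0, 1\].
#' @export
retained_fraction <- function(structure_mask, keep) {
  if (inherits(keep, "retain_mask")) keep <- keep$keep
  if (!identical(dim(structure_mask), dim(keep))) {
    stop_geometry("retained_fraction: masks are on different grids")
  }
  n <- sum(structure_mask)
  if (n == 0) stop_geometry("retained_fraction: empty structure")
  sum(structure_mask & keep) / n
}

#' Optimal match threshold by Youden index
#'
#' A "positive" is a same-patient pair; a pair matches when its distance is
#' `<=` the threshold. Candidate thresholds are the midpoints of consecutive
#' sorted unique pooled distances plus sentinels below and above the data,
#' and the threshold maximizing `J = TPR - FPR` is returned (ties broken by
#' the smallest threshold).
#'
#' @param same Distances for same-patient pairs (positives).
#' @param different Distances for different-patient pairs (negatives).
#' @return List with `threshold`, `tpr`, `fpr`, `j`.
#' @export
youden_threshold <- function(same, different) {
  if (length(same) == 0 || length(different) == 0) {
    stop_io("youden_threshold: empty distance list")
  }
  stopifnot(all(is.finite(same)), all(is.finite(different)))
  pooled <- sort(unique(c(same, different)))
  candidates <- c(pooled[1] - 1,
                  if (length(pooled) > 1) (pooled[-1] + pooled[-length(pooled)]) / 2,
                  pooled[length(pooled)] + 1)
  tpr <- vapply(candidates, function(t) mean(same <= t), numeric(1))
  fpr <- vapply(candidates, function(t) mean(different <= t), numeric(1))
  j <- tpr - fpr
  best <- which(j == max(j))[1]  # candidates ascend, so first max = smallest t
  list(threshold = candidates[best], tpr = tpr[best], fpr = fpr[best], j = j[best])
}

#' Fraction of pairs matching at a threshold
#'
#' @param distances Distance list (one per pair).
#' @param threshold Finite match threshold; a pair matches when
#'   `distance <= threshold`.
#' @return Matched fraction in \[0, 1\].
#' @export
match_rate <- function(distances, threshold) {
  if (length(distances) == 0) stop_io("match_rate: empty distance list")
  stopifnot(is.finite(threshold))
  mean(distances <= threshold)
}

#' Read a two-column pair-distance file
#'
#' Delimited text with columns `pair_id` and `distance` (header optional,
#' tab/comma/whitespace separated).
#'
#' @param path File path.
#' @return Numeric vector of distances, named by pair id.
#' @export
read_distances <- function(path) {
  if (!file.exists(path)) stop_io("distance file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[\t, ]+")
  if (length(parts) > 1 && suppressWarnings(is.na(as.numeric(parts[[1]][2])))) {
    parts <- parts[-1]  # header row
  }
  if (length(parts) == 0) stop_io("no distance rows in ", path)
  ids <- vapply(parts, `[`, character(1), 1)
  d <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2)))
  if (anyNA(d)) stop_io("non-numeric distance in ", path)
  if (any(d < 0)) stop_io("negative distance in ", path)
  stats::setNames(d, ids)
}

#' Recognition summary for the three pairing groups
#'
#' Given cosine-distance lists for same-patient, different-patient and
#' defaced-same-patient pairs, selects the Youden-optimal threshold on the
#' baseline groups and reports the match rates before and after defacing and
#' the false-positive rate.
#'
#' @param same,different,defaced_same Numeric distance vectors.
#' @return List with `threshold`, `j`, `baseline_match_rate`,
#'   `false_positive_rate`, `defaced_match_rate`.
#' @export
recognition_summary <- function(same, different, defaced_same) {
  th <- youden_threshold(same, different)
  list(threshold = th$threshold,
       j = th$j,
       baseline_match_rate = match_rate(same, th$threshold),
       false_positive_rate = match_rate(different, th$threshold),
       defaced_match_rate = match_rate(defaced_same, th$threshold))
}
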