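# Object- and image-level measurements: counts, areas, percent area
# occupied, count subtraction, and a convenience two-sample t test.

#' Count objects in a label map
#'
#' @param labels A [label_map()].
#' @return Integer object count.
#' @export
count_objects <- function(labels) {
  if (!inherits(labels, "label_map"))
    .stop_validation("'labels' must be a label_map")
  labels$n_objects
}

#' Measure per-object areas
#'
#' Returns one row per object: pixel `area`, `equivalent_diameter`
#' (`2*sqrt(area/pi)`), and centroid coordinates (0-based row/col).
#'
#' @param labels A [label_map()].
#' @return Data frame with columns `label`, `area`, `equivalent_diameter`,
#'   `centroid_row`, `centroid_col`.
#' @export
measure_object_areas <- function(labels) {
  if (!inherits(labels, "label_map"))
    .stop_validation("'labels' must be a label_map")
  .object_table(labels$labels)
}

#' Area occupied by a binary mask
#'
#' Counts foreground (value 1) pixels and divides by the total pixel count
#' of the frame; the denominator is always the full image area.
#'
#' @param mask Binary mask matrix.
#' @return List of class `area_occupied` with `foreground_pixels`,
#'   `total_pixels`, `fraction` and `percent`.
#' @export
area_occupied <- function(mask) {
  .assert_mask(mask)
  fg <- sum(mask == 1)
  tot <- length(mask)
  structure(list(foreground_pixels = as.integer(fg),
                 total_pixels = as.integer(tot),
                 fraction = fg / tot,
                 percent = 100 * fg / tot),
            class = "area_occupied")
}

#' Subtract an excluded count from a total count
#'
#' Returns `max(total - excluded, 0)`. When `excluded > total` (the two
#' identification passes disagreed) the result is clamped to 0 and flagged:
#' the returned integer carries attribute `clamped = TRUE` so callers can
#' attach a discrepancy warning to the result record.
#'
#' @param total,excluded Non-negative counts.
#' @return Integer count with logical attribute `clamped`.
#' @export
subtract_counts <- function(total, excluded) {
  if (!.is_number(total) || !.is_number(excluded) ||
      total < 0 || excluded < 0)
    .stop_validation("counts must be non-negative numbers")
  out <- as.integer(max(total - excluded, 0))
  attr(out, "clamped") <- excluded > total
  out
}

#' Unpaired two-sample t test
#'
#' Classical two-sided Student (equal-variance) t test, provided as a
#' convenience for comparing per-image quantities between experimental
#' groups. When both groups are constant: equal constants give
#' `t = 0, p = 1`; different constants give an infinite statistic with
#' `p = 0`.
#'
#' @param group_a,group_b Numeric vectors with at least 2 values each.
#' @return List with elements `t` and `p`.
#' @export
two_sample_ttest <- function(group_a, group_b) {
  if (!is.numeric(group_a) || !is.numeric(group_b) ||
      length(group_a) < 2L || length(group_b) < 2L)
    .stop_validation("each group needs at least 2 numeric values")
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(group_a) - mean(group_b)) * Inf, p = 0))
  }
  ht <- t.test(group_a, group_b, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value)
}
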