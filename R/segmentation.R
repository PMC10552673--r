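# Primary object identification: threshold, clean, declump touching objects
# by shape (smoothed distance-transform watershed), and filter by
# area-equivalent diameter.

#' Segmentation parameters
#'
#' @param min_diameter,max_diameter Inclusive bounds (pixels) on the
#'   area-equivalent diameter `2*sqrt(area/pi)` of retained objects.
#' @param threshold A [threshold_config()] used to binarize the image.
#' @param declump Split touching objects by shape (default `TRUE`): the
#'   Euclidean distance transform of the foreground is Gaussian-smoothed,
#'   its local maxima (separated by at least `min_seed_distance`) seed a
#'   watershed-style label propagation over the foreground.
#' @param smoothing_sigma Gaussian sigma (pixels) for the distance-map
#'   smoothing, or `"auto"` = `min_diameter / 4`. Larger values suppress
#'   spurious seeds (fixes over-segmentation); smaller values recover
#'   merged objects (fixes under-segmentation).
#' @param min_seed_distance Minimum separation (pixels) between watershed
#'   seeds, or `"auto"` = `min_diameter / 2`.
#' @param fill_holes Fill enclosed background holes in the foreground before
#'   declumping (default `TRUE`), so the distance transform reflects whole
#'   object geometry.
#' @param discard_border Remove objects touching any image edge (default
#'   `FALSE`: edge-clipped fibers are counted).
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(min_diameter, max_diameter,
                                threshold = threshold_config(),
                                declump = TRUE,
                                smoothing_sigma = "auto",
                                min_seed_distance = "auto",
                                fill_holes = TRUE,
                                discard_border = FALSE) {
  if (!.is_number(min_diameter) || min_diameter <= 0)
    .stop_validation("'min_diameter' must be > 0")
  if (!.is_number(max_diameter) || max_diameter < min_diameter)
    .stop_validation("'max_diameter' must be >= min_diameter")
  if (!inherits(threshold, "threshold_config"))
    .stop_validation("'threshold' must be a threshold_config")
  chk_auto <- function(x, nm) {
    if (identical(x, "auto")) return(x)
    if (!.is_number(x) || x < 0)
      .stop_validation("'", nm, "' must be \"auto\" or a non-negative number")
    x
  }
  smoothing_sigma <- chk_auto(smoothing_sigma, "smoothing_sigma")
  min_seed_distance <- chk_auto(min_seed_distance, "min_seed_distance")
  if (!identical(min_seed_distance, "auto") && min_seed_distance <= 0)
    .stop_validation("'min_seed_distance' must be > 0")
  structure(list(min_diameter = min_diameter, max_diameter = max_diameter,
                 threshold = threshold, declump = isTRUE(declump),
                 smoothing_sigma = smoothing_sigma,
                 min_seed_distance = min_seed_distance,
                 fill_holes = isTRUE(fill_holes),
                 discard_border = isTRUE(discard_border)),
            class = "segmentation_params")
}

#' Integer-labeled segmentation map
#'
#' Wraps an `H x W` integer matrix where 0 is background and objects carry
#' the consecutive labels `1..n_objects`, each 8-connected.
#'
#' @param labels Integer matrix of non-negative labels.
#' @return An object of class `label_map` with fields `labels` (integer
#'   matrix) and `n_objects`.
#' @export
label_map <- function(labels) {
  if (!is.matrix(labels) || !is.numeric(labels))
    .stop_validation("'labels' must be an integer matrix")
  lab <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  if (anyNA(lab) || any(lab < 0L))
    .stop_validation("labels must be non-negative integers")
  n <- if (length(lab) && max(lab) > 0L) max(lab) else 0L
  if (n > 0L) {
    present <- sort(unique(lab[lab > 0L]))
    if (!identical(present, seq_len(n)))
      .stop_validation("labels must be consecutive 1..n with no gaps")
  }
  structure(list(labels = lab, n_objects = n), class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %d x %d, %d object(s)\n",
              nrow(x$labels), ncol(x$labels), x$n_objects))
  invisible(x)
}

# relabel nonzero labels consecutively 1..k preserving relative order
.relabel <- function(lab) {
  u <- sort(unique(lab[lab > 0L]))
  if (length(u) == 0L) return(matrix(0L, nrow(lab), ncol(lab)))
  remap <- integer(max(u))
  remap[u] <- seq_along(u)
  out <- lab
  out[out > 0L] <- remap[out[out > 0L]]
  out
}

# 8-connected component labeling: EBImage::bwlabel is 4-connected, so merge
# labels that touch diagonally with a small union-find over the label graph.
.label8 <- function(mask) {
  lab <- .mat(EBImage::bwlabel(mask))
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  mx <- if (length(lab)) max(lab) else 0L
  if (mx <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1L, -1L]          # down-right diagonal
  cc <- lab[-nr, -1L]; dd <- lab[-1L, -nc]        # down-left diagonal
  pairs <- rbind(cbind(as.vector(a), as.vector(b)),
                 cbind(as.vector(cc), as.vector(dd)))
  pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L &
                 pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  if (nrow(pairs) > 0L) {
    pairs <- unique(pairs)
    parent <- seq_len(mx)
    for (r in seq_len(nrow(pairs))) {
      ra <- pairs[r, 1L]; rb <- pairs[r, 2L]
      while (parent[ra] != ra) ra <- parent[ra]
      while (parent[rb] != rb) rb <- parent[rb]
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- seq_len(mx)
    for (i in seq_len(mx)) {
      r <- i
      while (parent[r] != r) r <- parent[r]
      root[i] <- r
    }
    lab[lab > 0L] <- root[lab[lab > 0L]]
  }
  .relabel(lab)
}

# per-object measurements from a raw label matrix
.object_table <- function(lab) {
  idx <- which(lab > 0L)
  if (length(idx) == 0L)
    return(data.frame(label = integer(0L), area = integer(0L),
                      equivalent_diameter = numeric(0L),
                      centroid_row = numeric(0L), centroid_col = numeric(0L)))
  labs <- lab[idx]
  n <- max(labs)
  area <- tabulate(labs, nbins = n)
  nr <- nrow(lab)
  rows <- (idx - 1L) %% nr
  cols <- (idx - 1L) %/% nr
  crow <- rowsum(rows, labs)[, 1L] / area
  ccol <- rowsum(cols, labs)[, 1L] / area
  data.frame(label = seq_len(n), area = area,
             equivalent_diameter = 2 * sqrt(area / pi),
             centroid_row = as.numeric(crow), centroid_col = as.numeric(ccol))
}

# depth tolerance for merging watershed maxima: peaks rising less than half
# a pixel of (smoothed) distance above their common saddle are treated as
# one object, so flat medial ridges -- common in edge-clipped fibers -- do
# not fragment, while genuinely overlapping objects still split
.watershed_tolerance <- 0.5

#' Identify primary objects in a gray image
#'
#' The full identification pipeline: (1) select a threshold with
#' `params$threshold` and apply it (objects must appear brighter than the
#' background -- invert first if needed); (2) fill holes; (3) declump by
#' smoothed distance-transform watershed, or plain 8-connected labeling if
#' `declump` is off; (4) remove objects whose equivalent diameter falls
#' outside `[min_diameter, max_diameter]`; (5) optionally remove
#' edge-touching objects; (6) relabel consecutively.
#'
#' An empty foreground is a valid result with zero objects, not an error.
#'
#' @param gray Gray matrix on \[0, 1\].
#' @param params A [segmentation_params()].
#' @return List with elements `labels` (a [label_map()]) and `table` (the
#'   per-object measurement data frame).
#' @export
identify_primary_objects <- function(gray, params) {
  .assert_gray(gray)
  if (!inherits(params, "segmentation_params"))
    .stop_validation("'params' must be segmentation_params")
  thr <- compute_threshold(gray, params$threshold)
  g_apply <- if (params$threshold$apply_smooth_sigma > 0)
    pmin(pmax(.gblur_replicate(gray, params$threshold$apply_smooth_sigma), 0), 1)
  else gray
  mask <- apply_threshold(g_apply, thr)
  if (params$fill_holes && any(mask > 0))
    mask <- (.mat(EBImage::fillHull(mask)) > 0) * 1
  lmask <- mask > 0
  if (!any(lmask)) {
    lm <- label_map(matrix(0L, nrow(gray), ncol(gray)))
    return(list(labels = lm, table = .object_table(lm$labels)))
  }
  sigma <- if (identical(params$smoothing_sigma, "auto"))
    params$min_diameter / 4 else params$smoothing_sigma
  min_dist <- if (identical(params$min_seed_distance, "auto"))
    params$min_diameter / 2 else params$min_seed_distance
  if (all(lmask)) {
    # no background at all: the frame is a single object and the distance
    # transform is unbounded, so declumping is moot
    lab <- matrix(1L, nrow(gray), ncol(gray))
  } else if (params$declump) {
    dm <- .mat(EBImage::distmap(mask))
    dsm <- if (sigma > 0) .gblur_replicate(dm, sigma) else dm
    dsm[!lmask] <- 0   # flood only the true foreground
    lab <- .mat(EBImage::watershed(EBImage::Image(dsm),
                                   tolerance = .watershed_tolerance,
                                   ext = max(1L, as.integer(ceiling(min_dist)))))
    lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
    # any foreground pixel left unassigned joins via plain labeling
    orphan <- lmask & lab == 0L
    if (any(orphan)) {
      oc <- .label8(orphan * 1)
      lab[orphan] <- max(lab) + oc[orphan]
    }
    lab <- .relabel(lab)
  } else {
    lab <- .label8(mask)
  }
  tab <- .object_table(lab)
  keep <- tab$label[tab$equivalent_diameter >= params$min_diameter &
                    tab$equivalent_diameter <= params$max_diameter]
  lab[!(lab %in% keep)] <- 0L
  if (params$discard_border && length(keep)) {
    edge <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
    lab[lab %in% edge[edge > 0L]] <- 0L
  }
  lab <- .relabel(lab)
  lm <- label_map(lab)
  list(labels = lm, table = .object_table(lm$labels))
}

#' Filter objects by area-equivalent diameter
#'
#' Removes objects whose equivalent diameter lies outside `[min_d, max_d]`
#' (inclusive); survivors are relabeled `1..k` preserving their original
#' relative order.
#'
#' @param labels A [label_map()].
#' @param table Matching per-object table (as returned by
#'   [measure_object_areas()]); recomputed when omitted.
#' @param min_d,max_d Diameter bounds in pixels, `min_d <= max_d`.
#' @return List with updated `labels` and `table`.
#' @export
filter_by_diameter <- function(labels, table = NULL, min_d, max_d) {
  if (!inherits(labels, "label_map"))
    .stop_validation("'labels' must be a label_map")
  if (min_d > max_d)
    .stop_validation("'min_d' must be <= 'max_d'")
  if (is.null(table)) table <- .object_table(labels$labels)
  if (nrow(table) != labels$n_objects)
    .stop_validation("'table' does not match 'labels'")
  keep <- table$label[table$equivalent_diameter >= min_d &
                      table$equivalent_diameter <= max_d]
  lab <- labels$labels
  lab[!(lab %in% keep)] <- 0L
  lm <- label_map(.relabel(lab))
  list(labels = lm, table = .object_table(lm$labels))
}

#' Convert labeled objects to a binary mask
#'
#' @param labels A [label_map()].
#' @return Binary mask matrix: 1 wherever the label is nonzero.
#' @export
objects_to_binary <- function(labels) {
  if (!inherits(labels, "label_map"))
    .stop_validation("'labels' must be a label_map")
  (labels$labels > 0L) * 1
}
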