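# The four assay orchestrations. Each consumes one multichannel image and a
# pipeline_config and produces an assay_result; run_batch maps an assay
# over many files and writes the CSV exports.

#' Per-image assay result
#'
#' @param image_id Identifier string (usually the file name).
#' @param assay Assay tag.
#' @param counts Named list of integer counts.
#' @param percent Named list of percent values.
#' @param sizes Optional numeric vector of per-object pixel areas.
#' @param warnings Character vector of warnings attached to this image.
#' @return An object of class `assay_result`.
#' @export
assay_result <- function(image_id, assay, counts = list(), percent = list(),
                         sizes = NULL, warnings = character(0L)) {
  structure(list(image_id = as.character(image_id),
                 assay = match.arg(assay, .assay_names),
                 counts = counts, percent = percent, sizes = sizes,
                 warnings = as.character(warnings)),
            class = "assay_result")
}

#' @export
print.assay_result <- function(x, ...) {
  cat(sprintf("<assay_result> %s  [%s]\n", x$image_id, x$assay))
  for (nm in names(x$counts))
    cat(sprintf("  %s: %d\n", nm, x$counts[[nm]]))
  for (nm in names(x$percent))
    cat(sprintf("  %s: %.4g\n", nm, x$percent[[nm]]))
  if (!is.null(x$sizes))
    cat(sprintf("  sizes: %d object(s), median %.4g px\n",
                length(x$sizes), stats::median(x$sizes)))
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

.check_roles <- function(img, cfg) {
  need <- .required_roles(cfg$assay)
  for (role in need) {
    ch <- cfg$channel_roles[[role]]
    if (is.null(ch) || !(ch %in% img$channel_names))
      stop("config error: role '", role, "' maps to channel '", ch,
           "' which is not present in the image", call. = FALSE)
  }
  invisible(TRUE)
}

#' Quantify membrane-damaged (dye-positive) fibers
#'
#' Damaged fibers take up Evans Blue Dye but have poorly defined borders, so
#' they are not segmented directly. Instead the image is inverted, the dye
#' and laminin channels are averaged to gray, and pixel intensities are
#' squared: dye-filled fibers turn dark and are ignored by the first
#' identification pass, which therefore counts only intact
#' (`not_ebd`) fibers. A second pass on the inverted laminin plane counts
#' all fibers; the difference is the dye-positive count.
#'
#' @param img A [multichannel_image()] carrying the laminin and dye
#'   channels named in `cfg$channel_roles`.
#' @param cfg A [pipeline_config()] for the `ebd` assay.
#' @param details Keep the intermediate label maps in the result (for
#'   overlays / quality control)?
#' @return An `assay_result` with counts `total_cells`, `not_ebd_cells`,
#'   `ebd_pos_cells` and percent `pct_ebd_pos`.
#' @export
run_ebd <- function(img, cfg = default_pipeline_config("ebd"),
                    details = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"), cfg$assay == "ebd")
  .check_roles(img, cfg)
  roles <- cfg$channel_roles
  inv <- invert(img)
  gray <- combine_to_gray(inv, c(roles$ebd, roles$laminin))
  masked <- power_transform(gray, cfg$square_exponent)
  seg_not <- identify_primary_objects(masked, cfg$cell_params)
  not_ebd <- count_objects(seg_not$labels)
  planes <- split_channels(img)
  lam_inv <- invert(planes[[roles$laminin]])
  seg_all <- identify_primary_objects(lam_inv, cfg$cell_params)
  total <- count_objects(seg_all$labels)
  ebd_pos <- subtract_counts(total, not_ebd)
  warns <- character(0L)
  if (isTRUE(attr(ebd_pos, "clamped")))
    warns <- c(warns, sprintf(
      "count discrepancy: not_ebd (%d) exceeds total (%d); clamped to 0",
      not_ebd, total))
  if (total == 0L)
    warns <- c(warns, "no muscle cells identified")
  pct <- if (total > 0L) list(pct_ebd_pos = 100 * as.integer(ebd_pos) / total)
         else list()
  res <- assay_result(
    image_id = img$source_path %||% "<in-memory>", assay = "ebd",
    counts = list(total_cells = total, not_ebd_cells = not_ebd,
                  ebd_pos_cells = as.integer(ebd_pos)),
    percent = pct, warnings = warns)
  if (details) res$details <- list(cells = seg_all$labels,
                                   not_ebd = seg_not$labels)
  res
}

#' Quantify regenerating (embryonic-myosin-positive) fibers
#'
#' Counts all fibers from the inverted laminin plane, then identifies
#' marker-positive fibers directly on the un-inverted marker plane (they
#' already appear light on a dark background) and measures their areas,
#' supporting the size-distribution analysis of regenerating fibers.
#'
#' @inheritParams run_ebd
#' @param cfg A [pipeline_config()] for the `emyhc` assay.
#' @return An `assay_result` with counts `total_cells`, `emyhc_pos_cells`,
#'   percent `pct_emyhc_pos`, and `sizes` holding the marker-positive
#'   object areas in pixels.
#' @export
run_emyhc <- function(img, cfg = default_pipeline_config("emyhc"),
                      details = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"), cfg$assay == "emyhc")
  .check_roles(img, cfg)
  roles <- cfg$channel_roles
  planes <- split_channels(img)
  lam_inv <- invert(planes[[roles$laminin]])
  seg_all <- identify_primary_objects(lam_inv, cfg$cell_params)
  total <- count_objects(seg_all$labels)
  seg_pos <- identify_primary_objects(planes[[roles$marker]],
                                      cfg$marker_params)
  pos <- count_objects(seg_pos$labels)
  warns <- character(0L)
  if (total == 0L) warns <- c(warns, "no muscle cells identified")
  if (pos > total)
    warns <- c(warns, sprintf(
      "marker-positive count (%d) exceeds total cells (%d)", pos, total))
  pct <- if (total > 0L) list(pct_emyhc_pos = 100 * pos / total) else list()
  res <- assay_result(
    image_id = img$source_path %||% "<in-memory>", assay = "emyhc",
    counts = list(total_cells = total, emyhc_pos_cells = pos),
    percent = pct, sizes = seg_pos$table$area, warnings = warns)
  if (details) res$details <- list(cells = seg_all$labels,
                                   marker = seg_pos$labels)
  res
}

#' Quantify macrophage (CD68) percent-area
#'
#' Macrophages aggregate in necrotic regions, making individual cells
#' uncountable, so inflammation is reported as the percent of the frame
#' covered by marker signal: objects are identified on the marker plane by
#' minimum cross-entropy thresholding, converted to a binary mask, and the
#' area occupied is measured against the full image area.
#'
#' @inheritParams run_ebd
#' @param cfg A [pipeline_config()] for the `cd68` assay.
#' @return An `assay_result` with counts `foreground_pixels`,
#'   `total_pixels` and percent `pct_area`.
#' @export
run_cd68 <- function(img, cfg = default_pipeline_config("cd68"),
                     details = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"), cfg$assay == "cd68")
  .check_roles(img, cfg)
  planes <- split_channels(img)
  seg <- identify_primary_objects(planes[[cfg$channel_roles$marker]],
                                  cfg$marker_params)
  occ <- area_occupied(objects_to_binary(seg$labels))
  res <- assay_result(
    image_id = img$source_path %||% "<in-memory>", assay = "cd68",
    counts = list(foreground_pixels = occ$foreground_pixels,
                  total_pixels = occ$total_pixels),
    percent = list(pct_area = occ$percent))
  if (details) res$details <- list(marker = seg$labels)
  res
}

#' Quantify collagen percent-area from a Picrosirius-red brightfield image
#'
#' Collagen stains red, so it appears dark in the green plane; that plane
#' is inverted to make collagen light, identified at myofiber-scale
#' diameters by minimum cross-entropy thresholding, converted to a binary
#' mask and measured as percent of the total image area.
#'
#' @inheritParams run_ebd
#' @param cfg A [pipeline_config()] for the `collagen` assay.
#' @return An `assay_result` with counts `foreground_pixels`,
#'   `total_pixels` and percent `pct_area`.
#' @export
run_collagen <- function(img, cfg = default_pipeline_config("collagen"),
                         details = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"), cfg$assay == "collagen")
  .check_roles(img, cfg)
  planes <- split_channels(img)
  col_inv <- invert(planes[[cfg$channel_roles$collagen]])
  seg <- identify_primary_objects(col_inv, cfg$marker_params)
  occ <- area_occupied(objects_to_binary(seg$labels))
  res <- assay_result(
    image_id = img$source_path %||% "<in-memory>", assay = "collagen",
    counts = list(foreground_pixels = occ$foreground_pixels,
                  total_pixels = occ$total_pixels),
    percent = list(pct_area = occ$percent))
  if (details) res$details <- list(collagen = seg$labels)
  res
}

#' Run the assay selected by a configuration on one image
#'
#' @param img A [multichannel_image()].
#' @param cfg A [pipeline_config()].
#' @param details Keep intermediate label maps?
#' @return An `assay_result`.
#' @export
run_assay <- function(img, cfg, details = FALSE) {
  switch(cfg$assay,
    ebd = run_ebd(img, cfg, details),
    emyhc = run_emyhc(img, cfg, details),
    cd68 = run_cd68(img, cfg, details),
    collagen = run_collagen(img, cfg, details))
}

#' Run an assay over a batch of image files
#'
#' Reads every path, runs the configured assay, and writes one CSV row per
#' image via [write_results_csv()]. A failing image becomes a warning row,
#' not an abort. For the regeneration assay a second per-object file
#' (`<out>_objects.csv` with columns `image_id,label,area_px`) records the
#' marker-positive size list.
#'
#' @param paths Character vector of image file paths.
#' @param cfg A [pipeline_config()].
#' @param out_csv Output CSV path.
#' @return Invisibly, the list of `assay_result`s, with attribute
#'   `n_failed` giving the number of images that could not be processed.
#' @export
run_batch <- function(paths, cfg, out_csv) {
  if (length(paths) == 0L)
    stop("no input images given", call. = FALSE)
  results <- vector("list", length(paths))
  n_failed <- 0L
  for (i in seq_along(paths)) {
    results[[i]] <- tryCatch({
      run_assay(read_image(paths[i]), cfg)
    }, error = function(e) {
      n_failed <<- n_failed + 1L
      assay_result(image_id = paths[i], assay = cfg$assay,
                   warnings = paste("failed:", conditionMessage(e)))
    })
  }
  if (n_failed == length(paths))
    stop("no valid images in batch (all ", n_failed, " failed)",
         call. = FALSE)
  write_results_csv(results, out_csv)
  if (cfg$assay == "emyhc") {
    obj_path <- sub("\\.csv$", "_objects.csv", out_csv)
    if (identical(obj_path, out_csv)) obj_path <- paste0(out_csv, "_objects")
    con <- file(obj_path, open = "wb")
    lines <- "image_id,label,area_px"
    for (r in results) {
      if (length(r$sizes))
        lines <- c(lines, sprintf("%s,%d,%s", r$image_id,
                                  seq_along(r$sizes),
                                  vapply(r$sizes, .fmt_num, character(1L))))
    }
    writeLines(lines, con, sep = "\n")
    close(con)
  }
  attr(results, "n_failed") <- n_failed
  invisible(results)
}
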