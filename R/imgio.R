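# Image and table input/output. Establishes the intensity convention
# ([0,1] floating point) and coordinate convention (row-major, 0-based
# reasoning, origin top-left) that every other module assumes.

#' Multichannel raster image
#'
#' Container for a 2-D multichannel image: an `H x W x C` numeric array of
#' intensities on \[0, 1\] plus an ordered vector of channel names drawn
#' from `"red"`, `"green"`, `"blue"`.
#'
#' @param pixels Numeric `H x W x C` array (a plain matrix is accepted for
#'   `C = 1`), every value finite and in \[0, 1\].
#' @param channel_names Character vector of length `C`; entries must be
#'   `"red"`, `"green"` or `"blue"` and are kept in the order given.
#' @param source_path Optional provenance string (file the image came from).
#' @return An object of class `mh_image` with fields `pixels`,
#'   `channel_names` and `source_path`.
#' @seealso [read_image()], [split_channels()]
#' @export
multichannel_image <- function(pixels, channel_names, source_path = NULL) {
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    .stop_validation("'pixels' must be an H x W x C array")
  if (dim(pixels)[1L] < 1L || dim(pixels)[2L] < 1L)
    .stop_validation("image must have H >= 1 and W >= 1")
  if (!all(is.finite(pixels)) || any(pixels < 0) || any(pixels > 1))
    .stop_validation("all intensities must be finite and in [0, 1]")
  channel_names <- as.character(channel_names)
  if (length(channel_names) != dim(pixels)[3L])
    .stop_validation("length(channel_names) must equal the number of planes")
  if (!all(channel_names %in% c("red", "green", "blue")))
    .stop_validation("channel names must be drawn from red/green/blue")
  structure(
    list(pixels = pixels, channel_names = channel_names,
         source_path = source_path),
    class = "mh_image")
}

#' @export
print.mh_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<mh_image> %d x %d, channels: %s\n", d[1L], d[2L],
              paste(x$channel_names, collapse = ", ")))
  if (!is.null(x$source_path)) cat("  source:", x$source_path, "\n")
  invisible(x)
}

.is_gray <- function(m) {
  is.matrix(m) && is.numeric(m) && all(is.finite(m)) &&
    all(m >= 0) && all(m <= 1)
}

.assert_gray <- function(m, what = "gray image") {
  if (!.is_gray(m))
    .stop_validation(what, " must be a numeric matrix with values in [0, 1]")
  invisible(m)
}

.assert_mask <- function(m) {
  .assert_gray(m, "binary mask")
  if (!all(m %in% c(0, 1)))
    .stop_validation("binary mask may contain only the values 0 and 1")
  invisible(m)
}

#' Read a TIFF or PNG image
#'
#' Reads an 8- or 16-bit TIFF, or an 8-bit PNG, into a [multichannel_image()].
#' Integer sample values are divided by the maximum representable value of
#' their bit depth (255 or 65535), so all intensities land on \[0, 1\].
#'
#' @details A single-plane grayscale file yields `C = 1`; an RGB file yields
#'   `channel_names = c("red", "green", "blue")` in file order. Alpha
#'   channels are dropped. Palette/indexed PNG is expanded to RGB by the
#'   reader. The pipelines consume RGB input; the single-channel path exists
#'   for round-tripping intermediate images.
#'
#' @param path Path to an existing `.tif`/`.tiff` or `.png` file.
#' @return A [multichannel_image()].
#' @export
read_image <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    .stop_validation("'path' must be a single file path")
  if (!file.exists(path))
    stop("cannot read image: no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  px <- tryCatch({
    if (ext %in% c("tif", "tiff")) {
      tiff::readTIFF(path, all = TRUE)
    } else if (ext == "png") {
      png::readPNG(path)
    } else {
      stop("unsupported image format '", ext, "' (use TIFF or PNG)")
    }
  }, error = function(e) {
    stop("cannot read image '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (is.list(px)) {
    if (length(px) > 1L)
      stop("unsupported format: '", path,
           "' holds more than one plane (z-stack or time series)",
           call. = FALSE)
    px <- px[[1L]]
  }
  if (is.array(px) && length(dim(px)) > 3L)
    stop("unsupported format: '", path,
         "' has more than 2 spatial dimensions", call. = FALSE)
  if (is.matrix(px)) {
    return(multichannel_image(px, "red", source_path = path))
  }
  nchan <- dim(px)[3L]
  if (nchan == 2L) {         # gray + alpha
    px <- px[, , 1L, drop = FALSE]
    return(multichannel_image(px, "red", source_path = path))
  }
  if (nchan >= 4L) px <- px[, , 1:3, drop = FALSE]  # drop alpha
  if (dim(px)[3L] == 1L)
    return(multichannel_image(px, "red", source_path = path))
  multichannel_image(px, c("red", "green", "blue"), source_path = path)
}

#' Write an image to TIFF or PNG
#'
#' Accepts a [multichannel_image()], a gray matrix or a binary mask. TIFF
#' output is written at 16 bits per sample (so a read/write round trip
#' preserves intensities to within one 16-bit quantization step,
#' `1/65535`); PNG output is 8-bit.
#'
#' @param img A `mh_image`, or a numeric matrix on \[0, 1\].
#' @param path Output path ending in `.tif`, `.tiff` or `.png`; the parent
#'   directory must exist.
#' @return Invisibly, `path`.
#' @export
write_image <- function(img, path) {
  px <- if (inherits(img, "mh_image")) {
    if (dim(img$pixels)[3L] == 1L) img$pixels[, , 1L] else img$pixels
  } else {
    .assert_gray(img)
    img
  }
  if (!dir.exists(dirname(path)))
    stop("cannot write image: directory does not exist: ", dirname(path),
         call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  ok <- tryCatch({
    if (ext %in% c("tif", "tiff")) {
      tiff::writeTIFF(px, path, bits.per.sample = 16L)
    } else if (ext == "png") {
      png::writePNG(px, path)
    } else {
      stop("unsupported output format '", ext, "'")
    }
    TRUE
  }, error = function(e) {
    stop("cannot write image '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(path)
}

# per-assay CSV schemas (the per-object size table of the regeneration assay
# is written separately by run_batch)
.assay_csv_columns <- function(assay) {
  switch(assay,
    ebd = c("image_id", "total_cells", "not_ebd_cells", "ebd_pos_cells",
            "pct_ebd_pos", "warnings"),
    emyhc = c("image_id", "total_cells", "emyhc_pos_cells",
              "pct_emyhc_pos", "warnings"),
    cd68 = ,
    collagen = c("image_id", "foreground_pixels", "total_pixels",
                 "pct_area", "warnings"),
    .stop_validation("unknown assay '", assay, "'"))
}

.fmt_num <- function(x) {
  if (is.null(x) || length(x) == 0L || is.na(x)) return("")
  format(x, scientific = FALSE, trim = TRUE)
}

.result_csv_row <- function(r) {
  w <- paste(r$warnings, collapse = "; ")
  switch(r$assay,
    ebd = c(r$image_id, .fmt_num(r$counts$total_cells),
            .fmt_num(r$counts$not_ebd_cells),
            .fmt_num(r$counts$ebd_pos_cells),
            .fmt_num(r$percent$pct_ebd_pos), w),
    emyhc = c(r$image_id, .fmt_num(r$counts$total_cells),
              .fmt_num(r$counts$emyhc_pos_cells),
              .fmt_num(r$percent$pct_emyhc_pos), w),
    cd68 = ,
    collagen = c(r$image_id, .fmt_num(r$counts$foreground_pixels),
                 .fmt_num(r$counts$total_pixels),
                 .fmt_num(r$percent$pct_area), w))
}

#' Write assay results to a comma-delimited file
#'
#' One header row plus one row per image. Columns depend on the assay:
#' membrane-damage counts for `ebd`, regeneration counts for `emyhc`, and
#' pixel/percent-area columns for `cd68` and `collagen`. Numeric fields are
#' rendered in plain decimal notation.
#'
#' @param results A list of `assay_result` objects, all from the same assay.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_results_csv <- function(results, path) {
  if (inherits(results, "assay_result")) results <- list(results)
  if (!is.list(results) ||
      !all(vapply(results, inherits, logical(1L), "assay_result")))
    .stop_validation("'results' must be a list of assay_result objects")
  assays <- unique(vapply(results, `[[`, character(1L), "assay"))
  if (length(assays) > 1L)
    .stop_validation("all results must come from the same assay; got: ",
                     paste(assays, collapse = ", "))
  assay <- if (length(assays) == 1L) assays else "cd68"
  cols <- .assay_csv_columns(assay)
  con <- file(path, open = "wb")  # binary mode: byte-identical across runs
  on.exit(close(con))
  lines <- c(paste(cols, collapse = ","),
             vapply(results, function(r)
               paste(.result_csv_row(r), collapse = ","), character(1L)))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
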