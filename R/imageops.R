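# Pointwise image arithmetic and channel operations. All operations are
# shape-preserving and keep intensities on [0,1].

#' Invert an image
#'
#' Every intensity `x` becomes `1 - x`, per channel. Fluorescence images are
#' inverted before fiber identification so that objects delineated by bright
#' laminin boundaries appear lighter than the boundary network.
#'
#' @param img A [multichannel_image()] or a gray matrix on \[0, 1\].
#' @return The same type as the input.
#' @export
invert <- function(img) {
  if (inherits(img, "mh_image")) {
    img$pixels <- 1 - img$pixels
    return(img)
  }
  .assert_gray(img)
  1 - img
}

#' Raise pixel intensities to a power
#'
#' With the default exponent 2 this squares every intensity, darkening gray
#' pixels while leaving values near 1 close to 1 -- the masking step used to
#' suppress dye-filled fibers before the damage-free fiber count.
#' The transform is monotone, so pixel ordering is preserved.
#'
#' @param img Gray matrix on \[0, 1\].
#' @param exponent Positive real; default 2.
#' @return Gray matrix.
#' @export
power_transform <- function(img, exponent = 2) {
  .assert_gray(img)
  if (!.is_number(exponent) || exponent <= 0)
    .stop_validation("'exponent' must be a positive number")
  img^exponent
}

#' Combine channels into a grayscale image
#'
#' Weighted mean of the selected channel planes; weights are normalized to
#' sum to 1 (default: equal), so the result cannot leave \[0, 1\].
#'
#' @param img A [multichannel_image()].
#' @param channels Character vector of channel names to combine.
#' @param weights Optional positive weights, one per selected channel.
#' @return Gray matrix.
#' @export
combine_to_gray <- function(img, channels, weights = NULL) {
  if (!inherits(img, "mh_image"))
    .stop_validation("'img' must be a multichannel image")
  channels <- as.character(channels)
  if (length(channels) < 1L)
    .stop_validation("at least one channel must be selected")
  miss <- setdiff(channels, img$channel_names)
  if (length(miss) > 0L)
    .stop_validation("unknown channel name(s): ", paste(miss, collapse = ", "))
  if (is.null(weights)) weights <- rep(1, length(channels))
  if (length(weights) != length(channels) || any(weights <= 0))
    .stop_validation("'weights' must be positive, one per selected channel")
  weights <- weights / sum(weights)
  out <- matrix(0, dim(img$pixels)[1L], dim(img$pixels)[2L])
  for (i in seq_along(channels)) {
    k <- match(channels[i], img$channel_names)
    out <- out + weights[i] * img$pixels[, , k]
  }
  pmin(pmax(out, 0), 1)
}

#' Split an image into per-channel grayscale planes
#'
#' @param img A [multichannel_image()].
#' @return Named list of gray matrices, one per channel, in channel order.
#' @export
split_channels <- function(img) {
  if (!inherits(img, "mh_image"))
    .stop_validation("'img' must be a multichannel image")
  out <- lapply(seq_along(img$channel_names),
                function(k) img$pixels[, , k])
  names(out) <- img$channel_names
  out
}
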