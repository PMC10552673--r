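# Automatic global threshold selection. Two selectors are provided:
#
# * robust background: trim the brightest and dimmest pixel fractions, model
#   the retained pixels as Gaussian background, threshold at mean + N sd;
# * minimum cross entropy: exhaustive search over histogram bin edges for
#   the threshold minimizing Li's cross-entropy objective between each class
#   and its mean.
#
# Both clamp the result to configurable [lower_bound, upper_bound] -- the
# practical fix when an automatic threshold fails on an atypical frame.

#' Threshold selection configuration
#'
#' @param method One of `"robust_background"`, `"min_cross_entropy"`,
#'   `"manual"`.
#' @param n_sd The N in mean + N standard deviations for the robust
#'   background method (default 2; larger is more stringent).
#' @param trim_low,trim_high Fractions of the dimmest / brightest pixels to
#'   discard before the background statistics are computed (defaults 0.05
#'   each); each must lie in \[0, 0.5) and their sum below 1.
#' @param lower_bound,upper_bound Clamp applied to the selected threshold,
#'   both in \[0, 1\]. Defaults 0 and 1 (no clamping).
#' @param manual_value Fixed threshold, required iff `method = "manual"`.
#' @param bins Histogram bin count for minimum cross entropy (default 256);
#'   candidate thresholds are the interior bin edges `k/bins`.
#' @param apply_smooth_sigma Optional Gaussian sigma (pixels) applied to the
#'   image before the threshold is *applied* (never before it is computed);
#'   default 0 (off).
#' @return An object of class `threshold_config`.
#' @export
threshold_config <- function(method = c("robust_background",
                                        "min_cross_entropy", "manual"),
                             n_sd = 2, trim_low = 0.05, trim_high = 0.05,
                             lower_bound = 0, upper_bound = 1,
                             manual_value = NULL, bins = 256L,
                             apply_smooth_sigma = 0) {
  method <- match.arg(method)
  for (v in c(trim_low, trim_high))
    if (!.is_number(v) || v < 0 || v >= 0.5)
      .stop_validation("trim fractions must lie in [0, 0.5)")
  if (trim_low + trim_high >= 1)
    .stop_validation("trim_low + trim_high must be < 1")
  if (!.is_number(lower_bound) || !.is_number(upper_bound) ||
      lower_bound < 0 || upper_bound > 1 || lower_bound > upper_bound)
    .stop_validation("bounds must satisfy 0 <= lower_bound <= upper_bound <= 1")
  if (!.is_number(n_sd))
    .stop_validation("'n_sd' must be a number")
  if (method == "manual") {
    if (!.is_number(manual_value) || manual_value < 0 || manual_value > 1)
      .stop_validation("'manual_value' in [0,1] is required for manual method")
  } else if (!is.null(manual_value)) {
    .stop_validation("'manual_value' is only allowed with method = 'manual'")
  }
  bins <- as.integer(bins)
  if (is.na(bins) || bins < 2L)
    .stop_validation("'bins' must be a positive integer >= 2")
  if (!.is_number(apply_smooth_sigma) || apply_smooth_sigma < 0)
    .stop_validation("'apply_smooth_sigma' must be >= 0")
  structure(list(method = method, n_sd = n_sd, trim_low = trim_low,
                 trim_high = trim_high, lower_bound = lower_bound,
                 upper_bound = upper_bound, manual_value = manual_value,
                 bins = bins, apply_smooth_sigma = apply_smooth_sigma),
            class = "threshold_config")
}

.clamp <- function(x, lo, hi) min(max(x, lo), hi)

#' Robust background threshold
#'
#' Sorts all pixel intensities, discards the lowest `trim_low` and highest
#' `trim_high` fractions (`floor(fraction * n)` pixels each side), computes
#' the mean and population standard deviation of the retained pixels, and
#' returns `mean + n_sd * sd` clamped to the configured bounds. The upper
#' trim doubles as the foreground-removal step: after trimming, the retained
#' distribution is treated as approximately Gaussian background.
#'
#' @param gray Gray matrix with at least 3 pixels.
#' @param cfg A [threshold_config()] with `method = "robust_background"`.
#' @return Threshold in `[lower_bound, upper_bound]`.
#' @export
robust_background_threshold <- function(gray, cfg = threshold_config()) {
  .assert_gray(gray)
  if (!inherits(cfg, "threshold_config") || cfg$method != "robust_background")
    .stop_validation("cfg must be a threshold_config with method 'robust_background'")
  x <- sort(as.vector(gray))
  n <- length(x)
  if (n < 3L) .stop_validation("image must have at least 3 pixels")
  k_lo <- floor(cfg$trim_low * n)
  k_hi <- floor(cfg$trim_high * n)
  if (k_lo + k_hi >= n)
    .stop_validation("trims remove all pixels")
  kept <- x[(k_lo + 1L):(n - k_hi)]
  mu <- mean(kept)
  sigma <- sqrt(mean((kept - mu)^2))   # population sd
  .clamp(mu + cfg$n_sd * sigma, cfg$lower_bound, cfg$upper_bound)
}

#' Minimum cross-entropy threshold
#'
#' Evaluates Li's cross-entropy objective at every interior histogram bin
#' edge `t = k/bins`: pixels with intensity `< t` form the background with
#' mean `mu0`, pixels `>= t` the foreground with mean `mu1`, and
#' `eta(t) = -sum_bg x log(mu0) - sum_fg x log(mu1)` (zero-intensity pixels
#' contribute nothing). The edge minimizing `eta` is returned, clamped to
#' the configured bounds; ties break toward the smallest threshold, and
#' candidates with an empty class are skipped. An image with fewer than two
#' distinct values returns its single value, clamped.
#'
#' @param gray Gray matrix.
#' @param cfg A [threshold_config()] with `method = "min_cross_entropy"`.
#' @return Threshold in `[lower_bound, upper_bound]`.
#' @export
min_cross_entropy_threshold <- function(gray,
    cfg = threshold_config("min_cross_entropy")) {
  .assert_gray(gray)
  if (!inherits(cfg, "threshold_config") || cfg$method != "min_cross_entropy")
    .stop_validation("cfg must be a threshold_config with method 'min_cross_entropy'")
  xs <- sort(as.vector(gray))
  n <- length(xs)
  if (xs[1L] == xs[n])
    return(.clamp(xs[1L], cfg$lower_bound, cfg$upper_bound))
  cs <- cumsum(xs)
  total <- cs[n]
  edges <- seq_len(cfg$bins - 1L) / cfg$bins
  # background = strictly below the candidate edge
  n0 <- findInterval(edges, xs, left.open = TRUE)
  best_t <- NA_real_
  best_eta <- Inf
  for (i in seq_along(edges)) {
    k <- n0[i]
    if (k == 0L || k == n) next            # empty class: skip
    s0 <- cs[k]; s1 <- total - s0
    term0 <- if (s0 > 0) s0 * log(s0 / k) else 0
    term1 <- if (s1 > 0) s1 * log(s1 / (n - k)) else 0
    eta <- -(term0 + term1)
    if (eta < best_eta) {                  # strict: ties keep the smaller t
      best_eta <- eta
      best_t <- edges[i]
    }
  }
  if (is.na(best_t)) {
    # all candidates had an empty class (data squeezed inside one bin edge
    # interval); fall back to the midpoint between the two value groups
    best_t <- mean(range(xs))
  }
  .clamp(best_t, cfg$lower_bound, cfg$upper_bound)
}

#' Compute a threshold according to a configuration
#'
#' Dispatches to [robust_background_threshold()],
#' [min_cross_entropy_threshold()] or the manual value (clamped).
#'
#' @param gray Gray matrix.
#' @param cfg A [threshold_config()].
#' @return Threshold in `[lower_bound, upper_bound]`.
#' @export
compute_threshold <- function(gray, cfg) {
  if (!inherits(cfg, "threshold_config"))
    .stop_validation("'cfg' must be a threshold_config")
  switch(cfg$method,
    robust_background = robust_background_threshold(gray, cfg),
    min_cross_entropy = min_cross_entropy_threshold(gray, cfg),
    manual = .clamp(cfg$manual_value, cfg$lower_bound, cfg$upper_bound))
}

#' Apply a threshold to a gray image
#'
#' Foreground is closed on the bright side: mask pixel = 1 where intensity
#' `>= threshold`, else 0.
#'
#' @param gray Gray matrix.
#' @param threshold Number in \[0, 1\].
#' @return Binary mask matrix of the same shape.
#' @export
apply_threshold <- function(gray, threshold) {
  .assert_gray(gray)
  if (!.is_number(threshold) || threshold < 0 || threshold > 1)
    .stop_validation("'threshold' must be a number in [0, 1]")
  (gray >= threshold) * 1
}
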