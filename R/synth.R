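# Synthetic muscle cross-section generator. Produces tessellated polygonal
# fibers (jittered-lattice Voronoi regions) outlined by a laminin boundary
# network, optional marker-positive fiber interiors, macrophage-like
# aggregate blobs, and interstitial collagen -- together with exact ground
# truth for every assay. The original mouse microscopy images behind the
# method are unpublished; these scenes stand in for them in all validation.

# run code under a private, explicitly seeded random stream, restoring any
# global state afterwards
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

#' Synthetic scene parameters
#'
#' Defaults emulate the study conditions the pipelines were built for:
#' 400 x 400 px frames with 100 fibers give mean fiber diameters of about
#' 45 px (in the 30--80 px range typical of cross-sections imaged at this
#' scale), a 3 px laminin boundary, mild optics blur (sigma 1) and additive
#' Gaussian noise (sd 0.01).
#'
#' @param height,width Frame size in pixels.
#' @param n_fibers Number of fibers placed in the frame.
#' @param fiber_jitter Centroid perturbation as a fraction of the lattice
#'   spacing (uniform on `+/- fiber_jitter * spacing / 2`).
#' @param boundary_width Laminin ring thickness in pixels (default 3).
#' @param marker_fraction Fraction of fibers that are marker-positive;
#'   `ceiling(marker_fraction * n_fibers)` fibers are flagged.
#' @param marker_size_bias `"none"` (uniform draw) or `"small"` (positive
#'   fibers drawn from the small end of the size range, matching the
#'   observation that regenerating fibers are relatively small).
#' @param aggregate_count,aggregate_radius Number and nominal radius (px)
#'   of macrophage-like aggregate blobs painted into the marker mask.
#' @param collagen_fraction Target fraction of the frame covered by
#'   interstitial collagen (grown outward from the boundary network).
#' @param noise_sd Additive Gaussian noise sigma in intensity units
#'   (default 0.01).
#' @param blur_sigma Gaussian optics blur in pixels (default 1).
#' @param seed Integer seed; fully determines the scene.
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(height = 400L, width = 400L, n_fibers = 100L,
                         fiber_jitter = 0.45, boundary_width = 3,
                         marker_fraction = 0,
                         marker_size_bias = c("none", "small"),
                         aggregate_count = 0L, aggregate_radius = 15,
                         collagen_fraction = 0,
                         noise_sd = 0.01, blur_sigma = 1, seed = 1L) {
  marker_size_bias <- match.arg(marker_size_bias)
  for (v in list(height, width, n_fibers))
    if (!.is_number(v) || v < 1) .stop_validation("sizes must be positive")
  for (v in list(marker_fraction, collagen_fraction))
    if (!.is_number(v) || v < 0 || v > 1)
      .stop_validation("fractions must lie in [0, 1]")
  if (!.is_number(boundary_width) || boundary_width <= 0)
    .stop_validation("'boundary_width' must be > 0")
  if (!.is_number(noise_sd) || noise_sd < 0 ||
      !.is_number(blur_sigma) || blur_sigma < 0)
    .stop_validation("'noise_sd' and 'blur_sigma' must be >= 0")
  if (!.is_number(aggregate_count) || aggregate_count < 0 ||
      !.is_number(aggregate_radius) || aggregate_radius <= 0)
    .stop_validation("aggregate parameters must be non-negative")
  mean_diam <- 2 * sqrt(height * width / n_fibers / pi)
  if (mean_diam < 4 * boundary_width)
    .stop_validation("n_fibers too large for the frame: mean fiber ",
                     "diameter ", round(mean_diam, 1),
                     " px < 4 * boundary_width")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_fibers = as.integer(n_fibers),
                 fiber_jitter = fiber_jitter,
                 boundary_width = boundary_width,
                 marker_fraction = marker_fraction,
                 marker_size_bias = marker_size_bias,
                 aggregate_count = as.integer(aggregate_count),
                 aggregate_radius = aggregate_radius,
                 collagen_fraction = collagen_fraction,
                 noise_sd = noise_sd, blur_sigma = blur_sigma,
                 seed = as.integer(seed)),
            class = "scene_params")
}

# nearest-point partition of the frame (squared Euclidean distance),
# iterating over points with vectorized updates
.voronoi_labels <- function(h, w, py, px) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  best_d <- matrix(Inf, h, w)
  lab <- matrix(0L, h, w)
  for (i in seq_along(py)) {
    d <- (rows - py[i])^2 + (cols - px[i])^2
    upd <- d < best_d
    best_d[upd] <- d[upd]
    lab[upd] <- i
  }
  lab
}

# distance of every pixel to the nearest pixel of `set` (logical matrix)
.dist_to_set <- function(set) {
  if (!any(set)) return(matrix(Inf, nrow(set), ncol(set)))
  .mat(EBImage::distmap((!set) * 1))
}

#' Generate a synthetic muscle cross-section with ground truth
#'
#' Places `n_fibers` jittered lattice points, partitions the frame into
#' their nearest-point (Voronoi) regions, and erodes each region by the
#' boundary width to produce convex fiber interiors separated by a laminin
#' boundary network. Marker-positive fibers, aggregate blobs and an
#' interstitial collagen mask are drawn as configured. Everything is
#' deterministic given `params$seed`.
#'
#' @param params A [scene_params()].
#' @return An object of class `scene_truth` with fields
#'   `fiber_label_map` ([label_map()] of true interiors), `marker_flags`,
#'   `fiber_areas`, `boundary_mask`, `marker_pixel_mask` (aggregates),
#'   `collagen_mask`, `params` and `summary` (true counts and percents,
#'   recomputable from the masks).
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  .with_seed(params$seed, {
    h <- params$height; w <- params$width; n <- params$n_fibers
    nc <- max(1L, as.integer(ceiling(sqrt(n * w / h))))
    nr <- as.integer(ceiling(n / nc))
    sy <- h / nr; sx <- w / nc
    centers <- expand.grid(r = seq_len(nr), c = seq_len(nc))
    cy <- (centers$r - 0.5) * sy
    cx <- (centers$c - 0.5) * sx
    pick <- if (nr * nc > n) sort(sample.int(nr * nc, n)) else seq_len(n)
    jy <- runif(n, -1, 1) * params$fiber_jitter * sy / 2
    jx <- runif(n, -1, 1) * params$fiber_jitter * sx / 2
    py <- pmin(pmax(cy[pick] + jy, 1), h)
    px <- pmin(pmax(cx[pick] + jx, 1), w)
    vor <- .voronoi_labels(h, w, py, px)
    # inter-cell boundary lines (pixels whose 4-neighbor carries another label)
    line <- matrix(FALSE, h, w)
    line[-h, ] <- line[-h, ] | (vor[-h, ] != vor[-1L, ])
    line[-1L, ] <- line[-1L, ] | (vor[-1L, ] != vor[-h, ])
    line[, -w] <- line[, -w] | (vor[, -w] != vor[, -1L])
    line[, -1L] <- line[, -1L] | (vor[, -1L] != vor[, -w])
    d_line <- .dist_to_set(line)
    interior <- d_line > params$boundary_width / 2
    lab <- vor
    lab[!interior] <- 0L
    areas <- tabulate(lab[lab > 0L], nbins = n)
    if (any(areas == 0L))
      .stop_validation("scene degenerate: a fiber interior vanished; ",
                       "reduce n_fibers or boundary_width")
    flags <- rep(FALSE, n)
    k <- as.integer(ceiling(round(params$marker_fraction * n, 9)))
    if (k > 0L) {
      if (params$marker_size_bias == "small") {
        pool_size <- max(k, ceiling(n / 3))
        pool <- order(areas)[seq_len(pool_size)]
        flags[sample(pool, k)] <- TRUE
      } else {
        flags[sample.int(n, k)] <- TRUE
      }
    }
    agg <- matrix(FALSE, h, w)
    if (params$aggregate_count > 0L) {
      rows <- matrix(seq_len(h), h, w)
      cols <- matrix(seq_len(w), h, w, byrow = TRUE)
      r0 <- params$aggregate_radius
      for (i in seq_len(params$aggregate_count)) {
        ay <- runif(1, 1.5 * r0, h - 1.5 * r0)
        ax <- runif(1, 1.5 * r0, w - 1.5 * r0)
        # irregular blob: one main disk plus satellite disks on its rim
        rmain <- r0 * runif(1, 0.9, 1.1)
        agg <- agg | ((rows - ay)^2 + (cols - ax)^2 <= rmain^2)
        for (s in seq_len(3L)) {
          ang <- runif(1, 0, 2 * pi)
          rs <- rmain * runif(1, 0.4, 0.6)
          sy2 <- ay + 0.8 * rmain * sin(ang)
          sx2 <- ax + 0.8 * rmain * cos(ang)
          agg <- agg | ((rows - sy2)^2 + (cols - sx2)^2 <= rs^2)
        }
      }
    }
    collagen <- matrix(FALSE, h, w)
    if (params$collagen_fraction > 0) {
      target <- ceiling(params$collagen_fraction * h * w)
      # grow outward from the boundary network: take the `target` pixels
      # closest to an inter-fiber line (ties broken by pixel order)
      ord <- order(d_line, seq_along(d_line))
      collagen[ord[seq_len(target)]] <- TRUE
    }
    flm <- label_map(lab)
    truth <- structure(list(
      params = params,
      fiber_label_map = flm,
      marker_flags = flags,
      fiber_areas = areas,
      boundary_mask = (!interior) * 1,
      marker_pixel_mask = agg * 1,
      collagen_mask = collagen * 1,
      summary = list(
        n_fibers = n,
        n_marker_pos = sum(flags),
        pct_marker_pos = 100 * sum(flags) / n,
        pct_aggregate_area = 100 * sum(agg) / (h * w),
        pct_collagen_area = 100 * sum(collagen) / (h * w))),
      class = "scene_truth")
    truth
  })
}

#' @export
print.scene_truth <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<scene_truth> %d x %d, %d fibers ",
                     "(%d marker+), aggregates %.2f%%, collagen %.2f%%\n"),
              x$params$height, x$params$width, s$n_fibers, s$n_marker_pos,
              s$pct_aggregate_area, s$pct_collagen_area))
  invisible(x)
}

.finish_channel <- function(m, blur_sigma, noise_sd) {
  if (blur_sigma > 0) m <- .gblur_replicate(m, blur_sigma)
  if (noise_sd > 0) m <- m + rnorm(length(m), 0, noise_sd)
  pmin(pmax(m, 0), 1)
}

#' Render a fluorescence image from a synthetic scene
#'
#' The laminin channel shows the boundary network at intensity 0.8 over
#' dark (0.05) interiors; the marker channel shows marker-positive fiber
#' interiors (`ebd`, `emyhc`) or aggregate blobs (`cd68`) at per-object
#' intensities drawn from 0.7--0.9 over a 0.02 background. Channel-role
#' placement follows each assay's staining convention: the damage assay
#' puts laminin in green and dye in red; the regeneration and inflammation
#' assays put laminin in red and the marker in green. Gaussian blur and
#' additive noise are applied per channel, then clipped to \[0, 1\].
#'
#' @param truth A [generate_scene()] result.
#' @param assay One of `"ebd"`, `"emyhc"`, `"cd68"`.
#' @param params Scene parameters (defaults to `truth$params`).
#' @return A [multichannel_image()] with channels red, green, blue.
#' @export
render_fluorescence <- function(truth, assay = c("ebd", "emyhc", "cd68"),
                                params = truth$params) {
  stopifnot(inherits(truth, "scene_truth"))
  assay <- match.arg(assay)
  if (assay == "cd68" && params$aggregate_count > 0L &&
      sum(truth$marker_pixel_mask) == 0)
    .stop_validation("truth carries no aggregate mask for the cd68 assay")
  .with_seed(params$seed + 1000003L, {
    h <- params$height; w <- params$width
    lam <- matrix(0.05, h, w)
    lam[truth$boundary_mask == 1] <- 0.8
    mark <- matrix(0.02, h, w)
    if (assay %in% c("ebd", "emyhc")) {
      lab <- truth$fiber_label_map$labels
      lev <- runif(truth$summary$n_fibers, 0.7, 0.9)
      pos <- which(truth$marker_flags)
      sel <- lab > 0L & truth$marker_flags[ifelse(lab == 0L, 1L, lab)]
      mark[sel] <- lev[lab[sel]]
    } else {
      mark[truth$marker_pixel_mask == 1] <- runif(1, 0.7, 0.9)
    }
    lam <- .finish_channel(lam, params$blur_sigma, params$noise_sd)
    mark <- .finish_channel(mark, params$blur_sigma, params$noise_sd)
    blue <- .finish_channel(matrix(0.02, h, w),
                            params$blur_sigma, params$noise_sd)
    px <- array(0, c(h, w, 3L))
    if (assay == "ebd") {
      px[, , 1L] <- mark; px[, , 2L] <- lam   # dye red, laminin green
    } else {
      px[, , 1L] <- lam; px[, , 2L] <- mark   # laminin red, marker green
    }
    px[, , 3L] <- blue
    multichannel_image(px, c("red", "green", "blue"))
  })
}

#' Render a Picrosirius-red brightfield image from a synthetic scene
#'
#' Collagen pixels are rendered red-dominant (R 0.75, G 0.15, B 0.20) and
#' muscle pale (R 0.85, G 0.70, B 0.55), so the green plane is dark over
#' collagen -- the contrast the collagen pipeline inverts and segments.
#'
#' @param truth A [generate_scene()] result whose `collagen_mask` was drawn
#'   (i.e. `collagen_fraction > 0`, or an explicitly empty mask).
#' @param params Scene parameters (defaults to `truth$params`).
#' @return A [multichannel_image()] with channels red, green, blue.
#' @export
render_brightfield_collagen <- function(truth, params = truth$params) {
  stopifnot(inherits(truth, "scene_truth"))
  .with_seed(params$seed + 2000003L, {
    h <- params$height; w <- params$width
    cm <- truth$collagen_mask == 1
    red <- matrix(0.85, h, w); red[cm] <- 0.75
    grn <- matrix(0.70, h, w); grn[cm] <- 0.15
    blu <- matrix(0.55, h, w); blu[cm] <- 0.20
    px <- array(0, c(h, w, 3L))
    px[, , 1L] <- .finish_channel(red, params$blur_sigma, params$noise_sd)
    px[, , 2L] <- .finish_channel(grn, params$blur_sigma, params$noise_sd)
    px[, , 3L] <- .finish_channel(blu, params$blur_sigma, params$noise_sd)
    multichannel_image(px, c("red", "green", "blue"))
  })
}
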