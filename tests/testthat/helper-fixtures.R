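# Programmatic fixtures shared across test files.

# gray frame with filled disks (centers as rows of (r, c), one radius each)
disk_image <- function(h = 100, w = 100, centers, radius,
                       fg = 0.9, bg = 0.05) {
  m <- matrix(bg, h, w)
  rr <- row(m); cc <- col(m)
  centers <- matrix(centers, ncol = 2L)
  radius <- rep_len(radius, nrow(centers))
  for (i in seq_len(nrow(centers)))
    m[(rr - centers[i, 1L])^2 + (cc - centers[i, 2L])^2 <= radius[i]^2] <- fg
  m
}

two_disjoint_disks <- function() disk_image(centers = rbind(c(30, 30), c(70, 70)), radius = 10)

two_overlapping_disks <- function() disk_image(centers = rbind(c(50, 43), c(50, 58)), radius = 10)

# random two-component Gaussian-mixture test image for threshold oracles
mixture_image <- function(n = 64, p = 0.3, mu = c(0.2, 0.7), sd = 0.08) {
  z <- runif(n * n) < p
  x <- ifelse(z, rnorm(n * n, mu[2L], sd), rnorm(n * n, mu[1L], sd))
  matrix(pmin(pmax(x, 0), 1), n, n)
}

# small clean scene for fast end-to-end checks
quick_scene <- function(seed = 1, ...) {
  generate_scene(scene_params(noise_sd = 0, blur_sigma = 0, seed = seed, ...))
}
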