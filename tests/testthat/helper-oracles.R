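# Independent oracles, deliberately naive: direct sorted-list trimmed
# statistics and an exhaustive double-loop cross-entropy search. These stay
# independent of the package's internal code paths.

oracle_robust_background <- function(x, trim_low = 0.05, trim_high = 0.05,
                                     n_sd = 2, lower = 0, upper = 1) {
  s <- sort(as.vector(x))
  n <- length(s)
  drop_lo <- floor(trim_low * n)
  drop_hi <- floor(trim_high * n)
  kept <- s[seq(drop_lo + 1L, n - drop_hi)]
  mu <- sum(kept) / length(kept)
  sigma <- sqrt(sum((kept - mu)^2) / length(kept))
  min(max(mu + n_sd * sigma, lower), upper)
}

oracle_min_cross_entropy <- function(x, bins = 256L) {
  x <- as.vector(x)
  best_eta <- Inf
  best_t <- NA_real_
  for (k in seq_len(bins - 1L)) {
    t <- k / bins
    bg <- x[x < t]
    fg <- x[x >= t]
    if (length(bg) == 0L || length(fg) == 0L) next
    term0 <- if (sum(bg) > 0) sum(bg) * log(mean(bg)) else 0
    term1 <- if (sum(fg) > 0) sum(fg) * log(mean(fg)) else 0
    eta <- -(term0 + term1)
    if (eta < best_eta) {
      best_eta <- eta
      best_t <- t
    }
  }
  best_t
}
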