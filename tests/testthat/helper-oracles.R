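# Independent oracles used across the suite. These deliberately avoid the
# package's fitting/summary code paths.

# Dense grid-search oracle for a two-Gaussian fit with shared width:
# midpoints on a `res`-spaced grid over the support, widths over
# `width_grid`; heights by exact 2x2 linear least squares at each candidate.
grid_two_peak_oracle <- function(x, y, res = 0.1,
                                 width_grid = seq(0.5, 6, by = 0.1)) {
  mids <- seq(min(x), max(x), by = res)
  nm <- length(mids)
  best <- list(rss = Inf)
  yy <- sum(y^2)
  for (w in width_grid) {
    B <- vapply(mids, function(m) exp(-(x - m)^2 / (2 * w^2)),
                numeric(length(x)))
    G <- crossprod(B)
    cvec <- drop(crossprod(B, y))
    D1 <- matrix(diag(G), nm, nm)
    D2 <- t(D1)
    C1 <- matrix(cvec, nm, nm)
    C2 <- t(C1)
    det <- D1 * D2 - G^2
    h1 <- (D2 * C1 - G * C2) / det
    h2 <- (D1 * C2 - G * C1) / det
    rss <- yy - 2 * (h1 * C1 + h2 * C2) +
      h1^2 * D1 + 2 * h1 * h2 * G + h2^2 * D2
    bad <- det < 1e-12 | h1 < 0 | h2 < 0 | !upper.tri(det)
    rss[bad] <- Inf
    k <- which.min(rss)
    if (rss[k] < best$rss) {
      i <- (k - 1) %% nm + 1
      j <- (k - 1) %/% nm + 1
      best <- list(rss = rss[k], mid = sort(c(mids[i], mids[j])), width = w)
    }
  }
  best
}

# Sort-based percentile oracle: expand a frequency vector into a large
# sample and take the nearest-rank order statistic directly.
sort_quantile_oracle <- function(keys, freq, p, n_expand = 20000) {
  counts <- round(freq / sum(freq) * n_expand)
  sample_vec <- rep(keys, counts)
  sample_vec <- sort(sample_vec)
  idx <- pmax(1, ceiling(p / 100 * length(sample_vec)))
  sample_vec[idx]
}

# Brute-force rotarod oracle: loops over days and attempts.
brute_rotarod_oracle <- function(records, speed) {
  rec <- records[records$speed_rpm == speed, ]
  out <- c()
  for (id in sort(unique(rec$animal_id))) {
    r <- rec[rec$animal_id == id, ]
    bests <- c()
    for (d in sort(unique(r$day))) {
      bests <- c(bests, max(r$time_s[r$day == d]))
    }
    out[id] <- mean(bests)
  }
  out
}

# helper: point-mass somatic_change object for constructed pooling tests
point_change <- function(delta, animal_id = "A", tissue = "STR") {
  structure(
    list(animal_id = animal_id, tissue = tissue,
         frequencies = stats::setNames(1, delta),
         mean_change = delta, n_support = 1L),
    class = "somatic_change"
  )
}

# helper: somatic_change with arbitrary frequencies
make_change <- function(deltas, freqs, animal_id = "A", tissue = "STR") {
  freqs <- freqs / sum(freqs)
  structure(
    list(animal_id = animal_id, tissue = tissue,
         frequencies = stats::setNames(freqs, deltas),
         mean_change = sum(deltas * freqs), n_support = length(deltas)),
    class = "somatic_change"
  )
}

# average two-speed rotarod scores (the full fixed-speed protocol)
pooled_scores <- function(performance) {
  p10 <- summarize_rotarod(performance, 10)
  p20 <- summarize_rotarod(performance, 20)
  data.frame(animal_id = p20$animal_id,
             score = (p10$score + p20$score) / 2,
             grip_passed = p20$grip_passed)
}
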