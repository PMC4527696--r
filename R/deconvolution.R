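# Gaussian allele-peak fitting and inherited-allele normalization.
#
# The inherited allele(s) of an animal are estimated by fitting a Gaussian
# peak-shape model to the birth-reference repeat distribution. Peak position
# and width are the nonlinear parameters; peak height is linear and solved
# by regression at every iterate (a separable / variable-projection least
# squares scheme). Homozygotes are fit with two peaks and classified by the
# overlap of the fitted components; the mathematical resolution of the two
# peaks happens once per animal, on the birth reference.

# design matrix of Gaussian components at positions x
gauss_basis <- function(x, mid, width) {
  vapply(seq_along(mid),
         function(k) exp(-(x - mid[k])^2 / (2 * width[k]^2)),
         numeric(length(x)))
}

# solve heights by linear least squares, clamping negatives to zero
solve_heights <- function(A, y) {
  h <- tryCatch(qr.solve(A, y), error = function(e) rep(0, ncol(A)))
  if (any(h < 0)) {
    for (k in which(h < 0)) {
      h[k] <- 0
      pos <- setdiff(seq_along(h), k)
      if (length(pos)) {
        hp <- tryCatch(qr.solve(A[, pos, drop = FALSE], y),
                       error = function(e) rep(0, length(pos)))
        hp[hp < 0] <- 0
        h[pos] <- hp
      }
    }
  }
  h
}

varpro_rss <- function(theta, x, y, n_peaks, width_min) {
  mid <- theta[seq_len(n_peaks) * 2 - 1]
  width <- pmax(exp(theta[seq_len(n_peaks) * 2]), width_min)
  A <- gauss_basis(x, mid, width)
  h <- solve_heights(A, y)
  sum((y - A %*% h)^2)
}

# initial midpoints: the two highest local maxima separated by at least
# `min_sep` classes (or the single mode, split symmetrically)
init_midpoints <- function(x, y, n_peaks, min_sep = 3) {
  is_max <- vapply(seq_along(y), function(i) {
    left <- if (i > 1) y[i - 1] else -Inf
    right <- if (i < length(y)) y[i + 1] else -Inf
    y[i] >= left && y[i] >= right
  }, logical(1))
  cand <- x[is_max][order(y[is_max], decreasing = TRUE)]
  if (n_peaks == 1L) return(x[which.max(y)])
  picked <- cand[1]
  for (c2 in cand[-1]) {
    if (abs(c2 - picked[1]) >= min_sep) { picked <- c(picked, c2); break }
  }
  if (length(picked) < 2L) {
    picked <- c(picked[1] - 1.5, picked[1] + 1.5)
  }
  sort(picked)
}

#' Fit Gaussian allele peaks to a repeat distribution
#'
#' Separable nonlinear least squares: midpoints and widths are optimized
#' iteratively (bounded quasi-Newton, iteration cap 200, relative RSS
#' convergence 1e-10) while heights are solved by linear regression at each
#' iterate. For two-peak fits the overlap of the components is classified
#' from the fitted separation `s` and mean width `w`: `coincident` if
#' `s < 0.5 w` (refit as a single peak), `separated` if `s > 4 w`, else
#' `partial`. Degenerate widths are bounded below at 0.25 repeats. A
#' distribution with fewer than 3 support points per requested peak is
#' returned as a degenerate point fit rather than an error, so noiseless
#' point-mass references remain usable.
#'
#' @param dist a [repeat_distribution()].
#' @param n_peaks 1 or 2 (number of inherited alleles expected).
#' @param init optional numeric midpoint initialization.
#' @return An object of class `allele_fit`: data.frame with one row per
#'   fitted peak (`midpoint`, `width`, `weight`, `rss`), sorted by midpoint,
#'   with attribute `overlap` in {"single", "coincident", "partial",
#'   "separated"}.
#' @export
fit_allele_peaks <- function(dist, n_peaks = 1L, init = NULL) {
  stopifnot(n_peaks %in% c(1L, 2L))
  x <- as.numeric(names(dist$frequencies))
  y <- as.numeric(dist$frequencies)
  width_min <- 0.25
  if (length(x) < 3L * n_peaks) {
    if (length(x) < 3L && n_peaks == 2L) {
      # cannot resolve two components on <3 points: collapse to one
      return(fit_allele_peaks(dist, 1L, init = init))
    }
    mid <- sum(x * y) / sum(y)
    fit <- data.frame(midpoint = mid, width = width_min, weight = 1,
                      rss = 0)
    class(fit) <- c("allele_fit", "data.frame")
    attr(fit, "overlap") <- "single"
    attr(fit, "converged") <- TRUE
    return(fit)
  }
  mid0 <- if (!is.null(init)) sort(init) else init_midpoints(x, y, n_peaks)
  width0 <- rep(3, n_peaks)
  theta0 <- as.numeric(rbind(mid0, log(width0)))
  lower <- as.numeric(rbind(rep(min(x) - 2, n_peaks), rep(log(width_min), n_peaks)))
  upper <- as.numeric(rbind(rep(max(x) + 2, n_peaks),
                            rep(log(max(diff(range(x)), 4)), n_peaks)))
  opt <- stats::optim(
    theta0, varpro_rss, x = x, y = y, n_peaks = n_peaks,
    width_min = width_min, method = "L-BFGS-B", lower = lower, upper = upper,
    control = list(maxit = 200, factr = 1e-10 / .Machine$double.eps)
  )
  # a second start from a symmetric split guards against merged optima
  if (n_peaks == 2L && is.null(init)) {
    mode <- x[which.max(y)]
    alt0 <- as.numeric(rbind(c(mode - 2, mode + 2), log(c(2, 2))))
    opt2 <- stats::optim(
      alt0, varpro_rss, x = x, y = y, n_peaks = n_peaks,
      width_min = width_min, method = "L-BFGS-B", lower = lower,
      upper = upper,
      control = list(maxit = 200, factr = 1e-10 / .Machine$double.eps)
    )
    if (opt2$value < opt$value) opt <- opt2
  }
  mid <- opt$par[seq_len(n_peaks) * 2 - 1]
  width <- pmax(exp(opt$par[seq_len(n_peaks) * 2]), width_min)
  A <- gauss_basis(x, mid, width)
  h <- solve_heights(A, y)
  rss <- sum((y - A %*% h)^2)
  overlap <- "single"
  if (n_peaks == 2L) {
    s <- abs(diff(mid))
    w <- mean(width)
    if (s < 0.5 * w || min(h) <= 0) {
      single <- fit_allele_peaks(dist, 1L)
      attr(single, "overlap") <- "coincident"
      return(single)
    }
    overlap <- if (s > 4 * w) "separated" else "partial"
  }
  mass <- h * width * sqrt(2 * pi)
  o <- order(mid)
  fit <- data.frame(midpoint = mid[o], width = width[o],
                    weight = (mass / sum(mass))[o], rss = rss)
  class(fit) <- c("allele_fit", "data.frame")
  attr(fit, "overlap") <- overlap
  attr(fit, "converged") <- opt$convergence == 0
  fit
}

#' Normalize an age sample against the inherited allele(s)
#'
#' Maps every repeat class to a signed change relative to the (rounded)
#' fitted inherited midpoint. Heterozygotes (one fitted peak) subtract the
#' single midpoint. For resolved homozygotes the distribution's mass is
#' split equally between the two alleles at the mixture median (the two
#' alleles contribute equal template copies): the lower half of the mass is
#' referenced to the lower midpoint and the upper half to the upper
#' midpoint, with the boundary class divided fractionally. This makes the
#' frequency-weighted mean change equal to `mean(distribution) -
#' mean(midpoints)`, which is unbiased under equal allele weights.
#'
#' @param age_dist a [repeat_distribution()] measured at the age of
#'   interest.
#' @param inherited an `allele_fit` from the birth reference.
#' @param animal_id,tissue identifiers carried into the result.
#' @return An object of class `somatic_change`: list with `animal_id`,
#'   `tissue`, `frequencies` (named by signed integer change), `mean_change`
#'   and `n_support`.
#' @export
normalize_somatic <- function(age_dist, inherited, animal_id = NA_character_,
                              tissue = NA_character_) {
  if (is.null(inherited) || nrow(inherited) == 0L) {
    stop_somex("no inherited reference available",
               class = "somex_missing_reference")
  }
  x <- as.integer(names(age_dist$frequencies))
  f <- as.numeric(age_dist$frequencies)
  mids <- round_half_away(inherited$midpoint)
  if (nrow(inherited) == 1L) {
    delta <- x - mids[1L]
    freq <- f
  } else {
    m_lo <- min(mids); m_hi <- max(mids)
    cdf <- cumsum(f)
    # boundary class: first class where cumulative mass reaches 1/2
    b <- which(cdf >= 0.5)[1L]
    lower_mass <- if (b > 1L) f[seq_len(b - 1L)] else numeric(0)
    frac_lo <- 0.5 - (if (b > 1L) cdf[b - 1L] else 0)
    frac_hi <- f[b] - frac_lo
    delta <- c(if (b > 1L) x[seq_len(b - 1L)] - m_lo else integer(0),
               x[b] - m_lo, x[b] - m_hi,
               if (b < length(x)) x[(b + 1L):length(x)] - m_hi else integer(0))
    freq <- c(lower_mass, frac_lo, frac_hi,
              if (b < length(x)) f[(b + 1L):length(x)] else numeric(0))
    keep <- freq > 0
    delta <- delta[keep]
    freq <- freq[keep]
  }
  agg <- tapply(freq, delta, sum)
  keys <- as.integer(names(agg))
  vals <- as.numeric(agg) / sum(agg)
  o <- order(keys)
  keys <- keys[o]; vals <- vals[o]
  structure(
    list(animal_id = animal_id, tissue = tissue,
         frequencies = stats::setNames(vals, keys),
         mean_change = sum(keys * vals),
         n_support = length(keys)),
    class = "somatic_change"
  )
}

#' @export
print.somatic_change <- function(x, ...) {
  cat(sprintf("somatic change [%s %s]: mean %+.2f repeats over %d classes\n",
              x$animal_id, x$tissue, x$mean_change, x$n_support))
  invisible(x)
}

#' Mean somatic change with its between-animal standard error
#'
#' @param changes list of `somatic_change` objects (or numeric vector of
#'   per-animal mean changes).
#' @return list with `mean`, `se` (between-animal SD / sqrt(n)) and `n`.
#' @export
mean_change_with_se <- function(changes) {
  m <- if (is.numeric(changes)) changes else
    vapply(changes, function(ch) ch$mean_change, numeric(1))
  if (length(m) < 2L) {
    stop_somex("need at least 2 animals for a standard error",
               class = "somex_insufficient_data")
  }
  list(mean = mean(m), se = stats::sd(m) / sqrt(length(m)), n = length(m))
}
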