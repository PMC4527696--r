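# Peak-table input/output and conversion of fragment sizes (bp) into
# normalized distributions over integer CAG repeat counts.
#
# A peak table is the delimited export of a fragment-analysis run: one row
# per called peak with its apparent size in base pairs and its height/area.
# The repeat count of a fragment is (size_bp - flank_bp) / 3, where flank_bp
# is the total length of primer-flanked sequence outside the repeat tract.

PEAK_COLUMNS <- c("sample_id", "animal_id", "tissue", "size_bp", "height", "area")

#' Construct a normalized distribution over integer repeat counts
#'
#' @param repeats integer repeat counts (unique).
#' @param freq non-negative weights; normalized to sum to 1.
#' @return An object of class `repeat_distribution`: a list with
#'   `frequencies` (named numeric, names are integer repeat counts),
#'   `support_min` and `support_max`.
#' @export
repeat_distribution <- function(repeats, freq) {
  if (length(repeats) != length(freq)) {
    stop_somex("repeats and freq lengths differ", class = "somex_format_error")
  }
  if (any(!is.finite(freq)) || any(freq < 0)) {
    stop_somex("frequencies must be finite and non-negative",
               class = "somex_format_error")
  }
  if (any(repeats != floor(repeats))) {
    stop_somex("repeat counts must be integers", class = "somex_format_error")
  }
  keep <- freq > 0
  repeats <- as.integer(repeats[keep])
  freq <- freq[keep]
  if (length(freq) == 0L || sum(freq) <= 0) {
    stop_somex("distribution has no mass", class = "somex_empty_distribution")
  }
  o <- order(repeats)
  repeats <- repeats[o]
  freq <- freq[o] / sum(freq[o])
  structure(
    list(
      frequencies = stats::setNames(freq, repeats),
      support_min = repeats[1L],
      support_max = repeats[length(repeats)]
    ),
    class = "repeat_distribution"
  )
}

#' @export
print.repeat_distribution <- function(x, ...) {
  cat(sprintf(
    "repeat distribution: %d classes on [%d, %d], mean %.2f\n",
    length(x$frequencies), x$support_min, x$support_max,
    distribution_mean(x)
  ))
  invisible(x)
}

#' Frequency-weighted mean of a distribution's support
#' @param dist a `repeat_distribution` or `somatic_change` object.
#' @export
distribution_mean <- function(dist) {
  sum(as.numeric(names(dist$frequencies)) * dist$frequencies)
}

#' Write a peak table to delimited text
#'
#' Comma-delimited, dot decimal, UTF-8, sizes and intensities at 6 decimal
#' places; the dialect read back by [read_peak_table()].
#' @param table data.frame with columns sample_id, animal_id, tissue,
#'   size_bp, height, area.
#' @param path output file path.
#' @export
write_peak_table <- function(table, path) {
  missing_cols <- setdiff(PEAK_COLUMNS, names(table))
  if (length(missing_cols)) {
    stop_somex("peak table lacks column(s): %s",
               paste(missing_cols, collapse = ", "),
               class = "somex_format_error")
  }
  out <- table[order(table$size_bp), PEAK_COLUMNS]
  for (col in c("size_bp", "height", "area")) {
    out[[col]] <- sprintf("%.6f", out[[col]])
  }
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a peak table from delimited text
#'
#' @param path file written by [write_peak_table()] (or any delimited file
#'   with the documented columns).
#' @return data.frame of class `peak_table`, rows sorted by `size_bp`.
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) {
    stop_somex("no such file: %s", path, class = "somex_io_error")
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                         colClasses = "character")
  missing_cols <- setdiff(PEAK_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop_somex("peak table file lacks column(s): %s",
               paste(missing_cols, collapse = ", "),
               class = "somex_format_error")
  }
  if (nrow(raw) == 0L) {
    stop_somex("peak table is empty: %s", path, class = "somex_empty_table")
  }
  for (col in c("size_bp", "height", "area")) {
    val <- suppressWarnings(as.numeric(raw[[col]]))
    if (any(is.na(val))) {
      stop_somex("malformed numeric field in column %s", col,
                 class = "somex_format_error")
    }
    raw[[col]] <- val
  }
  if (any(raw$size_bp <= 0) || any(raw$height < 0)) {
    stop_somex("size_bp must be > 0 and heights >= 0",
               class = "somex_format_error")
  }
  raw <- raw[order(raw$size_bp), , drop = FALSE]
  rownames(raw) <- NULL
  class(raw) <- c("peak_table", "data.frame")
  raw
}

#' Convert a fragment size in bp to a (real-valued) repeat count
#'
#' Exactly linear and invertible: `(size_bp - flank_bp) / unit_bp`, no
#' rounding.
#' @param size_bp apparent fragment size, base pairs.
#' @param flank_bp total non-repeat flank length amplified (user calibration;
#'   not derivable from primer sequences alone).
#' @param unit_bp repeat unit length, 3 for CAG.
#' @export
size_to_repeats <- function(size_bp, flank_bp, unit_bp = 3) {
  if (unit_bp <= 0) {
    stop_somex("unit_bp must be > 0", class = "somex_calibration_error")
  }
  rep_count <- (size_bp - flank_bp) / unit_bp
  if (any(rep_count <= 0)) {
    stop_somex("fragment size at or below the flank length; check flank_bp",
               class = "somex_calibration_error")
  }
  rep_count
}

#' Collapse a peak table into a normalized repeat distribution
#'
#' Peaks below `min_rel_height` times the tallest peak are discarded (noise
#' floor), sizes converted with [size_to_repeats()] and rounded to the nearest
#' integer repeat (half away from zero; ties cannot occur for exact 3-bp
#' spacing), heights summed per repeat class and renormalized. With
#' `stutter_correct = TRUE` the configured geometric stutter ladder is divided
#' out first (see Details).
#'
#' @details Stutter correction inverts the linear ladder model used by
#' [render_trace()]: each true class `n` contributes `decay` of its height to
#' `n-1`, `decay^2` to `n-2` and `plus1` to `n+1`. The correction solves the
#' corresponding banded linear system by least squares, clamps negative
#' solutions to zero and renormalizes. With noiseless input the inversion is
#' exact.
#'
#' @param table a `peak_table` (or data.frame with `size_bp`, `height`).
#' @param flank_bp calibration flank length, bp.
#' @param min_rel_height relative height threshold in (0, 1); default 0.05.
#' @param stutter_correct logical; default FALSE (peak lists taken as-is).
#' @param stutter_decay,stutter_plus1 ladder ratios used when
#'   `stutter_correct` is TRUE.
#' @param unit_bp repeat unit, bp.
#' @return a [repeat_distribution()].
#' @export
peaks_to_distribution <- function(table, flank_bp, min_rel_height = 0.05,
                                  stutter_correct = FALSE,
                                  stutter_decay = 0.35, stutter_plus1 = 0.10,
                                  unit_bp = 3) {
  if (nrow(table) == 0L) {
    stop_somex("peak table is empty", class = "somex_empty_table")
  }
  keep <- table$height >= min_rel_height * max(table$height)
  table <- table[keep, , drop = FALSE]
  if (nrow(table) == 0L) {
    stop_somex("all peaks fell below the height threshold",
               class = "somex_empty_distribution")
  }
  reps <- round_half_away(size_to_repeats(table$size_bp, flank_bp, unit_bp))
  height <- tapply(table$height, reps, sum)
  repeats <- as.integer(names(height))
  freq <- as.numeric(height)
  if (stutter_correct) {
    freq <- stutter_deconvolve(repeats, freq, stutter_decay, stutter_plus1)
    keep <- freq > max(freq) * 1e-9
    repeats <- repeats[keep]
    freq <- freq[keep]
    if (length(freq) == 0L) {
      stop_somex("stutter correction removed all mass",
                 class = "somex_empty_distribution")
    }
  }
  repeat_distribution(repeats, freq)
}

# Solve observed = K %*% true for the stutter ladder kernel K on the dense
# integer support spanned by `repeats`.
stutter_deconvolve <- function(repeats, freq, decay, plus1) {
  support <- seq(min(repeats), max(repeats))
  y <- numeric(length(support))
  y[match(repeats, support)] <- freq
  n <- length(support)
  K <- diag(n)
  for (j in seq_len(n)) {
    if (j - 1 >= 1) K[j - 1, j] <- decay
    if (j - 2 >= 1) K[j - 2, j] <- decay^2
    if (j + 1 <= n) K[j + 1, j] <- plus1
  }
  x <- nnls_active_set(K, y)
  x[match(repeats, support)]
}

# non-negative least squares by active-set elimination: solve, drop negative
# coordinates, resolve on the support that remains
nnls_active_set <- function(K, y) {
  n <- ncol(K)
  active <- rep(TRUE, n)
  x <- numeric(n)
  for (it in seq_len(n)) {
    x[] <- 0
    sol <- qr.coef(qr(K[, active, drop = FALSE]), y)
    sol[is.na(sol)] <- 0
    x[active] <- sol
    if (all(x >= -1e-12)) break
    active[x < -1e-12] <- FALSE
    if (!any(active)) break
  }
  x[x < 0] <- 0
  x
}
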