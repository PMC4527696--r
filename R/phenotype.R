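# Motor-phenotype summaries and genotype/covariate analyses: rotarod
# best-of-three daily scores, Tukey box summaries, least-squares covariate
# regression, percentile-performance association and onset-delay detection.

#' Summarize rotarod records into per-animal scores
#'
#' Per day the best (maximum) time over the attempts at the requested
#' speed; the score is the mean of the daily bests.
#' @param records data.frame with `animal_id`, `day`, `attempt`,
#'   `speed_rpm`, `time_s` (and optionally `grip_pass`).
#' @param speed rpm to summarize (analyses default to 20 rpm).
#' @return data.frame, one row per animal: `animal_id`, `score`,
#'   `n_days`, `grip_passed` (any successful day, NA if no grip data).
#' @export
summarize_rotarod <- function(records, speed = 20) {
  rec <- records[records$speed_rpm == speed, , drop = FALSE]
  if (nrow(rec) == 0L) {
    stop_somex("no records at %g rpm", speed, class = "somex_missing_data")
  }
  best <- stats::aggregate(time_s ~ animal_id + day, data = rec, FUN = max)
  score <- stats::aggregate(time_s ~ animal_id, data = best, FUN = mean)
  names(score)[2] <- "score"
  ndays <- stats::aggregate(day ~ animal_id, data = best,
                            FUN = function(d) length(unique(d)))
  names(ndays)[2] <- "n_days"
  out <- merge(score, ndays, by = "animal_id")
  if ("grip_pass" %in% names(records)) {
    grip <- stats::aggregate(grip_pass ~ animal_id, data = records, FUN = any)
    names(grip)[2] <- "grip_passed"
    out <- merge(out, grip, by = "animal_id", all.x = TRUE)
  } else {
    out$grip_passed <- NA
  }
  out[order(out$animal_id), , drop = FALSE]
}

#' Tukey five-number box summary of a group's scores
#'
#' Quartiles are Tukey hinges (median-of-halves).
#' @param scores numeric vector, length >= 4.
#' @param label group label.
#' @return data.frame row: `label`, `min`, `q1`, `median`, `q3`, `max`, `n`.
#' @export
box_summary <- function(scores, label = NA_character_) {
  if (length(scores) < 4L) {
    stop_somex("need at least 4 animals for a box summary",
               class = "somex_insufficient_data")
  }
  f <- stats::fivenum(scores)
  data.frame(label = label, min = f[1], q1 = f[2], median = f[3],
             q3 = f[4], max = f[5], n = length(scores),
             stringsAsFactors = FALSE)
}

#' Least-squares regression of rotarod score on covariates
#'
#' Fits `score ~ female + ogg1_ko + hd_homo + age` (plus optional separate
#' age slopes per HD-homozygous genotype). Also reports the fitted grand
#' mean (mean of fitted values, i.e. the covariate-adjusted cohort
#' average).
#' @param perf data.frame with `animal_id`, `score`.
#' @param covariates data.frame with `animal_id`, `sex`, `ogg1_status`,
#'   `hd_zygosity`, `age_weeks`.
#' @param genotype_age_slopes add separate age slopes for each
#'   HD-homozygous-by-ogg1 genotype.
#' @return list with `coefficients` (data.frame: term, estimate, se, p),
#'   `grand_mean`, and the underlying `lm` fit.
#' @export
performance_regression <- function(perf, covariates,
                                   genotype_age_slopes = FALSE) {
  df <- merge(perf, covariates, by = "animal_id")
  df$female <- as.integer(df$sex == "F")
  df$ogg1_ko <- as.integer(df$ogg1_status == "-/-")
  df$hd_homo <- as.integer(df$hd_zygosity == "Q150/Q150")
  df$age <- df$age_weeks
  terms <- c("female", "ogg1_ko", "hd_homo", "age")
  constant <- terms[vapply(terms, function(t) stats::sd(df[[t]]) == 0,
                           logical(1))]
  if (length(constant)) {
    stop_somex("constant covariate column(s): %s",
               paste(constant, collapse = ", "), class = "somex_design_error")
  }
  form <- score ~ female + ogg1_ko + hd_homo + age
  if (genotype_age_slopes) {
    # separate age slopes for each HD-homozygous-by-knockout genotype
    form <- score ~ female + ogg1_ko + hd_homo + age + hd_homo:age +
      hd_homo:ogg1_ko:age
  }
  fit <- stats::lm(form, data = df)
  if (any(is.na(stats::coef(fit)))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop_somex("collinear design; aliased term(s): %s",
               paste(aliased, collapse = ", "), class = "somex_design_error")
  }
  ct <- stats::coef(summary(fit))
  list(
    coefficients = data.frame(
      term = rownames(ct), estimate = ct[, 1], se = ct[, 2], p = ct[, 4],
      row.names = NULL, stringsAsFactors = FALSE
    ),
    grand_mean = mean(stats::fitted(fit)),
    fit = fit
  )
}

#' Association of motor performance with per-animal repeat percentiles
#'
#' For each (tissue, percentile): each animal's change value at that
#' percentile of its own somatic-change distribution is regressed against
#' its rotarod score, adjusted for HD zygosity, ogg1 status, age and sex.
#' The slope sign is mapped to the reporting semantics: a significant
#' negative slope (longer repeats, shorter time on the rod) is labeled
#' `fewer-repeats-better` at percentiles up to 50 and `more-repeats-worse`
#' above; non-significant or positive slopes are `none`.
#' @param perf per-animal scores ([summarize_rotarod()]).
#' @param changes list of `somatic_change` objects (animal x tissue).
#' @param covariates data.frame with `animal_id`, `sex`, `ogg1_status`,
#'   `hd_zygosity`, `age_weeks`.
#' @param percentiles percentile cells.
#' @param alpha significance threshold for the sign label.
#' @return data.frame grid: `tissue`, `percentile`, `slope`, `p`, `sign`,
#'   plus attribute `n_excluded` (animals lacking a tissue distribution).
#' @export
quantile_performance_association <- function(perf, changes, covariates,
                                             percentiles = PERCENTILE_CELLS,
                                             alpha = 0.05) {
  tissues <- unique(vapply(changes, function(ch) ch$tissue, character(1)))
  grid <- list()
  n_excluded <- 0L
  for (t in tissues) {
    t_changes <- Filter(function(ch) identical(ch$tissue, t), changes)
    ids <- vapply(t_changes, function(ch) ch$animal_id, character(1))
    avail <- intersect(ids, perf$animal_id)
    n_excluded <- n_excluded + length(setdiff(perf$animal_id, ids))
    qv <- t(vapply(t_changes[match(avail, ids)], function(ch)
      quantile_values(ch, percentiles), numeric(length(percentiles))))
    df0 <- merge(perf[perf$animal_id %in% avail, c("animal_id", "score")],
                 covariates, by = "animal_id")
    df0$female <- as.integer(df0$sex == "F")
    df0$ogg1_ko <- as.integer(df0$ogg1_status == "-/-")
    df0$hd_homo <- as.integer(df0$hd_zygosity == "Q150/Q150")
    for (j in seq_along(percentiles)) {
      df <- df0
      df$value <- qv[match(df$animal_id, avail), j]
      keep_terms <- c("value", "female", "ogg1_ko", "hd_homo", "age_weeks")
      varying <- keep_terms[vapply(keep_terms, function(k)
        stats::sd(df[[k]]) > 0, logical(1))]
      if (!"value" %in% varying) {
        slope <- 0; p <- 1
      } else {
        form <- stats::as.formula(paste("score ~",
                                        paste(varying, collapse = " + ")))
        ct <- stats::coef(summary(stats::lm(form, data = df)))
        slope <- ct["value", 1]; p <- ct["value", 4]
      }
      lab <- if (p <= alpha && slope < 0) {
        if (percentiles[j] <= 50) "fewer-repeats-better" else "more-repeats-worse"
      } else "none"
      grid[[length(grid) + 1L]] <- data.frame(
        tissue = t, percentile = percentiles[j], slope = slope, p = p,
        sign = lab, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, grid)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Detect the onset age group of motor decline
#'
#' Baseline-adjusted comparison against a wild-type reference: per age
#' group the deficit is (reference median - genotype median), centered by
#' the deficit in the earliest shared group so constant genotype offsets
#' do not register as decline. Onset is the earliest group whose adjusted
#' deficit exceeds `margin` (default: 1.5 times the reference group's
#' interquartile range, the Tukey outer-fence factor applied to the
#' wild-type spread), with the deficit persisting in the following group (trailing
#' groups cannot be confirmed and count as onset only if they exceed the
#' margin themselves).
#'
#' @param scores,groups per-animal scores and age-group labels for the
#'   genotype of interest.
#' @param ref_scores,ref_groups the wild-type reference.
#' @param group_order age-group labels in chronological order; defaults to
#'   the order of appearance in `groups`.
#' @param margin seconds; NULL uses `margin_factor` times the per-group
#'   reference IQR.
#' @param margin_factor multiplier on the reference IQR (default 1.5).
#' @param min_per_group minimum animals per group in both cohorts.
#' @return list with `onset_group` (label or NA), `onset_midpoint` (weeks,
#'   NA if no onset; midpoint parsed from "lo-hi" labels), and the
#'   per-group `deficits` table.
#' @export
detect_onset <- function(scores, groups, ref_scores, ref_groups,
                         group_order = NULL, margin = NULL,
                         margin_factor = 1.5, min_per_group = 5L) {
  if (is.null(group_order)) group_order <- unique(groups)
  if (!all(group_order %in% ref_groups)) {
    stop_somex("reference cohort lacks age group(s): %s",
               paste(setdiff(group_order, ref_groups), collapse = ", "),
               class = "somex_coverage_error")
  }
  if (length(group_order) < 3L) {
    stop_somex("need at least 3 age groups", class = "somex_insufficient_data")
  }
  med <- vapply(group_order, function(g) stats::median(scores[groups == g]),
                numeric(1))
  ref_med <- vapply(group_order, function(g)
    stats::median(ref_scores[ref_groups == g]), numeric(1))
  counts <- vapply(group_order, function(g) sum(groups == g), numeric(1))
  ref_counts <- vapply(group_order, function(g) sum(ref_groups == g),
                       numeric(1))
  if (any(counts < min_per_group) || any(ref_counts < min_per_group)) {
    stop_somex("fewer than %d animals in some age group", min_per_group,
               class = "somex_insufficient_data")
  }
  iqr <- vapply(group_order, function(g) {
    f <- stats::fivenum(ref_scores[ref_groups == g])
    f[4] - f[2]
  }, numeric(1))
  margins <- if (is.null(margin)) margin_factor * iqr
             else rep(margin, length(group_order))
  deficit <- (ref_med - med) - (ref_med[1] - med[1])
  exceeds <- deficit > margins
  exceeds[1] <- FALSE  # the baseline group defines zero
  onset_idx <- NA_integer_
  for (i in seq_along(group_order)) {
    if (!exceeds[i]) next
    if (i < length(group_order)) {
      if (exceeds[i + 1]) { onset_idx <- i; break }
    } else {
      onset_idx <- i
      break
    }
  }
  midpoint <- function(label) {
    parts <- suppressWarnings(as.numeric(strsplit(label, "-", fixed = TRUE)[[1]]))
    if (length(parts) == 2 && !any(is.na(parts))) mean(parts) else NA_real_
  }
  list(
    onset_group = if (is.na(onset_idx)) NA_character_ else group_order[onset_idx],
    onset_midpoint = if (is.na(onset_idx)) NA_real_ else
      midpoint(group_order[onset_idx]),
    deficits = data.frame(
      age_group = group_order, median = med, ref_median = ref_med,
      deficit = deficit, margin = margins, exceeds = exceeds,
      stringsAsFactors = FALSE
    )
  )
}

#' Grip-test pass and fail rates of a group
#'
#' An animal passes if any of its daily grip outcomes is a success.
#' @param grip_passed logical vector, one entry per animal.
#' @return list with `pass_rate` and `fail_rate` in percent, and `n`.
#' @export
grip_pass_rate <- function(grip_passed) {
  if (length(grip_passed) == 0L) {
    stop_somex("no animals", class = "somex_insufficient_data")
  }
  pass <- 100 * mean(grip_passed)
  list(pass_rate = pass, fail_rate = 100 - pass, n = length(grip_passed))
}
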