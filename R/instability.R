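# Distribution-level instability statistics: pooled global distributions,
# quantile cells with animal-level bootstrap, age-window summaries, and the
# genotype-structure checks (zygosity interaction, inherited-length
# independence, two-group Z comparison).

PERCENTILE_CELLS <- c(1, 5, 10, 20, 30, 40, 50, 60, 70, 80, 90, 95, 99)

#' Pool per-animal somatic-change distributions into a global distribution
#'
#' Animal-equal-weight average of the per-animal frequency vectors (so
#' high-signal samples do not dominate), renormalized.
#' @param changes list of `somatic_change` objects from one stratum.
#' @param stratum optional label recorded on the result.
#' @return object of class `global_distribution`: list with `stratum`,
#'   `frequencies` (named by signed integer change) and `n_animals`.
#' @export
pool_distributions <- function(changes, stratum = NA_character_) {
  if (length(changes) == 0L) {
    stop_somex("no distributions to pool", class = "somex_empty_stratum")
  }
  keys <- sort(unique(unlist(lapply(changes, function(ch)
    as.integer(names(ch$frequencies))))))
  acc <- stats::setNames(numeric(length(keys)), keys)
  for (ch in changes) {
    acc[names(ch$frequencies)] <- acc[names(ch$frequencies)] +
      ch$frequencies / length(changes)
  }
  structure(
    list(stratum = stratum, frequencies = acc / sum(acc),
         n_animals = length(changes)),
    class = "global_distribution"
  )
}

#' Weighted nearest-rank percentiles of a pooled distribution
#'
#' The value at percentile p is the smallest support value whose cumulative
#' frequency reaches p/100, keeping cell values on the integer repeat grid.
#' @param g a `global_distribution` (or any object with a named
#'   `frequencies` vector).
#' @param percentiles percentile levels in (0, 100].
#' @return named numeric, one value per percentile.
#' @export
quantile_values <- function(g, percentiles = PERCENTILE_CELLS) {
  f <- g$frequencies
  if (length(f) == 0L) {
    stop_somex("empty distribution", class = "somex_empty_distribution")
  }
  x <- as.numeric(names(f))
  cdf <- cumsum(f)
  vals <- vapply(percentiles, function(p) {
    x[which(cdf >= p / 100 - 1e-12)[1L]]
  }, numeric(1))
  stats::setNames(vals, percentiles)
}

# pool with optional stratification: equal stratum weights, animal-equal
# weights within stratum ("combined and adjusted" for HD zygosity)
pool_stratified <- function(changes, strata = NULL) {
  if (is.null(strata)) return(pool_distributions(changes))
  parts <- split(changes, strata)
  pooled <- lapply(parts, pool_distributions)
  keys <- sort(unique(unlist(lapply(pooled, function(g)
    as.integer(names(g$frequencies))))))
  acc <- stats::setNames(numeric(length(keys)), keys)
  for (g in pooled) {
    acc[names(g$frequencies)] <- acc[names(g$frequencies)] +
      g$frequencies / length(pooled)
  }
  structure(
    list(stratum = NA_character_, frequencies = acc / sum(acc),
         n_animals = length(changes)),
    class = "global_distribution"
  )
}

significance_code <- function(p) {
  ifelse(p <= 0.005, "‡", ifelse(p <= 0.01, "†",
                                      ifelse(p <= 0.05, "*", "")))
}

#' Quantile-cell differences between two genotype groups
#'
#' The pooled distribution of each group is segmented at the given
#' percentiles; each cell is the difference in cell value between the
#' groups, with standard error and two-sided p-value from an animal-level
#' bootstrap (animals resampled with replacement within group, optional
#' stratified pooling with equal stratum weights, e.g. to combine HD
#' zygosities adjusted for zygosity). Significance codes follow the
#' convention `*` p<=0.05, dagger p<=0.01, double dagger p<=0.005.
#'
#' @param g1_changes,g2_changes lists of `somatic_change` objects.
#' @param percentiles percentile cells.
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed RNG seed for the bootstrap (fixed seed => identical output).
#' @param g1_strata,g2_strata optional per-animal stratum labels for
#'   adjusted pooling.
#' @param min_animals minimum group size.
#' @return data.frame: `percentile`, `value_g1`, `value_g2`, `difference`,
#'   `se`, `p`, `code`.
#' @export
cell_differences <- function(g1_changes, g2_changes,
                             percentiles = PERCENTILE_CELLS,
                             n_boot = 2000, seed = 1,
                             g1_strata = NULL, g2_strata = NULL,
                             min_animals = 5L) {
  n1 <- length(g1_changes); n2 <- length(g2_changes)
  if (n1 < min_animals || n2 < min_animals) {
    stop_somex("need at least %d animals per group (got %d and %d)",
               min_animals, n1, n2, class = "somex_insufficient_data")
  }
  q1 <- quantile_values(pool_stratified(g1_changes, g1_strata), percentiles)
  q2 <- quantile_values(pool_stratified(g2_changes, g2_strata), percentiles)
  diff_obs <- q1 - q2
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      i1 <- sample.int(n1, n1, replace = TRUE)
      i2 <- sample.int(n2, n2, replace = TRUE)
      b1 <- quantile_values(
        pool_stratified(g1_changes[i1],
                        if (is.null(g1_strata)) NULL else g1_strata[i1]),
        percentiles)
      b2 <- quantile_values(
        pool_stratified(g2_changes[i2],
                        if (is.null(g2_strata)) NULL else g2_strata[i2]),
        percentiles)
      b1 - b2
    }, numeric(length(percentiles)))
  })
  boot <- matrix(boot, nrow = length(percentiles))
  se <- apply(boot, 1, stats::sd)
  p <- vapply(seq_along(percentiles), function(i) {
    lo <- (1 + sum(boot[i, ] <= 0)) / (n_boot + 1)
    hi <- (1 + sum(boot[i, ] >= 0)) / (n_boot + 1)
    min(1, 2 * min(lo, hi))
  }, numeric(1))
  data.frame(
    percentile = percentiles, value_g1 = as.numeric(q1),
    value_g2 = as.numeric(q2), difference = as.numeric(diff_obs),
    se = se, p = p, code = significance_code(p),
    stringsAsFactors = FALSE
  )
}

#' Age-window summary of mean somatic change by knockout status
#'
#' Unadjusted means with between-animal standard errors, all brain regions
#' pooled (per-animal mean change averaged over tissues first), reported
#' for (a) both HD genotypes combined and (b) homozygotes alone. Windows
#' with no animals are flagged, not dropped.
#' @param summary data.frame from [process_cohort()]`$summary`.
#' @param windows age-group labels to summarize.
#' @return data.frame: `age_group`, `ogg1_status`, `genotypes`
#'   ("combined" or "Q150/Q150"), `mean`, `se`, `n`, `flagged`.
#' @export
age_window_summary <- function(summary,
                               windows = c("5-10", "11-20", "21-30", "31-40")) {
  per_animal <- stats::aggregate(
    mean_change ~ animal_id + hd_zygosity + ogg1_status + age_group,
    data = summary, FUN = mean
  )
  out <- list()
  for (w in windows) {
    for (status in c("+/+", "-/-")) {
      for (set in c("combined", "Q150/Q150")) {
        sel <- per_animal$age_group == w & per_animal$ogg1_status == status &
          (if (set == "combined") per_animal$hd_zygosity %in%
             c("Q150/wt", "Q150/Q150")
           else per_animal$hd_zygosity == "Q150/Q150")
        m <- per_animal$mean_change[sel]
        out[[length(out) + 1L]] <- data.frame(
          age_group = w, ogg1_status = status, genotypes = set,
          mean = if (length(m)) mean(m) else NA_real_,
          se = if (length(m) >= 2) stats::sd(m) / sqrt(length(m)) else NA_real_,
          n = length(m),
          flagged = length(m) == 0L,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, out)
}

#' Interaction of HD zygosity and ogg1 status on somatic change
#'
#' Linear model of per-animal mean change on zygosity, knockout status and
#' their interaction; returns the interaction p-value.
#' @param summary data.frame with `animal_id`, `hd_zygosity`,
#'   `ogg1_status`, `mean_change` (tissue rows are averaged per animal).
#' @export
zygosity_interaction_test <- function(summary) {
  per_animal <- stats::aggregate(
    mean_change ~ animal_id + hd_zygosity + ogg1_status,
    data = summary, FUN = mean
  )
  if (length(unique(per_animal$hd_zygosity)) < 2L ||
      length(unique(per_animal$ogg1_status)) < 2L) {
    stop_somex("need both zygosities and both ogg1 statuses represented",
               class = "somex_design_error")
  }
  fit <- stats::lm(mean_change ~ hd_zygosity * ogg1_status, data = per_animal)
  av <- stats::anova(fit)
  p <- av["hd_zygosity:ogg1_status", "Pr(>F)"]
  if (is.na(p)) {
    stop_somex("rank-deficient design: interaction not estimable",
               class = "somex_design_error")
  }
  p
}

#' Association of somatic change with inherited allele length
#'
#' Per tissue, the slope p-value from regressing per-animal mean change on
#' the inherited repeat count; also reported for all tissues averaged
#' (per-animal mean over regions).
#' @param summary data.frame from [process_cohort()]`$summary` (needs
#'   `inherited_allele_1`).
#' @param min_animals minimum animals per tissue.
#' @return named numeric of p-values: one per tissue plus `"all"`.
#' @export
inherited_length_association <- function(summary, min_animals = 10L) {
  summary$inherited <- ifelse(
    is.na(summary$inherited_allele_2), summary$inherited_allele_1,
    (summary$inherited_allele_1 + summary$inherited_allele_2) / 2
  )
  slope_p <- function(df) {
    if (nrow(df) < 3L) {
      stop_somex("insufficient data for association",
                 class = "somex_insufficient_data")
    }
    if (stats::sd(df$inherited) == 0) {
      stop_somex("inherited sizes are constant; slope undefined",
                 class = "somex_undefined_slope")
    }
    stats::coef(summary(stats::lm(mean_change ~ inherited,
                                  data = df)))["inherited", 4]
  }
  tissues <- unique(summary$tissue)
  out <- numeric(0)
  for (t in tissues) {
    df <- summary[summary$tissue == t, , drop = FALSE]
    if (nrow(df) < min_animals) {
      stop_somex("fewer than %d animals for tissue %s", min_animals, t,
                 class = "somex_insufficient_data")
    }
    out[t] <- slope_p(df)
  }
  all_df <- stats::aggregate(cbind(mean_change, inherited) ~ animal_id,
                             data = summary, FUN = mean)
  out["all"] <- slope_p(all_df)
  out
}

#' Two-sample Z score from means and standard errors
#'
#' `Z = (mean1 - mean2) / sqrt(se1^2 + se2^2)`.
#' @param mean1,se1,mean2,se2 group means and standard errors.
#' @export
two_sample_z <- function(mean1, se1, mean2, se2) {
  if (se1 < 0 || se2 < 0) {
    stop_somex("standard errors must be >= 0", class = "somex_config_error")
  }
  if (se1 == 0 && se2 == 0) {
    stop_somex("both standard errors are zero; Z undefined",
               class = "somex_undefined_z")
  }
  (mean1 - mean2) / sqrt(se1^2 + se2^2)
}
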