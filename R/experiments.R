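# Self-contained calibration experiments: each simulates a cohort under the
# study conditions and recovers one of the quantities the pipeline is
# validated against. They are used by the test suite and the acceptance
# script, and serve as worked examples of the full workflow.

# parse a long peak table into per-sample distributions, stutter-corrected
split_samples <- function(peaks, config, min_rel_height = 0.05) {
  lapply(split(peaks, peaks$sample_id), function(tab) {
    peaks_to_distribution(tab, config$flank_bp, min_rel_height,
                          stutter_correct = TRUE,
                          stutter_decay = config$stutter_decay,
                          stutter_plus1 = config$stutter_plus1,
                          unit_bp = config$unit_bp)
  })
}

#' Inherited-allele recovery on a synthetic birth cohort
#'
#' Generates `n` heterozygous birth (tail) samples under the default
#' inherited-allele model, renders and re-parses every trace, fits each with
#' the single-Gaussian peak fitter and summarizes the fitted midpoints.
#' @param n number of animals.
#' @param seed generator seed.
#' @return list with `mean` and `sd` of the fitted midpoints, and the
#'   vector of `midpoints`.
#' @export
inherited_calibration <- function(n = 20000, seed = 1) {
  cfg <- cohort_config(
    seed = seed, animals_per_cell = as.integer(n),
    genotypes = data.frame(hd_zygosity = "Q150/wt", ogg1_status = "+/+"),
    age_groups = default_age_groups()[1, ], tissues = character(0)
  )
  coh <- generate_cohort(cfg)
  dists <- split_samples(coh$peaks, cfg)
  mids <- vapply(dists, function(d) fit_allele_peaks(d, 1L)$midpoint,
                 numeric(1))
  list(mean = mean(mids), sd = stats::sd(mids), midpoints = mids)
}

#' Pooled somatic-change recovery for one 10-week striatum arm
#'
#' Simulates homozygous animals in the 5-10-week group, striatum only, at
#' the default (calibrated) expansion mean for the requested knockout
#' status, runs the full pipeline and pools the per-animal mean changes.
#' @param ogg1_status "+/+" or "-/-".
#' @param seed generator seed.
#' @param n_animals animals in the arm.
#' @return list with `mean`, `se`, `n`.
#' @export
striatum_arm_recovery <- function(ogg1_status = "+/+", seed = 1,
                                  n_animals = 20) {
  cfg <- cohort_config(
    seed = seed, animals_per_cell = as.integer(n_animals),
    genotypes = data.frame(hd_zygosity = "Q150/Q150",
                           ogg1_status = ogg1_status),
    age_groups = default_age_groups()[1, ], tissues = "STR"
  )
  res <- process_cohort(generate_cohort(cfg))
  mean_change_with_se(res$summary$mean_change)
}

#' Age-window recovery of the combined-genotype 5-10-week means
#'
#' Simulates all four disease-carrying genotype arms over the four brain
#' regions at 5-10 weeks with the calibrated expansion table and
#' summarizes mean somatic change by knockout status, genotypes combined.
#' @param seed generator seed.
#' @param animals_per_cell animals per genotype stratum.
#' @return the [age_window_summary()] rows for the 5-10-week window.
#' @export
window_calibration <- function(seed = 1, animals_per_cell = 20) {
  g <- expand.grid(hd_zygosity = c("Q150/wt", "Q150/Q150"),
                   ogg1_status = c("+/+", "-/-"), stringsAsFactors = FALSE)
  cfg <- cohort_config(seed = seed,
                       animals_per_cell = as.integer(animals_per_cell),
                       genotypes = g, age_groups = default_age_groups()[1, ])
  res <- process_cohort(generate_cohort(cfg))
  age_window_summary(res$summary, windows = "5-10")
}

#' Recovery of a configured hippocampal knockout effect
#'
#' Configures the hippocampal expansion means so the between-status
#' difference equals `difference`, simulates both homozygous arms and
#' reports the estimated difference of pooled means.
#' @param seed generator seed.
#' @param n_animals animals per arm.
#' @param difference configured between-status difference, repeats.
#' @param baseline knockout-arm mean, repeats.
#' @return list with `difference`, `se`, and the per-arm summaries.
#' @export
hippocampus_effect <- function(seed = 1, n_animals = 30, difference = 2.20,
                               baseline = 1.8) {
  arms <- lapply(c("+/+", "-/-"), function(st) {
    tab <- data.frame(hd_zygosity = "Q150/Q150", ogg1_status = st,
                      tissue = "HIP", age_group = "5-10",
                      mean_delta = if (st == "+/+") baseline + difference
                                   else baseline)
    cfg <- cohort_config(
      seed = seed + (st == "-/-"), animals_per_cell = as.integer(n_animals),
      genotypes = data.frame(hd_zygosity = "Q150/Q150", ogg1_status = st),
      age_groups = default_age_groups()[1, ], tissues = "HIP",
      expansion_mean_table = tab
    )
    mean_change_with_se(process_cohort(generate_cohort(cfg))$summary$mean_change)
  })
  list(difference = arms[[1]]$mean - arms[[2]]$mean,
       se = sqrt(arms[[1]]$se^2 + arms[[2]]$se^2),
       plus = arms[[1]], minus = arms[[2]])
}

#' Rotarod covariate-effect recovery on a pre-onset cohort
#'
#' Simulates `n` animals over the six analysis genotypes at ages 5-15
#' weeks (before any decline onset, so the intercept effects are
#' identifiable), scores the full two-speed protocol and fits the
#' covariate regression.
#' @param seed generator seed.
#' @param n number of animals.
#' @return the [performance_regression()] result.
#' @export
regression_calibration <- function(seed = 1, n = 600) {
  with_seed(seed, {
    g <- expand.grid(hd_zygosity = c("wt/wt", "Q150/wt", "Q150/Q150"),
                     ogg1_status = c("+/+", "-/-"), stringsAsFactors = FALSE)
    animals <- data.frame(
      animal_id = sprintf("R%05d", seq_len(n)),
      sex = rep(c("M", "F"), length.out = n),
      hd_zygosity = rep(g$hd_zygosity, length.out = n),
      ogg1_status = rep(g$ogg1_status, length.out = n),
      age_weeks = rep(5:15, length.out = n)
    )
    rec <- generate_performance(animals, phenotype_params())
    p10 <- summarize_rotarod(rec, 10)
    p20 <- summarize_rotarod(rec, 20)
    perf <- data.frame(animal_id = p20$animal_id,
                       score = (p10$score + p20$score) / 2)
    performance_regression(perf, animals)
  })
}

#' Onset-delay detection between the two homozygous arms
#'
#' Simulates wild-type, ogg1-intact and ogg1-null homozygous arms across
#' the age groups up to 41-60 weeks, scores the two-speed protocol and
#' applies [detect_onset()] to each disease arm against the wild-type
#' reference.
#' @param seed generator seed.
#' @param animals_per_cell animals per (genotype, age group).
#' @return list with `onset_plus` and `onset_minus` (midpoints, weeks) and
#'   `delay` (their difference).
#' @export
onset_delay_experiment <- function(seed = 1, animals_per_cell = 20) {
  g <- data.frame(hd_zygosity = c("wt/wt", "Q150/Q150", "Q150/Q150"),
                  ogg1_status = c("+/+", "+/+", "-/-"))
  cfg <- cohort_config(seed = seed,
                       animals_per_cell = as.integer(animals_per_cell),
                       genotypes = g,
                       age_groups = default_age_groups()[1:5, ],
                       tissues = character(0))
  coh <- generate_cohort(cfg, render_peaks = FALSE)
  p10 <- summarize_rotarod(coh$performance, 10)
  p20 <- summarize_rotarod(coh$performance, 20)
  perf <- data.frame(animal_id = p20$animal_id,
                     score = (p10$score + p20$score) / 2)
  m <- merge(perf, coh$animals, by = "animal_id")
  arm <- function(zyg, st) m[m$hd_zygosity == zyg & m$ogg1_status == st, ]
  wt <- arm("wt/wt", "+/+")
  go <- default_age_groups()$label[1:5]
  o1 <- detect_onset(arm("Q150/Q150", "+/+")$score,
                     arm("Q150/Q150", "+/+")$age_group,
                     wt$score, wt$age_group, go)
  o2 <- detect_onset(arm("Q150/Q150", "-/-")$score,
                     arm("Q150/Q150", "-/-")$age_group,
                     wt$score, wt$age_group, go)
  list(onset_plus = o1$onset_midpoint, onset_minus = o2$onset_midpoint,
       delay = o2$onset_midpoint - o1$onset_midpoint)
}

#' Grip-failure calibration at 40 weeks
#'
#' Simulates ogg1-intact homozygous animals in the 31-40-week group and
#' reports the percent failing the five-day grip test.
#' @param seed generator seed.
#' @param n number of animals.
#' @return list with `fail_rate` (percent), `pass_rate`, `n`.
#' @export
grip_calibration <- function(seed = 1, n = 200) {
  cfg <- cohort_config(
    seed = seed, animals_per_cell = as.integer(n),
    genotypes = data.frame(hd_zygosity = "Q150/Q150", ogg1_status = "+/+"),
    age_groups = default_age_groups()[4, ], tissues = character(0)
  )
  coh <- generate_cohort(cfg, render_peaks = FALSE)
  perf <- summarize_rotarod(coh$performance, 20)
  grip_pass_rate(perf$grip_passed)
}
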