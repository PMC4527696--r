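test_that("cohort strata have the configured size and balanced sexes", {
  g <- data.frame(hd_zygosity = c("Q150/wt", "Q150/Q150"),
                  ogg1_status = c("+/+", "+/+"))
  cfg <- cohort_config(seed = 1, animals_per_cell = 4, genotypes = g,
                       age_groups = default_age_groups()[1, ],
                       tissues = character(0))
  coh <- generate_cohort(cfg, render_peaks = FALSE)
  expect_equal(nrow(coh$animals), 8L)
  tab <- table(coh$animals$hd_zygosity)
  expect_true(all(tab == 4L))
  sex_tab <- table(coh$animals$hd_zygosity, coh$animals$sex)
  expect_true(all(abs(sex_tab[, "M"] - sex_tab[, "F"]) <= 1))
})

test_that("same config and seed regenerates an identical cohort", {
  cfg <- cohort_config(seed = 77, animals_per_cell = 3,
                       genotypes = data.frame(hd_zygosity = "Q150/Q150",
                                              ogg1_status = "-/-"),
                       age_groups = default_age_groups()[2, ],
                       tissues = c("STR", "HIP"))
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
})

test_that("allele counts follow zygosity and are positive integers", {
  cfg <- cohort_config(seed = 2, animals_per_cell = 6,
                       age_groups = default_age_groups()[1, ],
                       tissues = character(0))
  coh <- generate_cohort(cfg, render_peaks = FALSE)
  a <- coh$animals
  expect_true(all(is.na(a$inherited_allele_1[a$hd_zygosity == "wt/wt"])))
  het <- a[a$hd_zygosity == "Q150/wt", ]
  expect_true(all(!is.na(het$inherited_allele_1) & is.na(het$inherited_allele_2)))
  hom <- a[a$hd_zygosity == "Q150/Q150", ]
  expect_true(all(!is.na(hom$inherited_allele_1) & !is.na(hom$inherited_allele_2)))
  all_alleles <- c(a$inherited_allele_1, a$inherited_allele_2)
  expect_true(all(all_alleles[!is.na(all_alleles)] >= 1))
})

test_that("inherited-allele law has the configured moments and span", {
  set.seed(401)
  draws <- draw_inherited_alleles(20000, 117, 12)
  expect_lt(abs(mean(draws) - 117), 0.3)
  expect_lt(abs(sd(draws) - 12), 0.3)
  # fraction within +-24 repeats of the mean matches the Gaussian CDF
  # (rounding widens each bin by half a repeat on each side)
  expected <- pnorm(141.5, 117, 12) - pnorm(92.5, 117, 12)
  expect_lt(abs(mean(abs(draws - 117) <= 24) - expected), 0.005)
  # +-2SD span
  expect_equal(2 * 2 * 12, 48)
  expect_identical(unique(draw_inherited_alleles(50, 117, 0)), 117L)
})

test_that("somatic change law matches its configured net mean and is right-skewed", {
  set.seed(402)
  d <- draw_somatic_delta(1e5, 4.89, 1.5, contraction_prob = 0.05)
  expect_lt(abs(mean(d) - 4.89), 0.05)
  skew <- mean((d - mean(d))^3) / sd(d)^3
  expect_gt(skew, 0.5)
  # analytic pmf agrees with the sampler
  pmf <- somatic_delta_pmf(4.89, 1.5, 0.05)
  expect_lt(abs(sum(as.numeric(names(pmf)) * pmf) - 4.89), 0.02)
  expect_equal(sum(pmf), 1, tolerance = 1e-9)
  # degenerate cases
  expect_identical(draw_somatic_delta(10, 0, 1.5), integer(10))
  expect_identical(somatic_delta_pmf(0, 1.5), c(`0` = 1))
  expect_error(draw_somatic_delta(5, -1, 1.5), class = "somex_config_error")
})

test_that("point-mass distribution with no expansion stays at the inherited size", {
  cfg <- cohort_config(seed = 3, contraction_prob = 0, animal_cv = 0,
                       pcr_spread = 0)
  d <- draw_somatic_distribution(117L, "Q150/wt", "+/+", "STR", "5-10",
                                 cfg, mean_override = 0)
  expect_identical(names(d$frequencies), "117")
  expect_equal(unname(d$frequencies), 1)
})

test_that("missing stratum in the expansion table is a named configuration error", {
  cfg <- cohort_config(seed = 4, tissues = c("STR"))
  expect_error(
    draw_somatic_distribution(117L, "Q150/wt", "+/+", "LIVER", "5-10", cfg),
    regexp = "LIVER", class = "somex_config_error"
  )
})

test_that("render places a lone peak at flank + 3n and stutter at the configured ratio", {
  cfg0 <- cohort_config(seed = 5, stutter_decay = 0, stutter_plus1 = 0,
                        trace_noise_cv = 0, flank_bp = 80)
  pm <- repeat_distribution(117L, 1)
  tr <- render_trace(pm, cfg0)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$size_bp, 80 + 351)
  cfg1 <- cohort_config(seed = 5, stutter_decay = 0.35, stutter_plus1 = 0,
                        trace_noise_cv = 0, flank_bp = 80)
  tr1 <- render_trace(pm, cfg1)
  h <- setNames(tr1$height, round((tr1$size_bp - 80) / 3))
  expect_equal(unname(h["116"] / h["117"]), 0.35, tolerance = 1e-9)
  expect_equal(unname(h["115"] / h["117"]), 0.35^2, tolerance = 1e-9)
})

test_that("noiseless render then parse with stutter correction round-trips", {
  cfg <- cohort_config(seed = 6, trace_noise_cv = 0)
  pmf <- somatic_delta_pmf(3, 1.5, 0.05)
  d <- repeat_distribution(as.integer(names(pmf)) + 117L, as.numeric(pmf))
  tr <- render_trace(d, cfg)
  back <- peaks_to_distribution(tr, cfg$flank_bp, min_rel_height = 0,
                                stutter_correct = TRUE,
                                stutter_decay = cfg$stutter_decay,
                                stutter_plus1 = cfg$stutter_plus1)
  keys <- sort(unique(c(names(d$frequencies), names(back$frequencies))))
  f1 <- setNames(numeric(length(keys)), keys)
  f2 <- f1
  f1[names(d$frequencies)] <- d$frequencies
  f2[names(back$frequencies)] <- back$frequencies
  tv <- sum(abs(f1 - f2)) / 2
  expect_lt(tv, 0.01)
})

test_that("rotarod generation honors the protocol ceiling and deterministic mean", {
  animals <- data.frame(animal_id = c("A1", "A2"), sex = c("M", "F"),
                        hd_zygosity = c("wt/wt", "Q150/Q150"),
                        ogg1_status = c("+/+", "-/-"), age_weeks = c(10, 10))
  p0 <- phenotype_params(female_effect = 0, ogg1ko_effect = 0,
                         hd_homo_effect = 0, residual_sd = 0)
  rec <- generate_performance(animals, p0)
  expect_true(all(rec$time_s == 91.9))
  expect_equal(nrow(rec), 2 * 2 * 5 * 3)  # animals x speeds x days x attempts
  set.seed(403)
  rec2 <- generate_performance(animals, phenotype_params())
  expect_true(all(rec2$time_s <= 120 & rec2$time_s >= 0))
})

test_that("female performance advantage matches its configured size", {
  set.seed(404)
  n <- 2000
  animals <- data.frame(
    animal_id = sprintf("F%04d", 1:n),
    sex = rep(c("M", "F"), length.out = n),
    hd_zygosity = "Q150/Q150", ogg1_status = "+/+", age_weeks = 10
  )
  # moderate daily noise keeps the 120 s cap from censoring the upper sex
  # cell; censoring attenuation at the default noise is characterized by
  # the regression-recovery tests
  rec <- generate_performance(animals, phenotype_params(residual_sd = 10))
  perf <- merge(summarize_rotarod(rec, 20), animals, by = "animal_id")
  diff <- mean(perf$score[perf$sex == "F"]) - mean(perf$score[perf$sex == "M"])
  expect_lt(abs(diff - 7.7), 0.5)
})

test_that("cohort files round-trip through the run directory format", {
  cfg <- cohort_config(seed = 9, animals_per_cell = 2,
                       genotypes = data.frame(hd_zygosity = "Q150/wt",
                                              ogg1_status = "+/+"),
                       age_groups = default_age_groups()[1, ],
                       tissues = "STR")
  coh <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "metadata.csv")))
  expect_true(file.exists(file.path(dir, "calibration.txt")))
  sid <- unique(coh$peaks$sample_id)[1]
  back <- read_peak_table(file.path(dir, "peaks", paste0(sid, ".csv")))
  orig <- coh$peaks[coh$peaks$sample_id == sid, ]
  expect_equal(back$size_bp, orig$size_bp, tolerance = 1e-6)
  expect_equal(back$height, orig$height, tolerance = 1e-6)
})
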