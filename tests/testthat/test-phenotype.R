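make_records <- function(times_by_day, animal_id = "A1", speed = 20) {
  do.call(rbind, lapply(seq_along(times_by_day), function(d) {
    data.frame(animal_id = animal_id, day = d,
               attempt = seq_along(times_by_day[[d]]), speed_rpm = speed,
               time_s = times_by_day[[d]], stringsAsFactors = FALSE)
  }))
}

test_that("rotarod scores are best-of-attempts averaged over days", {
  rec <- make_records(list(c(90, 100, 95), c(70, 80, 60), c(120, 10, 30),
                           c(60, 55, 20), c(90, 85, 88)))
  out <- summarize_rotarod(rec, 20)
  expect_equal(out$score, mean(c(100, 80, 120, 60, 90)))
  expect_equal(out$score, 90.0)
  all_ceiling <- make_records(replicate(5, rep(120, 3), simplify = FALSE))
  expect_equal(summarize_rotarod(all_ceiling, 20)$score, 120)
  expect_error(summarize_rotarod(rec, 10), class = "somex_missing_data")
})

test_that("rotarod summaries equal the brute-force oracle on random records", {
  set.seed(414)
  rec <- do.call(rbind, lapply(1:100, function(i) {
    days <- sample(3:5, 1)
    r <- make_records(replicate(days, runif(3, 0, 120), simplify = FALSE),
                      animal_id = sprintf("A%03d", i))
    r
  }))
  rec$speed_rpm <- 20
  out <- summarize_rotarod(rec, 20)
  oracle <- brute_rotarod_oracle(rec, 20)
  expect_equal(setNames(out$score, out$animal_id), oracle)
})

test_that("box summaries are Tukey five-number summaries", {
  b <- box_summary(c(25, 75, 85, 120), "g")
  expect_equal(b$min, 25)
  expect_equal(b$median, 80)
  expect_equal(b$max, 120)
  same <- box_summary(rep(60, 5))
  expect_equal(same$min, same$max)
  expect_error(box_summary(c(1, 2, 3)), class = "somex_insufficient_data")
  set.seed(415)
  for (r in 1:50) {
    x <- runif(sample(4:30, 1), 0, 120)
    b <- box_summary(x)
    f <- fivenum(x)
    expect_equal(unlist(b[c("min", "q1", "median", "q3", "max")],
                        use.names = FALSE), f)
    expect_true(all(diff(f) >= 0))
  }
})

test_that("regression solves the normal equations exactly on a designed dataset", {
  cov6 <- data.frame(
    animal_id = paste0("A", 1:6),
    sex = c("M", "F", "M", "F", "M", "F"),
    ogg1_status = c("+/+", "+/+", "-/-", "-/-", "+/+", "-/-"),
    hd_zygosity = c("wt/wt", "Q150/Q150", "wt/wt", "Q150/Q150",
                    "Q150/wt", "Q150/wt"),
    age_weeks = c(10, 20, 30, 10, 20, 30)
  )
  perf6 <- data.frame(animal_id = paste0("A", 1:6),
                      score = c(95, 80, 105, 70, 92, 101))
  reg <- performance_regression(perf6, cov6)
  X <- cbind(1, cov6$sex == "F", cov6$ogg1_status == "-/-",
             cov6$hd_zygosity == "Q150/Q150", cov6$age_weeks)
  beta <- solve(t(X) %*% X, t(X) %*% perf6$score)
  expect_equal(reg$coefficients$estimate, as.numeric(beta), tolerance = 1e-10)
  expect_equal(reg$grand_mean, mean(perf6$score))
})

test_that("regression rejects constant covariate columns", {
  cov_bad <- data.frame(animal_id = paste0("A", 1:6), sex = "M",
                        ogg1_status = c("+/+", "-/-"), hd_zygosity = "wt/wt",
                        age_weeks = 1:6)
  perf6 <- data.frame(animal_id = paste0("A", 1:6), score = rnorm(6, 90, 5))
  expect_error(performance_regression(perf6, cov_bad),
               class = "somex_design_error")
})

test_that("null generator yields genotype coefficients within noise of zero", {
  set.seed(416)
  n <- 400
  animals <- data.frame(
    animal_id = sprintf("N%04d", 1:n), sex = rep(c("M", "F"), n / 2),
    hd_zygosity = rep(c("wt/wt", "Q150/wt", "Q150/Q150"), length.out = n),
    ogg1_status = rep(c("+/+", "-/-"), each = 2, length.out = n),
    age_weeks = rep(5:14, length.out = n)
  )
  p0 <- phenotype_params(female_effect = 0, ogg1ko_effect = 0,
                         hd_homo_effect = 0,
                         decline_onset_week = numeric(0))
  rec <- generate_performance(animals, p0)
  reg <- performance_regression(summarize_rotarod(rec, 20), animals)
  est <- reg$coefficients
  for (term in c("female", "ogg1_ko", "hd_homo")) {
    row <- est[est$term == term, ]
    expect_lt(abs(row$estimate), 3 * row$se)
  }
})

test_that("percentile-performance association is null-calibrated and signed", {
  set.seed(417)
  n <- 60
  cov <- data.frame(
    animal_id = sprintf("Q%03d", 1:n), sex = rep(c("M", "F"), n / 2),
    hd_zygosity = rep(c("Q150/wt", "Q150/Q150"), each = n / 2),
    ogg1_status = rep(c("+/+", "-/-"), n / 2),
    age_weeks = rep(c(10, 20, 30), length.out = n)
  )
  # lower and upper halves of each animal's distribution vary independently:
  # 40% of the mass sits at a per-animal low value, the rest on a fixed
  # upper tail, so low percentiles carry animal signal the upper ones lack
  low_pos <- sample(0:6, n, replace = TRUE)
  changes <- lapply(1:n, function(i) {
    upper <- 10:20
    w_up <- dgamma(upper - 9, 2) * runif(length(upper), 0.9, 1.1)
    make_change(c(low_pos[i], upper), c(0.4, 0.6 * w_up / sum(w_up)),
                cov$animal_id[i])
  })
  perf <- data.frame(animal_id = cov$animal_id, score = rnorm(n, 90, 10))
  grid <- quantile_performance_association(perf, changes, cov)
  expect_equal(nrow(grid), 13L)
  expect_true(all(grid$p >= 0 & grid$p <= 1))
  # coupling injected through the low-percentile values concentrates
  # significance in the lower cells
  perf_dep <- data.frame(animal_id = cov$animal_id,
                         score = 100 - 4 * low_pos + rnorm(n, 0, 4))
  grid_dep <- quantile_performance_association(perf_dep, changes, cov)
  expect_lt(grid_dep$p[grid_dep$percentile == 20], 0.05)
  sig_low <- mean(grid_dep$p[grid_dep$percentile <= 30] <= 0.05)
  sig_high <- mean(grid_dep$p[grid_dep$percentile >= 70] <= 0.05)
  expect_gt(sig_low, sig_high)
  expect_identical(grid_dep$sign[grid_dep$percentile == 20],
                   "fewer-repeats-better")
  # sign semantics at the upper extreme
  hi <- grid_dep[grid_dep$percentile == 99 & grid_dep$p <= 0.05, ]
  expect_true(all(hi$sign == "more-repeats-worse"))
})

test_that("onset detection ignores flat profiles and locates injected steps", {
  groups <- c("5-10", "11-20", "21-30", "31-40")
  per_group <- 8
  glab <- rep(groups, each = per_group)
  flat <- rep(100, length(glab))
  none <- detect_onset(flat, glab, flat, glab, groups)
  expect_true(is.na(none$onset_group))
  # noiseless step decline injected at week 15: the 11-20 group (assessed at
  # its designated age, 20 weeks) is the first to drop
  stepped <- ifelse(glab %in% c("11-20", "21-30", "31-40"), 70, 100)
  hit <- detect_onset(stepped, glab, flat, glab, groups)
  expect_identical(hit$onset_group, "11-20")
  expect_equal(hit$onset_midpoint, 15.5)
  expect_error(detect_onset(stepped, glab, flat[1:8], glab[1:8], groups),
               class = "somex_coverage_error")
})

test_that("delaying an injected decline never advances the detected onset", {
  groups <- c("5-10", "11-20", "21-30", "31-40", "41-60")
  glab <- rep(groups, each = 10)
  ref <- rep(100, length(glab))
  onsets <- c()
  for (k in 2:5) {
    dec <- ifelse(match(glab, groups) >= k, 60, 100)
    onsets <- c(onsets, detect_onset(dec, glab, ref, glab, groups)$onset_midpoint)
  }
  expect_true(all(diff(onsets) > 0))
})

test_that("grip rates are exact percentages", {
  expect_equal(grip_pass_rate(rep(TRUE, 10))$pass_rate, 100)
  r <- grip_pass_rate(c(rep(TRUE, 5), rep(FALSE, 3)))
  expect_equal(r$pass_rate, 62.5)
  expect_equal(r$fail_rate, 37.5)
  expect_error(grip_pass_rate(logical(0)), class = "somex_insufficient_data")
})
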