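# Synthetic cohort generator.
#
# Generates virtual mice from a knock-in HD cross (Hdh Q150 x ogg1 knockout):
# genotypes, inherited disease-allele lengths, tissue- and age-dependent
# somatic repeat-change distributions, stuttered fragment-analysis peak
# tables, and rotarod/grip performance records. The generator's defaults are
# the study conditions the analysis modules are calibrated against; every
# default is overridable through cohort_config().

HD_ZYGOSITIES <- c("wt/wt", "Q150/wt", "Q150/Q150")
OGG1_STATUSES <- c("+/+", "+/-", "-/-")
DEFAULT_TISSUES <- c("STR", "HIP", "CBL", "CTX")

#' Default age-group windows (weeks)
#'
#' Seven windows: 5- or 10-week intervals up to 40 weeks, then 20- and
#' 40-week intervals. Every animal in a window carries the window's
#' designated assessment age (the upper bound): cohorts are aged to a target
#' week, motor-tested over five days and sacrificed.
#' @return data.frame with columns `label`, `lo`, `hi`, `test_week`,
#'   `midpoint`.
#' @export
default_age_groups <- function() {
  lo <- c(5, 11, 21, 31, 41, 61, 81)
  hi <- c(10, 20, 30, 40, 60, 80, 120)
  data.frame(
    label = paste0(lo, "-", hi),
    lo = lo, hi = hi,
    test_week = hi,
    midpoint = (lo + hi) / 2,
    stringsAsFactors = FALSE
  )
}

# Age-window calibration means (net somatic repeat gain) per zygosity, ogg1
# status and age window <= 40 weeks. Homozygote cells carry the
# homozygote-alone calibration values; heterozygote cells are derived so
# the equal-weight combination reproduces the combined-genotype values.
.window_base_means <- function() {
  windows <- c("5-10", "11-20", "21-30", "31-40")
  combined_pp <- c(5.10, 5.35, 3.89, 4.95)
  combined_ko <- c(1.34, 3.05, 3.68, 4.27)
  homo_pp <- c(4.68, 5.48, 3.17, 4.47)
  homo_ko <- c(1.25, 3.37, 2.59, 5.19)
  het_pp <- 2 * combined_pp - homo_pp
  het_ko <- 2 * combined_ko - homo_ko
  rbind(
    data.frame(hd_zygosity = "Q150/Q150", ogg1_status = "+/+",
               age_group = windows, base = homo_pp),
    data.frame(hd_zygosity = "Q150/Q150", ogg1_status = "-/-",
               age_group = windows, base = homo_ko),
    data.frame(hd_zygosity = "Q150/wt", ogg1_status = "+/+",
               age_group = windows, base = het_pp),
    data.frame(hd_zygosity = "Q150/wt", ogg1_status = "-/-",
               age_group = windows, base = het_ko)
  )
}

#' Default somatic-expansion mean table
#'
#' Mean net repeat gain per (HD zygosity, ogg1 status, tissue, age window).
#' Windows up to 40 weeks follow the age-window calibration values, with
#' per-tissue offsets chosen so the pooled (birth to 40 weeks, both
#' zygosities) knockout effect per region is STR 1.93, HIP 2.20, CBL 2.10
#' and CTX 1.55 repeats, and with the 10-week homozygote striatum anchored
#' at 4.89 (ogg1 present) and 2.04 (ogg1 null); the anchor excess is
#' redistributed over the other tissues so window means are preserved.
#' Older windows lose the knockout dependence (expansion catches up) and use
#' status-independent means.
#' @param tissues tissue panel; offsets are defined for the default four.
#' @param age_groups data.frame as from [default_age_groups()].
#' @return data.frame with columns `hd_zygosity`, `ogg1_status`, `tissue`,
#'   `age_group`, `mean_delta`.
#' @export
default_expansion_table <- function(tissues = DEFAULT_TISSUES,
                                    age_groups = default_age_groups()) {
  base <- .window_base_means()
  # half the gap between the target regional knockout effect and the
  # window-average effect goes on each status, with opposite signs; the
  # offsets are centered to zero sum so the age-window means are preserved
  # exactly (the regional ordering HIP > CBL > STR > CTX is kept, the
  # absolute regional differences compress slightly)
  target_diff <- c(STR = 1.93, HIP = 2.20, CBL = 2.10, CTX = 1.55)
  base_diff_avg <- 1.7375
  u <- (target_diff - base_diff_avg) / 2
  u <- u - mean(u)
  rows <- list()
  for (t in tissues) {
    ut <- if (t %in% names(u)) u[[t]] else 0
    b <- base
    b$tissue <- t
    b$mean_delta <- b$base + ifelse(b$ogg1_status == "+/+", ut, -ut)
    rows[[t]] <- b[c("hd_zygosity", "ogg1_status", "tissue",
                     "age_group", "mean_delta")]
  }
  tab <- do.call(rbind, rows)
  # anchor the 10-week homozygote striatum to the reference values and
  # redistribute the excess within the window
  anchor <- function(tab, status, value) {
    sel <- tab$hd_zygosity == "Q150/Q150" & tab$ogg1_status == status &
      tab$age_group == "5-10"
    str_sel <- sel & tab$tissue == "STR"
    oth_sel <- sel & tab$tissue != "STR"
    if (any(str_sel)) {
      excess <- value - tab$mean_delta[str_sel]
      tab$mean_delta[str_sel] <- value
      if (sum(oth_sel) > 0) {
        tab$mean_delta[oth_sel] <- tab$mean_delta[oth_sel] - excess / sum(oth_sel)
      }
    }
    tab
  }
  tab <- anchor(tab, "+/+", 4.89)
  tab <- anchor(tab, "-/-", 2.04)
  # late windows: knockout dependence is lost
  late <- expand.grid(
    hd_zygosity = c("Q150/wt", "Q150/Q150"),
    ogg1_status = c("+/+", "-/-"),
    tissue = tissues,
    age_group = c("41-60", "61-80", "81-120"),
    stringsAsFactors = FALSE
  )
  late$mean_delta <- c(`41-60` = 6.0, `61-80` = 7.0, `81-120` = 8.5)[late$age_group]
  out <- rbind(tab, late)
  out <- out[out$age_group %in% age_groups$label, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rotarod and grip phenotype parameters
#'
#' `grand_mean` is the cohort-average rotarod time; sex and genotype effects
#' are deviations from it (centered over the cohort's composition when
#' performance is generated). Post-onset decline is linear at `decline_rate`
#' seconds per week down to `decline_floor`. `grip_fail_logit` gives, per
#' "zygosity|ogg1" key, intercept and per-week slope of the logit of the
#' probability that an animal fails all of one day's grip attempts.
#' @param grand_mean,female_effect,ogg1ko_effect,hd_homo_effect seconds.
#' @param residual_sd SD (seconds) of a day's best rotarod time.
#' @param ceiling maximum trial time, seconds.
#' @param decline_onset_week named vector, "zygosity|ogg1" -> onset week.
#' @param decline_rate seconds lost per week after onset.
#' @param decline_floor lowest post-onset expected time, seconds.
#' @param expansion_coupling seconds lost per unit of a per-animal repeat
#'   summary supplied at generation time (0 = uncoupled).
#' @param grip_fail_logit named list "zygosity|ogg1" -> c(intercept, slope);
#'   `default` used for unlisted genotypes.
#' @export
phenotype_params <- function(grand_mean = 91.9,
                             female_effect = 7.7,
                             ogg1ko_effect = 11,
                             hd_homo_effect = -23.7,
                             residual_sd = 20,
                             ceiling = 120,
                             decline_onset_week = c("Q150/Q150|+/+" = 15,
                                                    "Q150/Q150|-/-" = 45),
                             decline_rate = 5,
                             decline_floor = 25,
                             expansion_coupling = 0,
                             grip_fail_logit = list(
                               "Q150/Q150|+/+" = c(-1.3, 0.09),
                               "Q150/Q150|-/-" = c(-1.5, 0.07),
                               "Q150/wt|+/+" = c(-2.0, 0.05),
                               "Q150/wt|-/-" = c(-2.2, 0.045),
                               default = c(-2.5, 0.03)
                             )) {
  if (ceiling <= 0) stop_somex("ceiling must be > 0", class = "somex_config_error")
  if (residual_sd < 0) stop_somex("residual_sd must be >= 0",
                                  class = "somex_config_error")
  structure(
    list(grand_mean = grand_mean, female_effect = female_effect,
         ogg1ko_effect = ogg1ko_effect, hd_homo_effect = hd_homo_effect,
         residual_sd = residual_sd, ceiling = ceiling,
         decline_onset_week = decline_onset_week,
         decline_rate = decline_rate, decline_floor = decline_floor,
         expansion_coupling = expansion_coupling,
         grip_fail_logit = grip_fail_logit),
    class = "phenotype_params"
  )
}

#' Cohort configuration
#'
#' @param seed integer; identical configs (including seed) regenerate
#'   byte-identical cohorts.
#' @param animals_per_cell animals per (genotype, age-group) stratum.
#' @param genotypes data.frame with `hd_zygosity`, `ogg1_status`; defaults
#'   to the six genotypes of the analysis cross.
#' @param age_groups data.frame as [default_age_groups()].
#' @param tissues brain-region panel sampled at sacrifice.
#' @param inherited_mean,inherited_sd Gaussian law of the inherited
#'   disease-allele repeat count.
#' @param expansion_mean_table data.frame mapping
#'   (hd_zygosity, ogg1_status, tissue, age_group) to mean net repeat gain.
#' @param expansion_shape gamma shape of the repeat-gain magnitude (smaller
#'   = more right-skewed).
#' @param contraction_prob probability a somatic change is a contraction
#'   (sign flip); the configured means are net of contractions.
#' @param animal_cv coefficient of variation of the per-animal-per-tissue
#'   multiplicative heterogeneity on the stratum mean.
#' @param pcr_spread SD, in repeats, of the within-sample peak width (PCR /
#'   electrophoretic dispersion around each true repeat class).
#' @param stutter_decay,stutter_plus1 geometric stutter ladder ratios below
#'   and above the main peak.
#' @param trace_noise_cv multiplicative (lognormal) noise CV on rendered
#'   peak heights.
#' @param flank_bp,unit_bp size calibration shared by renderer and parser.
#' @param phenotype a [phenotype_params()] object.
#' @export
cohort_config <- function(seed = 1L,
                          animals_per_cell = 20L,
                          genotypes = NULL,
                          age_groups = default_age_groups(),
                          tissues = DEFAULT_TISSUES,
                          inherited_mean = 117,
                          inherited_sd = 12,
                          expansion_mean_table = NULL,
                          expansion_shape = 1.5,
                          contraction_prob = 0.05,
                          animal_cv = 0.4,
                          pcr_spread = 1.0,
                          stutter_decay = 0.35,
                          stutter_plus1 = 0.10,
                          trace_noise_cv = 0.05,
                          flank_bp = 80,
                          unit_bp = 3,
                          phenotype = phenotype_params()) {
  if (is.null(genotypes)) {
    genotypes <- expand.grid(
      hd_zygosity = c("wt/wt", "Q150/wt", "Q150/Q150"),
      ogg1_status = c("+/+", "-/-"),
      stringsAsFactors = FALSE
    )
  }
  if (!all(genotypes$hd_zygosity %in% HD_ZYGOSITIES) ||
      !all(genotypes$ogg1_status %in% OGG1_STATUSES)) {
    stop_somex("unknown genotype labels in `genotypes`",
               class = "somex_config_error")
  }
  if (is.null(expansion_mean_table)) {
    expansion_mean_table <- default_expansion_table(tissues, age_groups)
  }
  probs <- c(contraction_prob, stutter_decay, stutter_plus1)
  if (any(probs < 0) || any(probs > 1)) {
    stop_somex("probabilities/ratios must lie in [0, 1]",
               class = "somex_config_error")
  }
  if (contraction_prob >= 0.5) {
    stop_somex("contraction_prob must be < 0.5 for a positive net mean",
               class = "somex_config_error")
  }
  if (inherited_sd < 0) {
    stop_somex("inherited_sd must be >= 0", class = "somex_config_error")
  }
  if (!is_count(animals_per_cell)) {
    stop_somex("animals_per_cell must be a positive integer",
               class = "somex_config_error")
  }
  structure(
    list(seed = as.integer(seed), animals_per_cell = as.integer(animals_per_cell),
         genotypes = genotypes, age_groups = age_groups, tissues = tissues,
         inherited_mean = inherited_mean, inherited_sd = inherited_sd,
         expansion_mean_table = expansion_mean_table,
         expansion_shape = expansion_shape,
         contraction_prob = contraction_prob, animal_cv = animal_cv,
         pcr_spread = pcr_spread, stutter_decay = stutter_decay,
         stutter_plus1 = stutter_plus1, trace_noise_cv = trace_noise_cv,
         flank_bp = flank_bp, unit_bp = unit_bp, phenotype = phenotype),
    class = "cohort_config"
  )
}

#' Draw inherited disease-allele repeat counts
#'
#' Rounded Gaussian, floored at 1 repeat.
#' @param n number of draws.
#' @param mean,sd Gaussian parameters in repeat units.
#' @export
draw_inherited_alleles <- function(n, mean = 117, sd = 12) {
  if (sd < 0) stop_somex("sd must be >= 0", class = "somex_config_error")
  pmax(1L, as.integer(round_half_away(stats::rnorm(n, mean, sd))))
}

#' Analytic probability mass function of the somatic repeat change
#'
#' Magnitudes follow a gamma law discretized to the nearest integer; the
#' gamma mean is inflated to `mean / (1 - 2 * contraction_prob)` so the NET
#' mean change (after sign flips to contractions) equals `mean`.
#' @param mean net mean change, repeats (>= 0).
#' @param shape gamma shape.
#' @param contraction_prob probability of a contraction (< 0.5).
#' @return named numeric: names are signed integer changes, values sum to 1.
#' @export
somatic_delta_pmf <- function(mean, shape, contraction_prob = 0) {
  if (mean < 0) {
    stop_somex("configured mean change must be >= 0",
               class = "somex_config_error")
  }
  if (mean == 0) return(c(`0` = 1))
  mag_mean <- mean / (1 - 2 * contraction_prob)
  scale <- mag_mean / shape
  upper <- ceiling(stats::qgamma(1 - 1e-9, shape, scale = scale))
  n <- 0:upper
  hi <- stats::pgamma(n + 0.5, shape, scale = scale)
  lo <- stats::pgamma(pmax(n - 0.5, 0), shape, scale = scale)
  q <- hi - lo
  q <- q / sum(q)
  pos <- stats::setNames((1 - contraction_prob) * q, n)
  neg <- stats::setNames(contraction_prob * q[-1], -n[-1])
  pmf <- c(rev(neg), pos)
  pmf[pmf > 1e-12] / sum(pmf[pmf > 1e-12])
}

#' Sample somatic repeat changes
#'
#' Monte-Carlo counterpart of [somatic_delta_pmf()]; draws gamma magnitudes,
#' rounds to integers and flips signs with `contraction_prob`.
#' @inheritParams somatic_delta_pmf
#' @param n number of draws.
#' @export
draw_somatic_delta <- function(n, mean, shape, contraction_prob = 0) {
  if (mean < 0) {
    stop_somex("configured mean change must be >= 0",
               class = "somex_config_error")
  }
  if (mean == 0) return(integer(n))
  mag_mean <- mean / (1 - 2 * contraction_prob)
  g <- stats::rgamma(n, shape, scale = mag_mean / shape)
  d <- as.integer(round_half_away(g))
  flip <- stats::runif(n) < contraction_prob
  d[flip] <- -d[flip]
  d
}

# symmetric discrete Gaussian kernel over integers (within-sample spread)
discrete_kernel <- function(sd) {
  if (sd <= 0) return(c(`0` = 1))
  k <- ceiling(4 * sd)
  w <- stats::dnorm(-k:k, sd = sd)
  stats::setNames(w / sum(w), -k:k)
}

# convolve two named pmfs over integers
convolve_pmf <- function(a, b) {
  if (length(b) == 1L && names(b) == "0") return(a)
  xa <- as.integer(names(a)); xb <- as.integer(names(b))
  grid <- outer(xa, xb, `+`)
  mass <- outer(as.numeric(a), as.numeric(b))
  out <- tapply(as.numeric(mass), as.integer(grid), sum)
  stats::setNames(as.numeric(out), names(out))
}

# look up a stratum's configured mean change, erroring with the stratum name
lookup_expansion_mean <- function(config, zyg, ogg1, tissue, age_group) {
  tab <- config$expansion_mean_table
  hit <- tab$hd_zygosity == zyg & tab$ogg1_status == ogg1 &
    tab$tissue == tissue & tab$age_group == age_group
  if (!any(hit)) {
    stop_somex(
      "expansion_mean_table has no entry for stratum (%s, %s, %s, %s)",
      zyg, ogg1, tissue, age_group, class = "somex_config_error"
    )
  }
  tab$mean_delta[which(hit)[1L]]
}

#' Inherited (birth-reference) repeat distribution of an animal
#'
#' Equal-weight mixture of the animal's allele point masses convolved with
#' the within-sample spread kernel; this is the zero-change reference.
#' @param alleles integer repeat counts (one or two).
#' @param pcr_spread within-sample SD, repeats.
#' @export
inherited_distribution <- function(alleles, pcr_spread = 1.0) {
  if (length(alleles) == 0L) {
    stop_somex("animal carries no disease allele", class = "somex_config_error")
  }
  base <- table(alleles) / length(alleles)
  pmf <- stats::setNames(as.numeric(base), names(base))
  pmf <- convolve_pmf(pmf, discrete_kernel(pcr_spread))
  repeat_distribution(as.integer(names(pmf)), as.numeric(pmf))
}

#' Draw one animal's somatic repeat distribution for a tissue
#'
#' The stratum's configured mean is scaled by a per-animal-per-tissue gamma
#' heterogeneity factor (mean 1, CV `animal_cv`), turned into a discretized
#' right-skewed change law, shifted by each inherited allele (equal-weight
#' mixture for homozygotes) and convolved with the within-sample spread.
#' @param alleles the animal's inherited allele repeat counts.
#' @param zyg,ogg1,tissue,age_group stratum labels.
#' @param config a [cohort_config()].
#' @param mean_override optional mean change overriding the table lookup.
#' @return a [repeat_distribution()] over absolute repeat counts.
#' @export
draw_somatic_distribution <- function(alleles, zyg, ogg1, tissue, age_group,
                                      config, mean_override = NULL) {
  mu <- if (is.null(mean_override)) {
    lookup_expansion_mean(config, zyg, ogg1, tissue, age_group)
  } else mean_override
  if (mu < 0) {
    stop_somex("configured mean change must be >= 0",
               class = "somex_config_error")
  }
  h <- if (config$animal_cv > 0) {
    stats::rgamma(1, shape = 1 / config$animal_cv^2,
                  scale = config$animal_cv^2)
  } else 1
  delta <- somatic_delta_pmf(mu * h, config$expansion_shape,
                             config$contraction_prob)
  mix <- list()
  for (a in alleles) {
    shifted <- stats::setNames(as.numeric(delta),
                               as.integer(names(delta)) + a)
    mix[[length(mix) + 1L]] <- shifted
  }
  pmf <- Reduce(function(x, y) {
    all_keys <- sort(unique(c(as.integer(names(x)), as.integer(names(y)))))
    vx <- stats::setNames(numeric(length(all_keys)), all_keys)
    vx[names(x)] <- vx[names(x)] + x
    vx[names(y)] <- vx[names(y)] + y
    vx
  }, lapply(mix, function(m) m / length(mix)))
  pmf <- convolve_pmf(pmf, discrete_kernel(config$pcr_spread))
  repeat_distribution(as.integer(names(pmf)), as.numeric(pmf))
}

#' Render a repeat distribution as a fragment-analysis peak table
#'
#' Each repeat class n gives a main peak at `flank_bp + unit_bp * n` plus
#' stutter satellites one and two units below (heights decaying
#' geometrically by `stutter_decay`) and one unit above (`stutter_plus1`),
#' with multiplicative lognormal noise of CV `trace_noise_cv`.
#' @param dist a [repeat_distribution()].
#' @param config a [cohort_config()] supplying calibration and artifact
#'   parameters.
#' @param sample_id,animal_id,tissue identifiers written into the table.
#' @return a `peak_table` data.frame.
#' @export
render_trace <- function(dist, config, sample_id = "S1", animal_id = "A1",
                         tissue = "STR") {
  f <- dist$frequencies
  n <- as.integer(names(f))
  support <- seq(min(n) - 2L, max(n) + 1L)
  fv <- stats::setNames(numeric(length(support)), support)
  fv[names(f)] <- f
  get0s <- function(shift) {
    idx <- match(as.integer(support) + shift, as.integer(support))
    out <- fv[idx]
    out[is.na(out)] <- 0
    out
  }
  height <- fv + config$stutter_decay * get0s(1L) +
    config$stutter_decay^2 * get0s(2L) + config$stutter_plus1 * get0s(-1L)
  if (config$trace_noise_cv > 0) {
    sdlog <- sqrt(log(1 + config$trace_noise_cv^2))
    height <- height * stats::rlnorm(length(height), -sdlog^2 / 2, sdlog)
  }
  keep <- height > max(height) * 1e-9
  support <- support[keep]
  height <- as.numeric(height[keep]) * 1000
  out <- data.frame(
    sample_id = sample_id, animal_id = animal_id, tissue = tissue,
    size_bp = config$flank_bp + config$unit_bp * support,
    height = height, area = height * config$unit_bp,
    stringsAsFactors = FALSE
  )
  class(out) <- c("peak_table", "data.frame")
  out
}

# expected rotarod time for each animal (before daily noise), with effects
# centered over the cohort composition so grand_mean is the cohort average
expected_rotarod <- function(animals, pheno, coupling_values = NULL) {
  eff <- pheno$female_effect * (animals$sex == "F") +
    pheno$ogg1ko_effect * (animals$ogg1_status == "-/-") +
    pheno$hd_homo_effect * (animals$hd_zygosity == "Q150/Q150")
  mu <- pheno$grand_mean + eff - mean(eff)
  key <- paste(animals$hd_zygosity, animals$ogg1_status, sep = "|")
  onset <- pheno$decline_onset_week[key]
  decline <- ifelse(is.na(onset), 0,
                    pheno$decline_rate * pmax(0, animals$age_weeks - onset))
  declined <- mu - decline
  declined <- ifelse(decline > 0, pmax(declined, pmin(mu, pheno$decline_floor)),
                     declined)
  if (!is.null(coupling_values) && pheno$expansion_coupling != 0) {
    declined <- declined - pheno$expansion_coupling * coupling_values
  }
  declined
}

#' Generate rotarod and grip performance records
#'
#' Five consecutive daily sessions at each fixed speed (10 and 20 rpm),
#' three attempts per session with a `ceiling`-second cap. A day's best time
#' is drawn around the animal's expected value (SD `residual_sd`), the two
#' remaining attempts fall below it. One grip outcome per day: failure of
#' all of a day's grip attempts has the genotype- and age-dependent logit
#' probability in `grip_fail_logit`.
#' @param animals data.frame with `animal_id`, `sex`, `hd_zygosity`,
#'   `ogg1_status`, `age_weeks`.
#' @param pheno a [phenotype_params()] object.
#' @param coupling_values optional per-animal repeat summaries for
#'   `expansion_coupling`.
#' @return data.frame with columns `animal_id`, `day`, `attempt`,
#'   `speed_rpm`, `time_s`, `grip_pass`.
#' @export
generate_performance <- function(animals, pheno = phenotype_params(),
                                 coupling_values = NULL) {
  mu <- expected_rotarod(animals, pheno, coupling_values)
  n <- nrow(animals)
  key <- paste(animals$hd_zygosity, animals$ogg1_status, sep = "|")
  logit_tab <- pheno$grip_fail_logit
  grip_par <- t(vapply(key, function(k) {
    if (!is.null(logit_tab[[k]])) logit_tab[[k]] else logit_tab[["default"]]
  }, numeric(2)))
  rows <- vector("list", n)
  deficit_scale <- 0.75 * pheno$residual_sd
  for (i in seq_len(n)) {
    q_fail <- stats::plogis(grip_par[i, 1] + grip_par[i, 2] * animals$age_weeks[i])
    grip_day <- stats::runif(5) >= q_fail  # TRUE = held the bar that day
    per_speed <- lapply(c(10, 20), function(speed) {
      best <- pmin(pmax(stats::rnorm(5, mu[i], pheno$residual_sd), 0),
                   pheno$ceiling)
      times <- matrix(0, nrow = 5, ncol = 3)
      for (d in 1:5) {
        others <- if (deficit_scale > 0) {
          pmax(best[d] - stats::rexp(2, rate = 1 / deficit_scale), 0)
        } else rep(best[d], 2)
        slot <- sample.int(3, 1)
        times[d, slot] <- best[d]
        times[d, -slot] <- others
      }
      data.frame(
        animal_id = animals$animal_id[i],
        day = rep(1:5, each = 3),
        attempt = rep(1:3, times = 5),
        speed_rpm = speed,
        time_s = as.numeric(t(times)),
        grip_pass = rep(grip_day, each = 3),
        stringsAsFactors = FALSE
      )
    })
    rows[[i]] <- do.call(rbind, per_speed)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic cohort
#'
#' Every (genotype, age-group) stratum receives `animals_per_cell` animals
#' with sexes balanced to within one. Animals carrying a disease allele get
#' a birth-reference (tail) peak table with zero somatic change and one peak
#' table per tissue at the sacrifice age; all animals get performance
#' records. Regeneration with the same config (including seed) is identical.
#'
#' @param config a [cohort_config()].
#' @param render_peaks logical; set FALSE to skip trace rendering (for
#'   phenotype-only experiments).
#' @return An object of class `somex_cohort`: list with `animals`
#'   (metadata data.frame), `peaks` (one long `peak_table` data.frame
#'   including TAIL birth references), `performance`, and `config`.
#' @export
generate_cohort <- function(config = cohort_config(), render_peaks = TRUE) {
  with_seed(config$seed, {
    cells <- merge(config$genotypes, config$age_groups, by = NULL)
    n_cell <- config$animals_per_cell
    total <- nrow(cells) * n_cell
    sexes <- rep(c("M", "F"), length.out = n_cell)
    animals <- data.frame(
      animal_id = sprintf("A%05d", seq_len(total)),
      sex = rep(sexes, nrow(cells)),
      hd_zygosity = rep(cells$hd_zygosity, each = n_cell),
      ogg1_status = rep(cells$ogg1_status, each = n_cell),
      age_weeks = rep(cells$test_week, each = n_cell),
      age_group = rep(cells$label, each = n_cell),
      treatment_arm = "none",
      stringsAsFactors = FALSE
    )
    n_alleles <- c("wt/wt" = 0L, "Q150/wt" = 1L, "Q150/Q150" = 2L)
    k <- n_alleles[animals$hd_zygosity]
    alleles <- draw_inherited_alleles(sum(k), config$inherited_mean,
                                      config$inherited_sd)
    idx <- cumsum(k)
    animals$inherited_allele_1 <- NA_integer_
    animals$inherited_allele_2 <- NA_integer_
    has1 <- k >= 1L
    animals$inherited_allele_1[has1] <- alleles[idx[has1] - k[has1] + 1L]
    has2 <- k >= 2L
    animals$inherited_allele_2[has2] <- alleles[idx[has2]]
    peaks <- NULL
    if (render_peaks) {
      tabs <- list()
      for (i in which(k > 0L)) {
        al <- stats::na.omit(c(animals$inherited_allele_1[i],
                               animals$inherited_allele_2[i]))
        aid <- animals$animal_id[i]
        birth <- inherited_distribution(al, config$pcr_spread)
        tabs[[length(tabs) + 1L]] <- render_trace(
          birth, config, sample_id = paste0(aid, "_TAIL"),
          animal_id = aid, tissue = "TAIL"
        )
        for (t in config$tissues) {
          dist <- draw_somatic_distribution(
            al, animals$hd_zygosity[i], animals$ogg1_status[i], t,
            animals$age_group[i], config
          )
          tabs[[length(tabs) + 1L]] <- render_trace(
            dist, config, sample_id = paste0(aid, "_", t),
            animal_id = aid, tissue = t
          )
        }
      }
      peaks <- if (length(tabs)) do.call(rbind, tabs) else NULL
      if (!is.null(peaks)) class(peaks) <- c("peak_table", "data.frame")
    }
    performance <- generate_performance(animals, config$phenotype)
    structure(
      list(animals = animals, peaks = peaks, performance = performance,
           config = config),
      class = "somex_cohort"
    )
  })
}

#' @export
print.somex_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic cohort: %d animals, %d genotypes, %d age groups%s\n",
    nrow(x$animals), nrow(unique(x$animals[c("hd_zygosity", "ogg1_status")])),
    length(unique(x$animals$age_group)),
    if (is.null(x$peaks)) "" else
      sprintf(", %d peak-table samples", length(unique(x$peaks$sample_id)))
  ))
  invisible(x)
}

#' Write a cohort to a run directory
#'
#' Emits `metadata.csv`, `performance.csv`, one peak table per sample under
#' `peaks/`, and a `calibration.txt` sidecar recording `flank_bp`, the
#' repeat unit and the stutter ladder ratios.
#' @param cohort a `somex_cohort`.
#' @param dir output directory (created if missing).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "peaks"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$animals, file.path(dir, "metadata.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$performance, file.path(dir, "performance.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(cohort$peaks)) {
    for (sid in unique(cohort$peaks$sample_id)) {
      write_peak_table(cohort$peaks[cohort$peaks$sample_id == sid, ],
                       file.path(dir, "peaks", paste0(sid, ".csv")))
    }
  }
  cfg <- cohort$config
  writeLines(
    c(sprintf("flank_bp=%g", cfg$flank_bp),
      sprintf("unit_bp=%g", cfg$unit_bp),
      sprintf("stutter_decay=%g", cfg$stutter_decay),
      sprintf("stutter_plus1=%g", cfg$stutter_plus1)),
    file.path(dir, "calibration.txt")
  )
  invisible(dir)
}
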