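test_that("subject summaries aggregate volume, count and median eccentricity", {
  rec <- data.frame(
    subject_id = "S001", lesion_id = 1:3, volume_ml = c(0.1, 0.1, 0.1),
    eccentricity = c(1.5, 2.0, 4.0),
    lesion_class = c("non_punctuate", "non_punctuate", "non_punctuate"),
    stringsAsFactors = FALSE)
  meta <- data.frame(subject_id = "S001", icv = 1500)
  s <- subject_summary(rec, meta)
  all_row <- s[s$stratum == "all", ]
  expect_equal(all_row$wmh_volume_pct_icv, 0.02, tolerance = 1e-12)
  expect_equal(all_row$n_lesions, 3)
  expect_equal(all_row$median_eccentricity, 2.0)
  # empty punctuate stratum: n 0, median absent
  pd <- s[s$stratum == "punctuate_deep", ]
  expect_equal(pd$n_lesions, 0)
  expect_true(is.na(pd$median_eccentricity))
  # single lesion: median equals that lesion's value
  s1 <- subject_summary(rec[1, ], meta)
  expect_equal(s1$median_eccentricity[s1$stratum == "all"], 1.5)
  expect_error(subject_summary(rec, data.frame(subject_id = "S001", icv = 0)),
               "ICV")
})

test_that("natural-log transform scales volumes and rejects nonpositives", {
  expect_equal(nl_transform(0.0001), 0)
  expect_equal(nl_transform(0.0002), log(2), tolerance = 1e-12)
  expect_equal(nl_transform(40, scale = 1), log(40), tolerance = 1e-12)
  expect_true(all(diff(nl_transform(c(0.001, 0.002, 0.01))) > 0))
  expect_error(nl_transform(c(0.1, 0)), "positive")
})

test_that("group regression: null effect, closed form, singular design", {
  cohort <- fake_cohort(40)
  # identical outcome in both groups -> b = 0, beta = 0
  reg0 <- suppressWarnings(group_regression(rep(3.3, 40), cohort))
  expect_equal(reg0$b, 0)
  expect_equal(reg0$beta, 0)
  # covariate-free: b equals the difference in group means
  set.seed(2)
  y <- rnorm(40) + 0.8 * (cohort$group == "patient")
  reg <- group_regression(y, cohort, covariates = character(0))
  expect_equal(reg$b,
               mean(y[cohort$group == "patient"]) -
                 mean(y[cohort$group == "control"]),
               tolerance = 1e-9)
  expect_equal(sign(reg$beta), sign(reg$b))
  expect_lt(reg$b_ci[1], reg$b_ci[2])
  expect_equal(reg$beta, reg$b * sd(cohort$group == "patient") / sd(y),
               tolerance = 1e-12)
  # duplicated covariate -> singular design error naming the column
  expect_error(group_regression(y, cohort,
                                extra = data.frame(age_copy = cohort$age)),
               "singular design.*age_copy")
  # preconditions
  expect_error(group_regression(rnorm(5), fake_cohort(5)), "10")
  one_group <- fake_cohort(20)
  one_group$group <- "patient"
  expect_error(group_regression(rnorm(20), one_group), "both groups")
})

test_that("beta confidence intervals cover an injected effect at nominal rate", {
  n_sim <- 100
  delta <- 0.7
  covered <- signif_pos <- logical(n_sim)
  for (s in seq_len(n_sim)) {
    cohort <- fake_cohort(200, seed = 1000 + s)
    set.seed(2000 + s)
    ind <- as.integer(cohort$group == "patient")
    y <- delta * ind + 0.02 * (cohort$age - 71) + rnorm(200)
    reg <- group_regression(y, cohort)
    # truth on the beta scale
    truth <- delta * sd(ind) / sd(y)
    covered[s] <- reg$beta_ci[1] <= truth && truth <= reg$beta_ci[2]
    signif_pos[s] <- reg$p < 0.05 && reg$beta > 0
  }
  expect_gte(mean(covered), 0.90)
  expect_gte(mean(signif_pos), 0.95)  # delta = 0.7 SD at n = 200 is near-certain
})

test_that("secondary associations adjust correctly and control type I error", {
  n_sim <- 200
  cover0 <- logical(n_sim)
  for (s in seq_len(n_sim)) {
    cohort <- fake_cohort(60, seed = 3000 + s)
    set.seed(4000 + s)
    cohort$diabetes_duration <- runif(60, 1, 25)
    y <- rnorm(60)  # independent of the covariate
    reg <- secondary_association(y, "diabetes_duration", cohort)
    cover0[s] <- reg$beta_ci[1] <= 0 && 0 <= reg$beta_ci[2]
  }
  expect_gte(mean(cover0), 0.89)
  expect_lte(mean(cover0), 1.0)

  # injected slope: sign recovered
  cohort <- fake_cohort(80, seed = 99)
  set.seed(99)
  cohort$wm_volume <- rnorm(80, 30, 2)
  y <- -0.4 * cohort$wm_volume + rnorm(80)
  reg <- secondary_association(y, "wm_volume", cohort)
  expect_lt(reg$beta, 0)
  expect_lt(reg$p, 0.05)
  # ICV enters the design exactly for volume outcomes; a duplicate collides
  expect_error(
    secondary_association(y, "icv", cohort, outcome_is_volume = TRUE),
    "singular")
  expect_error(secondary_association(y, "nope", cohort), "missing")
})

test_that("per-lobe chi-square reproduces printed percentages and totals", {
  patients <- c(frontal = 594, temporal = 46, parietal = 213, occipital = 13)
  controls <- c(frontal = 561, temporal = 74, parietal = 234, occipital = 12)
  res <- lobe_chi2(patients, controls)
  expect_equal(sum(res$patient_n), 866)
  expect_equal(sum(res$control_n), 881)
  expect_equal(res$control_pct_rounded[res$lobe == "frontal"], 64)
  expect_equal(res$patient_pct_rounded[res$lobe == "parietal"], 25)
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  # percentages sum to 100 within rounding
  expect_equal(sum(res$patient_pct), 100, tolerance = 0.5)
  expect_equal(sum(res$control_pct), 100, tolerance = 0.5)
  # identical distributions -> p = 1 everywhere
  same <- lobe_chi2(patients, patients)
  expect_true(all(abs(same$p_value - 1) < 1e-12))
  expect_error(lobe_chi2(c(frontal = 0), c(frontal = 0)), "zero total")
})

test_that("per-lobe Mann-Whitney detects shifts and handles degenerate input", {
  x <- list(frontal = rep(c(1.8, 2.0, 2.2), 10))
  expect_equal(lobe_mwu(x, x)$p_value, 1, tolerance = 1e-9)
  set.seed(13)
  pat <- list(frontal = rnorm(100, 1))
  ctl <- list(frontal = rnorm(100, 0))
  expect_lt(lobe_mwu(pat, ctl)$p_value, 0.001)
  # single observation per side: a valid p-value
  p11 <- lobe_mwu(list(frontal = 2), list(frontal = 1))$p_value
  expect_true(is.finite(p11) && p11 > 0 && p11 <= 1)
  # empty side: skipped with a warning
  expect_warning(res <- lobe_mwu(list(frontal = c(1, 2)),
                                 list(frontal = numeric(0))), "skipped")
  expect_true(is.na(res$p_value))
})

test_that("feature distribution summaries: skewness and KS behaviour", {
  s <- feature_distribution_summary(c(-1, 0, 1))
  expect_equal(s$skewness, 0)
  expect_equal(s$mean, 0)
  expect_equal(c(s$min, s$max), c(-1, 1))
  expect_gt(feature_distribution_summary(c(0, 0, 0, 10))$skewness, 0)
  expect_true(is.na(feature_distribution_summary(rep(2, 10))$skewness))
  # heavy right tail rejected as normal; power check over repeated draws
  set.seed(17)
  rejections <- vapply(1:20, function(i)
    feature_distribution_summary(rlnorm(1000, 0, 1))$ks_p < 0.05, logical(1))
  expect_gte(mean(rejections), 0.95)
  # a clean normal sample is usually not rejected
  set.seed(18)
  expect_gt(feature_distribution_summary(rnorm(500))$ks_p, 0.05)
})

test_that("analyses are invariant to subject ordering", {
  cohort <- fake_cohort(30, seed = 77)
  set.seed(77)
  y <- rnorm(30) + 0.5 * (cohort$group == "patient")
  perm <- sample(30)
  a <- group_regression(y, cohort)
  b <- group_regression(y[perm], cohort[perm, ])
  expect_equal(a$b, b$b, tolerance = 1e-12)
  expect_equal(a$beta_ci, b$beta_ci, tolerance = 1e-12)
})
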