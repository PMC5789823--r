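#' Per-subject WMH summaries by lesion class
#'
#' Aggregates one subject's lesion records into the three analysis strata
#' (all lesions, non-punctuate, punctuate-deep): total lesion volume as a
#' percentage of intracranial volume, lesion count, and the median of the
#' per-lesion eccentricities (absent when the stratum is empty, in which case
#' the subject drops out of that stratum's analyses).
#'
#' @param records lesion records of one subject (data frame).
#' @param meta one-row subject metadata (needs `subject_id`, `icv` in ml).
#' @return data frame with one row per stratum: `subject_id`, `stratum`,
#'   `n_lesions`, `wmh_volume_pct_icv`, `median_eccentricity`.
#' @export
subject_summary <- function(records, meta) {
  if (!is.finite(meta$icv) || meta$icv <= 0)
    stop("subject_summary: ICV must be > 0", call. = FALSE)
  if (nrow(records) > 0 && !all(records$subject_id == meta$subject_id))
    stop("subject_summary: records belong to a different subject",
         call. = FALSE)
  one <- function(stratum, rows) {
    data.frame(
      subject_id = meta$subject_id, stratum = stratum,
      n_lesions = nrow(rows),
      wmh_volume_pct_icv = sum(rows$volume_ml) / meta$icv * 100,
      median_eccentricity = if (nrow(rows) >= 1)
        stats::median(rows$eccentricity, na.rm = TRUE) else NA_real_
    )
  }
  rbind(one("all", records),
        one("non_punctuate",
            records[records$lesion_class == "non_punctuate", , drop = FALSE]),
        one("punctuate_deep",
            records[records$lesion_class == "punctuate_deep", , drop = FALSE]))
}

#' Natural-log transform with pre-scaling
#'
#' `ln(value * scale)`. WMH volume fractions are first multiplied by 10000 so
#' the transformed values stay above 0 and the direction of effect is
#' retained; counts use `scale = 1`.
#'
#' @param values strictly positive numeric vector.
#' @param scale multiplicative pre-scaling (default 10000).
#' @return transformed values.
#' @export
nl_transform <- function(values, scale = 10000) {
  if (any(!is.finite(values)) || any(values <= 0))
    stop("nl_transform: values must be strictly positive", call. = FALSE)
  log(values * scale)
}

# shared OLS machinery: coefficient of interest with t-based 95% CI plus the
# standardized (beta) version b * SD(predictor) / SD(outcome)
ols_effect <- function(outcome, design, term) {
  keep <- stats::complete.cases(design) & is.finite(outcome)
  design <- design[keep, , drop = FALSE]
  outcome <- outcome[keep]
  df <- cbind(data.frame(.y = outcome), design)
  fit <- stats::lm(.y ~ ., data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("singular design; collinear column(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  ci <- stats::confint(fit, level = 0.95)
  rn <- names(cf)
  hit <- grep(paste0("^", term), rn)
  if (length(hit) != 1)
    stop("ols_effect: cannot identify term '", term, "'", call. = FALSE)
  b <- unname(cf[hit])
  b_ci <- unname(ci[hit, ])
  x <- stats::model.matrix(fit)[, hit]
  sy <- stats::sd(outcome)
  if (sy == 0) {
    # constant outcome: exact null effect, standardization undefined -> 0
    return(list(b = 0, b_ci = c(0, 0), beta = 0, beta_ci = c(0, 0),
                n = length(outcome), p = NA_real_))
  }
  ratio <- stats::sd(x) / sy
  list(b = b, b_ci = b_ci, beta = b * ratio, beta_ci = b_ci * ratio,
       n = length(outcome), p = summary(fit)$coefficients[hit, 4])
}

#' Group difference by age- and sex-adjusted linear regression
#'
#' Ordinary least squares of a per-subject outcome on the patient/control
#' indicator plus age and sex (and any extra covariates). `b` is the
#' unstandardized group coefficient (patient minus control) with its 95%
#' confidence interval; `beta` is the standardized coefficient
#' `b * SD(indicator) / SD(outcome)`, with the interval scaled identically.
#'
#' @param outcome numeric per-subject outcome.
#' @param cohort data frame aligned with `outcome`; needs `group`
#'   (`patient`/`control`), `age`, `sex`.
#' @param extra optional data frame of additional covariates.
#' @param covariates which cohort covariates to adjust for (default age and
#'   sex; `character(0)` gives the unadjusted two-group comparison, whose `b`
#'   equals the difference in group means).
#' @return list with `b`, `b_ci`, `beta`, `beta_ci`, `n`, `p`.
#' @export
group_regression <- function(outcome, cohort, extra = NULL,
                             covariates = c("age", "sex")) {
  stopifnot(length(outcome) == nrow(cohort))
  keep <- is.finite(outcome)
  if (sum(keep) < 10)
    stop("group_regression: fewer than 10 usable subjects", call. = FALSE)
  if (length(unique(cohort$group[keep])) < 2)
    stop("group_regression: both groups must be represented", call. = FALSE)
  design <- data.frame(group = as.integer(cohort$group == "patient"))
  if ("age" %in% covariates) design$age <- cohort$age
  if ("sex" %in% covariates) design$sex <- as.integer(cohort$sex == "M")
  if (!is.null(extra)) design <- cbind(design, extra)
  ols_effect(outcome, design, "group")
}

#' Association of a WMH feature with a covariate of interest
#'
#' Within-group analysis (e.g. patients only): OLS of a per-subject WMH
#' feature on a covariate of interest (white matter volume, gray matter
#' volume, diabetes duration, ...) adjusted for age and sex, and additionally
#' for intracranial volume exactly when the outcome is a volume.
#'
#' @param outcome numeric per-subject feature values.
#' @param covariate name of the covariate column in `cohort`.
#' @param cohort data frame aligned with `outcome` (needs `age`, `sex`,
#'   `icv`, and the covariate).
#' @param outcome_is_volume add ICV to the design (default `FALSE`).
#' @return as [group_regression()].
#' @export
secondary_association <- function(outcome, covariate, cohort,
                                  outcome_is_volume = FALSE) {
  if (!covariate %in% names(cohort))
    stop("secondary_association: covariate '", covariate,
         "' missing from cohort", call. = FALSE)
  design <- data.frame(coi = cohort[[covariate]],
                       age = cohort$age,
                       sex = as.integer(cohort$sex == "M"))
  if (outcome_is_volume) design$icv <- cohort$icv
  ols_effect(outcome, design, "coi")
}

#' Per-lobe lesion count comparison (chi-square)
#'
#' For each lobe, a 2x2 chi-square test without continuity correction of
#' lobe-vs-all-other-lobes against patient-vs-control, on lesion counts.
#' Percentages (count / group total x 100) are reported at full precision and
#' rounded half-up to integers for report tables.
#'
#' @param patient_counts,control_counts named nonnegative integer vectors
#'   (same lobe names).
#' @return data frame with counts, percentages and p-values per lobe.
#' @export
lobe_chi2 <- function(patient_counts, control_counts) {
  stopifnot(identical(names(patient_counts), names(control_counts)))
  if (any(patient_counts < 0) || any(control_counts < 0))
    stop("lobe_chi2: counts must be nonnegative", call. = FALSE)
  tp <- sum(patient_counts)
  tc <- sum(control_counts)
  if (tp == 0 || tc == 0)
    stop("lobe_chi2: zero total count in a group", call. = FALSE)
  p <- vapply(seq_along(patient_counts), function(i) {
    m <- matrix(c(patient_counts[i], tp - patient_counts[i],
                  control_counts[i], tc - control_counts[i]), nrow = 2)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0))
      suppressWarnings(stats::chisq.test(m, correct = FALSE)$p.value)
    else 1
  }, numeric(1))
  # zero statistic (identical proportions) yields p = 1 via the chi-square CDF
  p[!is.finite(p)] <- 1
  data.frame(
    lobe = names(patient_counts),
    patient_n = as.integer(patient_counts),
    patient_pct = patient_counts / tp * 100,
    patient_pct_rounded = floor(patient_counts / tp * 100 + 0.5),
    control_n = as.integer(control_counts),
    control_pct = control_counts / tc * 100,
    control_pct_rounded = floor(control_counts / tc * 100 + 0.5),
    p_value = p,
    row.names = NULL
  )
}

#' Per-lobe eccentricity comparison (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney U test per lobe of patient versus control lesion
#' eccentricities (exact for small untied samples, otherwise the normal
#' approximation with tie correction, as implemented by [stats::wilcox.test]).
#' Lobes with an empty side are skipped with a warning (`NA` p-value).
#'
#' @param patient_values,control_values named lists of numeric vectors (one
#'   element per lobe).
#' @return data frame with per-lobe sample sizes, medians and p-values.
#' @export
lobe_mwu <- function(patient_values, control_values) {
  stopifnot(identical(names(patient_values), names(control_values)))
  rows <- lapply(names(patient_values), function(lb) {
    x <- patient_values[[lb]]
    y <- control_values[[lb]]
    if (length(x) == 0 || length(y) == 0) {
      warning("lobe_mwu: lobe '", lb, "' skipped (empty group)",
              call. = FALSE)
      p <- NA_real_
    } else {
      p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
    }
    data.frame(lobe = lb, patient_n = length(x), control_n = length(y),
               patient_median = if (length(x)) stats::median(x) else NA_real_,
               control_median = if (length(y)) stats::median(y) else NA_real_,
               p_value = p)
  })
  do.call(rbind, rows)
}

#' Distribution summary of a per-lesion feature
#'
#' Mean, minimum, maximum, Fisher's moment-based skewness
#' `g1 = m3 / m2^(3/2)`, and the p-value of a one-sample Kolmogorov-Smirnov
#' test against a normal distribution with the sample mean and SD (plain KS
#' p-values with estimated parameters -- approximate, flagged as such).
#'
#' @param values numeric vector (>= 3 values for skewness, >= 8 for the KS
#'   test; below these the corresponding entries are `NA`).
#' @return one-row data frame: `n`, `mean`, `min`, `max`, `skewness`, `ks_p`.
#' @export
feature_distribution_summary <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  skew <- NA_real_
  if (n >= 3) {
    m <- mean(values)
    m2 <- mean((values - m)^2)
    skew <- if (m2 < 1e-24) NA_real_ else mean((values - m)^3) / m2^1.5
  }
  ks <- NA_real_
  if (n >= 8 && stats::sd(values) > 0)
    ks <- suppressWarnings(
      stats::ks.test(values, "pnorm", mean(values), stats::sd(values))$p.value)
  data.frame(n = n, mean = mean(values), min = min(values),
             max = max(values), skewness = skew, ks_p = ks)
}
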