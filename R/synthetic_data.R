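#' Configuration for the synthetic case-base generator
#'
#' The generator draws cases from a finite mixture with known latent
#' cluster structure: a cluster is sampled from `cluster_weights`, every
#' categorical/ordinal attribute from that cluster's probability table, and
#' restoration longevity from a truncated Normal whose mean and standard
#' deviation depend on both cluster and restoration type.  A
#' `censoring_fraction` of cases is censored (no observed failure): their
#' restoration date is synthesized backward from the reference date so the
#' recorded duration-to-present equals the drawn longevity; failed cases
#' get a restoration date uniform in `restoration_years` and a failure date
#' `longevity` later.
#'
#' @param n_cases number of cases to draw.
#' @param cluster_weights probability vector over latent clusters.
#' @param age_mean,age_sd per-cluster patient age (years) at restoration.
#' @param flag_prob named list: per boolean attribute, per-cluster
#'   probability of "yes".
#' @param severity_presence named list: per dental sickness, per-cluster
#'   probability the sickness is present (severity then drawn from
#'   `severity_profile`).
#' @param severity_profile per-cluster list of length-10 probability vectors
#'   over severities 1..10.
#' @param tooth_prob per-cluster probability vectors over tooth numbers 1..32.
#' @param level_prob per-cluster probability vectors over restoration level
#'   1..10.
#' @param composite_prob per-cluster probability that the (solution)
#'   restoration type is composite; also used for the prior restoration type.
#' @param longevity_mean,longevity_sd K x 2 matrices (columns `amalgam`,
#'   `composite`) of longevity means / standard deviations in years.
#' @param censoring_fraction fraction of cases with no observed failure.
#' @param reference_date the present date of the case-base.
#' @param restoration_years inclusive calendar-year window for failed
#'   restorations.
#' @param seed integer seed; the generator is fully reproducible from it.
#' @return A validated `generator_config` object.
#' @export
generator_config <- function(n_cases, cluster_weights, age_mean, age_sd,
                             flag_prob, severity_presence, severity_profile,
                             tooth_prob, level_prob, composite_prob,
                             longevity_mean, longevity_sd,
                             censoring_fraction = 0.6,
                             reference_date = as.Date("2014-06-30"),
                             restoration_years = c(1993L, 2003L),
                             seed = 1L) {
  K <- length(cluster_weights)
  fail <- function(field, why)
    abort_dcbr(sprintf("invalid generator config: %s (%s)", field, why),
               "dcbr_config_error", field = field)
  if (!is.numeric(n_cases) || n_cases < 0) fail("n_cases", "must be >= 0")
  if (K < 1L || abs(sum(cluster_weights) - 1) > 1e-8 ||
      any(cluster_weights < 0))
    fail("cluster_weights", "must be a probability vector")
  if (length(age_mean) != K || length(age_sd) != K || any(age_sd <= 0))
    fail("age_mean/age_sd", "need one positive sd per cluster")
  check_ptab <- function(tab, field, len = NULL) {
    for (k in seq_along(tab)) {
      p <- tab[[k]]
      if (!is.null(len) && length(p) != len) fail(field, "wrong length")
      if (any(p < 0) || abs(sum(p) - 1) > 1e-8) fail(field, "rows must sum to 1")
    }
  }
  for (nm in names(flag_prob))
    if (length(flag_prob[[nm]]) != K ||
        any(flag_prob[[nm]] < 0 | flag_prob[[nm]] > 1))
      fail(paste0("flag_prob$", nm), "probabilities per cluster")
  for (nm in names(severity_presence))
    if (length(severity_presence[[nm]]) != K ||
        any(severity_presence[[nm]] < 0 | severity_presence[[nm]] > 1))
      fail(paste0("severity_presence$", nm), "probabilities per cluster")
  check_ptab(severity_profile, "severity_profile", 10L)
  check_ptab(tooth_prob, "tooth_prob", 32L)
  check_ptab(level_prob, "level_prob", 10L)
  if (length(composite_prob) != K ||
      any(composite_prob < 0 | composite_prob > 1))
    fail("composite_prob", "one probability per cluster")
  longevity_mean <- as.matrix(longevity_mean)
  longevity_sd <- as.matrix(longevity_sd)
  if (!all(dim(longevity_mean) == c(K, 2L)) ||
      !all(dim(longevity_sd) == c(K, 2L)))
    fail("longevity_mean/longevity_sd", "must be K x 2 (amalgam, composite)")
  if (any(longevity_sd <= 0)) fail("longevity_sd", "must be > 0")
  if (censoring_fraction < 0 || censoring_fraction > 1)
    fail("censoring_fraction", "must be in [0, 1]")
  colnames(longevity_mean) <- colnames(longevity_sd) <- TYPE_LEVELS
  structure(list(
    n_cases = as.integer(n_cases), n_clusters = K,
    cluster_weights = cluster_weights, age_mean = age_mean, age_sd = age_sd,
    flag_prob = flag_prob, severity_presence = severity_presence,
    severity_profile = severity_profile, tooth_prob = tooth_prob,
    level_prob = level_prob, composite_prob = composite_prob,
    longevity_mean = longevity_mean, longevity_sd = longevity_sd,
    censoring_fraction = censoring_fraction,
    reference_date = as.Date(reference_date),
    restoration_years = as.integer(restoration_years),
    seed = as.integer(seed)), class = "generator_config")
}

#' Default generator configuration emulating the study case-base
#'
#' Three latent patient-profile clusters (young/low-wear, middle-aged,
#' older/high-wear) separated in more than five attributes (age, smoking,
#' drinking, gingivitis, abrasion, attrition, multicaries, blood pressure,
#' restoration level, tooth distribution, severity profile).  Composite
#' prevalence is about 93%; longevity means are 14/15/16 years for amalgam
#' and 8/9.5/11 years for composite across the clusters, with a 1.3-year
#' standard deviation.
#'
#' @param seed integer seed.
#' @param n_cases number of cases (default 3000).
#' @return A `generator_config`.
#' @export
default_casebase_config <- function(seed = 1L, n_cases = 3000L) {
  K <- 3L
  tooth1 <- rep(1, 32); tooth1[c(4:13, 20:29)] <- 3      # premolar-heavy
  tooth2 <- rep(1, 32)                                    # uniform
  tooth3 <- rep(1, 32); tooth3[c(1:3, 14:19, 30:32)] <- 4 # molar-heavy
  level1 <- c(6, 6, 6, 2, 2, 1, 1, 0.5, 0.5, 0.5)
  level2 <- c(1, 1, 2, 5, 5, 5, 4, 2, 1, 1)
  level3 <- c(0.5, 0.5, 1, 1, 2, 3, 4, 6, 6, 6)
  sev_mild <- c(5, 4, 3, 2, 1, 0.5, 0.25, 0.25, 0.25, 0.25)
  sev_mod  <- c(1, 2, 3, 4, 4, 3, 2, 1, 0.5, 0.5)
  sev_high <- c(0.25, 0.5, 1, 1, 2, 3, 4, 4, 4, 4)
  norm <- function(x) x / sum(x)
  base_flags <- list(
    infectious_disease = 0.03, liver_complaint = 0.02, aids = 0.005,
    allergic_pharmacology = 0.05, allergic_antibiotic = 0.04,
    allergic_analgesic = 0.02, allergic_anaesthetic = 0.01,
    allergic_metal = 0.03, allergic_latex = 0.02, mental_illness = 0.03,
    epilepsy = 0.01, malignant_tumors = 0.01,
    failure_fracture_restoration = 0.12, failure_fracture_tooth = 0.07,
    failure_accident = 0.03, failure_caries = 0.2)
  flag_prob <- c(list(
    smoke = c(0.15, 0.35, 0.55), drink = c(0.2, 0.45, 0.6),
    diabetes = c(0.02, 0.08, 0.2), high_blood_pressure = c(0.03, 0.15, 0.45),
    cardiac_disease = c(0.01, 0.05, 0.2),
    surgical_operation = c(0.05, 0.2, 0.45),
    family_history = c(0.2, 0.3, 0.4),
    aesthetic_importance = c(0.8, 0.6, 0.35)),
    lapply(base_flags, rep, K))
  severity_presence <- list(
    gingivitis = c(0.15, 0.4, 0.7), abrasion = c(0.1, 0.3, 0.6),
    attrition = c(0.1, 0.25, 0.55), amelogenesis = c(0.03, 0.03, 0.03),
    dentinogenesis = c(0.02, 0.02, 0.02), pressed_dental = c(0.05, 0.1, 0.15),
    multicaries = c(0.5, 0.25, 0.1), other_dental = c(0.05, 0.08, 0.12))
  generator_config(
    n_cases = n_cases,
    cluster_weights = c(0.45, 0.35, 0.20),
    age_mean = c(28, 45, 63), age_sd = c(7, 7, 7),
    flag_prob = flag_prob,
    severity_presence = severity_presence,
    severity_profile = list(norm(sev_mild), norm(sev_mod), norm(sev_high)),
    tooth_prob = list(norm(tooth1), norm(tooth2), norm(tooth3)),
    level_prob = list(norm(level1), norm(level2), norm(level3)),
    composite_prob = c(0.96, 0.93, 0.88),
    longevity_mean = rbind(c(14, 8), c(15, 9.5), c(16, 11)),
    longevity_sd = matrix(1.3, 3, 2),
    censoring_fraction = 0.6,
    seed = as.integer(seed))
}

rtruncnorm0 <- function(n, mean, sd, lower = 0.05) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower)
  tries <- 0L
  while (length(bad) > 0L && tries < 50L) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] < lower]
    tries <- tries + 1L
  }
  pmax(x, lower)
}

#' Generate a synthetic case-base with known cluster labels
#'
#' @param config a [generator_config()] (for example
#'   [default_casebase_config()]).
#' @return A list with elements `casebase` (a validated [casebase()]) and
#'   `labels` (the true cluster index of each case).
#' @export
#' @examples
#' gen <- generate_casebase(default_casebase_config(seed = 7, n_cases = 50))
#' print(gen$casebase)
generate_casebase <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_cases
  if (n == 0L)
    return(list(casebase = casebase(empty_cases(), config$reference_date),
                labels = integer(0)))
  K <- config$n_clusters
  with_seed(config$seed, {
    z <- sample.int(K, n, replace = TRUE, prob = config$cluster_weights)

    draw_flag <- function(p_by_cluster)
      stats::runif(n) < p_by_cluster[z]
    draw_cat <- function(prob_list, m) {
      out <- integer(n)
      for (k in seq_len(K)) {
        idx <- which(z == k)
        if (length(idx) > 0L)
          out[idx] <- sample.int(m, length(idx), replace = TRUE,
                                 prob = prob_list[[k]])
      }
      out
    }

    type <- ifelse(stats::runif(n) < config$composite_prob[z],
                   "composite", "amalgam")
    mu <- config$longevity_mean[cbind(z, match(type, TYPE_LEVELS))]
    sg <- config$longevity_sd[cbind(z, match(type, TYPE_LEVELS))]
    longevity_days <- round(rtruncnorm0(n, mu, sg) * DAYS_PER_YEAR)

    censored <- stats::runif(n) < config$censoring_fraction
    window_start <- as.Date(sprintf("%d-01-01", config$restoration_years[1L]))
    window_end <- as.Date(sprintf("%d-12-31", config$restoration_years[2L]))
    restoration_date <- window_start +
      floor(stats::runif(n) * (as.numeric(window_end - window_start) + 1))
    # censored: duration-to-present equals the drawn longevity
    restoration_date[censored] <- config$reference_date -
      longevity_days[censored]
    early <- censored & restoration_date < window_start
    if (any(early)) {                       # clamp into the collection window
      restoration_date[early] <- window_start
      longevity_days[early] <-
        as.numeric(config$reference_date - window_start)
    }

    age_years <- pmax(stats::rnorm(n, config$age_mean[z], config$age_sd[z]), 12)
    date_of_birth <- restoration_date - round(age_years * DAYS_PER_YEAR)

    # prior restoration history reflects the patient profile (cluster), not
    # the solution of the current case
    prior_mu <- 0.85 * rowMeans(config$longevity_mean)[z]
    prior_longevity_days <-
      round(rtruncnorm0(n, prior_mu, sg * 1.2) * DAYS_PER_YEAR)
    prior_gap_days <- prior_longevity_days +
      round(stats::runif(n, 0, 2) * DAYS_PER_YEAR)
    prior_restoration_date <- restoration_date - prior_gap_days

    cases <- data.frame(
      patient_number = sample.int(max(1L, ceiling(n / 2)), n, replace = TRUE),
      sex = ifelse(stats::runif(n) < 0.5, "female", "male"),
      stringsAsFactors = FALSE)
    cases$smoke <- draw_flag(config$flag_prob$smoke)
    cases$drink <- draw_flag(config$flag_prob$drink)
    cases$date_of_birth <- date_of_birth
    for (col in SEVERITY_COLS) {
      present <- draw_flag(config$severity_presence[[col]])
      sev <- draw_cat(config$severity_profile, 10L)
      cases[[col]] <- ifelse(present, sev, 0L)
    }
    for (col in SICKNESS_COLS) cases[[col]] <- draw_flag(config$flag_prob[[col]])
    cases$tooth_number <- draw_cat(config$tooth_prob, 32L)
    cases$prior_restoration_date <- prior_restoration_date
    cases$prior_restoration_longevity <- prior_longevity_days / DAYS_PER_YEAR
    cases$prior_restoration_type <-
      ifelse(stats::runif(n) < config$composite_prob[z], "composite", "amalgam")
    cases$restoration_level <- draw_cat(config$level_prob, 10L)
    for (col in c("failure_fracture_restoration", "failure_fracture_tooth",
                  "failure_accident", "failure_caries"))
      cases[[col]] <- draw_flag(config$flag_prob[[col]])
    cases$aesthetic_importance <- draw_flag(config$flag_prob$aesthetic_importance)
    cases$restoration_date <- restoration_date
    cases$restoration_longevity <- longevity_days / DAYS_PER_YEAR
    cases$restoration_type <- type
    cases$failed <- !censored
    cases$censored <- censored

    # (patient, tooth, restoration date) must be a unique key
    key <- paste(cases$patient_number, cases$tooth_number,
                 cases$restoration_date)
    dup <- which(duplicated(key))
    guard <- 0L
    while (length(dup) > 0L && guard < 100L) {
      cases$tooth_number[dup] <- sample.int(32L, length(dup), replace = TRUE)
      key <- paste(cases$patient_number, cases$tooth_number,
                   cases$restoration_date)
      dup <- which(duplicated(key))
      guard <- guard + 1L
    }

    list(casebase = casebase(cases, config$reference_date), labels = z)
  })
}
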