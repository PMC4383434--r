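#' The 43-attribute dental restoration case schema
#'
#' One case describes one restored posterior tooth: 41 problem attributes
#' (patient demographics and habits, dental and systemic sicknesses, tooth
#' identity, prior restoration history, failure-cause flags, aesthetic
#' importance, restoration date) plus a 2-attribute solution (restoration
#' type, restoration longevity).  Attribute 1 (patient number) is an
#' identifier and never enters model encodings.
#'
#' @return A data.frame with one row per attribute and columns `name`,
#'   `index`, `kind` (one of `identifier`, `boolean`, `ordinal_1_10`,
#'   `nominal`, `date`, `real`) and `role` (`problem` or `solution`).
#' @export
#' @examples
#' sch <- restoration_schema()
#' table(sch$role)
restoration_schema <- function() {
  attrs <- list(
    list("patient_number", "identifier"),
    list("sex", "nominal"),
    list("smoke", "boolean"),
    list("drink", "boolean"),
    list("date_of_birth", "date"),
    list("gingivitis", "ordinal_1_10"),
    list("abrasion", "ordinal_1_10"),
    list("attrition", "ordinal_1_10"),
    list("amelogenesis", "ordinal_1_10"),
    list("dentinogenesis", "ordinal_1_10"),
    list("pressed_dental", "ordinal_1_10"),
    list("multicaries", "ordinal_1_10"),
    list("other_dental", "ordinal_1_10"),
    list("diabetes", "boolean"),
    list("high_blood_pressure", "boolean"),
    list("cardiac_disease", "boolean"),
    list("infectious_disease", "boolean"),
    list("liver_complaint", "boolean"),
    list("aids", "boolean"),
    list("allergic_pharmacology", "boolean"),
    list("allergic_antibiotic", "boolean"),
    list("allergic_analgesic", "boolean"),
    list("allergic_anaesthetic", "boolean"),
    list("allergic_metal", "boolean"),
    list("allergic_latex", "boolean"),
    list("mental_illness", "boolean"),
    list("epilepsy", "boolean"),
    list("malignant_tumors", "boolean"),
    list("surgical_operation", "boolean"),
    list("family_history", "boolean"),
    list("tooth_number", "nominal"),
    list("prior_restoration_date", "date"),
    list("prior_restoration_longevity", "real"),
    list("prior_restoration_type", "nominal"),
    list("restoration_level", "ordinal_1_10"),
    list("failure_fracture_restoration", "boolean"),
    list("failure_fracture_tooth", "boolean"),
    list("failure_accident", "boolean"),
    list("failure_caries", "boolean"),
    list("aesthetic_importance", "boolean"),
    list("restoration_date", "date"),
    list("restoration_longevity", "date"),
    list("restoration_type", "nominal")
  )
  data.frame(
    name  = vapply(attrs, `[[`, "", 1L),
    index = seq_along(attrs),
    kind  = vapply(attrs, `[[`, "", 2L),
    role  = c(rep("problem", 41L), rep("solution", 2L)),
    stringsAsFactors = FALSE
  )
}

SEVERITY_COLS <- c("gingivitis", "abrasion", "attrition", "amelogenesis",
                   "dentinogenesis", "pressed_dental", "multicaries",
                   "other_dental")
SICKNESS_COLS <- c("diabetes", "high_blood_pressure", "cardiac_disease",
                   "infectious_disease", "liver_complaint", "aids",
                   "allergic_pharmacology", "allergic_antibiotic",
                   "allergic_analgesic", "allergic_anaesthetic",
                   "allergic_metal", "allergic_latex", "mental_illness",
                   "epilepsy", "malignant_tumors", "surgical_operation",
                   "family_history")
FLAG_COLS <- c("smoke", "drink", SICKNESS_COLS,
               "failure_fracture_restoration", "failure_fracture_tooth",
               "failure_accident", "failure_caries", "aesthetic_importance")
TYPE_LEVELS <- c("amalgam", "composite")

#' Construct a case-base from a typed data.frame
#'
#' @param cases data.frame with one row per case using the internal column
#'   types: `Date` for date attributes, integer severities 0--10 (0 = the
#'   sickness is absent), logical flags, `restoration_longevity` in fractional
#'   years, and logical `failed`.
#' @param reference_date the "present" date against which censored
#'   longevities are measured.
#' @param validate validate every row (default `TRUE`).
#' @return An object of class `casebase`.
#' @export
casebase <- function(cases, reference_date, validate = TRUE) {
  reference_date <- as.Date(reference_date)
  if (!"censored" %in% names(cases) && "failed" %in% names(cases))
    cases$censored <- !cases$failed
  cb <- structure(list(cases = cases, schema = restoration_schema(),
                       reference_date = reference_date),
                  class = "casebase")
  if (validate && nrow(cases) > 0L) validate_casebase(cb)
  cb
}

#' @export
print.casebase <- function(x, ...) {
  cat(sprintf("Dental restoration case-base: %d cases, %d patients\n",
              nrow(x$cases), length(unique(x$cases$patient_number))))
  cat(sprintf("Reference date: %s\n", format(x$reference_date)))
  if (nrow(x$cases) > 0L) {
    tab <- table(x$cases$restoration_type)
    cat("Restoration types:", paste(sprintf("%s=%d", names(tab), tab),
                                    collapse = ", "), "\n")
    cat(sprintf("Censored (no observed failure): %d (%.0f%%)\n",
                sum(x$cases$censored), 100 * mean(x$cases$censored)))
  }
  invisible(x)
}

#' @export
summary.casebase <- function(object, ...) {
  cc <- object$cases
  out <- list(n = nrow(cc), reference_date = object$reference_date)
  if (nrow(cc) > 0L) {
    out$longevity_by_type <- tapply(cc$restoration_longevity,
                                    cc$restoration_type, mean)
    out$censored_fraction <- mean(cc$censored)
    out$years <- range(as.integer(format(cc$restoration_date, "%Y")))
  }
  structure(out, class = "summary.casebase")
}

#' @export
print.summary.casebase <- function(x, ...) {
  cat(sprintf("Case-base of %d cases (reference date %s)\n", x$n,
              format(x$reference_date)))
  if (x$n > 0L) {
    cat(sprintf("Restoration years %d-%d; censored fraction %.2f\n",
                x$years[1], x$years[2], x$censored_fraction))
    cat("Mean longevity (years):",
        paste(sprintf("%s %.1f", names(x$longevity_by_type),
                      x$longevity_by_type), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.casebase <- function(x) nrow(x$cases)

# -- validation ---------------------------------------------------------------

row_error <- function(row, column, value, why) {
  abort_dcbr(sprintf("invalid case: row %d, column '%s', value '%s' (%s)",
                     row, column, paste(format(value), collapse = ","), why),
             "dcbr_validation_error", row = row, column = column)
}

#' Validate every case in a case-base
#'
#' Checks attribute domains (tooth number 1--32, restoration level 1--10,
#' severities 0--10, known factor levels), date ordering
#' (birth <= restoration date, prior restoration <= restoration,
#' restoration <= failure/reference date), nonnegative longevity, and
#' uniqueness of the (patient, tooth, restoration date) case key.
#'
#' @param cb a [casebase()].
#' @return `cb` invisibly; signals a validation error describing the first
#'   offending row, column and value otherwise.
#' @export
validate_casebase <- function(cb) {
  cc <- cb$cases
  need <- c(restoration_schema()$name, "failed", "censored")
  miss <- setdiff(need, names(cc))
  if (length(miss) > 0L)
    abort_dcbr(paste("case-base is missing columns:",
                     paste(miss, collapse = ", ")), "dcbr_schema_error")
  n <- nrow(cc)
  if (n == 0L) return(invisible(cb))

  check_range <- function(col, lo, hi) {
    v <- cc[[col]]
    bad <- which(is.na(v) | v < lo | v > hi)
    if (length(bad) > 0L)
      row_error(bad[1L], col, v[bad[1L]], sprintf("must be in [%d, %d]", lo, hi))
  }
  check_range("tooth_number", 1L, 32L)
  check_range("restoration_level", 1L, 10L)
  for (col in SEVERITY_COLS) check_range(col, 0L, 10L)

  check_levels <- function(col, levels) {
    v <- as.character(cc[[col]])
    bad <- which(is.na(v) | !(v %in% levels))
    if (length(bad) > 0L)
      row_error(bad[1L], col, v[bad[1L]],
                paste("must be one of", paste(levels, collapse = "/")))
  }
  check_levels("sex", c("female", "male"))
  check_levels("restoration_type", TYPE_LEVELS)
  check_levels("prior_restoration_type", TYPE_LEVELS)

  for (col in c(FLAG_COLS, "failed", "censored")) {
    v <- cc[[col]]
    bad <- which(is.na(v) | !is.logical(v))
    if (length(bad) > 0L) row_error(bad[1L], col, v[bad[1L]], "must be yes/no")
  }

  for (col in c("date_of_birth", "prior_restoration_date", "restoration_date")) {
    bad <- which(is.na(cc[[col]]))
    if (length(bad) > 0L) row_error(bad[1L], col, NA, "invalid date")
  }
  bad <- which(cc$date_of_birth > cc$restoration_date)
  if (length(bad) > 0L)
    row_error(bad[1L], "date_of_birth", cc$date_of_birth[bad[1L]],
              "birth after restoration date")
  bad <- which(cc$prior_restoration_date > cc$restoration_date)
  if (length(bad) > 0L)
    row_error(bad[1L], "prior_restoration_date",
              cc$prior_restoration_date[bad[1L]],
              "prior restoration after current restoration")
  bad <- which(is.na(cc$restoration_longevity) | cc$restoration_longevity < 0 |
                 cc$prior_restoration_longevity < 0)
  if (length(bad) > 0L)
    row_error(bad[1L], "restoration_longevity",
              cc$restoration_longevity[bad[1L]], "longevity must be >= 0")
  bad <- which(!cc$failed &
                 cc$restoration_date > cb$reference_date)
  if (length(bad) > 0L)
    row_error(bad[1L], "restoration_date", cc$restoration_date[bad[1L]],
              "restoration after the reference date")

  key <- paste(cc$patient_number, cc$tooth_number, cc$restoration_date)
  if (anyDuplicated(key) > 0L) {
    d <- which(duplicated(key))[1L]
    row_error(d, "patient_number", cc$patient_number[d],
              "duplicate (patient, tooth, restoration date) key")
  }
  invisible(cb)
}

# -- longevity ----------------------------------------------------------------

#' Restoration longevity in fractional years
#'
#' Longevity runs from the restoration date to the failure date when the
#' restoration failed, or to the present (reference) date when it did not;
#' in the latter case the value is right-censored.  A 365.25-day year is
#' used throughout.
#'
#' @param restoration_date,end_date `Date` (or coercible) vectors; `end_date`
#'   is the failure date for failed restorations and the reference date for
#'   surviving ones.
#' @param failed logical vector.
#' @return A data.frame with columns `longevity_years` and `censored`
#'   (`censored = !failed`).
#' @export
#' @examples
#' compute_longevity("2000-01-01", "2010-01-01", failed = TRUE)
compute_longevity <- function(restoration_date, end_date, failed) {
  restoration_date <- as.Date(restoration_date)
  end_date <- as.Date(end_date)
  if (any(end_date < restoration_date))
    abort_dcbr("end_date precedes restoration_date", "dcbr_date_order_error")
  data.frame(
    longevity_years = as.numeric(end_date - restoration_date) / DAYS_PER_YEAR,
    censored = !failed
  )
}

# -- CSV I/O ------------------------------------------------------------------

yn <- function(x) ifelse(x, "yes", "no")
parse_yn <- function(x, col) {
  out <- rep(NA, length(x))
  out[x %in% c("yes", "y", "true", "1")] <- TRUE
  out[x %in% c("no", "n", "false", "0")] <- FALSE
  out
}

#' Read a case-base from its CSV interchange format
#'
#' The file is UTF-8 comma-separated with a header naming all 43 schema
#' attributes (snake_case) plus `failed`.  Booleans are `yes`/`no`, dates
#' ISO-8601, severities empty when the sickness is absent and 1--10
#' otherwise, and `restoration_longevity` holds the failure date for failed
#' restorations and is empty for surviving (censored) ones, whose longevity
#' is computed against `reference_date`.
#'
#' @param path path to the CSV file.
#' @param reference_date the present date used for censored longevities.
#' @return A validated [casebase()].
#' @export
load_casebase <- function(path, reference_date) {
  if (!file.exists(path))
    abort_dcbr(paste("no such file:", path), "dcbr_io_error")
  reference_date <- as.Date(reference_date)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  sch <- restoration_schema()
  expected <- c(sch$name, "failed")
  missing_cols <- setdiff(expected, names(raw))
  unknown_cols <- setdiff(names(raw), expected)
  if (length(missing_cols) > 0L || length(unknown_cols) > 0L)
    abort_dcbr(sprintf(
      "case-base header mismatch; missing: [%s]; unknown: [%s]",
      paste(missing_cols, collapse = ", "),
      paste(unknown_cols, collapse = ", ")), "dcbr_schema_error")
  n <- nrow(raw)
  if (n == 0L) return(casebase(empty_cases(), reference_date))

  parse_date_col <- function(col, allow_empty = FALSE) {
    v <- raw[[col]]
    out <- as.Date(rep(NA_integer_, n), origin = "1970-01-01")
    nonempty <- !(v == "")
    parsed <- as.Date(v[nonempty], format = "%Y-%m-%d")
    bad <- which(is.na(parsed))
    if (length(bad) > 0L)
      row_error(which(nonempty)[bad[1L]], col, v[nonempty][bad[1L]],
                "not an ISO-8601 date")
    out[nonempty] <- parsed
    if (!allow_empty && any(!nonempty))
      row_error(which(!nonempty)[1L], col, "", "date may not be empty")
    out
  }
  parse_int_col <- function(col) {
    v <- raw[[col]]
    out <- suppressWarnings(as.integer(v))
    bad <- which(is.na(out))
    if (length(bad) > 0L) row_error(bad[1L], col, v[bad[1L]], "not an integer")
    out
  }
  parse_severity <- function(col) {
    v <- raw[[col]]
    out <- integer(n)
    nonempty <- v != "" & tolower(v) != "no"
    parsed <- suppressWarnings(as.integer(v[nonempty]))
    bad <- which(is.na(parsed) | parsed < 1L | parsed > 10L)
    if (length(bad) > 0L)
      row_error(which(nonempty)[bad[1L]], col, v[nonempty][bad[1L]],
                "severity must be empty (absent) or 1..10")
    out[nonempty] <- parsed
    out
  }
  parse_flag <- function(col) {
    v <- parse_yn(tolower(raw[[col]]), col)
    bad <- which(is.na(v))
    if (length(bad) > 0L)
      row_error(bad[1L], col, raw[[col]][bad[1L]], "must be yes/no")
    v
  }

  cases <- data.frame(
    patient_number = parse_int_col("patient_number"),
    sex = tolower(raw$sex),
    stringsAsFactors = FALSE
  )
  cases$smoke <- parse_flag("smoke")
  cases$drink <- parse_flag("drink")
  cases$date_of_birth <- parse_date_col("date_of_birth")
  for (col in SEVERITY_COLS) cases[[col]] <- parse_severity(col)
  for (col in SICKNESS_COLS) cases[[col]] <- parse_flag(col)
  cases$tooth_number <- parse_int_col("tooth_number")
  cases$prior_restoration_date <- parse_date_col("prior_restoration_date")
  cases$prior_restoration_longevity <- {
    v <- suppressWarnings(as.numeric(raw$prior_restoration_longevity))
    bad <- which(is.na(v))
    if (length(bad) > 0L)
      row_error(bad[1L], "prior_restoration_longevity",
                raw$prior_restoration_longevity[bad[1L]], "not a number")
    v
  }
  cases$prior_restoration_type <- tolower(raw$prior_restoration_type)
  cases$restoration_level <- parse_int_col("restoration_level")
  for (col in c("failure_fracture_restoration", "failure_fracture_tooth",
                "failure_accident", "failure_caries", "aesthetic_importance"))
    cases[[col]] <- parse_flag(col)
  cases$restoration_date <- parse_date_col("restoration_date")
  cases$failed <- parse_flag("failed")
  end_date <- parse_date_col("restoration_longevity", allow_empty = TRUE)
  bad <- which(cases$failed & is.na(end_date))
  if (length(bad) > 0L)
    row_error(bad[1L], "restoration_longevity", "",
              "failed restorations need a failure date")
  end_date[!cases$failed] <- reference_date
  lv <- compute_longevity(cases$restoration_date, end_date, cases$failed)
  cases$restoration_longevity <- lv$longevity_years
  cases$censored <- lv$censored
  cases$restoration_type <- tolower(raw$restoration_type)

  casebase(cases[, c(restoration_schema()$name, "failed", "censored")],
           reference_date)
}

#' Write a case-base to the CSV interchange format
#'
#' Inverse of [load_casebase()]: `load_casebase(save_casebase(cb, p), ref)`
#' reproduces `cb` field-by-field (longevities are stored as dates, so they
#' round-trip exactly when they were derived from dates, as all generated
#' and loaded case-bases are).
#'
#' @param cb a [casebase()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_casebase <- function(cb, path) {
  cc <- cb$cases
  sch <- restoration_schema()
  out <- data.frame(row.names = seq_len(max(1L, nrow(cc))))[seq_len(nrow(cc)), ,
                                                            drop = FALSE]
  out <- as.data.frame(matrix("", nrow = nrow(cc), ncol = 0L))
  for (col in sch$name) {
    out[[col]] <- if (nrow(cc) == 0L) character(0) else switch(
      col,
      restoration_longevity = {
        end <- cc$restoration_date +
          as.integer(round(cc$restoration_longevity * DAYS_PER_YEAR))
        ifelse(cc$failed, format(end, "%Y-%m-%d"), "")
      },
      prior_restoration_longevity =
        format(cc[[col]], digits = 15, scientific = FALSE, trim = TRUE),
      if (col %in% FLAG_COLS) yn(cc[[col]])
      else if (col %in% SEVERITY_COLS) ifelse(cc[[col]] == 0L, "",
                                              as.character(cc[[col]]))
      else if (sch$kind[sch$name == col] == "date") format(cc[[col]], "%Y-%m-%d")
      else as.character(cc[[col]])
    )
  }
  out$failed <- if (nrow(cc) == 0L) character(0) else yn(cc$failed)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    abort_dcbr(paste("cannot write case-base:", conditionMessage(ok)),
               "dcbr_io_error")
  invisible(path)
}

empty_cases <- function() {
  sch <- restoration_schema()
  cols <- list()
  for (i in seq_len(nrow(sch))) {
    col <- sch$name[i]
    cols[[col]] <-
      if (col %in% FLAG_COLS) logical(0)
      else if (col %in% SEVERITY_COLS) integer(0)
      else switch(sch$kind[i],
                  identifier = integer(0),
                  date = as.Date(character(0)),
                  real = numeric(0),
                  ordinal_1_10 = integer(0),
                  nominal = character(0))
  }
  cols$tooth_number <- integer(0)
  cols$restoration_longevity <- numeric(0)
  cols$failed <- logical(0)
  cols$censored <- logical(0)
  as.data.frame(cols, stringsAsFactors = FALSE)
}

# -- model encodings ----------------------------------------------------------

# Severities (0 = absent, 1..10 when present) are zero-inflated ordinals:
# they go into the categorical block, where a category table models the
# zero mass exactly; a Gaussian factor would reward variance-collapsed
# splits on the zeros instead of the latent patient clusters.
ENC_CAT <- c("sex", "smoke", "drink", SEVERITY_COLS, SICKNESS_COLS,
             "tooth_number", "restoration_level",
             "prior_restoration_type", "failure_fracture_restoration",
             "failure_fracture_tooth", "failure_accident", "failure_caries",
             "aesthetic_importance")
ENC_NUM <- c("age_at_restoration", "prior_restoration_longevity")

cat_levels_for <- function(col) {
  if (col == "sex") c("female", "male")
  else if (col == "tooth_number") as.character(1:32)
  else if (col %in% SEVERITY_COLS) as.character(0:10)
  else if (col == "restoration_level") as.character(1:10)
  else if (col %in% c("prior_restoration_type", "restoration_type")) TYPE_LEVELS
  else c("no", "yes")
}

derived_numeric <- function(cc) {
  data.frame(
    age_at_restoration = as.numeric(cc$restoration_date - cc$date_of_birth) /
      DAYS_PER_YEAR,
    prior_restoration_longevity = as.numeric(cc$prior_restoration_longevity)
  )
}

# Integer-coded categorical matrix + numeric matrix for the problem
# descriptor.  Dates are never emitted raw: they enter as durations (age at
# restoration, years since the prior restoration).  The current
# restoration's calendar date is an administrative timestamp used for
# reports and year-stratified splits, not a patient attribute, so it is
# not encoded.
encode_mixed <- function(cb, include_type = FALSE) {
  cc <- if (inherits(cb, "casebase")) cb$cases else cb
  der <- derived_numeric(cc)
  cat_cols <- ENC_CAT
  if (include_type) cat_cols <- c(cat_cols, "restoration_type")
  cat_mat <- matrix(0L, nrow(cc), length(cat_cols),
                    dimnames = list(NULL, cat_cols))
  levels <- list()
  for (col in cat_cols) {
    lv <- cat_levels_for(col)
    v <- cc[[col]]
    chr <- if (is.logical(v)) yn(v) else as.character(v)
    code <- match(chr, lv)
    cat_mat[, col] <- code
    levels[[col]] <- lv
  }
  num_mat <- matrix(0, nrow(cc), length(ENC_NUM),
                    dimnames = list(NULL, ENC_NUM))
  for (col in ENC_NUM)
    num_mat[, col] <- if (col %in% names(der)) der[[col]]
                      else as.numeric(cc[[col]])
  structure(list(cat = cat_mat, num = num_mat, cat_levels = levels),
            class = "encoded_cases")
}

# Equal-frequency discretization used by the Bayesian-network encoding.
equal_freq_edges <- function(x, bins) {
  qs <- stats::quantile(x, probs = seq(0, 1, length.out = bins + 1L),
                        names = FALSE, type = 7)
  edges <- unique(qs)
  if (length(edges) < 2L) edges <- c(edges[1L] - 0.5, edges[1L] + 0.5)
  edges[1L] <- -Inf
  edges[length(edges)] <- Inf
  edges
}

discretize_with_edges <- function(x, edges) {
  as.integer(cut(x, breaks = edges, include.lowest = TRUE, labels = FALSE))
}

# All-discrete data.frame for the Bayesian network; real attributes are
# binned (equal-frequency, `bins` levels) with reusable edges.
encode_discrete <- function(cb, include_type = FALSE, bins = 4L,
                            edges = NULL) {
  enc <- encode_mixed(cb, include_type = include_type)
  out <- as.data.frame(enc$cat)
  if (is.null(edges)) {
    edges <- lapply(colnames(enc$num), function(col)
      equal_freq_edges(enc$num[, col], bins))
    names(edges) <- colnames(enc$num)
  }
  for (col in colnames(enc$num))
    out[[col]] <- discretize_with_edges(enc$num[, col], edges[[col]])
  n_levels <- c(lapply(enc$cat_levels, length),
                lapply(edges, function(e) length(e) - 1L))
  structure(out, bin_edges = edges, n_levels = n_levels)
}

# One-hot numeric design matrix for the perceptron (unscaled).  Severities
# re-enter as plain 0..10 reals here: the perceptron consumes min-max
# scaled numerics, where the ordinal scale is meaningful.
encode_onehot <- function(cb, include_type = FALSE) {
  enc <- encode_mixed(cb, include_type = include_type)
  blocks <- list()
  sev <- intersect(colnames(enc$cat), SEVERITY_COLS)
  sev_num <- enc$cat[, sev, drop = FALSE] - 1
  if ("restoration_level" %in% colnames(enc$cat))
    sev_num <- cbind(sev_num,
                     restoration_level = enc$cat[, "restoration_level"])
  ordinal_as_num <- c(sev, "restoration_level")
  for (col in setdiff(colnames(enc$cat), ordinal_as_num)) {
    lv <- enc$cat_levels[[col]]
    if (length(lv) == 2L) {
      m <- matrix(as.numeric(enc$cat[, col] == 2L), ncol = 1L,
                  dimnames = list(NULL, paste0(col, "_", lv[2L])))
    } else {
      m <- matrix(0, nrow(enc$cat), length(lv),
                  dimnames = list(NULL, paste0(col, "_", lv)))
      m[cbind(seq_len(nrow(enc$cat)), enc$cat[, col])] <- 1
    }
    blocks[[col]] <- m
  }
  cbind(do.call(cbind, blocks), sev_num, enc$num)
}

#' Encode cases for a model family
#'
#' Produces the numeric view of the 41-attribute problem descriptor used by
#' each model family.  `em` keeps booleans/nominals as integer category
#' codes and ordinals plus date-derived durations as reals; `bn`
#' additionally discretizes the reals by equal-frequency binning; `mlp`
#' one-hot encodes nominals and min--max scales every component into the
#' sigmoid working range \[0.2, 0.8\].  The patient identifier never enters
#' an encoding and dates are always converted to durations in years.
#'
#' @param cb a [casebase()] (or its `cases` data.frame).
#' @param target `"em"`, `"bn"` or `"mlp"`.
#' @param include_type include the restoration type (solution attribute) as
#'   an input, as the per-type experts require.
#' @param bins number of bins for the `bn` discretization.
#' @return For `em`, a list with integer `cat` and numeric `num` matrices;
#'   for `bn`, an all-discrete data.frame with a `bin_edges` attribute; for
#'   `mlp`, a numeric matrix with values in \[0.2, 0.8\] and a `scaler`
#'   attribute.
#' @export
encode_cases <- function(cb, target = c("em", "bn", "mlp"),
                         include_type = FALSE, bins = 4L) {
  target <- match.arg(target)
  switch(target,
    em = encode_mixed(cb, include_type),
    bn = encode_discrete(cb, include_type, bins = bins),
    mlp = {
      x <- encode_onehot(cb, include_type)
      sc <- range_scaler(x)
      structure(scale_to_working_range(x, sc), scaler = sc)
    })
}
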