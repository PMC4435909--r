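#' Cohort column dictionary
#'
#' The canonical participant-level data dictionary used throughout the
#' package. Every model specification may only reference variables listed
#' here. Units are fixed: age in years, height in metres, weight in kg,
#' BMI in kg/m^2, waist circumference in cm, blood pressure in mmHg and
#' glucose in mmol/L; no automatic unit conversion is performed.
#'
#' @param derived If `TRUE`, include the variables computed by
#'   [derive_variables()] (family-history summaries, bands, outcome).
#' @return A data frame with columns `variable`, `type` (`"continuous"`,
#'   `"binary"` or `"categorical"`) and `levels` (comma-separated legal
#'   categories, `NA` otherwise).
#' @export
cohort_dictionary <- function(derived = TRUE) {
  base <- data.frame(
    variable = c("id", "sex", "age", "height", "weight", "bmi", "waist",
                 "sbp", "dbp", "on_htn_meds", "smoker", "corticosteroids",
                 "fh_mother", "fh_father", "fh_sister", "fh_brother",
                 "fpg", "glucose_2h", "prior_diagnosis",
                 "hdl", "triglycerides"),
    type = c("id", "categorical", rep("continuous", 7),
             rep("binary", 7), "continuous", "continuous", "binary",
             "continuous", "continuous"),
    levels = NA_character_,
    stringsAsFactors = FALSE
  )
  base$levels[base$variable == "sex"] <- "male,female"
  if (!derived) return(base)
  der <- data.frame(
    variable = c("fh_parent", "fh_sibling", "fh_any", "fh_count", "fh_cat",
                 "age_band", "bmi_band", "y"),
    type = c("binary", "binary", "binary", "continuous", "categorical",
             "categorical", "categorical", "binary"),
    levels = c(NA, NA, NA, NA,
               "none,parent_or_sibling,parent_and_sibling",
               "<60,>=60", "<25,>=25", NA),
    stringsAsFactors = FALSE
  )
  rbind(base, der)
}

#' Body mass index from weight and height
#'
#' @param weight Weight in kilograms; must be strictly positive.
#' @param height Height in metres; must be strictly positive.
#' @return BMI in kg/m^2 (`weight / height^2`). Missing inputs propagate.
#' @examples
#' compute_bmi(80, 2)     # 20
#' compute_bmi(72.3, 1.7) # 25.02
#' @export
compute_bmi <- function(weight, height) {
  bad <- function(x) !is.na(x) & x <= 0
  if (any(bad(weight)) || any(bad(height))) {
    stop("compute_bmi(): weight and height must be strictly positive",
         call. = FALSE)
  }
  weight / height^2
}

#' Classify prevalent diabetes by the WHO OGTT criteria
#'
#' A participant is classified as having prevalent (screen-detected)
#' diabetes when fasting plasma glucose is at least 7.0 mmol/L and/or the
#' 2-hour post-load glucose is at least 11.1 mmol/L; both thresholds are
#' inclusive. If one measurement is missing and the other is below its
#' threshold the result is indeterminate (diabetes cannot be ruled out)
#' and is returned as `NA`; a single measurement at or above its threshold
#' is sufficient for a positive classification.
#'
#' @param fpg Fasting plasma glucose, mmol/L.
#' @param glucose_2h 2-hour post-load plasma glucose, mmol/L.
#' @param na_action `"na"` (default) returns `NA` when both values are
#'   missing; `"error"` raises a missing-outcome error instead.
#' @return Integer vector of 0/1 outcome labels, `NA` where indeterminate.
#' @export
classify_diabetes_who <- function(fpg, glucose_2h, na_action = c("na", "error")) {
  na_action <- match.arg(na_action)
  if (length(fpg) != length(glucose_2h)) {
    stop("fpg and glucose_2h must have the same length", call. = FALSE)
  }
  both_missing <- is.na(fpg) & is.na(glucose_2h)
  if (na_action == "error" && any(both_missing)) {
    stop("missing outcome: both fasting and 2-h glucose are missing for ",
         sum(both_missing), " record(s)", call. = FALSE)
  }
  pos <- (!is.na(fpg) & fpg >= 7.0) | (!is.na(glucose_2h) & glucose_2h >= 11.1)
  neg <- !is.na(fpg) & fpg < 7.0 & !is.na(glucose_2h) & glucose_2h < 11.1
  y <- rep(NA_integer_, length(fpg))
  y[pos] <- 1L
  y[neg] <- 0L
  y
}

#' Derive analysis variables on a cohort table
#'
#' Fills BMI from height and weight where the recorded BMI is missing (a
#' recorded BMI always takes precedence), builds the family-history
#' summaries (`fh_parent`, `fh_sibling`, `fh_any`, `fh_count` and the
#' category `fh_cat` with levels none / parent_or_sibling /
#' parent_and_sibling), the age and BMI subgroup bands, and the WHO
#' outcome label `y` (only for participants without a prior diagnosis).
#'
#' @param cohort A data frame using the [cohort_dictionary()] columns.
#' @return The cohort with derived columns appended.
#' @export
derive_variables <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  if (!"bmi" %in% names(cohort)) cohort$bmi <- NA_real_
  fill <- is.na(cohort$bmi) & !is.na(cohort$height) & !is.na(cohort$weight)
  if (any(fill)) {
    cohort$bmi[fill] <- compute_bmi(cohort$weight[fill], cohort$height[fill])
  }

  fh <- cohort[c("fh_mother", "fh_father", "fh_sister", "fh_brother")]
  fh <- lapply(fh, function(x) as.integer(x))
  cohort$fh_parent <- pmax(fh$fh_mother, fh$fh_father)
  cohort$fh_sibling <- pmax(fh$fh_sister, fh$fh_brother)
  cohort$fh_count <- fh$fh_mother + fh$fh_father + fh$fh_sister + fh$fh_brother
  cohort$fh_any <- as.integer(cohort$fh_count > 0)
  cohort$fh_cat <- ifelse(
    is.na(cohort$fh_parent) | is.na(cohort$fh_sibling), NA_character_,
    ifelse(cohort$fh_parent == 1 & cohort$fh_sibling == 1, "parent_and_sibling",
           ifelse(cohort$fh_parent == 1 | cohort$fh_sibling == 1,
                  "parent_or_sibling", "none")))

  cohort$age_band <- ifelse(is.na(cohort$age), NA_character_,
                            ifelse(cohort$age >= 60, ">=60", "<60"))
  cohort$bmi_band <- ifelse(is.na(cohort$bmi), NA_character_,
                            ifelse(cohort$bmi >= 25, ">=25", "<25"))

  y <- classify_diabetes_who(cohort$fpg, cohort$glucose_2h)
  # the outcome is defined only for participants without a prior diagnosis
  y[!is.na(cohort$prior_diagnosis) & cohort$prior_diagnosis] <- NA_integer_
  cohort$y <- y
  cohort
}

#' Read a cohort table from delimited text
#'
#' @param path Path to a CSV file whose columns follow [cohort_dictionary()].
#' @param missing_token Token(s) denoting missing values (default `NA` and
#'   the empty string).
#' @return A data frame with derived variables appended.
#' @export
read_cohort <- function(path, missing_token = c("NA", "")) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  cohort <- utils::read.csv(path, na.strings = missing_token,
                            stringsAsFactors = FALSE)
  need <- setdiff(cohort_dictionary(derived = FALSE)$variable,
                  c("id", "hdl", "triglycerides", "bmi", "height", "weight"))
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    stop("cohort file lacks required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!("bmi" %in% names(cohort)) &&
      !all(c("height", "weight") %in% names(cohort))) {
    stop("cohort file must contain either bmi or height and weight",
         call. = FALSE)
  }
  for (lv in c("on_htn_meds", "smoker", "corticosteroids", "prior_diagnosis",
               "fh_mother", "fh_father", "fh_sister", "fh_brother")) {
    if (lv %in% names(cohort)) cohort[[lv]] <- as.logical(cohort[[lv]])
  }
  derive_variables(cohort)
}

#' Apply the eligibility and exclusion cascade
#'
#' Two fixed stages: (1) participants with a prior diabetes diagnosis are
#' excluded; (2) among the remainder, records with a missing outcome or a
#' missing value on any required predictor are excluded (complete-case
#' analysis set). The exclusion log reports the counts removed at each
#' stage and the per-variable missingness tallies among stage-1 survivors.
#'
#' @param cohort Cohort data frame (derived variables are computed if the
#'   outcome column `y` is absent).
#' @param required_vars Character vector of variable names that must be
#'   non-missing; each must appear in the cohort dictionary. BMI counts as
#'   observed when it is recorded or derivable from height and weight.
#' @return A list with `analysis` (the complete-case analysis set) and
#'   `log` (counts: `n_input`, `n_prior_diagnosis`, `n_missing_excluded`,
#'   `n_analysis`, and `missing_by_variable`).
#' @export
apply_eligibility <- function(cohort, required_vars) {
  dict <- cohort_dictionary()$variable
  unknown <- setdiff(required_vars, dict)
  if (length(unknown)) {
    stop("required_vars not in the cohort dictionary: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!"y" %in% names(cohort)) cohort <- derive_variables(cohort)
  n_input <- nrow(cohort)
  if (n_input == 0) {
    return(list(analysis = cohort,
                log = list(n_input = 0L, n_prior_diagnosis = 0L,
                           n_missing_excluded = 0L, n_analysis = 0L,
                           missing_by_variable = stats::setNames(
                             integer(length(required_vars)), required_vars))))
  }
  prior <- !is.na(cohort$prior_diagnosis) & as.logical(cohort$prior_diagnosis)
  stage1 <- cohort[!prior, , drop = FALSE]

  req <- setdiff(required_vars, "y")
  miss_mat <- vapply(req, function(v) is.na(stage1[[v]]),
                     logical(nrow(stage1)))
  if (!is.matrix(miss_mat)) miss_mat <- matrix(miss_mat, nrow = nrow(stage1))
  missing_outcome <- is.na(stage1$y)
  any_missing <- missing_outcome | (rowSums(miss_mat) > 0)
  analysis <- stage1[!any_missing, , drop = FALSE]

  tall <- c(colSums(miss_mat), outcome = sum(missing_outcome))
  list(
    analysis = analysis,
    log = list(
      n_input = n_input,
      n_prior_diagnosis = sum(prior),
      n_missing_excluded = sum(any_missing),
      n_analysis = nrow(analysis),
      missing_by_variable = as.list(tall)
    )
  )
}

#' Stratify an analysis set into pre-specified subgroups
#'
#' Subgroup axes follow the validation plan: sex (male vs female), age
#' (`<60` vs `>=60` years) and BMI (`<25` vs `>=25` kg/m^2). Boundary
#' values belong to the upper band. Levels partition the analysis set.
#'
#' @param cohort Analysis set with derived variables.
#' @param axis One of `"sex"`, `"age_band"`, `"bmi_band"`.
#' @return A named list of sub-cohorts, one per level.
#' @export
stratify <- function(cohort, axis = c("sex", "age_band", "bmi_band")) {
  axis <- match.arg(axis)
  levels <- switch(axis,
                   sex = c("male", "female"),
                   age_band = c("<60", ">=60"),
                   bmi_band = c("<25", ">=25"))
  if (anyNA(cohort[[axis]])) {
    stop("stratify(): axis variable '", axis, "' has missing values",
         call. = FALSE)
  }
  out <- lapply(levels, function(l) cohort[cohort[[axis]] == l, , drop = FALSE])
  names(out) <- levels
  out
}

#' Outcome prevalence in an analysis set
#'
#' @param x Either an analysis-set data frame with outcome column `y`, or a
#'   0/1 outcome vector.
#' @return List with `count`, `n` and `percent` (full precision; display
#'   convention is one decimal).
#' @export
prevalence <- function(x) {
  y <- if (is.data.frame(x)) x$y else x
  y <- y[!is.na(y)]
  if (length(y) == 0) stop("prevalence undefined for an empty set", call. = FALSE)
  list(count = sum(y), n = length(y), percent = 100 * mean(y))
}
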