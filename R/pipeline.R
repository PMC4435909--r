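#' Full validation pipeline
#'
#' Runs the complete external-validation analysis on one cohort: derive
#' variables, apply the eligibility cascade (one common complete-case
#' analysis set over the union of all models' predictors), score every
#' model, compute the overall performance block, repeat within the
#' pre-specified subgroups (sex, age band, BMI band), fit and apply the
#' intercept adjustment, recompute the adjusted performance block
#' (re-estimating the optimal threshold on the adjusted probabilities),
#' compare all model pairs' C-statistics, and — optionally — run the
#' multiple-imputation sensitivity analysis on the pre-exclusion roster.
#'
#' A subgroup (or the imputation stage) that is degenerate, e.g. has no
#' events, is reported as undefined and the run continues.
#'
#' @param cohort Cohort data frame (raw columns; a file path is also
#'   accepted and read with [read_cohort()]).
#' @param models Named list of [model_spec] objects, or a character vector
#'   of spec file paths (default: the bundled specs).
#' @param n_bins Calibration-curve bins (default 10).
#' @param imputation If `TRUE`, run the multiple-imputation sensitivity
#'   stage.
#' @param imputation_m Number of imputed datasets (default 5).
#' @param seed Seed for the imputation stage.
#' @return Object of class `validation_run`.
#' @export
run_validation <- function(cohort, models = bundled_models(), n_bins = 10,
                           imputation = FALSE, imputation_m = 5, seed = 1) {
  if (is.character(cohort) && length(cohort) == 1) {
    cohort <- read_cohort(cohort)
  }
  if (is.character(models)) {
    models <- lapply(models, load_model_spec)
  }
  if (is.null(names(models)) || any(!nzchar(names(models)))) {
    names(models) <- vapply(models, `[[`, character(1), "name")
  }
  if (!length(models)) stop("at least one model is required", call. = FALSE)

  cohort <- derive_variables(cohort)
  required_raw <- unique(c(
    unlist(lapply(models, required_variables, raw = TRUE)),
    "fpg", "glucose_2h"))
  elig <- apply_eligibility(cohort, required_raw)
  a <- elig$analysis
  if (nrow(a) == 0) stop("analysis set is empty after exclusions", call. = FALSE)
  y <- a$y

  block <- function(p, yy) {
    if (sum(yy == 1) == 0 || sum(yy == 0) == 0) {
      return(list(defined = FALSE, n = length(yy), events = sum(yy)))
    }
    eo <- eo_ratio(p, yy)
    list(
      defined = TRUE, n = length(yy), events = sum(yy),
      eo = eo, miscalibration = miscalibration_percent(eo),
      brier = brier_score(p, yy), yates = yates_slope(p, yy),
      c_stat = c_statistic(p, yy),
      threshold = optimal_threshold(p, yy),
      calibration = if (length(yy) >= n_bins)
        calibration_curve(p, yy, n_bins) else NULL
    )
  }

  results <- list()
  for (nm in names(models)) {
    spec <- models[[nm]]
    p <- predict_probability(spec, a)
    overall <- block(p, y)
    adj <- fit_intercept_adjustment(p, y)
    spec_adj <- apply_intercept_adjustment(spec, adj)
    p_adj <- predict_probability(spec_adj, a)
    adjusted <- block(p_adj, y)
    subgroups <- list()
    for (axis in c("sex", "age_band", "bmi_band")) {
      strata <- stratify(a, axis)
      for (lv in names(strata)) {
        sub <- strata[[lv]]
        psub <- predict_probability(spec, sub)
        subgroups[[paste(axis, lv, sep = ":")]] <-
          c(list(axis = axis, level = lv), block(psub, sub$y))
      }
    }
    results[[nm]] <- list(
      model = spec, adjustment = adj, model_adjusted = spec_adj,
      original = overall, adjusted = adjusted, subgroups = subgroups)
  }

  # pairwise DeLong comparisons of discrimination, with a Bonferroni
  # column added as a clearly-labelled multiplicity extension
  nm <- names(models)
  pairs <- if (length(nm) > 1) utils::combn(nm, 2, simplify = FALSE) else list()
  comparisons <- do.call(rbind, lapply(pairs, function(pr) {
    pa <- predict_probability(models[[pr[1]]], a)
    pb <- predict_probability(models[[pr[2]]], a)
    cmp <- compare_c_statistics(pa, pb, y)
    data.frame(model_a = pr[1], model_b = pr[2], delta = cmp$delta,
               p_value = cmp$p_value, stringsAsFactors = FALSE)
  }))
  if (!is.null(comparisons)) {
    comparisons$p_bonferroni <- pmin(1, comparisons$p_value * nrow(comparisons))
  }

  imput <- NULL
  if (imputation) {
    prior <- !is.na(cohort$prior_diagnosis) & as.logical(cohort$prior_diagnosis)
    roster1 <- cohort[!prior, , drop = FALSE]
    imp_vars <- intersect(required_raw, names(roster1))
    imp <- impute_chained(roster1, imp_vars, m = imputation_m, seed = seed)
    imput <- lapply(models, function(spec) pooled_validation(imp, spec))
  }

  structure(list(
    n_input = elig$log$n_input,
    exclusion_log = elig$log,
    n_analysis = nrow(a),
    prevalence = prevalence(y),
    models = results,
    comparisons = comparisons,
    imputation = imput,
    n_bins = n_bins,
    seed = seed
  ), class = "validation_run")
}

.fmt <- function(x, digits) formatC(x, format = "f", digits = digits)

.fmt_block <- function(b) {
  if (!isTRUE(b$defined)) {
    return(c("E/O (95% CI)" = "—", "Brier score" = "—",
             "Yates slope" = "—", "C-statistic (95% CI)" = "—",
             "Optimal threshold" = "—", "Sensitivity" = "—",
             "Specificity" = "—", "Correctly classified" = "—"))
  }
  c(
    "E/O (95% CI)" = sprintf("%s (%s–%s)", .fmt(b$eo$ratio, 2),
                             .fmt(b$eo$ci_low, 2), .fmt(b$eo$ci_high, 2)),
    "Brier score" = .fmt(b$brier, 3),
    "Yates slope" = .fmt(b$yates, 3),
    "C-statistic (95% CI)" = sprintf("%s (%s–%s)", .fmt(b$c_stat$c, 2),
                                     .fmt(b$c_stat$ci_low, 2),
                                     .fmt(b$c_stat$ci_high, 2)),
    "Optimal threshold" = .fmt(b$threshold$threshold, 2),
    "Sensitivity" = as.character(round(b$threshold$sensitivity)),
    "Specificity" = as.character(round(b$threshold$specificity)),
    "Correctly classified" = as.character(round(b$threshold$correctly_classified))
  )
}

#' Render the overall performance table
#'
#' One column pair (original, intercept-adjusted) per model; rows are the
#' standard performance block in fixed order: E/O with CI, Brier score,
#' Yates slope, C-statistic with CI, optimal threshold, sensitivity,
#' specificity, correctly classified. Display rounding: ratios and C to
#' two decimals, Brier and Yates to three, percentages to whole numbers;
#' undefined cells show an em-dash.
#'
#' @param run A [run_validation()] result.
#' @return A data frame with a `metric` column plus two columns per model.
#' @export
render_performance_table <- function(run) {
  stopifnot(inherits(run, "validation_run"))
  metric_names <- c("E/O (95% CI)", "Brier score", "Yates slope",
                    "C-statistic (95% CI)", "Optimal threshold",
                    "Sensitivity", "Specificity", "Correctly classified")
  out <- data.frame(metric = metric_names, stringsAsFactors = FALSE)
  for (nm in names(run$models)) {
    res <- run$models[[nm]]
    out[[paste0(nm, "_original")]] <- unname(.fmt_block(res$original))
    out[[paste0(nm, "_adjusted")]] <- unname(.fmt_block(res$adjusted))
  }
  out
}

#' Render the subgroup performance table
#'
#' Mirrors the subgroup layout: six columns (male, female, age <60,
#' age >=60, BMI <25, BMI >=25) and, per model, the four summary rows
#' (E/O with CI, Brier score, Yates slope, C-statistic with CI) for the
#' original models.
#'
#' @param run A [run_validation()] result.
#' @return A data frame with `model`, `metric` and one column per
#'   subgroup level.
#' @export
render_subgroup_table <- function(run) {
  stopifnot(inherits(run, "validation_run"))
  cols <- c("sex:male", "sex:female", "age_band:<60", "age_band:>=60",
            "bmi_band:<25", "bmi_band:>=25")
  col_labels <- c("Male", "Female", "Age < 60", "Age >= 60",
                  "BMI < 25", "BMI >= 25")
  rows <- c("E/O (95% CI)", "Brier score", "Yates slope",
            "C-statistic (95% CI)")
  out <- list()
  for (nm in names(run$models)) {
    block_rows <- data.frame(model = nm, metric = rows,
                             stringsAsFactors = FALSE)
    for (j in seq_along(cols)) {
      b <- run$models[[nm]]$subgroups[[cols[j]]]
      block_rows[[col_labels[j]]] <- unname(.fmt_block(b)[rows])
    }
    out[[nm]] <- block_rows
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Serialise a validation run to JSON
#'
#' @param run A [run_validation()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_validation_run <- function(run, path) {
  stopifnot(inherits(run, "validation_run"))
  strip <- unclass(run)
  strip$models <- lapply(strip$models, function(m) {
    m$model <- unclass(m$model)
    m$model_adjusted <- unclass(m$model_adjusted)
    m$adjustment <- unclass(m$adjustment)
    m
  })
  jsonlite::write_json(strip, path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(path)
}

#' @export
print.validation_run <- function(x, ...) {
  cat("<validation_run>\n")
  cat("  roster:", x$n_input, "->", x$n_analysis,
      "after exclusions (", x$exclusion_log$n_prior_diagnosis,
      "prior diagnosis,", x$exclusion_log$n_missing_excluded,
      "missing data )\n")
  cat(sprintf("  prevalence: %d/%d (%.1f%%)\n", x$prevalence$count,
              x$prevalence$n, x$prevalence$percent))
  cat("  models validated:", paste(names(x$models), collapse = ", "), "\n")
  invisible(x)
}
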