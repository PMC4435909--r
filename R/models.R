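#' @title Risk model specifications
#' @description
#' A risk model is declared as data, not code: a YAML file with the model
#' name, an intercept on the logit scale, a list of predictor terms and the
#' probability link. Three term transforms are supported:
#'
#' * `identity` — `coefficient * x`, with logical predictors coded 0/1;
#' * `categorical` — a per-level contribution for a categorical variable
#'   (unlisted levels contribute 0), which also covers single-indicator
#'   terms and sex codings that differ between source models;
#' * `binned` — strictly increasing `cutpoints` and one value per bin
#'   (`length(values) == length(cutpoints) + 1`), used for point-score
#'   components such as age bands. A value `x` falls in bin `k` when
#'   `cutpoints[k-1] <= x < cutpoints[k]` (left-closed).
#'
#' Integer point scores are expressed with binned/categorical terms and an
#' optional `score_to_lp` block (`intercept`, `slope`) mapping the summed
#' score onto the logit scale, so that every model produces a predicted
#' probability through the same logistic link.
#' @name model_spec
NULL

.known_transforms <- c("identity", "categorical", "binned")

.legal_levels <- function(variable) {
  dict <- cohort_dictionary()
  lv <- dict$levels[dict$variable == variable]
  if (length(lv) == 0 || is.na(lv)) return(NULL)
  strsplit(lv, ",", fixed = TRUE)[[1]]
}

#' Construct a validated model specification
#'
#' @param name Model name.
#' @param intercept Intercept on the logit scale (for point-score models
#'   this is usually 0, with the mapping carried by `score_to_lp`).
#' @param terms List of predictor terms; each a list with `variable`,
#'   `transform`, and `coefficient` (identity), `levels` (categorical) or
#'   `cutpoints` + `values` (binned).
#' @param link Probability link; only `"logistic"` is recognised.
#' @param score_to_lp Optional list with `intercept` and `slope`: the
#'   linear predictor becomes `intercept + slope * score` where `score` is
#'   the model intercept plus the summed term contributions.
#' @param source_ref Free-text provenance of the coefficients.
#' @param synthetic_coefficients Logical flag recorded in the spec: `TRUE`
#'   marks coefficient values that are illustrative stand-ins rather than
#'   transcriptions of a published equation.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(name, intercept, terms, link = "logistic",
                       score_to_lp = NULL, source_ref = NULL,
                       synthetic_coefficients = FALSE) {
  spec <- structure(
    list(name = name, link = link, intercept = intercept, terms = terms,
         score_to_lp = score_to_lp, source_ref = source_ref,
         synthetic_coefficients = isTRUE(synthetic_coefficients)),
    class = "model_spec")
  validate_model_spec(spec)
  spec
}

validate_model_spec <- function(spec) {
  fail <- function(...) stop("invalid model spec: ", ..., call. = FALSE)
  if (is.null(spec$name) || !nzchar(spec$name)) fail("missing field 'name'")
  if (is.null(spec$link)) fail("missing field 'link' in model '", spec$name, "'")
  if (!identical(spec$link, "logistic")) {
    fail("unrecognised link '", spec$link, "' (only 'logistic' is supported)")
  }
  if (is.null(spec$intercept) || !is.numeric(spec$intercept)) {
    fail("field 'intercept' must be a number in model '", spec$name, "'")
  }
  if (is.null(spec$terms) || !length(spec$terms)) {
    fail("model '", spec$name, "' declares no predictor terms")
  }
  dict <- cohort_dictionary()
  vars <- vapply(spec$terms, function(t) t$variable %||% NA_character_,
                 character(1))
  if (anyNA(vars)) fail("a term lacks a 'variable' field in '", spec$name, "'")
  unknown <- setdiff(vars, dict$variable)
  if (length(unknown)) {
    fail("unknown variable(s) ", paste(unknown, collapse = ", "),
         " in model '", spec$name, "'; legal variables are: ",
         paste(dict$variable, collapse = ", "))
  }
  if (anyDuplicated(vars)) {
    fail("duplicated predictor variable '", vars[duplicated(vars)][1],
         "' in model '", spec$name, "'")
  }
  for (t in spec$terms) {
    tr <- t$transform %||% "identity"
    if (!tr %in% .known_transforms) {
      fail("unknown transform '", tr, "' for variable '", t$variable, "'")
    }
    if (tr == "identity") {
      if (!is.numeric(t$coefficient)) {
        fail("identity term on '", t$variable, "' needs a numeric 'coefficient'")
      }
    } else if (tr == "categorical") {
      if (is.null(t$levels) || !length(t$levels)) {
        fail("categorical term on '", t$variable, "' needs a 'levels' map")
      }
      legal <- .legal_levels(t$variable)
      if (is.null(legal)) {
        fail("variable '", t$variable, "' is not categorical in the dictionary")
      }
      bad <- setdiff(names(t$levels), legal)
      if (length(bad)) {
        fail("illegal categor", if (length(bad) > 1) "ies " else "y ",
             paste(bad, collapse = ", "), " for variable '", t$variable,
             "'; legal: ", paste(legal, collapse = ", "))
      }
    } else { # binned
      cp <- unlist(t$cutpoints); vl <- unlist(t$values)
      if (is.null(cp) || is.null(vl)) {
        fail("binned term on '", t$variable, "' needs 'cutpoints' and 'values'")
      }
      if (any(diff(cp) <= 0)) {
        fail("cutpoints for '", t$variable, "' must be strictly increasing")
      }
      if (length(vl) != length(cp) + 1L) {
        fail("binned term on '", t$variable, "' needs one value per bin (",
             length(cp) + 1L, " values for ", length(cp), " cutpoints)")
      }
    }
  }
  if (!is.null(spec$score_to_lp)) {
    if (!is.numeric(spec$score_to_lp$intercept) ||
        !is.numeric(spec$score_to_lp$slope)) {
      fail("'score_to_lp' needs numeric 'intercept' and 'slope'")
    }
  }
  invisible(spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a model specification from a YAML file
#'
#' The file is validated on load: an unknown variable, a duplicated
#' predictor, unordered cutpoints or a malformed field raise an error
#' naming the problem; nothing is silently repaired.
#'
#' @param path Path to a YAML model-specification file.
#' @return A validated [model_spec] object.
#' @export
load_model_spec <- function(path) {
  if (!file.exists(path)) stop("model spec file not found: ", path, call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("cannot parse model spec '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  spec <- structure(
    list(name = raw$name, link = raw$link, intercept = raw$intercept,
         terms = raw$terms, score_to_lp = raw$score_to_lp,
         source_ref = raw$source_ref,
         synthetic_coefficients = isTRUE(raw$synthetic_coefficients)),
    class = "model_spec")
  validate_model_spec(spec)
  spec
}

#' Write a model specification to a YAML file
#'
#' @param spec A [model_spec] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_spec <- function(spec, path) {
  validate_model_spec(spec)
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' Variables required by a model
#'
#' @param spec A [model_spec] object.
#' @param raw If `TRUE`, map derived variables back to the raw cohort
#'   columns they are computed from (e.g. the family-history category to
#'   the four per-relative flags), as needed for eligibility filtering.
#' @return Character vector of variable names.
#' @export
required_variables <- function(spec, raw = FALSE) {
  vars <- vapply(spec$terms, `[[`, character(1), "variable")
  if (!raw) return(vars)
  expand <- list(
    fh_parent = c("fh_mother", "fh_father"),
    fh_sibling = c("fh_sister", "fh_brother"),
    fh_any = c("fh_mother", "fh_father", "fh_sister", "fh_brother"),
    fh_count = c("fh_mother", "fh_father", "fh_sister", "fh_brother"),
    fh_cat = c("fh_mother", "fh_father", "fh_sister", "fh_brother"),
    age_band = "age", bmi_band = "bmi", y = c("fpg", "glucose_2h")
  )
  out <- unlist(lapply(vars, function(v) expand[[v]] %||% v))
  unique(out)
}

.term_contribution <- function(term, data) {
  x <- data[[term$variable]]
  tr <- term$transform %||% "identity"
  if (tr == "identity") {
    return(term$coefficient * as.numeric(x))
  }
  if (tr == "categorical") {
    out <- numeric(length(x))
    out[is.na(x)] <- NA_real_
    for (lv in names(term$levels)) {
      out[!is.na(x) & x == lv] <- term$levels[[lv]]
    }
    return(out)
  }
  # binned: bin k if cutpoints[k-1] <= x < cutpoints[k]
  cp <- unlist(term$cutpoints); vl <- unlist(term$values)
  idx <- findInterval(as.numeric(x), cp) + 1L
  vl[idx]
}

#' Linear predictor of a model on participant data
#'
#' Sums the intercept and each term's transformed contribution; for
#' point-score models the summed score is then mapped through the
#' `score_to_lp` calibration. Evaluation is a pure function of the inputs.
#'
#' @param spec A [model_spec] object.
#' @param data A data frame (one row per participant) containing every
#'   model variable, non-missing.
#' @return Numeric vector of linear predictors on the logit scale.
#' @export
linear_predictor <- function(spec, data) {
  validate_model_spec(spec)
  vars <- required_variables(spec)
  for (v in vars) {
    if (is.null(data[[v]])) {
      stop("missing predictor column '", v, "' for model '", spec$name, "'",
           call. = FALSE)
    }
    if (anyNA(data[[v]])) {
      stop("missing values in predictor '", v, "' for model '", spec$name,
           "'; exclude or impute before scoring", call. = FALSE)
    }
  }
  score <- spec$intercept
  for (t in spec$terms) score <- score + .term_contribution(t, data)
  if (!is.null(spec$score_to_lp)) {
    score <- spec$score_to_lp$intercept + spec$score_to_lp$slope * score
  }
  score
}

#' Predicted probability of prevalent undiagnosed diabetes
#'
#' @inheritParams linear_predictor
#' @return `plogis(linear_predictor)`, a probability in (0, 1), strictly
#'   increasing in the linear predictor.
#' @export
predict_probability <- function(spec, data) {
  stats::plogis(linear_predictor(spec, data))
}

#' Bundled model specifications
#'
#' Paths to (or loaded copies of) the model-specification files shipped
#' with the package: cambridge, kuwaiti, omani, rotterdam_1 and
#' finnish_simplified. The predictor structure of each file follows the
#' published models; the coefficient values bundled here are synthetic
#' stand-ins (flagged `synthetic_coefficients: true` in each file and
#' carried in the filename) because the package does not redistribute the
#' published equations. Replace them with transcribed coefficients for a
#' real validation study.
#'
#' @param load If `TRUE` (default) return named [model_spec] objects,
#'   otherwise the file paths.
#' @return Named list of model specs or a named character vector of paths.
#' @export
bundled_models <- function(load = TRUE) {
  dir <- system.file("extdata", "models", package = "prevalid")
  files <- list.files(dir, pattern = "\\.yaml$", full.names = TRUE)
  specs <- lapply(files, load_model_spec)
  nm <- vapply(specs, `[[`, character(1), "name")
  if (!load) return(stats::setNames(files, nm))
  stats::setNames(specs, nm)
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$name,
      if (x$synthetic_coefficients) "(synthetic coefficients)" else "", "\n")
  cat("  link:", x$link,
      if (!is.null(x$score_to_lp)) {
        sprintf("(score -> lp: %g + %g * score)",
                x$score_to_lp$intercept, x$score_to_lp$slope)
      } else "", "\n")
  cat("  intercept:", x$intercept, "\n")
  cat("  predictors:", paste(required_variables(x), collapse = ", "), "\n")
  invisible(x)
}
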