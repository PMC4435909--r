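#' Multiple imputation by chained equations
#'
#' Fills missing values in the requested variables by cycling conditional
#' models: continuous variables are imputed from a normal linear model
#' (regression parameters and residual variance drawn from their
#' approximate posterior, then a stochastic draw per missing cell), binary
#' variables from a logistic model (coefficients drawn from their
#' asymptotic normal distribution, then a Bernoulli draw). Cells observed
#' in the input are never altered and are identical across the completed
#' datasets. Ten cycles per dataset are run by default.
#'
#' If a conditional model cannot be fitted (e.g. separation in a sparse
#' binary variable), the imputation for that variable falls back to
#' drawing from its observed marginal distribution for that cycle.
#'
#' @param cohort Data frame with missing values.
#' @param vars Variables to impute and to use as predictors of each other;
#'   each must have at least one observed value.
#' @param m Number of completed datasets (default 5).
#' @param cycles Chained-equation cycles per dataset (default 10).
#' @param seed Integer seed; the whole imputation is reproducible from it.
#' @return Object of class `imputed_set`: list with `m`, `datasets` (list
#'   of completed cohorts), `vars`, `seed`, and `n_missing` per variable.
#' @export
impute_chained <- function(cohort, vars, m = 5, cycles = 10, seed = 1) {
  stopifnot(is.data.frame(cohort), m >= 1, cycles >= 1)
  vars <- intersect(vars, names(cohort))
  miss_n <- vapply(vars, function(v) sum(is.na(cohort[[v]])), integer(1))
  fully_missing <- vars[miss_n == nrow(cohort)]
  if (length(fully_missing)) {
    stop("cannot impute: variable(s) with no observed values: ",
         paste(fully_missing, collapse = ", "), call. = FALSE)
  }
  to_impute <- vars[miss_n > 0]

  is_binary <- vapply(vars, function(v) {
    x <- cohort[[v]]
    is.logical(x) || all(stats::na.omit(x) %in% c(0, 1))
  }, logical(1))
  names(is_binary) <- vars

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  datasets <- vector("list", m)
  for (k in seq_len(m)) {
    comp <- cohort
    # initialise by sampling from the observed marginals
    for (v in to_impute) {
      na_idx <- which(is.na(comp[[v]]))
      obs <- stats::na.omit(cohort[[v]])
      comp[[v]][na_idx] <- sample(obs, length(na_idx), replace = TRUE)
    }
    for (cyc in seq_len(cycles)) {
      for (v in to_impute) {
        na_idx <- which(is.na(cohort[[v]]))
        rhs <- setdiff(vars, v)
        X <- stats::model.matrix(
          ~ ., data = as.data.frame(lapply(comp[rhs], as.numeric)))
        yv <- as.numeric(comp[[v]])
        obs_idx <- setdiff(seq_len(nrow(comp)), na_idx)
        imp <- tryCatch({
          if (is_binary[[v]]) {
            fit <- suppressWarnings(stats::glm.fit(
              X[obs_idx, , drop = FALSE], yv[obs_idx],
              family = stats::binomial()))
            beta <- fit$coefficients
            ok <- !is.na(beta)
            qr_ok <- qr(X[obs_idx, ok, drop = FALSE] *
                          sqrt(fit$weights))
            V <- chol2inv(qr_ok$qr[seq_len(qr_ok$rank),
                                   seq_len(qr_ok$rank), drop = FALSE])
            bstar <- MASS::mvrnorm(1, beta[ok], V)
            pm <- stats::plogis(drop(X[na_idx, ok, drop = FALSE] %*% bstar))
            stats::rbinom(length(na_idx), 1, pm)
          } else {
            fit <- stats::lm.fit(X[obs_idx, , drop = FALSE], yv[obs_idx])
            ok <- !is.na(fit$coefficients)
            Xo <- X[obs_idx, ok, drop = FALSE]
            res <- fit$residuals
            df <- length(obs_idx) - sum(ok)
            if (df < 1) stop("insufficient residual df")
            s2 <- sum(res^2) / df
            s2_star <- s2 * df / stats::rchisq(1, df)
            XtXi <- chol2inv(chol(crossprod(Xo)))
            bstar <- MASS::mvrnorm(1, fit$coefficients[ok], s2_star * XtXi)
            mu <- drop(X[na_idx, ok, drop = FALSE] %*% bstar)
            stats::rnorm(length(na_idx), mu, sqrt(s2_star))
          }
        }, error = function(e) {
          obs <- stats::na.omit(cohort[[v]])
          sample(as.numeric(obs), length(na_idx), replace = TRUE)
        })
        if (is.logical(cohort[[v]])) imp <- as.logical(imp)
        comp[[v]][na_idx] <- imp
      }
    }
    datasets[[k]] <- comp
  }
  structure(list(m = m, datasets = datasets, vars = vars, seed = seed,
                 n_missing = as.list(miss_n)),
            class = "imputed_set")
}

#' Pooled discrimination across imputed datasets
#'
#' Scores a model on each completed dataset, classifies outcomes with the
#' WHO glucose rule (on imputed glucose where the outcome was missing),
#' and summarises the per-dataset C-statistics by their mean, with the
#' min-max spread reported alongside. Participants with a prior diagnosis
#' are excluded before scoring.
#'
#' @param imputed An [impute_chained()] result.
#' @param spec A [model_spec] to validate.
#' @return List with `c_values` (per dataset), `pooled` (mean) and
#'   `range` (min, max).
#' @export
pooled_validation <- function(imputed, spec) {
  stopifnot(inherits(imputed, "imputed_set"))
  cs <- vapply(imputed$datasets, function(d) {
    d <- derive_variables(d)
    prior <- !is.na(d$prior_diagnosis) & as.logical(d$prior_diagnosis)
    d <- d[!prior & !is.na(d$y), , drop = FALSE]
    p <- predict_probability(spec, d)
    c_statistic(p, d$y)$c
  }, numeric(1))
  list(c_values = cs, pooled = mean(cs), range = range(cs))
}
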