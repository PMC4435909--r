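#' @title Synthetic screening-cohort generator
#' @description
#' Generates participant rosters with the statistical structure of a
#' community-based OGTT screening sample: per-sex marginal distributions
#' for the continuous covariates coupled through a Gaussian copula,
#' per-sex Bernoulli prevalences for the binary covariates (family
#' history correlated within a family through a shared frailty,
#' antihypertensive treatment correlated with systolic pressure), a
#' latent diabetes liability built from the copula scores, and fasting /
#' 2-hour glucose generated as liability-driven mixtures so that applying
#' the WHO classification rule to the generated glucose yields the target
#' screen-detected prevalence. Prior-diagnosis flags and per-variable
#' missingness are injected on top.
#'
#' The fasting-glucose marginal is a two-component lognormal mixture: the
#' elevated-glycaemia component has fixed per-sex parameters and a fixed
#' per-sex membership probability (membership correlated with the latent
#' liability), and the normoglycaemic component is solved in closed form
#' so that the overall per-sex mean and SD equal the configured targets
#' exactly. The 2-hour glucose (not moment-constrained) is a second
#' mixture whose membership probability is a logistic function of the
#' latent liability; its intercept is the dial used by
#' [calibrate_outcome_intercept()] to hit the target prevalence, and
#' moving it never perturbs the fasting-glucose marginal.
#' @name synthetic_data
NULL

.lnorm_pars <- function(mean, sd) {
  v <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - v / 2, sdlog = sqrt(v))
}

.rlnorm_m <- function(z, mean, sd) {
  pr <- .lnorm_pars(mean, sd)
  exp(pr["meanlog"] + pr["sdlog"] * z)
}

# Normoglycaemic lognormal component with overall mixture moments (m, s)
# given elevated component (mD, sD) of weight w: closed-form moment match.
.solve_fpg_normo <- function(m, s, w, mD, sD) {
  mN <- (m - w * mD) / (1 - w)
  vN <- (s^2 + m^2 - w * (sD^2 + mD^2)) / (1 - w) - mN^2
  if (mN <= 0 || vN <= 0) {
    stop("infeasible fasting-glucose mixture: elevated component (mean ",
         mD, ", sd ", sD, ") with weight ", signif(w, 4),
         " cannot reproduce an overall mean ", m, " and sd ", s,
         call. = FALSE)
  }
  list(mean = mN, sd = sqrt(vN))
}

.default_corr <- function() {
  vars <- c("age", "bmi", "waist", "sbp", "dbp", "height", "weight",
            "hdl", "triglycerides")
  R <- diag(9); dimnames(R) <- list(vars, vars)
  set_ <- function(a, b, v) { R[a, b] <<- v; R[b, a] <<- v }
  set_("age", "bmi", 0.10); set_("age", "waist", 0.15)
  set_("age", "sbp", 0.35); set_("age", "dbp", 0.15)
  set_("age", "height", -0.10); set_("age", "hdl", 0.05)
  set_("age", "triglycerides", 0.10)
  set_("bmi", "waist", 0.80); set_("bmi", "sbp", 0.20)
  set_("bmi", "dbp", 0.20); set_("bmi", "height", -0.10)
  set_("bmi", "weight", 0.80); set_("bmi", "hdl", -0.15)
  set_("bmi", "triglycerides", 0.20)
  set_("waist", "sbp", 0.20); set_("waist", "dbp", 0.20)
  set_("waist", "weight", 0.65); set_("waist", "hdl", -0.15)
  set_("waist", "triglycerides", 0.25)
  set_("sbp", "dbp", 0.70); set_("sbp", "weight", 0.10)
  set_("sbp", "triglycerides", 0.10)
  set_("dbp", "weight", 0.10); set_("dbp", "triglycerides", 0.10)
  set_("height", "weight", 0.40)
  set_("weight", "hdl", -0.10); set_("weight", "triglycerides", 0.15)
  set_("hdl", "triglycerides", -0.30)
  R
}

#' Simulation configuration
#'
#' Builds the generator configuration. The default marginal means/SDs and
#' binary prevalences are the per-sex characteristics of the emulated
#' screening sample; the copula rank correlations, latent-effect sizes
#' and glucose mixture components are generator design constants (they
#' are not identifiable from published marginal summaries) and are
#' documented in the methods vignette.
#'
#' @param n_total Default roster size (1256).
#' @param female_frac Probability a participant is female (0.787).
#' @param frac_prior_diagnosis Probability of a prior diabetes diagnosis
#'   (173/1256).
#' @param target_prev Target screen-detected (WHO) prevalence among the
#'   undiagnosed (0.176).
#' @param continuous Per-variable list: `male`/`female` = c(mean, sd) and
#'   `dist` (`"normal"` with clamping `range`, or `"lognormal"`).
#' @param binary Per-variable c(male=, female=) prevalences.
#' @param corr Copula correlation matrix for the continuous latents.
#' @param risk_weights Latent-liability loadings on the age, BMI, waist
#'   copula scores and the family frailty.
#' @param fh_frailty_rho Within-family correlation of the per-relative
#'   history indicators.
#' @param htn_sbp_rho Latent correlation between antihypertensive
#'   treatment and systolic pressure.
#' @param fpg_elevated Per-sex membership probability `p`, `mean` and `sd`
#'   of the elevated fasting-glucose component.
#' @param rho_e Correlation of the elevated-glycaemia latent with the
#'   liability score.
#' @param g2h Mixture components for 2-h glucose.
#' @param outcome `intercept`, `slope_s` (liability) and `slope_e`
#'   (fasting-elevation) of the 2-h-elevation logistic model; the
#'   intercept is what [calibrate_outcome_intercept()] tunes.
#' @param missing_rates Named per-variable MCAR rates used by default when
#'   missingness is injected.
#' @param calibration List with `n` and `seed` for the internal
#'   calibration sample.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(
    n_total = 1256,
    female_frac = 0.787,
    frac_prior_diagnosis = 173 / 1256,
    target_prev = 0.176,
    continuous = list(
      age = list(male = c(53.5, 15.0), female = c(52.1, 14.3),
                 dist = "normal", range = c(15, 95)),
      bmi = list(male = c(25.5, 5.8), female = c(29.6, 7.0),
                 dist = "normal", range = c(11, 80)),
      waist = list(male = c(92.5, 15.2), female = c(95.6, 14.7),
                   dist = "normal", range = c(45, 180)),
      sbp = list(male = c(124.3, 16.6), female = c(121.6, 19.2),
                 dist = "normal", range = c(70, 260)),
      dbp = list(male = c(75.6, 11.1), female = c(74.7, 12.1),
                 dist = "normal", range = c(35, 160)),
      height = list(male = c(1.7, 0.1), female = c(1.6, 0.1),
                    dist = "normal", range = c(1.2, 2.2)),
      weight = list(male = c(72.3, 16.4), female = c(73.9, 17.7),
                    dist = "lognormal"),
      hdl = list(male = c(1.2, 0.4), female = c(1.3, 0.3),
                 dist = "lognormal"),
      triglycerides = list(male = c(1.4, 0.9), female = c(1.4, 0.9),
                           dist = "lognormal")
    ),
    binary = list(
      smoker = c(male = 0.561, female = 0.405),
      on_htn_meds = c(male = 0.274, female = 0.359),
      corticosteroids = c(male = 0.006, female = 0.007),
      fh_mother = c(male = 0.108, female = 0.159),
      fh_father = c(male = 0.089, female = 0.076),
      fh_sister = c(male = 0.076, female = 0.138),
      fh_brother = c(male = 0.057, female = 0.085)
    ),
    corr = .default_corr(),
    risk_weights = c(age = 0.35, bmi = 0.50, waist = 0.30, fam = 0.30),
    fh_frailty_rho = 0.5,
    htn_sbp_rho = 0.5,
    fpg_elevated = list(p = c(male = 0.14, female = 0.20),
                        mean = c(male = 7.4, female = 8.5),
                        sd = c(male = 1.6, female = 2.5)),
    rho_e = 0.75,
    g2h = list(normo = c(mean = 5.6, sd = 1.5),
               elevated = c(mean = 13.5, sd = 3.5)),
    outcome = list(intercept = -3.2, slope_s = 1.0, slope_e = 1.0),
    missing_rates = c(fh_mother = 0.07, fh_father = 0.07, fh_sister = 0.07,
                      fh_brother = 0.07, glucose_2h = 0.05, fpg = 0.01,
                      bmi = 0.01, waist = 0.01, sbp = 0.005, dbp = 0.005,
                      on_htn_meds = 0.01, smoker = 0.005,
                      corticosteroids = 0.005, height = 0.01, weight = 0.01),
    calibration = list(n = 1e5, seed = 104729)) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  fail <- function(...) stop("invalid sim_config: ", ..., call. = FALSE)
  probs <- c(cfg$female_frac, cfg$frac_prior_diagnosis, cfg$target_prev,
             unlist(cfg$binary), cfg$fpg_elevated$p, cfg$missing_rates)
  if (any(probs < 0 | probs > 1)) fail("probabilities must lie in [0, 1]")
  if (cfg$target_prev <= 0 || cfg$target_prev >= 1) {
    fail("target prevalence must be inside (0, 1)")
  }
  for (v in names(cfg$continuous)) {
    sp <- cfg$continuous[[v]]
    if (sp$male[2] <= 0 || sp$female[2] <= 0) {
      fail("non-positive SD for ", v)
    }
  }
  ev <- eigen(cfg$corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) fail("correlation matrix is not positive semi-definite")
  # feasibility of the fasting-glucose moment match
  for (sx in c("male", "female")) {
    tgt <- .fpg_targets
    .solve_fpg_normo(tgt[[sx]][1], tgt[[sx]][2], cfg$fpg_elevated$p[[sx]],
                     cfg$fpg_elevated$mean[[sx]], cfg$fpg_elevated$sd[[sx]])
  }
  invisible(cfg)
}

# Per-sex fasting glucose marginal targets (mean, sd); kept alongside the
# copula variables but generated through the liability-driven mixture.
.fpg_targets <- list(male = c(5.4, 1.4), female = c(5.7, 2.0))

# Draw every generator component that does not depend on the outcome-model
# intercept. Returned pieces allow prevalence to be re-evaluated for any
# intercept on common random numbers (used by the calibration bisection).
.sim_latents <- function(cfg, n) {
  female <- stats::runif(n) < cfg$female_frac
  sex <- ifelse(female, "female", "male")

  vars <- colnames(cfg$corr)
  Z <- matrix(stats::rnorm(n * length(vars)), n) %*% chol(cfg$corr)
  colnames(Z) <- vars

  cont <- list()
  for (v in vars) {
    sp <- cfg$continuous[[v]]
    ms <- rbind(male = sp$male, female = sp$female)[sex, , drop = FALSE]
    if (identical(sp$dist, "lognormal")) {
      pr <- rbind(male = .lnorm_pars(sp$male[1], sp$male[2]),
                  female = .lnorm_pars(sp$female[1], sp$female[2]))[sex, ,
                                                                   drop = FALSE]
      val <- exp(pr[, 1] + pr[, 2] * Z[, v])
    } else {
      val <- ms[, 1] + ms[, 2] * Z[, v]
      val <- pmin(pmax(val, sp$range[1]), sp$range[2])
    }
    cont[[v]] <- val
  }

  z_fam <- stats::rnorm(n)
  rho_f <- cfg$fh_frailty_rho
  fh <- list()
  for (v in c("fh_mother", "fh_father", "fh_sister", "fh_brother")) {
    zr <- rho_f * z_fam + sqrt(1 - rho_f^2) * stats::rnorm(n)
    thr <- stats::qnorm(1 - cfg$binary[[v]])[sex]
    fh[[v]] <- zr > thr
  }
  z_sm <- stats::rnorm(n)
  smoker <- z_sm > stats::qnorm(1 - cfg$binary$smoker)[sex]
  rho_h <- cfg$htn_sbp_rho
  z_ht <- rho_h * Z[, "sbp"] + sqrt(1 - rho_h^2) * stats::rnorm(n)
  on_htn_meds <- z_ht > stats::qnorm(1 - cfg$binary$on_htn_meds)[sex]
  z_cs <- stats::rnorm(n)
  corticosteroids <- z_cs > stats::qnorm(1 - cfg$binary$corticosteroids)[sex]

  # latent diabetes liability: standardised combination of copula scores
  w <- cfg$risk_weights
  w3 <- w[c("age", "bmi", "waist")]
  Rsub <- cfg$corr[c("age", "bmi", "waist"), c("age", "bmi", "waist")]
  var_s <- drop(t(w3) %*% Rsub %*% w3) + w[["fam"]]^2
  s <- (Z[, "age"] * w[["age"]] + Z[, "bmi"] * w[["bmi"]] +
          Z[, "waist"] * w[["waist"]] + z_fam * w[["fam"]]) / sqrt(var_s)

  # elevated fasting glucose membership (fixed marginal probability)
  z_e <- cfg$rho_e * s + sqrt(1 - cfg$rho_e^2) * stats::rnorm(n)
  pe <- cfg$fpg_elevated$p
  elev_fpg <- z_e > stats::qnorm(1 - pe)[sex]

  z_fpg1 <- stats::rnorm(n)
  z_fpg2 <- stats::rnorm(n)
  fpg_n <- fpg_e <- numeric(n)
  for (sx in c("male", "female")) {
    i <- sex == sx
    if (!any(i)) next
    tgt <- .fpg_targets[[sx]]
    comp <- .solve_fpg_normo(tgt[1], tgt[2], pe[[sx]],
                             cfg$fpg_elevated$mean[[sx]],
                             cfg$fpg_elevated$sd[[sx]])
    fpg_n[i] <- .rlnorm_m(z_fpg1[i], comp$mean, comp$sd)
    fpg_e[i] <- .rlnorm_m(z_fpg1[i], cfg$fpg_elevated$mean[[sx]],
                          cfg$fpg_elevated$sd[[sx]])
  }
  fpg <- ifelse(elev_fpg, fpg_e, fpg_n)

  u_g <- stats::runif(n)
  g2h_n <- .rlnorm_m(z_fpg2, cfg$g2h$normo[["mean"]], cfg$g2h$normo[["sd"]])
  z_fpg3 <- stats::rnorm(n)
  g2h_e <- .rlnorm_m(z_fpg3, cfg$g2h$elevated[["mean"]],
                     cfg$g2h$elevated[["sd"]])

  prior <- stats::runif(n) < cfg$frac_prior_diagnosis

  list(sex = sex, cont = cont, fh = fh, smoker = smoker,
       on_htn_meds = on_htn_meds, corticosteroids = corticosteroids,
       s = s, elev_fpg = elev_fpg, fpg = fpg, u_g = u_g,
       g2h_n = g2h_n, g2h_e = g2h_e, prior = prior)
}

.g2h_from_latents <- function(lat, cfg, intercept) {
  eta <- intercept + cfg$outcome$slope_s * lat$s +
    cfg$outcome$slope_e * lat$elev_fpg
  g <- lat$u_g < stats::plogis(eta)
  ifelse(g, lat$g2h_e, lat$g2h_n)
}

.prevalence_at <- function(lat, cfg, intercept) {
  g2h <- .g2h_from_latents(lat, cfg, intercept)
  mean(lat$fpg >= 7.0 | g2h >= 11.1)
}

#' Generate a synthetic screening cohort
#'
#' @param cfg A [sim_config()] object (ideally after
#'   [calibrate_outcome_intercept()]).
#' @param n Roster size (default `cfg$n_total`).
#' @param seed Integer seed; identical seed and configuration give an
#'   identical roster.
#' @param inject_missing If `TRUE` (default), apply the configured
#'   per-variable MCAR missingness to the roster after generation.
#' @return A participant data frame in the [cohort_dictionary()] layout
#'   (raw columns only; use [derive_variables()] downstream).
#' @export
generate_cohort <- function(cfg, n = cfg$n_total, seed = 1,
                            inject_missing = TRUE) {
  validate_sim_config(cfg)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  lat <- .sim_latents(cfg, n)
  g2h <- .g2h_from_latents(lat, cfg, cfg$outcome$intercept)
  roster <- data.frame(
    id = sprintf("P%06d", seq_len(n)),
    sex = lat$sex,
    age = lat$cont$age,
    height = lat$cont$height,
    weight = lat$cont$weight,
    bmi = lat$cont$bmi,
    waist = lat$cont$waist,
    sbp = lat$cont$sbp,
    dbp = lat$cont$dbp,
    on_htn_meds = lat$on_htn_meds,
    smoker = lat$smoker,
    corticosteroids = lat$corticosteroids,
    fh_mother = lat$fh$fh_mother,
    fh_father = lat$fh$fh_father,
    fh_sister = lat$fh$fh_sister,
    fh_brother = lat$fh$fh_brother,
    fpg = lat$fpg,
    glucose_2h = g2h,
    prior_diagnosis = lat$prior,
    hdl = lat$cont$hdl,
    triglycerides = lat$cont$triglycerides,
    stringsAsFactors = FALSE
  )
  if (inject_missing && length(cfg$missing_rates)) {
    roster <- inject_missingness(roster, rates = cfg$missing_rates)
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                 envir = globalenv())
  roster
}

#' Calibrate the outcome-model intercept to a target prevalence
#'
#' Bisects the 2-h-elevation intercept until the empirical WHO prevalence
#' of a large internal sample (common random numbers, fixed seed,
#' `cfg$calibration$n` records) is within `tol` of the target. Prevalence
#' is monotone in the intercept on common random numbers, so bisection
#' converges; a bracket that does not straddle the target is an error.
#'
#' @param cfg A [sim_config()].
#' @param target Target prevalence (default `cfg$target_prev`).
#' @param tol Acceptable absolute deviation of the achieved calibration
#'   prevalence (default 0.005).
#' @param bracket Search interval for the intercept.
#' @return The configuration with the calibrated intercept; the achieved
#'   calibration-sample prevalence is attached as attribute
#'   `achieved_prev`.
#' @export
calibrate_outcome_intercept <- function(cfg, target = cfg$target_prev,
                                        tol = 0.005, bracket = c(-7, 0)) {
  validate_sim_config(cfg)
  if (target <= 0 || target >= 1) {
    stop("target prevalence must be inside (0, 1)", call. = FALSE)
  }
  if (tol <= 0) {
    stop("calibration failure: a zero tolerance cannot be guaranteed by a ",
         "finite empirical calibration sample; use tol > 0", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(cfg$calibration$seed)
  lat <- .sim_latents(cfg, cfg$calibration$n)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                 envir = globalenv())
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- .prevalence_at(lat, cfg, lo)
  f_hi <- .prevalence_at(lat, cfg, hi)
  if (f_lo > target || f_hi < target) {
    stop("calibration failure: bracket [", lo, ", ", hi,
         "] gives prevalence [", signif(f_lo, 4), ", ", signif(f_hi, 4),
         "], which does not straddle the target ", target, call. = FALSE)
  }
  for (i in seq_len(60)) {
    mid <- (lo + hi) / 2
    if (.prevalence_at(lat, cfg, mid) < target) lo <- mid else hi <- mid
    if (hi - lo < 1e-9) break
  }
  c0 <- (lo + hi) / 2
  achieved <- .prevalence_at(lat, cfg, c0)
  if (abs(achieved - target) > tol) {
    stop("calibration failure: best achievable prevalence ",
         signif(achieved, 5), " misses the target ", target,
         " by more than tol = ", tol, call. = FALSE)
  }
  cfg$outcome$intercept <- c0
  attr(cfg, "achieved_prev") <- achieved
  cfg
}

#' Inject missing values into a roster
#'
#' @param roster Participant data frame.
#' @param rates Named per-variable missingness rates in \[0, 1\].
#' @param mechanism `"MCAR"` (default) or `"MAR"`; under MAR the
#'   missingness probability is a logistic function of the observed
#'   driver variable, with its intercept solved so the mean rate matches
#'   the requested rate.
#' @param driver Driver variable name (MAR only); must itself be fully
#'   observed.
#' @param mar_slope Logistic slope on the standardised driver (MAR).
#' @param seed Optional seed; if `NULL` the current RNG stream is used.
#' @return The roster with `NA` markers placed.
#' @export
inject_missingness <- function(roster, rates, mechanism = c("MCAR", "MAR"),
                               driver = NULL, mar_slope = 1, seed = NULL) {
  mechanism <- match.arg(mechanism)
  if (any(rates < 0 | rates > 1)) {
    stop("missingness rates must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(roster)
  if (mechanism == "MAR") {
    if (is.null(driver) || is.null(roster[[driver]])) {
      stop("MAR missingness needs a driver variable present in the roster",
           call. = FALSE)
    }
    if (anyNA(roster[[driver]])) {
      stop("MAR driver '", driver, "' has missing values", call. = FALSE)
    }
    zd <- as.numeric(scale(as.numeric(roster[[driver]])))
  }
  for (v in names(rates)) {
    if (is.null(roster[[v]]) || rates[[v]] == 0) next
    if (rates[[v]] == 1) { roster[[v]][] <- NA; next }
    if (mechanism == "MCAR") {
      hit <- stats::runif(n) < rates[[v]]
    } else {
      a <- stats::uniroot(
        function(a) mean(stats::plogis(a + mar_slope * zd)) - rates[[v]],
        c(-20, 20))$root
      hit <- stats::runif(n) < stats::plogis(a + mar_slope * zd)
    }
    roster[[v]][hit] <- NA
  }
  roster
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> n_total =", x$n_total,
      "| female fraction =", x$female_frac, "\n")
  cat("  target WHO prevalence:", x$target_prev,
      "| outcome intercept:", signif(x$outcome$intercept, 5), "\n")
  cat("  prior-diagnosis fraction:", signif(x$frac_prior_diagnosis, 4), "\n")
  invisible(x)
}
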