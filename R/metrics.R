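#' @title Discrimination, calibration and threshold statistics
#' @description
#' The performance block computed for every validated model: concordance
#' statistic with a DeLong confidence interval and paired model-to-model
#' comparison, expected/observed ratio with a log-scale Poisson interval,
#' Brier score, Yates slope, quantile-binned calibration curves and
#' Youden-index threshold statistics.
#' @name validation_metrics
NULL

.check_preds <- function(p, y) {
  if (length(p) != length(y)) stop("p and y must have the same length", call. = FALSE)
  if (length(p) < 1) stop("empty prediction set", call. = FALSE)
  if (anyNA(p) || anyNA(y)) stop("prediction set contains missing values", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("predicted probabilities must lie in [0, 1]", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("outcomes must be 0/1", call. = FALSE)
  invisible(TRUE)
}

.check_two_class <- function(y, what) {
  if (sum(y == 1) == 0 || sum(y == 0) == 0) {
    stop(what, " is undefined without at least one event and one non-event",
         call. = FALSE)
  }
}

# DeLong structural components via midranks (Sun & Xu fast algorithm):
# v10[i] = P(p_event_i > p_nonevent) + 0.5 P(tie), and symmetrically v01.
.delong_components <- function(p, y) {
  ev <- y == 1
  m <- sum(ev); n0 <- sum(!ev)
  r_all <- rank(p, ties.method = "average")
  r_ev <- rank(p[ev], ties.method = "average")
  r_ne <- rank(p[!ev], ties.method = "average")
  v10 <- (r_all[ev] - r_ev) / n0
  v01 <- 1 - (r_all[!ev] - r_ne) / m
  auc <- (sum(r_all[ev]) - m * (m + 1) / 2) / (m * n0)
  list(auc = auc, v10 = v10, v01 = v01, m = m, n0 = n0)
}

#' Concordance (C) statistic with DeLong confidence interval
#'
#' The probability that a randomly chosen event receives a higher
#' predicted probability than a randomly chosen non-event, with ties
#' counted half. The confidence interval uses the nonparametric variance
#' of the concordance estimator (DeLong structural components), truncated
#' to \[0, 1\].
#'
#' @param p Predicted probabilities.
#' @param y 0/1 outcomes.
#' @param conf Confidence level (default 0.95).
#' @return List with `c`, `se`, `ci_low`, `ci_high`, `n_events`,
#'   `n_nonevents`.
#' @export
c_statistic <- function(p, y, conf = 0.95) {
  .check_preds(p, y)
  .check_two_class(y, "the C-statistic")
  d <- .delong_components(p, y)
  s10 <- if (d$m > 1) stats::var(d$v10) else 0
  s01 <- if (d$n0 > 1) stats::var(d$v01) else 0
  se <- sqrt(s10 / d$m + s01 / d$n0)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(c = d$auc, se = se,
       ci_low = max(0, d$auc - z * se),
       ci_high = min(1, d$auc + z * se),
       n_events = d$m, n_nonevents = d$n0)
}

#' Compare two correlated C-statistics on the same subjects
#'
#' Paired nonparametric comparison of two models scored on the identical
#' subject list. The default is the DeLong test on the difference of the
#' structural components; `method = "bootstrap"` resamples subjects with
#' replacement and reports a percentile-type two-sided p-value, as a
#' cross-check on the asymptotic test.
#'
#' @param p_a,p_b Predicted probabilities from the two models.
#' @param y Shared 0/1 outcomes.
#' @param method `"delong"` (default) or `"bootstrap"`.
#' @param B Number of bootstrap replicates (bootstrap method only).
#' @param conf Confidence level for the delta interval.
#' @return List with `delta` (`c_a - c_b`), `p_value`, `c_a`, `c_b`,
#'   `ci_low`, `ci_high` (DeLong method) and `method`.
#' @export
compare_c_statistics <- function(p_a, p_b, y, method = c("delong", "bootstrap"),
                                 B = 2000, conf = 0.95) {
  method <- match.arg(method)
  .check_preds(p_a, y)
  .check_preds(p_b, y)
  .check_two_class(y, "a C-statistic comparison")
  if (method == "delong") {
    da <- .delong_components(p_a, y)
    db <- .delong_components(p_b, y)
    delta <- da$auc - db$auc
    if (da$m > 1 && da$n0 > 1) {
      s10 <- stats::cov(cbind(da$v10, db$v10))
      s01 <- stats::cov(cbind(da$v01, db$v01))
      S <- s10 / da$m + s01 / da$n0
      var_d <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
    } else var_d <- 0
    if (var_d <= .Machine$double.eps) {
      # identical rankings: no evidence of a difference
      return(list(delta = delta, p_value = 1, c_a = da$auc, c_b = db$auc,
                  ci_low = delta, ci_high = delta, method = "delong"))
    }
    se <- sqrt(var_d)
    z <- delta / se
    q <- stats::qnorm(1 - (1 - conf) / 2)
    list(delta = delta, p_value = 2 * stats::pnorm(-abs(z)),
         c_a = da$auc, c_b = db$auc,
         ci_low = delta - q * se, ci_high = delta + q * se,
         method = "delong")
  } else {
    n <- length(y)
    auc_of <- function(pp, yy) {
      m <- sum(yy == 1); n0 <- sum(yy == 0)
      r <- rank(pp, ties.method = "average")
      (sum(r[yy == 1]) - m * (m + 1) / 2) / (m * n0)
    }
    d_obs <- auc_of(p_a, y) - auc_of(p_b, y)
    d_star <- numeric(B)
    kept <- 0L
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      yy <- y[idx]
      if (sum(yy == 1) == 0 || sum(yy == 0) == 0) next
      kept <- kept + 1L
      d_star[kept] <- auc_of(p_a[idx], yy) - auc_of(p_b[idx], yy)
    }
    d_star <- d_star[seq_len(kept)]
    p_val <- 2 * min(mean(d_star <= 0), mean(d_star >= 0))
    p_val <- min(1, max(p_val, 1 / (kept + 1)))
    if (stats::sd(d_star) == 0 && d_obs == 0) p_val <- 1
    list(delta = d_obs, p_value = p_val,
         c_a = auc_of(p_a, y), c_b = auc_of(p_b, y),
         ci_low = unname(stats::quantile(d_star, (1 - conf) / 2)),
         ci_high = unname(stats::quantile(d_star, 1 - (1 - conf) / 2)),
         method = "bootstrap")
  }
}

#' Brier score
#'
#' Mean squared difference between predicted probability and outcome;
#' 0 for a perfect model, bounded by 1.
#'
#' @inheritParams c_statistic
#' @return The Brier score.
#' @export
brier_score <- function(p, y) {
  .check_preds(p, y)
  mean((p - y)^2)
}

#' Yates slope
#'
#' Difference between the mean predicted probability among events and
#' among non-events; higher values indicate better separation.
#'
#' @inheritParams c_statistic
#' @return The Yates slope.
#' @export
yates_slope <- function(p, y) {
  .check_preds(p, y)
  .check_two_class(y, "the Yates slope")
  mean(p[y == 1]) - mean(p[y == 0])
}

#' Expected/observed ratio with a Poisson confidence interval
#'
#' `E` is the sum of predicted probabilities (expected events), `O` the
#' observed event count. The 95% interval assumes the observed count is
#' Poisson and works on the log scale:
#' `ratio * exp(+/- z / sqrt(O))`.
#'
#' @inheritParams c_statistic
#' @return List of class `eo_ratio` with `e`, `o`, `ratio`, `ci_low`,
#'   `ci_high`.
#' @export
eo_ratio <- function(p, y, conf = 0.95) {
  .check_preds(p, y)
  e <- sum(p); o <- sum(y)
  if (o == 0) {
    stop("E/O ratio undefined: no observed events (expected events = ",
         signif(e, 4), ")", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ratio <- e / o
  structure(list(e = e, o = o, ratio = ratio,
                 ci_low = ratio * exp(-z / sqrt(o)),
                 ci_high = ratio * exp(z / sqrt(o))),
            class = "eo_ratio")
}

#' Express an E/O ratio as signed over/underestimation percent
#'
#' A ratio of 1.81 becomes "overestimated by 81%", a ratio of 0.26
#' "underestimated by 74%"; confidence limits are mapped by the same
#' affine function and reported in increasing order.
#'
#' @param r An [eo_ratio] result (or a list with `ratio`, `ci_low`,
#'   `ci_high`).
#' @return List with `direction` (`"overestimated"`/`"underestimated"`),
#'   `percent`, `ci_low`, `ci_high`.
#' @export
miscalibration_percent <- function(r) {
  stopifnot(is.numeric(r$ratio))
  if (r$ratio >= 1) {
    ci <- sort(100 * (c(r$ci_low, r$ci_high) - 1))
    list(direction = "overestimated", percent = 100 * (r$ratio - 1),
         ci_low = ci[1], ci_high = ci[2])
  } else {
    ci <- sort(100 * (1 - c(r$ci_low, r$ci_high)))
    list(direction = "underestimated", percent = 100 * (1 - r$ratio),
         ci_low = ci[1], ci_high = ci[2])
  }
}

#' Calibration curve by quantile bins of predicted risk
#'
#' Participants are ranked on predicted probability and grouped into
#' `n_bins` equal-occupancy bins (deciles by default); tied predicted
#' values always share a bin, so a constant predictor yields a single
#' occupied bin. Each bin reports the mean predicted risk, the observed
#' event rate and the count; the sorted predicted probabilities are
#' returned as rug data for the frequency strip under a calibration plot.
#'
#' @inheritParams c_statistic
#' @param n_bins Number of quantile bins (default 10).
#' @return List of class `calibration_curve` with `bins` (data frame:
#'   `bin`, `mean_pred`, `obs_rate`, `count`), `rug`, `n_bins_requested`.
#' @export
calibration_curve <- function(p, y, n_bins = 10) {
  .check_preds(p, y)
  n <- length(p)
  if (n < n_bins) {
    stop("cannot form ", n_bins, " calibration bins from ", n,
         " observations; choose n_bins <= ", n, call. = FALSE)
  }
  o <- order(p)
  ps <- p[o]; ys <- y[o]
  bin <- ceiling(seq_len(n) * n_bins / n)
  # tied predicted values must not straddle a bin boundary
  bin <- stats::ave(bin, ps, FUN = function(b) b[1])
  bins <- data.frame(
    bin = seq_along(unique(bin)),
    mean_pred = as.numeric(tapply(ps, bin, mean)),
    obs_rate = as.numeric(tapply(ys, bin, mean)),
    count = as.integer(tapply(ys, bin, length))
  )
  structure(list(bins = bins, rug = ps, n_bins_requested = n_bins),
            class = "calibration_curve")
}

.threshold_scan <- function(p, y) {
  o <- order(p, decreasing = TRUE)
  ps <- p[o]; ys <- y[o]
  m <- sum(ys); n0 <- length(ys) - m
  runs <- rle(ps)
  idx <- cumsum(runs$lengths)      # last index of each distinct value
  ctp <- cumsum(ys)[idx]           # events with p >= threshold
  cfp <- cumsum(1 - ys)[idx]       # non-events with p >= threshold
  data.frame(threshold = runs$values,
             sens = ctp / m,
             spec = (n0 - cfp) / n0,
             tp = ctp, fp = cfp)
}

.threshold_perf <- function(threshold, sens, spec, prev) {
  list(threshold = threshold,
       sensitivity = 100 * sens,
       specificity = 100 * spec,
       correctly_classified = 100 * (sens * prev + spec * (1 - prev)),
       youden_j = sens + spec - 1)
}

#' Optimal classification threshold by Youden's index
#'
#' Scans every distinct predicted probability as a candidate threshold
#' (classification rule: positive iff `p >= threshold`) and returns the
#' threshold maximising `J = sensitivity + specificity - 1`. Ties in `J`
#' are broken in favour of the lower threshold (higher sensitivity).
#'
#' @inheritParams c_statistic
#' @return List with `threshold`, `sensitivity`, `specificity`,
#'   `correctly_classified` (percentages) and `youden_j`.
#' @export
optimal_threshold <- function(p, y) {
  .check_preds(p, y)
  .check_two_class(y, "threshold selection")
  sc <- .threshold_scan(p, y)
  j <- sc$sens + sc$spec - 1
  best <- which(j == max(j))
  pick <- best[which.min(sc$threshold[best])]
  prev <- mean(y)
  .threshold_perf(sc$threshold[pick], sc$sens[pick], sc$spec[pick], prev)
}

#' Classification statistics at a fixed threshold
#'
#' @inheritParams c_statistic
#' @param threshold Probability threshold; positive iff `p >= threshold`.
#' @return List with `threshold`, `sensitivity`, `specificity`,
#'   `correctly_classified` (percentages) and `youden_j`. With a
#'   single-class outcome the undefined rate is returned as `NaN`.
#' @export
classification_at <- function(p, y, threshold) {
  .check_preds(p, y)
  pos <- p >= threshold
  m <- sum(y == 1); n0 <- sum(y == 0)
  sens <- if (m > 0) sum(pos & y == 1) / m else NaN
  spec <- if (n0 > 0) sum(!pos & y == 0) / n0 else NaN
  .threshold_perf(threshold, sens, spec, mean(y))
}

#' Correctly classified percentage from sensitivity, specificity and prevalence
#'
#' The accounting identity
#' `correctly_classified = sens * prev + spec * (1 - prev)` lets the
#' overall classification accuracy be reconstructed from a report that
#' prints only sensitivity, specificity and the outcome prevalence.
#'
#' @param sensitivity,specificity Percentages in \[0, 100\].
#' @param prev Outcome prevalence as a proportion in \[0, 1\].
#' @return Correctly classified percentage.
#' @export
expected_correct_classification <- function(sensitivity, specificity, prev) {
  stopifnot(prev >= 0, prev <= 1)
  sensitivity * prev + specificity * (1 - prev)
}
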