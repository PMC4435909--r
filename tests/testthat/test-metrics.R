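test_that("C-statistic handles separation, ties and the worked pair count", {
  expect_equal(c_statistic(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))$c, 1)
  expect_equal(c_statistic(rep(0.4, 6), c(1, 0, 1, 0, 0, 0))$c, 0.5)
  expect_equal(c_statistic(c(0.9, 0.8, 0.1, 0.3), c(1, 0, 0, 1))$c, 0.75)
  expect_error(c_statistic(c(0.2, 0.3), c(1, 1)), "undefined")
})

test_that("C-statistic equals brute-force pairwise enumeration", {
  set.seed(101)
  for (i in 1:200) {
    pr <- random_preds(sample(5:120, 1))
    expect_equal(c_statistic(pr$p, pr$y)$c, auc_brute(pr$p, pr$y))
  }
})

test_that("C-statistic is invariant under strictly increasing transforms", {
  set.seed(11)
  maps <- list(function(x) x^3, function(x) plogis(5 * x - 2),
               function(x) exp(x) / (1 + exp(1)), sqrt)
  for (i in 1:25) {
    pr <- random_preds(80)
    c0 <- c_statistic(pr$p, pr$y)$c
    f <- maps[[sample(length(maps), 1)]]
    expect_equal(c_statistic(f(pr$p), pr$y)$c, c0)
  }
})

test_that("DeLong interval and paired test agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(2024)
  pr <- random_preds(150, tie_prob = 0)
  cs <- c_statistic(pr$p, pr$y)
  roc <- pROC::roc(pr$y, pr$p, quiet = TRUE, direction = "<")
  ci <- suppressWarnings(pROC::ci.auc(roc, method = "delong"))
  expect_equal(cs$c, as.numeric(pROC::auc(roc)))
  expect_equal(cs$ci_low, as.numeric(ci[1]), tolerance = 1e-8)
  expect_equal(cs$ci_high, as.numeric(ci[3]), tolerance = 1e-8)

  p_b <- plogis(qlogis(pr$p) + rnorm(150, 0, 1.5))
  cmp <- compare_c_statistics(pr$p, p_b, pr$y)
  ref <- pROC::roc.test(roc, pROC::roc(pr$y, p_b, quiet = TRUE,
                                       direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(cmp$p_value, as.numeric(ref$p.value), tolerance = 1e-8)
  expect_equal(cmp$delta, as.numeric(ref$estimate[1] - ref$estimate[2]),
               tolerance = 1e-8)
})

test_that("paired comparison is symmetric and null for a model vs itself", {
  set.seed(5)
  pr <- random_preds(60)
  self <- compare_c_statistics(pr$p, pr$p, pr$y)
  expect_equal(self$delta, 0)
  expect_equal(self$p_value, 1)
  p_b <- runif(60)
  ab <- compare_c_statistics(pr$p, p_b, pr$y)
  ba <- compare_c_statistics(p_b, pr$p, pr$y)
  expect_equal(ab$delta, -ba$delta)
  expect_equal(ab$p_value, ba$p_value)
  expect_error(compare_c_statistics(pr$p, p_b[-1], pr$y), "length")
})

test_that("bootstrap comparison broadly matches the asymptotic test", {
  set.seed(99)
  pr <- random_preds(20, tie_prob = 0)
  p_b <- plogis(qlogis(pr$p) + rnorm(20, 0, 2))
  d <- compare_c_statistics(pr$p, p_b, pr$y, method = "delong")
  b <- compare_c_statistics(pr$p, p_b, pr$y, method = "bootstrap", B = 4000)
  expect_equal(b$delta, d$delta)
  expect_lt(abs(b$p_value - d$p_value), 0.15)
  same <- compare_c_statistics(pr$p, pr$p, pr$y, method = "bootstrap", B = 500)
  expect_equal(same$p_value, 1)
})

test_that("Brier score matches hand sums and its constant-p closed form", {
  expect_equal(brier_score(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(brier_score(rep(0.5, 8), rbinom(8, 1, 0.5)), 0.25)
  expect_equal(brier_score(c(0.8, 0.2, 0.6), c(1, 0, 0)),
               (0.04 + 0.04 + 0.36) / 3)
  set.seed(3)
  y <- rbinom(400, 1, 0.3)
  prev <- mean(y)
  expect_equal(brier_score(rep(prev, 400), y), prev * (1 - prev))
})

test_that("Yates slope separates mean risk between cases and non-cases", {
  expect_equal(yates_slope(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(yates_slope(rep(0.3, 5), c(1, 0, 0, 1, 0)), 0)
  expect_equal(yates_slope(c(0.8, 0.2, 0.6), c(1, 0, 0)), 0.4)
  expect_error(yates_slope(c(0.1, 0.2), c(1, 1)), "undefined")
})

test_that("E/O ratio carries the log-scale Poisson interval", {
  set.seed(8)
  y <- rbinom(50, 1, 0.4)
  eo1 <- eo_ratio(as.numeric(y), y)
  expect_equal(eo1$ratio, 1)
  expect_equal(eo_ratio(c(0.7, 0.8), c(1, 0))$ratio, 1.5)
  # o = 100, ratio = 1: interval exp(+/- 1.96.../10)
  p <- rep(0.5, 200); yy <- rep(c(1, 0), 100)
  eo <- eo_ratio(p, yy)
  z <- qnorm(0.975)
  expect_equal(eo$ci_low, exp(-z / 10))
  expect_equal(eo$ci_high, exp(z / 10))
  expect_true(eo$ci_low <= eo$ratio && eo$ratio <= eo$ci_high)
  err <- tryCatch(eo_ratio(c(0.2, 0.3), c(0, 0)), error = identity)
  expect_match(conditionMessage(err), "no observed events")
  expect_match(conditionMessage(err), "0.5")  # expected events carried
})

test_that("calibration curve bins by quantile with tie-safe grouping", {
  set.seed(12)
  # perfectly calibrated: bin observed rates sit on the diagonal
  p <- runif(5000)
  y <- rbinom(5000, 1, p)
  cc <- calibration_curve(p, y, 10)
  expect_equal(sum(cc$bins$count), 5000)
  expect_true(all(diff(cc$bins$mean_pred) > 0))
  binom_se <- sqrt(cc$bins$mean_pred * (1 - cc$bins$mean_pred) /
                     cc$bins$count)
  expect_true(all(abs(cc$bins$obs_rate - cc$bins$mean_pred) < 4 * binom_se))
  expect_equal(cc$rug, sort(p))

  # constant predictor: one occupied bin
  cc1 <- calibration_curve(rep(0.3, 40), rbinom(40, 1, 0.3))
  expect_equal(nrow(cc1$bins), 1)
  expect_equal(cc1$bins$mean_pred, 0.3)
  expect_equal(cc1$bins$count, 40)

  # 100 distinct values in 10 bins of 10
  p100 <- (1:100) / 101
  cc2 <- calibration_curve(p100, rbinom(100, 1, p100), 10)
  expect_equal(cc2$bins$count, rep(10L, 10))

  expect_error(calibration_curve(runif(5), rbinom(5, 1, 0.5), 10),
               "n_bins <= 5")
})

test_that("Youden threshold scan matches the worked example and edge cases", {
  res <- optimal_threshold(c(0.9, 0.6, 0.7, 0.2, 0.1), c(1, 1, 0, 0, 0))
  expect_equal(res$threshold, 0.6)
  expect_equal(res$sensitivity, 100)
  expect_equal(res$specificity, 100 * 2 / 3)
  expect_equal(res$youden_j, 2 / 3)

  sep <- optimal_threshold(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(sep$youden_j, 1)
  expect_equal(sep$sensitivity, 100)
  expect_equal(sep$specificity, 100)

  flat <- optimal_threshold(rep(0.4, 10), rep(c(1, 0), 5))
  expect_equal(flat$youden_j, 0)
  expect_error(optimal_threshold(runif(4), rep(1, 4)), "undefined")
})

test_that("ties in J are broken towards the lower threshold", {
  # thresholds 0.2 and 0.6 both give J = 0.5; the lower (higher
  # sensitivity) must win
  p <- c(0.6, 0.2, 0.6, 0.2)
  y <- c(1, 1, 0, 0)
  sc_j <- function(t) {
    sum(p >= t & y == 1) / 2 + sum(p < t & y == 0) / 2 - 1
  }
  expect_equal(sc_j(0.2), sc_j(0.6))  # genuine tie
  expect_equal(optimal_threshold(p, y)$threshold, 0.2)
})

test_that("classification accounting identity holds at every threshold", {
  set.seed(21)
  pr <- random_preds(150)
  prev <- mean(pr$y)
  for (t in c(0, sort(unique(pr$p)), 1)) {
    cl <- classification_at(pr$p, pr$y, t)
    expect_equal(cl$correctly_classified,
                 expected_correct_classification(cl$sensitivity,
                                                 cl$specificity, prev))
    expect_equal(cl$youden_j,
                 cl$sensitivity / 100 + cl$specificity / 100 - 1)
  }
  all_pos <- classification_at(pr$p, pr$y, 0)
  expect_equal(all_pos$sensitivity, 100)
  expect_equal(all_pos$specificity, 0)
})

test_that("miscalibration percent maps the ratio and CI affinely", {
  over <- miscalibration_percent(list(ratio = 1.5, ci_low = 1.2,
                                      ci_high = 1.9))
  expect_equal(over$direction, "overestimated")
  expect_equal(over$percent, 50)
  expect_equal(c(over$ci_low, over$ci_high), c(20, 90))
  under <- miscalibration_percent(list(ratio = 0.5, ci_low = 0.4,
                                       ci_high = 0.8))
  expect_equal(under$direction, "underestimated")
  expect_equal(under$percent, 50)
  expect_equal(c(under$ci_low, under$ci_high), c(20, 60))
  expect_equal(miscalibration_percent(list(ratio = 1, ci_low = 0.9,
                                           ci_high = 1.1))$percent, 0)
})
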