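test_that("bundled specs load and expose the published predictor structure", {
  ms <- bundled_models()
  expect_setequal(names(ms), c("cambridge", "kuwaiti", "omani",
                               "rotterdam_1", "finnish_simplified"))
  expected <- list(
    cambridge = c("age", "sex", "bmi", "on_htn_meds", "fh_cat", "smoker",
                  "corticosteroids"),
    kuwaiti = c("age", "on_htn_meds", "fh_any", "waist"),
    omani = c("age", "bmi", "waist", "fh_any", "sbp", "dbp"),
    rotterdam_1 = c("age", "sex", "bmi", "on_htn_meds"),
    finnish_simplified = c("age", "sex", "bmi", "on_htn_meds", "fh_cat",
                           "smoker", "corticosteroids")
  )
  for (nm in names(expected)) {
    expect_setequal(required_variables(ms[[nm]]), expected[[nm]])
    expect_true(ms[[nm]]$synthetic_coefficients)
  }
})

test_that("invalid specifications are rejected, not repaired", {
  terms_ok <- list(list(variable = "age", transform = "identity",
                        coefficient = 0.05))
  expect_error(model_spec("m", 0, c(terms_ok, terms_ok)), "duplicated")
  expect_error(model_spec("m", 0, list(list(variable = "shoe_size",
                                            transform = "identity",
                                            coefficient = 1))),
               "legal variables")
  expect_error(model_spec("m", 0, terms_ok, link = "probit"),
               "unrecognised link")
  expect_error(model_spec("m", 0, list(list(
    variable = "age", transform = "binned",
    cutpoints = c(50, 40), values = c(0, 1, 2)))), "strictly increasing")
  expect_error(model_spec("m", 0, list(list(
    variable = "age", transform = "binned",
    cutpoints = c(40, 50), values = c(0, 1)))), "one value per bin")
  expect_error(model_spec("m", 0, list(list(
    variable = "sex", transform = "categorical",
    levels = list(other = 1)))), "illegal categor")
  # parse failure surfaces as a format error naming the file
  bad <- tempfile(fileext = ".yaml")
  writeLines("name: [unclosed", bad)
  expect_error(load_model_spec(bad), "cannot parse")
  unlink(bad)
})

test_that("linear predictor sums transformed terms deterministically", {
  d <- data.frame(age = 52, sex = "female", bmi = 26, waist = 95,
                  on_htn_meds = TRUE, smoker = FALSE,
                  corticosteroids = FALSE, stringsAsFactors = FALSE)
  zero <- model_spec("zero", 0, list(list(variable = "age",
                                          transform = "identity",
                                          coefficient = 0)))
  expect_equal(linear_predictor(zero, d), 0)

  single <- model_spec("single", -1, list(list(variable = "age",
                                               transform = "identity",
                                               coefficient = 2)))
  expect_equal(linear_predictor(single, data.frame(age = 3)), 5)

  binned <- model_spec("bands", 0, list(list(
    variable = "age", transform = "binned",
    cutpoints = c(45, 55, 65), values = c(0, 2, 3, 4))))
  expect_equal(linear_predictor(binned, data.frame(age = 52)), 2)
  expect_equal(linear_predictor(binned, data.frame(age = 44.9)), 0)
  expect_equal(linear_predictor(binned, data.frame(age = 55)), 3)  # left-closed
  expect_equal(linear_predictor(binned, data.frame(age = 90)), 4)

  # pure function: identical input -> bit-identical output
  ms <- bundled_models()
  dd <- derive_variables(make_roster(10))
  expect_identical(predict_probability(ms$cambridge, dd),
                   predict_probability(ms$cambridge, dd))
})

test_that("missing predictors raise an error naming the variable", {
  single <- model_spec("single", 0, list(list(variable = "bmi",
                                              transform = "identity",
                                              coefficient = 1)))
  expect_error(linear_predictor(single, data.frame(bmi = c(25, NA))),
               "bmi")
  expect_error(linear_predictor(single, data.frame(age = 50)),
               "missing predictor column 'bmi'")
})

test_that("predicted probability is the logistic of the linear predictor", {
  lp0 <- model_spec("lp0", 0, list(list(variable = "age",
                                        transform = "identity",
                                        coefficient = 0)))
  expect_equal(predict_probability(lp0, data.frame(age = 1)), 0.5)
  lp3 <- model_spec("lp3", log(3), list(list(variable = "age",
                                             transform = "identity",
                                             coefficient = 0)))
  expect_equal(predict_probability(lp3, data.frame(age = 1)), 0.75)
  big <- model_spec("big", 0, list(list(variable = "age",
                                        transform = "identity",
                                        coefficient = 1)))
  p <- predict_probability(big, data.frame(age = c(1, 3, 10, 25)))
  expect_true(all(diff(p) > 0))
  expect_gt(predict_probability(big, data.frame(age = 500)), 1 - 1e-12)
})

test_that("probability is strictly monotone in the linear predictor", {
  set.seed(7)
  ms <- bundled_models()
  d <- derive_variables(generate_cohort(sim_config(), n = 300, seed = 11,
                                        inject_missing = FALSE))
  for (nm in names(ms)) {
    lp <- linear_predictor(ms[[nm]], d)
    p <- predict_probability(ms[[nm]], d)
    expect_identical(order(lp), order(p))
  }
})

test_that("point-score models map the score through score_to_lp", {
  sc <- model_spec("score", 0,
                   list(list(variable = "age", transform = "binned",
                             cutpoints = c(50), values = c(0, 2))),
                   score_to_lp = list(intercept = -4, slope = 0.5))
  expect_equal(linear_predictor(sc, data.frame(age = 60)), -4 + 0.5 * 2)
  expect_equal(linear_predictor(sc, data.frame(age = 40)), -4)
})

test_that("model specs survive a write/load round trip", {
  ms <- bundled_models()
  tmp <- tempfile(fileext = ".yaml")
  write_model_spec(ms$omani, tmp)
  back <- load_model_spec(tmp)
  d <- derive_variables(make_roster(15))
  expect_equal(predict_probability(back, d), predict_probability(ms$omani, d))
  unlink(tmp)
})
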