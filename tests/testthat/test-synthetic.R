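zero_error_params <- function(seed = 3, ...) {
  scenario_params(omission_rate = 0, phantom_rate = 0, name_error_rate = 0,
                  within_unit_location_error_rate = 0,
                  cross_unit_geocode_rate = 0, category_confusion = 0,
                  duplicate_rate = 0, seed = seed, ...)
}

test_that("a zero-error scenario lists exactly the field truth", {
  sc <- generate_scenario(zero_error_params())
  expect_equal(nrow(sc$db_listing), nrow(sc$field_truth))
  expect_setequal(sc$db_listing$name_norm, sc$field_truth$name_norm)
  disp <- classify_dispositions(sc$db_listing, sc$field_truth)
  expect_true(all(disp$disposition == "matched"))
  cc <- confusion_counts(disp, "traditional")
  expect_equal(sensitivity(cc), 1)
  expect_equal(ppv(cc), 1)
})

test_that("total omission empties the listing and zeroes sensitivity", {
  p <- zero_error_params(seed = 4)
  p$omission_rate <- 1
  sc <- generate_scenario(p)
  expect_equal(nrow(sc$db_listing), 0)
  disp <- classify_dispositions(sc$db_listing, sc$field_truth)
  expect_true(all(disp$disposition == "unlisted"))
  expect_equal(sensitivity(confusion_counts(disp, "traditional")), 0)
})

test_that("identical seeds give identical scenarios; the RNG stream is untouched", {
  p <- scenario_params(n_units = 4, outlets_per_unit = 20, seed = 42)
  a <- generate_scenario(p)
  set.seed(1); before <- runif(1)
  b <- generate_scenario(p)
  set.seed(1); after <- runif(1)
  expect_identical(a$db_listing, b$db_listing)
  expect_identical(a$field_truth, b$field_truth)
  expect_identical(a$truth_log, b$truth_log)
  expect_identical(before, after)
})

test_that("invalid rates and weights are configuration errors", {
  expect_error(scenario_params(omission_rate = 1.2),
               class = "poivalid_config_error")
  expect_error(scenario_params(category_weights = c(cafes = 0.5)),
               class = "poivalid_config_error")
})

test_that("expected metrics follow the closed forms", {
  p <- zero_error_params()
  expect_equal(unname(expected_metrics(p)), rep(1, 4))
  p$omission_rate <- 0.2
  em <- expected_metrics(p)
  expect_equal(em[["sensitivity_relaxed"]], 0.8)
  expect_equal(em[["sensitivity_traditional"]], 0.8)
  expect_equal(em[["ppv_relaxed"]], 1)
  q <- zero_error_params()
  q$phantom_rate <- 0.25
  expect_equal(expected_metrics(q)[["ppv_traditional"]], 0.75)
  expect_equal(expected_metrics(q)[["sensitivity_traditional"]], 1)
})

test_that("estimates track closed-form expectations on a handful of scenarios", {
  p <- scenario_params(n_units = 9, outlets_per_unit = 120, seed = 0)
  em <- expected_metrics(p)
  devs <- replicate(6, NA_real_)
  for (s in seq_along(devs)) {
    p$seed <- 500 + s
    sc <- generate_scenario(p)
    disp <- classify_dispositions(deduplicate(sc$db_listing)$kept,
                                  sc$field_truth)
    unl <- sc$field_truth[sc$field_truth$record_id %in%
                            disp$field_record_id[disp$disposition == "unlisted"], ]
    disp <- mark_ill_extracted(disp, find_ill_extracted(unl, sc$full_db)$ill_extracted)
    est <- sensitivity(confusion_counts(disp, "relaxed"))
    devs[s] <- est - em[["sensitivity_relaxed"]]
  }
  # ~1000 outlets per scenario: binomial sd ~ 0.015; mean of 6 within 4 se
  expect_lt(abs(mean(devs)), 4 * 0.015 / sqrt(length(devs)))
})

test_that("matched omission and phantoms in one category drive compensation", {
  p <- zero_error_params(seed = 8)
  p$omission_rate <- 0.25
  p$phantom_rate <- 0.2
  sc <- generate_scenario(p)
  disp <- classify_dispositions(sc$db_listing, sc$field_truth)
  cc <- confusion_counts(disp, "relaxed")
  pu <- unit_metrics(cc)
  comp <- sum(pmin(cc$fp, cc$fn))
  expect_gt(comp, 0)
  expect_equal(aggregate_weighted(pu, "representativity") -
                 aggregate_weighted(pu, "sensitivity"),
               comp / (sum(cc$tp) + sum(cc$fn)))
})
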