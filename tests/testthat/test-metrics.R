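test_that("sensitivity and PPV are the pooled confusion ratios", {
  expect_equal(sensitivity(confusion_cell(tp = 264, fp = 146, fn = 220)),
               264 / 484)
  expect_equal(sensitivity(confusion_cell(tp = 317, fp = 93, fn = 167)),
               317 / 484)
  expect_equal(ppv(confusion_cell(tp = 264, fp = 146, fn = 220)), 264 / 410)
  expect_equal(ppv(confusion_cell(tp = 317, fp = 93, fn = 167)), 317 / 410)
  expect_equal(sensitivity(confusion_cell(tp = 0, fp = 0, fn = 7)), 0)
  expect_equal(ppv(confusion_cell(tp = 5, fp = 0, fn = 2)), 1)
  expect_message(out <- sensitivity(confusion_cell(0, 3, 0)), "undefined")
  expect_true(is.na(out))
})

test_that("representativity compensates FNs with same-category FPs", {
  # a unit missing 10 outlets but listing 12 phantoms of that category
  over <- confusion_cell(tp = 0, fp = 12, fn = 10)
  expect_equal(representativity(over), 1)
  expect_equal(representativity(over, "as_printed_abs"), 0.2)
  # partial compensation, capped at the FP count
  part <- confusion_cell(tp = 3, fp = 0, fn = 1)
  expect_equal(representativity(part), 0.75)
  expect_equal(representativity(part, "as_printed_abs"), 1)
  # error-free cell
  clean <- confusion_cell(tp = 4, fp = 0, fn = 0)
  expect_equal(representativity(clean), 1)
  expect_equal(representativity(clean, "as_printed_abs"), 1)
  # per-category compensation within one unit
  cells <- dplyr::bind_rows(
    confusion_cell(tp = 2, fp = 3, fn = 1, category = "cafes"),
    confusion_cell(tp = 5, fp = 0, fn = 4, category = "grocery_stores"))
  expect_equal(representativity(cells), (7 + 1 + 0) / (7 + 5))
})

test_that("the absolute-difference variant can exceed 1 and is flagged", {
  odd <- confusion_cell(tp = 1, fp = 9, fn = 2)
  expect_warning(val <- representativity(odd, "as_printed_abs"),
                 "exceeds 1")
  expect_equal(val, (1 + 7) / 3)
  expect_silent(v2 <- representativity(odd))
  expect_equal(v2, 1)
})

test_that("compensated representativity stays between relaxed sensitivity and 1", {
  set.seed(13)
  for (i in 1:40) {
    k <- sample(1:6, 1)
    cells <- purrr::map_dfr(seq_len(k), function(j) {
      confusion_cell(tp = sample(0:9, 1), fp = sample(0:9, 1),
                     fn = sample(0:9, 1), category = paste0("c", j))
    })
    if (sum(cells$tp) + sum(cells$fn) == 0) next
    r <- suppressMessages(representativity(cells))
    s <- suppressMessages(sensitivity(cells))
    expect_gte(r, s)
    expect_lte(r, 1)
  }
})

test_that("the absolute-difference variant returns 1 whenever all FPs are zero", {
  set.seed(17)
  for (i in 1:20) {
    cells <- purrr::map_dfr(1:3, function(j) {
      confusion_cell(tp = sample(1:9, 1), fp = 0, fn = sample(0:9, 1),
                     category = paste0("c", j))
    })
    expect_equal(representativity(cells, "as_printed_abs"), 1)
  }
})

test_that("weighted aggregation equals the pooled ratio", {
  pu <- tibble::tibble(unit_id = c("a", "b"), mode = "traditional",
                       sensitivity = c(0.5, 0.7), ppv = c(0.5, 0.7),
                       representativity = c(0.5, 0.7),
                       n_field = c(10, 30), n_list = c(10, 30))
  expect_equal(aggregate_weighted(pu, "sensitivity"), 0.65)
  expect_equal(aggregate_weighted(pu[1, ], "ppv"), 0.5)
  # pooled-ratio property on random confusion tables
  set.seed(23)
  for (i in 1:10) {
    cc <- purrr::map_dfr(1:5, function(u) {
      confusion_cell(tp = sample(0:20, 1), fp = sample(0:10, 1),
                     fn = sample(0:10, 1), unit_id = paste0("u", u))
    })
    pu <- unit_metrics(cc)
    pooled <- sum(cc$tp) / (sum(cc$tp) + sum(cc$fn))
    expect_equal(aggregate_weighted(pu, "sensitivity"), pooled)
    pooled_p <- sum(cc$tp) / (sum(cc$tp) + sum(cc$fp))
    expect_equal(aggregate_weighted(pu, "ppv"), pooled_p)
  }
})

test_that("confidence intervals match their closed forms", {
  # wald, hand-evaluated: 0.5 +/- 1.96 * sqrt(0.25/100)
  ci <- confidence_interval(0.5, 100)
  expect_equal(unname(ci), c(0.402, 0.598), tolerance = 1e-3)
  expect_equal(unname(confidence_interval(0, 10)), c(0, 0))
  # wilson at p = 0 has an open upper bound: (z^2/(n+z^2)) for x = 0
  wil <- confidence_interval(0, 10, method = "wilson")
  z <- qnorm(0.975)
  expect_equal(unname(wil), c(0, z^2 / (10 + z^2)), tolerance = 1e-6)
  # between-unit interval centres on the weighted mean
  bu <- confidence_interval(NA, 40, method = "between_unit",
                            per_unit = c(0.5, 0.7), weights = c(10, 30))
  expect_lt(bu[["lo"]], 0.65)
  expect_gt(bu[["hi"]], 0.65)
  expect_error(confidence_interval(0.5, 0), class = "poivalid_data_error")
})

test_that("qualitative labels follow the half-open rating scale", {
  expect_identical(qualitative_label(0.545), "moderate")
  expect_identical(qualitative_label(0.777), "good")
  expect_identical(qualitative_label(c(0.30, 0.301, 0.50, 0.51, 0.70,
                                       0.71, 0.90, 0.91)),
                   c("poor", "fair", "fair", "moderate", "moderate",
                     "good", "good", "excellent"))
})
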