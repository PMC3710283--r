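demo_report <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- demo_foodscape()
      cache <<- run_validation(fx$db_listing, fx$field_truth, fx$units,
                               full_db = fx$full_db)
    }
    cache
  }
})

test_that("the end-to-end pipeline reports the fixture's overall block", {
  rep <- demo_report()
  ov <- rep$overall
  pick <- function(m, ms) ov$estimate[ov$mode == m & ov$measure == ms]
  expect_equal(pick("traditional", "sensitivity"), 264 / 484)
  expect_equal(pick("traditional", "ppv"), 264 / 410)
  expect_equal(pick("relaxed", "sensitivity"), 317 / 484)
  expect_equal(pick("relaxed", "ppv"), 317 / 410)
  expect_identical(ov$label[ov$mode == "traditional" &
                              ov$measure == "sensitivity"], "moderate")
  expect_equal(nrow(rep$per_unit), 24)  # 12 units x 2 modes
})

test_that("variation block covers groupings and categories in both modes", {
  rep <- demo_report()
  v <- rep$variation
  expect_setequal(unique(v$grouping), c("ses", "language", "category"))
  # the category tests on relaxed measures are significant on this fixture
  p_rel <- v$p_value[v$mode == "relaxed" & v$grouping == "category" &
                       v$measure == "sensitivity"]
  expect_lt(p_rel, 0.005)
})

test_that("report files are written and reruns are byte-identical", {
  rep <- demo_report()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_report(rep, d1)
  write_report(rep, d2)
  for (f in c("report.json", "dispositions.csv", "per_unit.csv")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  parsed <- jsonlite::fromJSON(file.path(d1, "report.json"))
  expect_equal(nrow(parsed$overall), 6)
  expect_true(nzchar(parsed$config_hash))
})

test_that("an empty field census warns and yields an all-FN listing", {
  fx <- demo_foodscape()
  expect_warning(
    rep <- run_validation(fx$db_listing, fx$field_truth[0, ], fx$units),
    "field census is empty")
  disp <- rep$dispositions
  expect_true(all(disp$disposition == "not_found"))
})

test_that("cmd_validate runs from files end to end", {
  dir <- withr::local_tempdir()
  paths <- write_demo_foodscape(dir)
  out <- file.path(dir, "out")
  rep <- cmd_validate(paths[["db"]], paths[["field"]], paths[["units"]],
                      out, full_db = paths[["full_db"]])
  expect_true(file.exists(file.path(out, "report.json")))
  expect_true(file.exists(file.path(out, "run.log")))
  ov <- rep$overall
  expect_equal(ov$estimate[ov$mode == "traditional" &
                             ov$measure == "sensitivity"], 264 / 484)
})

test_that("cmd_simulate recovers a zero-error scenario perfectly", {
  p <- scenario_params(n_units = 4, outlets_per_unit = 15,
                       omission_rate = 0, phantom_rate = 0,
                       name_error_rate = 0,
                       within_unit_location_error_rate = 0,
                       cross_unit_geocode_rate = 0, category_confusion = 0,
                       duplicate_rate = 0, seed = 6)
  out <- withr::local_tempdir()
  res <- cmd_simulate(p, out)
  expect_equal(unname(res$expected), rep(1, 4))
  est <- res$estimated[c("sensitivity_traditional", "ppv_traditional",
                         "sensitivity_relaxed", "ppv_relaxed")]
  expect_equal(unname(est), rep(1, 4))
  expect_true(file.exists(file.path(out, "recovery.csv")))
})

test_that("scenario YAML round-trips through read_scenario_params", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_units: 3", "outlets_per_unit: 10", "omission_rate: 0.1",
               "seed: 9"), p)
  params <- read_scenario_params(p)
  expect_equal(params$n_units, 3L)
  expect_equal(params$omission_rate, 0.1)
  writeLines("bogus_key: 1", p)
  expect_error(read_scenario_params(p), class = "poivalid_config_error")
})

test_that("the command-line script wires subcommands and exit codes", {
  cli <- system.file("cli", "poivalid", package = "poivalid")
  rscript <- file.path(R.home("bin"), "Rscript")
  bad <- suppressWarnings(system2(rscript, c(cli, "validate"),
                                  stdout = TRUE, stderr = TRUE))
  expect_equal(attr(bad, "status"), 2)
  none <- suppressWarnings(system2(rscript, c(cli, "nonsense"),
                                   stdout = TRUE, stderr = TRUE))
  expect_equal(attr(none, "status"), 2)
})
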