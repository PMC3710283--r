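test_that("identical records match; orphans become not-found / unlisted", {
  db <- mk_outlets("database", c("Provigo", "Lone Lister"),
                   c("1 Main St", "9 Side St"),
                   category = "chain_supermarkets", record_id = c("d1", "d2"))
  field <- mk_outlets("field", c("Provigo", "Lone Walker"),
                      c("1 Main St", "4 Back St"),
                      category = c("chain_supermarkets", "cafes"),
                      record_id = c("f1", "f2"))
  disp <- classify_dispositions(db, field)
  expect_identical(
    as.character(disp$disposition[disp$db_record_id == "d1" & !is.na(disp$db_record_id)][1]),
    "matched")
  expect_identical(
    as.character(disp$disposition[!is.na(disp$db_record_id) & disp$db_record_id == "d2"]),
    "not_found")
  expect_identical(
    as.character(disp$disposition[!is.na(disp$field_record_id) & disp$field_record_id == "f2"]),
    "unlisted")
})

test_that("a renamed outlet at the same address and category is a name error", {
  db <- mk_outlets("database", "Chez Luc", "1 Main St",
                   category = "full_service_restaurants")
  field <- mk_outlets("field", "Chez Marc", "1 Main St",
                      category = "full_service_restaurants",
                      record_id = "f1")
  disp <- classify_dispositions(db, field)
  hit <- disp[!is.na(disp$db_record_id) & !is.na(disp$field_record_id), ]
  expect_identical(as.character(hit$disposition), "name_error")
  # hand-scored token similarity: {chez luc} vs {chez marc} -> 0.5 < 0.85
  expect_equal(hit$similarity, 0.5)
})

test_that("every stage of the disposition taxonomy is reachable", {
  cats <- c("grocery_stores", "cafes")
  db <- mk_outlets("database",
                   c("Same", "Renamed", "Moved", "Recat", "Both"),
                   c("1 a st", "2 a st", "3 a st", "4 a st", "5 a st"),
                   category = cats[1], record_id = paste0("d", 1:5))
  field <- mk_outlets("field",
                      c("Same", "Newname", "Moved", "Recat", "Othername"),
                      c("1 a st", "2 a st", "30 b st", "4 a st", "5 a st"),
                      category = c(cats[1], cats[1], cats[1], cats[2], cats[2]),
                      record_id = paste0("f", 1:5))
  disp <- classify_dispositions(db, field)
  got <- table(disp$disposition)
  expect_equal(unname(got[c("matched", "name_error", "location_error",
                            "category_error", "name_category_error")]),
               rep(1L, 5), ignore_attr = TRUE)
})

test_that("dispositions partition the inputs and are order-invariant", {
  set.seed(77)
  for (i in 1:20) {
    case <- random_match_case(sample(1:6, 1), sample(1:6, 1))
    disp <- classify_dispositions(case$db, case$field)
    # partition: every record appears exactly once
    expect_setequal(stats::na.omit(disp$db_record_id), case$db$record_id)
    expect_setequal(stats::na.omit(disp$field_record_id),
                    case$field$record_id)
    # permuting input rows never changes the outcome
    disp2 <- classify_dispositions(case$db[sample(nrow(case$db)), ],
                                   case$field[sample(nrow(case$field)), ])
    expect_identical(disp, disp2)
  }
})

test_that("staged matching equals exhaustive lexicographic assignment on small units", {
  set.seed(99)
  for (i in 1:60) {
    case <- random_match_case(sample(1:6, 1), sample(1:6, 1))
    disp <- classify_dispositions(case$db, case$field)
    got <- vapply(1:5, function(s) sum(disp$stage == s, na.rm = TRUE), 1L)
    want <- oracle_stage_counts(case$db, case$field)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("duplicated ids across the two inputs are refused", {
  db <- mk_outlets("database", "A", "1 x", category = "cafes",
                   record_id = "r1")
  field <- mk_outlets("field", "B", "2 x", category = "cafes",
                      record_id = "r1")
  expect_error(classify_dispositions(db, field),
               class = "poivalid_data_error")
})

test_that("ill-extracted search recovers records geocoded outside their unit", {
  unlisted <- mk_outlets("field", c("Ghost Cafe", "Truly New"),
                         c("7 Elm St", "8 Elm St"), category = "cafes",
                         unit_id = "u1", record_id = c("f1", "f2"))
  full_db <- mk_outlets("database", "Ghost Cafe", "7 Elm St",
                        category = "cafes", unit_id = "u2",
                        record_id = "d1")
  out <- find_ill_extracted(unlisted, full_db)
  expect_identical(out$ill_extracted$record_id, "f1")
  expect_identical(out$truly_absent$record_id, "f2")
  expect_equal(nrow(out$ill_extracted) + nrow(out$truly_absent),
               nrow(unlisted))
  # empty database: everything is truly absent
  none <- find_ill_extracted(unlisted, full_db[0, ])
  expect_equal(nrow(none$ill_extracted), 0)
  expect_equal(nrow(none$truly_absent), 2)
})

test_that("inappropriately-included flags compare address unit to geocode unit", {
  nf <- mk_outlets("database", c("A", "B", "C"),
                   c("1 x st", "2 y st", "3 z st"),
                   category = "cafes", unit_id = c("u1", "u1", "u1"),
                   record_id = paste0("d", 1:3))
  ref <- tibble::tibble(address_norm = c("1 x st", "2 y st"),
                        unit_id = c("u1", "u2"))
  out <- check_inappropriately_included(nf, ref)
  expect_identical(out$inappropriately_included, c(FALSE, TRUE, NA))
  empty <- check_inappropriately_included(nf[0, ], ref)
  expect_equal(nrow(empty), 0)
})
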