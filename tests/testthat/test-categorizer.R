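db_record <- function(name, codes) {
  outlet_table(source = "database", name = name, address = "1 Rue A",
               x = 0, y = 0, codes = list(codes))
}

test_that("scope filter keeps food-retail and eating-place codes only", {
  rs <- default_ruleset()
  tb <- dplyr::bind_rows(
    db_record("Epicerie Untel", "5411"),
    db_record("Hotel Royal", "7011"),
    db_record("Le Vieux Bar", c("5813")))
  tb$record_id <- c("d1", "d2", "d3")
  out <- scope_filter(tb, rs)
  expect_identical(out$in_scope$record_id, "d1")
  expect_setequal(out$excluded$record_id, c("d2", "d3"))
  expect_identical(
    out$excluded$exclusion_reason[out$excluded$record_id == "d2"],
    "out_of_scope_code")
  expect_identical(
    out$excluded$exclusion_reason[out$excluded$record_id == "d3"],
    "exclusion_keyword")
})

test_that("a multi-code supermarket brand goes to chain supermarkets only", {
  rs <- default_ruleset()
  got <- categorize_all(db_record("Provigo",
                                  c("5411", "5461", "5431", "5421")), rs)
  expect_identical(got$category, "chain_supermarkets")
})

test_that("convenience brand names claim the convenience category", {
  rs <- default_ruleset()
  got <- categorize_all(db_record("Couche-Tard", "5411"), rs)
  expect_identical(got$category, "convenience_stores")
})

test_that("keyword-less eating places fall back to full-service restaurants", {
  rs <- default_ruleset()
  got <- categorize_all(db_record("Chez Lucille", "5812"), rs)
  expect_identical(got$category, "full_service_restaurants")
})

test_that("keyword matching is whole-token: 'barber' is not a bar", {
  rs <- default_ruleset()
  out <- scope_filter(db_record("Barber Gourmet Foods", "5499"), rs)
  expect_equal(nrow(out$in_scope), 1)
})

test_that("categorization partitions the in-scope pool", {
  rs <- default_ruleset()
  set.seed(31)
  n <- 60
  tb <- outlet_table(
    source = "database",
    name = sample(c("Provigo", "Couche-Tard", "Boulangerie du Coin",
                    "Fruiterie 440", "Resto Chez Paul", "Cafe Olimpico",
                    "Marche Untel", "McDonald", "Aliments Naturels Plus",
                    "Magasin X"), n, replace = TRUE),
    address = paste(1:n, "rue principale"),
    x = 0, y = 0,
    codes = replicate(n, sample(c("5411", "5431", "5461", "5499", "5812"),
                                sample(1:3, 1)), simplify = FALSE))
  got <- categorize_all(tb, rs)
  expect_equal(nrow(got), n)
  counts <- table(factor(got$category, levels = default_categories()),
                  useNA = "always")
  expect_equal(sum(counts), n)
  expect_true(all(is.na(got$category) |
                    got$category %in% default_categories()))
})

test_that("single-rule assignment is order-independent, full ruleset is not reshuffled", {
  rs <- default_ruleset()
  one <- rs
  one$rules <- rs$rules[rs$rules$category == "convenience_stores", ]
  tb <- dplyr::bind_rows(db_record("Couche-Tard", "5411"),
                         db_record("Depanneur 7 jours", "5411"))
  tb$record_id <- c("a", "b")
  fwd <- categorize_all(tb, one)
  rev <- categorize_all(tb[2:1, ], one)
  expect_identical(sort(fwd$category), sort(rev$category))
})

test_that("rule traces show the claiming rule and the fallback", {
  rs <- default_ruleset()
  tr <- explain_category(db_record("Provigo", "5411"), rs)
  expect_identical(tr$category[tr$claimed], "chain_supermarkets")
  expect_true(is.na(attr(tr, "fallback")))

  tr2 <- explain_category(db_record("Chez Lucille", "5812"), rs)
  expect_false(any(tr2$claimed))
  expect_identical(attr(tr2, "fallback"), "full_service_restaurants")

  empty <- rs
  empty$rules <- rs$rules[0, ]
  empty$fallbacks <- character(0)
  tr3 <- explain_category(db_record("Chez Lucille", "5812"), empty)
  expect_equal(nrow(tr3), 0)
})

test_that("duplicate rule priorities are a configuration error", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "categories: [cafes, grocery_stores]",
    "scope_codes: ['5411']",
    "rules:",
    "  - {category: cafes, priority: 1, code_prefixes: ['54'], include_keywords: [cafe]}",
    "  - {category: grocery_stores, priority: 1, code_prefixes: ['54'], include_keywords: [marche]}"),
    p)
  expect_error(read_ruleset(p), "priorit",
               class = "poivalid_config_error")
})
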