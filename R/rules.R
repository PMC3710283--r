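#' Read a category ruleset from YAML
#'
#' A ruleset drives the two-step categorization of database records: a scope
#' filter on industry classification codes (food retail 5411-5499, eating
#' places 5812, drinking places 5813, with bars / liquor stores / caterers
#' excluded by keyword), then prioritized category rules, each claiming
#' records that match a code prefix AND an include keyword and no exclude
#' keyword. Records a rule claims are withdrawn from the pool — an outlet is
#' never made available to another category once extracted. Pool remnants
#' fall back to a per-code default category, or stay unassigned.
#'
#' @param path Path to a YAML ruleset (see the shipped default for the
#'   format: `system.file("extdata", "default_rules.yaml", package =
#'   "poivalid")`).
#' @return A `ruleset` list with elements `categories`, `scope_codes`,
#'   `exclude_keywords`, `rules` (tibble ordered by priority), `fallbacks`
#'   (named character vector code -> category).
#' @export
read_ruleset <- function(path) {
  cfg <- yaml::read_yaml(path)
  rules <- purrr::map_dfr(cfg$rules, function(r) {
    tibble::tibble(
      category = r$category,
      priority = as.integer(r$priority),
      code_prefixes = list(as.character(r$code_prefixes %||% character(0))),
      include_keywords = list(normalize_text(as.character(r$include_keywords %||% character(0)))),
      exclude_keywords = list(normalize_text(as.character(r$exclude_keywords %||% character(0))))
    )
  })
  if (anyDuplicated(rules$priority)) {
    abort("ruleset has duplicate priorities", class = "poivalid_config_error")
  }
  rules <- rules[order(rules$priority), ]
  bad <- setdiff(rules$category, cfg$categories)
  if (length(bad)) {
    abort(paste0("rule category not in configured categories: ",
                 paste(bad, collapse = ", ")),
          class = "poivalid_config_error")
  }
  structure(list(
    categories = as.character(cfg$categories),
    scope_codes = as.character(cfg$scope_codes),
    exclude_keywords = normalize_text(as.character(cfg$exclusions$keywords %||% character(0))),
    rules = rules,
    fallbacks = unlist(cfg$fallbacks) %||% character(0)
  ), class = "ruleset")
}

#' @rdname read_ruleset
#' @export
default_ruleset <- function() {
  read_ruleset(system.file("extdata", "default_rules.yaml",
                           package = "poivalid", mustWork = TRUE))
}

# whole-token phrase match on normalized text ("bar" never matches "barber")
keyword_hit <- function(name_norm, phrases) {
  if (length(phrases) == 0L) return(rep(FALSE, length(name_norm)))
  hit <- rep(FALSE, length(name_norm))
  for (p in phrases[nzchar(phrases)]) {
    hit <- hit | grepl(paste0("\\b", p, "\\b"), name_norm)
  }
  hit
}

code_prefix_hit <- function(codes, prefixes) {
  vapply(codes, function(cc) {
    any(vapply(prefixes, function(p) any(startsWith(cc, p)), TRUE))
  }, TRUE)
}

#' Filter records to the food-outlet scope
#'
#' A record is in scope iff any of its codes is one of the ruleset's scope
#' codes. Records whose name hits an exclusion keyword (bars, liquor stores,
#' caterers) are excluded with a reason, as are records with no in-scope
#' code.
#'
#' @param records Outlet table (database source, with codes).
#' @param ruleset A [read_ruleset()] result.
#' @return List with `in_scope` and `excluded` (the latter carrying an
#'   `exclusion_reason` column).
#' @export
scope_filter <- function(records, ruleset = default_ruleset()) {
  in_code <- vapply(records$codes,
                    function(cc) any(cc %in% ruleset$scope_codes), TRUE)
  excl_kw <- keyword_hit(records$name_norm, ruleset$exclude_keywords)
  reason <- dplyr::case_when(
    excl_kw ~ "exclusion_keyword",
    !in_code ~ "out_of_scope_code",
    TRUE ~ NA_character_
  )
  excluded <- records[!is.na(reason), ]
  excluded$exclusion_reason <- reason[!is.na(reason)]
  list(in_scope = records[is.na(reason), ], excluded = excluded)
}

#' Categorize database records
#'
#' Applies the ruleset's category rules in priority order. Each rule claims,
#' from the remaining pool, every record with a matching code prefix, at
#' least one include keyword in the normalized name, and no exclude keyword;
#' claimed records leave the pool, so each record receives at most one
#' category. Remnants receive the fallback category configured for their
#' first (primary) code, or stay `NA` (unassigned).
#'
#' @param records Outlet table that passed [scope_filter()].
#' @param ruleset A [read_ruleset()] result.
#' @return `records` with `category` filled in.
#' @export
#' @examples
#' tb <- outlet_table(source = "database", name = "Provigo",
#'                    address = "1 Rue A", x = 0, y = 0,
#'                    codes = "5411;5461;5431;5421")
#' categorize_all(tb, default_ruleset())$category  # "chain_supermarkets"
categorize_all <- function(records, ruleset = default_ruleset()) {
  n <- nrow(records)
  assigned <- rep(NA_character_, n)
  pool <- rep(TRUE, n)
  for (i in seq_len(nrow(ruleset$rules))) {
    r <- ruleset$rules[i, ]
    if (!any(pool)) break
    idx <- which(pool)
    ok <- code_prefix_hit(records$codes[idx], r$code_prefixes[[1]]) &
      keyword_hit(records$name_norm[idx], r$include_keywords[[1]]) &
      !keyword_hit(records$name_norm[idx], r$exclude_keywords[[1]])
    assigned[idx[ok]] <- r$category
    pool[idx[ok]] <- FALSE
  }
  if (any(pool) && length(ruleset$fallbacks)) {
    idx <- which(pool)
    primary <- vapply(records$codes[idx],
                      function(cc) if (length(cc)) cc[[1]] else NA_character_, "")
    fb <- unname(ruleset$fallbacks[primary])
    assigned[idx] <- fb
  }
  records$category <- assigned
  records
}

#' Trace rule evaluation for one record
#'
#' Auditing aid: evaluates every rule against a single record, in priority
#' order, reporting which condition failed and which rule (if any) claims
#' it, plus the fallback that would apply.
#'
#' @param record One-row outlet table.
#' @param ruleset A [read_ruleset()] result.
#' @return Tibble with one row per rule (`category`, `priority`, `code_ok`,
#'   `keyword_ok`, `exclude_hit`, `claimed`) and attribute `fallback`.
#' @export
explain_category <- function(record, ruleset = default_ruleset()) {
  stopifnot(nrow(record) == 1L)
  claimed_yet <- FALSE
  tr <- purrr::map_dfr(seq_len(nrow(ruleset$rules)), function(i) {
    r <- ruleset$rules[i, ]
    code_ok <- code_prefix_hit(record$codes, r$code_prefixes[[1]])
    kw_ok <- keyword_hit(record$name_norm, r$include_keywords[[1]])
    ex_hit <- keyword_hit(record$name_norm, r$exclude_keywords[[1]])
    claims <- code_ok && kw_ok && !ex_hit && !claimed_yet
    if (claims) claimed_yet <<- TRUE
    tibble::tibble(category = r$category, priority = r$priority,
                   code_ok = code_ok, keyword_ok = kw_ok,
                   exclude_hit = ex_hit, claimed = claims)
  })
  primary <- if (length(record$codes[[1]])) record$codes[[1]][1] else NA_character_
  fb <- if (!is.na(primary)) unname(ruleset$fallbacks[primary]) else NA_character_
  attr(tr, "fallback") <- if (claimed_yet) NA_character_ else fb
  tr
}
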