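#' Run the full validation pipeline
#'
#' Wires the stages together: deduplicate the listing, categorize it if
#' categories are missing and a ruleset is given, assign areal units to
#' any record without one, restrict both sides to records inside the
#' units, classify dispositions, search the complete database for
#' ill-extracted records, tally confusion counts in both modes, and
#' compute per-unit, per-category, per-grouping and overall metrics with
#' confidence intervals, rating labels and chi-square variation tests.
#'
#' @param db Database outlet table.
#' @param field Field census outlet table (categories as observed).
#' @param units Areal units.
#' @param full_db Optional complete database (for the ill-extracted
#'   search); defaults to `db`.
#' @param ruleset Optional [read_ruleset()] result; applied when database
#'   categories are missing.
#' @param cfg A [match_config()].
#' @param variant Representativity variant (see [representativity()]).
#' @param ci_method Confidence-interval method (see
#'   [confidence_interval()]).
#' @return A `poi_report` list with blocks `overall`, `per_unit`,
#'   `per_category`, `per_grouping`, `variation`, `dispositions`,
#'   `dedup_removed`, `config`.
#' @export
run_validation <- function(db, field, units, full_db = NULL, ruleset = NULL,
                           cfg = match_config(),
                           variant = c("compensated_min", "as_printed_abs"),
                           ci_method = c("wald", "wilson", "between_unit")) {
  variant <- match.arg(variant)
  ci_method <- match.arg(ci_method)
  if (is.null(full_db)) full_db <- db

  dd <- deduplicate(db)
  db <- dd$kept
  if (all(is.na(db$category)) && !is.null(ruleset)) {
    sf <- scope_filter(db, ruleset)
    db <- categorize_all(sf$in_scope, ruleset)
  }
  if (anyNA(db$unit_id)) db <- assign_units_missing(db, units)
  if (anyNA(field$unit_id)) field <- assign_units_missing(field, units)
  db_in <- db[!is.na(db$unit_id) & !is.na(db$category), ]
  field_in <- field[!is.na(field$unit_id), ]
  if (nrow(field_in) == 0L) {
    warn("field census is empty: every listed outlet will be a false positive")
  }

  disp <- classify_dispositions(db_in, field_in, cfg)
  unl <- field_in[field_in$record_id %in%
                    disp$field_record_id[disp$disposition == "unlisted"], ]
  ill <- find_ill_extracted(unl, full_db, cfg)$ill_extracted
  disp <- mark_ill_extracted(disp, ill)

  modes <- c("traditional", "relaxed")
  conf <- lapply(setNames(modes, modes),
                 function(m) confusion_counts(disp, m, cfg))
  per_unit <- lapply(conf, unit_metrics, variant = variant)

  overall <- purrr::map_dfr(modes, function(m) {
    pu <- per_unit[[m]]
    purrr::map_dfr(c("sensitivity", "ppv", "representativity"), function(ms) {
      est <- suppressMessages(aggregate_weighted(pu, ms))
      n <- sum(if (ms == "ppv") pu$n_list else pu$n_field)
      ci <- if (!is.na(est) && n > 0) {
        if (ci_method == "between_unit") {
          confidence_interval(est, n, "between_unit", per_unit = pu[[ms]],
                              weights = if (ms == "ppv") pu$n_list else pu$n_field)
        } else confidence_interval(est, n, ci_method)
      } else c(lo = NA_real_, hi = NA_real_)
      tibble::tibble(mode = m, measure = ms, estimate = est,
                     ci_lo = ci[["lo"]], ci_hi = ci[["hi"]],
                     label = qualitative_label(est), n = n)
    })
  })

  per_category <- purrr::map_dfr(modes, function(m) {
    cc <- conf[[m]]
    purrr::map_dfr(split(cc, cc$category), function(cells) {
      tibble::tibble(
        mode = m, category = cells$category[1],
        sensitivity = suppressMessages(sensitivity(cells)),
        ppv = suppressMessages(ppv(cells)),
        n_field = sum(cells$tp) + sum(cells$fn),
        n_list = sum(cells$tp) + sum(cells$fp))
    })
  })

  group_attrs <- setdiff(names(units), c("unit_id", "ring"))
  per_grouping <- purrr::map_dfr(modes, function(m) {
    cc <- conf[[m]]
    purrr::map_dfr(group_attrs, function(a) {
      lev <- units[[a]][match(cc$unit_id, units$unit_id)]
      purrr::map_dfr(split(cc, lev), function(cells) {
        tibble::tibble(
          mode = m, grouping = a,
          level = units[[a]][match(cells$unit_id[1], units$unit_id)],
          sensitivity = suppressMessages(sensitivity(cells)),
          ppv = suppressMessages(ppv(cells)),
          n_field = sum(cells$tp) + sum(cells$fn),
          n_list = sum(cells$tp) + sum(cells$fp))
      })
    })
  })

  variation <- run_variation(conf, units)

  structure(list(
    overall = overall,
    per_unit = dplyr::bind_rows(per_unit),
    per_category = per_category,
    per_grouping = per_grouping,
    variation = variation,
    dispositions = disp,
    dedup_removed = dd$removed,
    config = list(match = unclass(cfg), variant = variant,
                  ci_method = ci_method)
  ), class = "poi_report")
}

assign_units_missing <- function(records, units) {
  miss <- is.na(records$unit_id)
  if (!any(miss)) return(records)
  records[miss, ] <- assign_units(records[miss, ], units)
  records
}

# chi-square variation tests across every grouping and across categories
# (sparse mega-market row merged into the chain-supermarket row first)
run_variation <- function(conf, units) {
  group_attrs <- setdiff(names(units), c("unit_id", "ring"))
  combos <- expand.grid(mode = names(conf),
                        measure = c("sensitivity", "ppv"),
                        grouping = c(group_attrs, "category"),
                        stringsAsFactors = FALSE)
  purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    m <- combos$mode[i]; ms <- combos$measure[i]; gr <- combos$grouping[i]
    tab <- build_contingency(conf[[m]], gr, ms, units)
    if (gr == "category" &&
        all(c("mega_markets", "chain_supermarkets") %in% tab$stratum)) {
      tab <- combine_rows(tab, list(
        "mega_chain_supermarkets" = c("mega_markets", "chain_supermarkets")))
    }
    res <- tryCatch(chi_square(tab), error = function(e) NULL)
    tibble::tibble(
      mode = m, measure = ms, grouping = gr,
      statistic = if (is.null(res)) NA_real_ else res$statistic,
      df = if (is.null(res)) NA_real_ else res$df,
      p_value = if (is.null(res)) NA_real_ else res$p_value,
      p_display = if (is.null(res)) NA_character_ else
        format_p_value(res$p_value),
      low_expected = if (is.null(res)) NA else
        "expected_cell_below_5" %in% res$warning_flags)
  })
}

#' Write a validation report to disk
#'
#' Writes `report.json` (all blocks, numbers unrounded), `dispositions.csv`
#' and `per_unit.csv`. The JSON carries the configuration echo and a hash
#' of it, so two runs with the same configuration are byte-comparable.
#'
#' @param report A `poi_report` from [run_validation()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  blocks <- report[c("overall", "per_unit", "per_category", "per_grouping",
                     "variation")]
  blocks$config <- report$config
  blocks$config_hash <- config_hash(report$config)
  writeLines(jsonlite::toJSON(blocks, dataframe = "rows", auto_unbox = TRUE,
                              digits = NA, na = "null", pretty = TRUE),
             file.path(dir, "report.json"))
  disp <- report$dispositions
  disp$disposition <- as.character(disp$disposition)
  write.csv(disp, file.path(dir, "dispositions.csv"), row.names = FALSE)
  write.csv(report$per_unit, file.path(dir, "per_unit.csv"),
            row.names = FALSE)
  invisible(dir)
}

# stable short hash of the configuration echo: polynomial rolling hash
# modulo a prime below 2^26, exact in double arithmetic
config_hash <- function(config) {
  bytes <- utf8ToInt(jsonlite::toJSON(config, auto_unbox = TRUE,
                                      digits = NA))
  h <- 17
  for (b in bytes) h <- (h * 257 + b) %% 67108859
  sprintf("%08x", as.integer(h))
}

#' @export
print.poi_report <- function(x, ...) {
  cat("Point-of-interest validation report\n")
  ov <- x$overall
  for (i in seq_len(nrow(ov))) {
    cat(sprintf("  %-11s %-16s %.3f [%.3f-%.3f] (%s, n=%d)\n",
                ov$mode[i], ov$measure[i], ov$estimate[i], ov$ci_lo[i],
                ov$ci_hi[i], ov$label[i], ov$n[i]))
  }
  invisible(x)
}
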