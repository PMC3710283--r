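#' Build an encountered/not-encountered contingency table
#'
#' Displays sensitivity or PPV as a binary outcome across strata. For
#' sensitivity a field outlet is "encountered" when listed (TP) and "not
#' encountered" when missed (FN); for PPV a listed outlet is "encountered"
#' when found in the field (TP) and "not encountered" when absent (FP).
#' Strata are either the outlet categories or a grouping attribute of the
#' areal units (e.g. socioeconomic tertile, predominant language).
#'
#' @param confusions Confusion tibble from [confusion_counts()] (pick the
#'   mode before building the table).
#' @param grouping `"category"`, or the name of a grouping attribute column
#'   in `units`.
#' @param measure `"sensitivity"` or `"ppv"`.
#' @param units Areal units (required when grouping by a unit attribute).
#' @return A `poi_contingency` tibble with columns `stratum`,
#'   `encountered`, `not_encountered` and attributes `measure` and `mode`.
#' @export
build_contingency <- function(confusions, grouping, measure = c("sensitivity", "ppv"),
                              units = NULL) {
  measure <- match.arg(measure)
  if (identical(grouping, "category")) {
    strata <- confusions$category
  } else {
    if (is.null(units) || !grouping %in% names(units)) {
      abort(paste0("unknown grouping: ", grouping),
            class = "poivalid_config_error")
    }
    strata <- units[[grouping]][match(confusions$unit_id, units$unit_id)]
  }
  neg <- if (measure == "sensitivity") confusions$fn else confusions$fp
  out <- tibble::tibble(stratum = strata, encountered = confusions$tp,
                        not_encountered = neg) |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(encountered = sum(.data$encountered),
                     not_encountered = sum(.data$not_encountered),
                     .groups = "drop")
  attr(out, "measure") <- measure
  attr(out, "mode") <- confusions$mode[1] %||% NA_character_
  class(out) <- c("poi_contingency", class(out))
  out
}

#' Combine contingency rows
#'
#' Sums named strata into a single labeled row, e.g. to merge the sparse
#' mega-market row with the chain-supermarket row before a chi-square test
#' so every cell reaches a usable size. Cell totals are conserved.
#'
#' @param table A `poi_contingency` table.
#' @param merge_spec Named list: new row label -> character vector of
#'   existing strata to merge.
#' @return The table with the named rows merged.
#' @export
#' @examples
#' # combine_rows(tab, list("mega+chain" =
#' #   c("mega_markets", "chain_supermarkets")))
combine_rows <- function(table, merge_spec) {
  for (label in names(merge_spec)) {
    rows <- merge_spec[[label]]
    missing <- setdiff(rows, table$stratum)
    if (length(missing)) {
      abort(paste0("unknown row(s): ", paste(missing, collapse = ", ")),
            class = "poivalid_config_error")
    }
    hit <- table$stratum %in% rows
    merged <- tibble::tibble(
      stratum = label,
      encountered = sum(table$encountered[hit]),
      not_encountered = sum(table$not_encountered[hit]))
    at <- attributes(table)
    table <- dplyr::bind_rows(table[!hit, ], merged)
    attr(table, "measure") <- at$measure
    attr(table, "mode") <- at$mode
    class(table) <- unique(c("poi_contingency", class(table)))
  }
  table
}

#' Pearson chi-square test of independence
#'
#' Standard Pearson X-squared on the encountered/not-encountered table,
#' expected counts from the margins, no continuity correction. Expected
#' cells below 5 are flagged (advice: [combine_rows()]). Fisher's exact
#' test is deliberately not offered: its fixed-margins assumption does not
#' hold for field-validation designs, where every margin is itself an
#' observation.
#'
#' @param table A `poi_contingency` table, or a numeric matrix with two
#'   columns.
#' @return List with `statistic`, `df`, `p_value`, `expected` (matrix) and
#'   `warning_flags` (character vector, possibly empty).
#' @export
#' @examples
#' chi_square(matrix(c(20, 5, 5, 20), 2, byrow = TRUE))$statistic  # 18
chi_square <- function(table) {
  if (inherits(table, "poi_contingency") || is.data.frame(table)) {
    m <- as.matrix(table[, c("encountered", "not_encountered")])
    rownames(m) <- table$stratum
  } else {
    m <- as.matrix(table)
  }
  if (nrow(m) < 2L) {
    abort("chi-square needs at least 2 rows", class = "poivalid_data_error")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("zero row or column total; combine rows first (see combine_rows)",
          class = "poivalid_data_error")
  }
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  flags <- character(0)
  if (any(ct$expected < 5)) {
    flags <- c(flags, "expected_cell_below_5")
  }
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), expected = ct$expected,
       warning_flags = flags)
}

# report rendering: three decimals, exact zeros shown as a bound
format_p_value <- function(p) {
  ifelse(round(p, 3) < 0.001, "<0.001", formatC(p, digits = 3, format = "f"))
}
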