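#' Tally confusion counts per areal unit and category
#'
#' Converts a disposition table into TP/FP/FN counts per (unit, category)
#' cell, under one of two matching modes. *Traditional*: only perfectly
#' matched pairs are TPs; any name, location or category error makes the
#' database record an FP and the field record an FN. *Relaxed*: name errors
#' and within-unit location imprecision are forgiven (those pairs become
#' TPs); category errors and records absent from the field stay FPs, and
#' field records the list misses (including ill-extracted ones) stay FNs.
#'
#' For pairs with a category mismatch the FP always lands in the
#' database-listed category cell; the FN cell follows
#' `cfg$category_attribution` (`"listed"` by default, which reproduces the
#' accounting identity field total = listed - not found + unlisted +
#' ill-extracted within every category). With
#' `cfg$treat_ill_extracted_as = "tp"` ill-extracted field records count as
#' TPs instead of FNs (the geocoding-correction counterfactual).
#'
#' TN is carried as `NA`: in an open business universe the true-negative
#' cell has no operational definition and is never used.
#'
#' @param dispositions Result of [classify_dispositions()] (after
#'   [mark_ill_extracted()] if the ill-extracted search was run).
#' @param mode `"traditional"` or `"relaxed"`.
#' @param cfg A [match_config()].
#' @return Tibble with `unit_id`, `category`, `tp`, `fp`, `fn`, `tn`,
#'   `mode`, one row per non-empty cell.
#' @export
confusion_counts <- function(dispositions, mode = c("traditional", "relaxed"),
                             cfg = match_config()) {
  mode <- match.arg(mode)
  d <- dispositions
  disp <- as.character(d$disposition)
  tp_set <- if (mode == "traditional") "matched" else
    c("matched", "name_error", "location_error")
  err_set <- setdiff(c("name_error", "location_error", "category_error",
                       "name_category_error"), tp_set)
  ill_as_tp <- cfg$treat_ill_extracted_as == "tp"
  fn_cat <- if (cfg$category_attribution == "listed") d$db_category else
    d$field_category

  pieces <- list(
    # TPs: cell of the (shared or listed) category
    tibble::tibble(unit_id = d$unit_id, category = d$db_category,
                   what = "tp")[disp %in% tp_set, ],
    # unresolved error pairs: FP to the listed cell, FN per attribution
    tibble::tibble(unit_id = d$unit_id, category = d$db_category,
                   what = "fp")[disp %in% err_set, ],
    tibble::tibble(unit_id = d$unit_id, category = fn_cat,
                   what = "fn")[disp %in% err_set, ],
    # listed but absent in the field
    tibble::tibble(unit_id = d$unit_id, category = d$db_category,
                   what = "fp")[disp == "not_found", ],
    # in the field but not on the list
    tibble::tibble(unit_id = d$unit_id, category = d$field_category,
                   what = "fn")[disp == "unlisted", ],
    tibble::tibble(unit_id = d$unit_id, category = d$field_category,
                   what = if (ill_as_tp) "tp" else "fn")[disp == "ill_extracted", ]
  )
  long <- dplyr::bind_rows(pieces)
  if (nrow(long) == 0L) {
    return(tibble::tibble(unit_id = character(0), category = character(0),
                          tp = integer(0), fp = integer(0), fn = integer(0),
                          tn = integer(0), mode = character(0)))
  }
  out <- long |>
    dplyr::count(.data$unit_id, .data$category, .data$what) |>
    tidyr::pivot_wider(names_from = "what", values_from = "n",
                       values_fill = 0L)
  for (col in c("tp", "fp", "fn")) {
    if (!col %in% names(out)) out[[col]] <- 0L
  }
  out$tn <- NA_integer_
  out$mode <- mode
  dplyr::arrange(out[, c("unit_id", "category", "tp", "fp", "fn", "tn",
                         "mode")],
                 .data$unit_id, .data$category)
}

#' Build a single confusion cell
#'
#' Convenience constructor for a one-row confusion tibble, mainly for
#' direct metric computations and examples.
#'
#' @param tp,fp,fn Counts.
#' @param unit_id,category,mode Cell labels.
#' @return One-row confusion tibble.
#' @export
#' @examples
#' sensitivity(confusion_cell(tp = 264, fp = 146, fn = 220))  # 0.545...
confusion_cell <- function(tp, fp, fn, unit_id = "u1", category = "all",
                           mode = "traditional") {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  tibble::tibble(unit_id = unit_id, category = category,
                 tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = NA_integer_, mode = mode)
}
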