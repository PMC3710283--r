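#' Sensitivity and positive predictive value
#'
#' Pooled over the rows of a confusion tibble: sensitivity is
#' `TP / (TP + FN)`, the proportion of field-observed outlets the database
#' lists; PPV is `TP / (TP + FP)`, the proportion of listed outlets that
#' exist in the field. A zero denominator yields `NA` with a message (the
#' cell is then excluded from any weighted aggregation).
#'
#' @param cc Confusion tibble (any number of rows; counts are summed).
#' @return A fraction in \[0, 1\], or `NA` if undefined.
#' @export
#' @examples
#' sensitivity(confusion_cell(tp = 317, fp = 93, fn = 167))  # 0.655
#' ppv(confusion_cell(tp = 264, fp = 146, fn = 220))         # 0.644
sensitivity <- function(cc) {
  tp <- sum(cc$tp); fn <- sum(cc$fn)
  if (tp + fn == 0) {
    inform("sensitivity undefined: no field outlets in this cell")
    return(NA_real_)
  }
  tp / (tp + fn)
}

#' @rdname sensitivity
#' @export
ppv <- function(cc) {
  tp <- sum(cc$tp); fp <- sum(cc$fp)
  if (tp + fp == 0) {
    inform("ppv undefined: no listed outlets in this cell")
    return(NA_real_)
  }
  tp / (tp + fp)
}

#' Representativity of a unit's listing
#'
#' Measures how well the listing represents the *composition* of a unit's
#' foodscape by letting false positives compensate false negatives within
#' the same outlet category. Computed over the per-category confusion cells
#' of one areal unit (relaxed-mode counts are the intended basis).
#'
#' Two variants:
#' \describe{
#'   \item{`compensated_min` (default)}{
#'     `(sum(tp) + sum(pmin(fp, fn))) / (sum(tp) + sum(fn))`. Each
#'     category's FNs are offset by that category's FPs, capped at full
#'     compensation, so the value always lies between the relaxed
#'     sensitivity and 1.}
#'   \item{`as_printed_abs`}{
#'     `(sum(tp) + sum(abs(fp - fn))) / (sum(tp) + sum(fn))`, the
#'     absolute-difference form. Anomalous by construction: it returns 1
#'     whenever every category has `fp = 0` regardless of how many outlets
#'     are missed, and exceeds 1 when `fp > 2 * fn` in a cell (flagged with
#'     a warning, not clamped). Retained for auditability.}
#' }
#'
#' @param cells Confusion tibble for one unit, one row per category (a
#'   single cell is allowed for category-restricted values).
#' @param variant `"compensated_min"` or `"as_printed_abs"`.
#' @return A fraction (`NA` if the unit has no field outlets).
#' @export
#' @examples
#' # 10 missed outlets offset by 12 phantoms in the same category:
#' representativity(confusion_cell(tp = 0, fp = 12, fn = 10))        # 1
#' representativity(confusion_cell(tp = 0, fp = 12, fn = 10),
#'                  variant = "as_printed_abs")                      # 0.2
representativity <- function(cells,
                             variant = c("compensated_min", "as_printed_abs")) {
  variant <- match.arg(variant)
  if (length(unique(cells$unit_id)) > 1L) {
    abort("representativity is a per-unit measure; got cells from several units",
          class = "poivalid_data_error")
  }
  denom <- sum(cells$tp) + sum(cells$fn)
  if (denom == 0) {
    inform("representativity undefined: no field outlets in this unit")
    return(NA_real_)
  }
  comp <- switch(variant,
                 compensated_min = sum(pmin(cells$fp, cells$fn)),
                 as_printed_abs = sum(abs(cells$fp - cells$fn)))
  val <- (sum(cells$tp) + comp) / denom
  if (val > 1) {
    warn(paste0("representativity ", format(val, digits = 4),
                " exceeds 1 (as-printed variant with fp > 2*fn)"))
  }
  val
}

#' Per-unit metric table
#'
#' Computes sensitivity, PPV and representativity for every areal unit in a
#' confusion tibble, along with the denominators used as aggregation
#' weights: `n_field = tp + fn` (sensitivity, representativity) and
#' `n_list = tp + fp` (PPV).
#'
#' @param confusions Confusion tibble from [confusion_counts()].
#' @param variant Representativity variant, see [representativity()].
#' @return Tibble with one row per unit: `unit_id`, `mode`, `sensitivity`,
#'   `ppv`, `representativity`, `n_field`, `n_list`.
#' @export
unit_metrics <- function(confusions, variant = "compensated_min") {
  purrr::map_dfr(split(confusions, confusions$unit_id), function(cells) {
    tibble::tibble(
      unit_id = cells$unit_id[1],
      mode = cells$mode[1],
      sensitivity = suppressMessages(sensitivity(cells)),
      ppv = suppressMessages(ppv(cells)),
      representativity = suppressMessages(representativity(cells, variant)),
      n_field = sum(cells$tp) + sum(cells$fn),
      n_list = sum(cells$tp) + sum(cells$fp)
    )
  })
}

#' Weighted overall value of a per-unit metric
#'
#' Overall values are averages of unit-level values weighted by the number
#' of outlets per unit — each measure's own denominator: `n_field` for
#' sensitivity and representativity, `n_list` for PPV. Under this weighting
#' the overall equals the pooled ratio computed from summed counts, which
#' is what makes unit-level and whole-study arithmetic agree. Units with an
#' undefined value are excluded.
#'
#' @param per_unit Result of [unit_metrics()].
#' @param measure `"sensitivity"`, `"ppv"` or `"representativity"`.
#' @return The weighted overall fraction (`NA` if no unit has a defined
#'   value).
#' @export
aggregate_weighted <- function(per_unit,
                               measure = c("sensitivity", "ppv",
                                           "representativity")) {
  measure <- match.arg(measure)
  w <- if (measure == "ppv") per_unit$n_list else per_unit$n_field
  v <- per_unit[[measure]]
  ok <- !is.na(v) & w > 0
  if (!any(ok)) {
    inform(paste0("overall ", measure, " undefined: no unit has a value"))
    return(NA_real_)
  }
  sum(w[ok] * v[ok]) / sum(w[ok])
}

#' Confidence interval for a proportion-type metric
#'
#' \describe{
#'   \item{`wald`}{`p +/- z * sqrt(p (1 - p) / n)`, truncated to \[0, 1\].}
#'   \item{`wilson`}{Wilson score interval (via
#'     `prop.test(correct = FALSE)`), better behaved near 0 and 1.}
#'   \item{`between_unit`}{weighted mean of unit-level values `+/- z *`
#'     the weighted between-unit standard error, with the effective number
#'     of units `(sum w)^2 / sum(w^2)`; captures unit-to-unit
#'     heterogeneity that the pooled intervals ignore.}
#' }
#'
#' @param p Point estimate in \[0, 1\] (ignored for `between_unit`, which
#'   recomputes the weighted mean).
#' @param n Denominator count behind `p`.
#' @param method `"wald"`, `"wilson"` or `"between_unit"`.
#' @param per_unit For `between_unit`: numeric vector of unit-level values.
#' @param weights For `between_unit`: their weights.
#' @param level Confidence level, default 0.95.
#' @return Named numeric `c(lo, hi)`.
#' @export
#' @examples
#' confidence_interval(0.5, 100)                 # 0.402 0.598
#' confidence_interval(0, 10, method = "wilson") # 0 0.2775
confidence_interval <- function(p, n,
                                method = c("wald", "wilson", "between_unit"),
                                per_unit = NULL, weights = NULL,
                                level = 0.95) {
  method <- match.arg(method)
  z <- qnorm(1 - (1 - level) / 2)
  if (method == "between_unit") {
    if (is.null(per_unit) || is.null(weights)) {
      abort("between_unit needs per_unit values and weights",
            class = "poivalid_config_error")
    }
    ok <- !is.na(per_unit) & weights > 0
    v <- per_unit[ok]; w <- weights[ok]
    m <- sum(w * v) / sum(w)
    var_b <- sum(w * (v - m)^2) / sum(w)
    n_eff <- sum(w)^2 / sum(w^2)
    half <- z * sqrt(var_b / n_eff)
    return(c(lo = max(0, m - half), hi = min(1, m + half)))
  }
  if (is.na(p) || n <= 0) {
    abort("confidence interval undefined for n = 0",
          class = "poivalid_data_error")
  }
  if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / n)
    return(c(lo = max(0, p - half), hi = min(1, p + half)))
  }
  ci <- prop.test(round(p * n), n, correct = FALSE,
                  conf.level = level)$conf.int
  c(lo = ci[1], hi = ci[2])
}

#' Qualitative rating of a validity measure
#'
#' Maps a fraction to the conventional descriptive scale used to compare
#' validation studies: up to 0.30 "poor", over 0.30 to 0.50 "fair", over
#' 0.50 to 0.70 "moderate", over 0.70 to 0.90 "good", over 0.90
#' "excellent". Intervals are half-open on the left, so 0.30 is "poor" and
#' 0.50 "fair". Indicative only — a "good" 0.71 still errs about one time
#' in three.
#'
#' @param value Numeric vector of fractions.
#' @return Character vector of labels.
#' @export
#' @examples
#' qualitative_label(c(0.545, 0.777))  # "moderate" "good"
qualitative_label <- function(value) {
  as.character(cut(value, breaks = c(-Inf, 0.30, 0.50, 0.70, 0.90, Inf),
                   labels = c("poor", "fair", "moderate", "good",
                              "excellent")))
}
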