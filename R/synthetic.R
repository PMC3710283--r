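# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Parameters of a synthetic foodscape scenario
#'
#' Defines a ground-truth foodscape (areal units, outlets per unit,
#' category mix) and the independent corruption process that turns it into
#' a database listing. Error types are applied per record in a fixed order:
#' omission, category confusion, name error, within-unit location jitter,
#' cross-unit geocoding shift; phantom entries and duplicates are appended
#' afterwards. Defaults emulate the error profile of a commercial
#' point-of-interest file validated one year after release in a dense urban
#' area: roughly a fifth of true outlets absent from the listing, a sixth
#' of listed outlets gone from the field, name discrepancies on about one
#' listed outlet in eight, and a several-percent rate of category and
#' geocoding errors.
#'
#' @param n_units Number of areal units (default 12).
#' @param outlets_per_unit Poisson mean of true outlets per unit
#'   (default 40).
#' @param category_weights Named probabilities over outlet categories
#'   (must sum to 1); default mirrors a dense-city field census dominated
#'   by full-service restaurants.
#' @param omission_rate Probability a true outlet is absent from the
#'   listing (default 0.22).
#' @param phantom_rate Expected fraction of the final listing that
#'   describes outlets absent from the field (default 0.16).
#' @param name_error_rate Probability a listed outlet trades under a
#'   different name (default 0.12).
#' @param within_unit_location_error_rate Probability of a wrong address
#'   that stays inside the true unit (default 0.01).
#' @param cross_unit_geocode_rate Probability a listed outlet is geocoded
#'   outside its true unit, producing an ill-extracted record
#'   (default 0.07).
#' @param category_confusion Probability a listed outlet carries the wrong
#'   category; scalar or named per-category vector (default 0.07).
#' @param duplicate_rate Probability a listed outlet appears twice
#'   (default 0.05).
#' @param admin_suffix_rate Probability a duplicate carries an
#'   administrative name suffix ("office") rather than being byte-identical
#'   (default 0.5).
#' @param seed Integer seed; identical seeds give byte-identical scenarios.
#' @return A `scenario_params` list.
#' @export
scenario_params <- function(n_units = 12, outlets_per_unit = 40,
                            category_weights = NULL,
                            omission_rate = 0.22, phantom_rate = 0.16,
                            name_error_rate = 0.12,
                            within_unit_location_error_rate = 0.01,
                            cross_unit_geocode_rate = 0.07,
                            category_confusion = 0.07,
                            duplicate_rate = 0.05,
                            admin_suffix_rate = 0.5,
                            seed = 1L) {
  if (is.null(category_weights)) {
    # field composition of a dense-city census: restaurants dominate
    category_weights <- c(
      mega_markets = 1, chain_supermarkets = 4, grocery_stores = 33,
      convenience_stores = 63, bakery_shops = 27,
      fruit_and_vegetable_stores = 11, specialty_markets = 14,
      natural_food_stores = 16, fast_food_restaurants = 42,
      full_service_restaurants = 223, cafes = 50) / 484
  }
  rates <- c(omission_rate = omission_rate, phantom_rate = phantom_rate,
             name_error_rate = name_error_rate,
             within_unit_location_error_rate = within_unit_location_error_rate,
             cross_unit_geocode_rate = cross_unit_geocode_rate,
             duplicate_rate = duplicate_rate,
             admin_suffix_rate = admin_suffix_rate,
             category_confusion = unname(category_confusion))
  if (any(rates < 0 | rates > 1)) {
    abort("all rates must lie in [0, 1]", class = "poivalid_config_error")
  }
  if (abs(sum(category_weights) - 1) > 1e-8) {
    abort("category_weights must sum to 1", class = "poivalid_config_error")
  }
  structure(list(
    n_units = as.integer(n_units), outlets_per_unit = outlets_per_unit,
    category_weights = category_weights, omission_rate = omission_rate,
    phantom_rate = phantom_rate, name_error_rate = name_error_rate,
    within_unit_location_error_rate = within_unit_location_error_rate,
    cross_unit_geocode_rate = cross_unit_geocode_rate,
    category_confusion = category_confusion,
    duplicate_rate = duplicate_rate, admin_suffix_rate = admin_suffix_rate,
    seed = as.integer(seed)
  ), class = "scenario_params")
}

# unit-square grid of areal units with alternating language / SES tertile
# attributes, half english half french, two units per (language, ses) cell
make_grid_units <- function(n_units) {
  ncol_grid <- ceiling(sqrt(n_units))
  ses_levels <- c("low", "medium", "high")
  ids <- sprintf("ct%02d", seq_len(n_units))
  rings <- vector("list", n_units)
  for (i in seq_len(n_units)) {
    cx <- (i - 1) %% ncol_grid
    cy <- (i - 1) %/% ncol_grid
    rings[[i]] <- cbind(c(cx, cx + 1, cx + 1, cx, cx),
                        c(cy, cy, cy + 1, cy + 1, cy))
  }
  half <- ceiling(n_units / 2)
  language <- ifelse(seq_len(n_units) <= half, "english", "french")
  within <- ave(seq_len(n_units), language, FUN = seq_along)
  ses <- ses_levels[((within - 1) %/% 2) %% 3 + 1]
  areal_units(ids, rings, ses = ses, language = language)
}

# deterministic in-unit coordinate for the g-th record of unit i
unit_point <- function(unit_idx, g, n_units) {
  ncol_grid <- ceiling(sqrt(n_units))
  cx <- (unit_idx - 1) %% ncol_grid
  cy <- (unit_idx - 1) %/% ncol_grid
  c(x = cx + 0.05 + 0.9 * ((g * 7) %% 97) / 97,
    y = cy + 0.05 + 0.9 * ((g * 13) %% 89) / 89)
}

#' Generate a synthetic foodscape and its corrupted listing
#'
#' Draws the ground truth (field census) per unit and category, then
#' derives the database listing by applying each error type independently
#' per record, in the order omission, category confusion, name error,
#' within-unit location jitter, cross-unit geocoding shift, and finally
#' appending phantom entries and duplicates. Cross-unit-shifted records
#' leave the extracted listing (they are geocoded outside every validated
#' unit, `unit_id = NA`) but remain in the full database, so the
#' ill-extracted search can recover them. Every applied error is recorded
#' in `truth_log`.
#'
#' @param params A [scenario_params()].
#' @return List with `field_truth`, `db_listing` (both outlet tables, unit
#'   ids assigned), `full_db` (listing plus records geocoded outside the
#'   units), `units`, and `truth_log` (tibble of per-record applied
#'   errors).
#' @export
generate_scenario <- function(params) {
  stopifnot(inherits(params, "scenario_params"))
  with_seed(params$seed, {
    units <- make_grid_units(params$n_units)
    cats <- names(params$category_weights)
    n_u <- rpois(params$n_units, params$outlets_per_unit)
    n <- sum(n_u)
    unit_idx <- rep(seq_len(params$n_units), n_u)
    g <- seq_len(n)
    pts <- t(vapply(g, function(i) unit_point(unit_idx[i], i, params$n_units),
                    c(x = 0, y = 0)))
    truth <- tibble::tibble(
      record_id = sprintf("f%06d", g),
      name = sprintf("outlet%06d", g),
      address = sprintf("%d rue %d", g, g),
      category = sample(cats, n, replace = TRUE,
                        prob = params$category_weights),
      unit_id = units$unit_id[unit_idx],
      x = pts[, "x"], y = pts[, "y"])

    eps <- params$category_confusion
    if (length(eps) > 1L) eps <- unname(eps[truth$category])
    omit <- runif(n) < params$omission_rate
    cat_err <- runif(n) < eps
    name_err <- runif(n) < params$name_error_rate
    loc_err <- runif(n) < params$within_unit_location_error_rate
    shift <- runif(n) < params$cross_unit_geocode_rate

    db <- truth
    db$record_id <- sprintf("d%06d", g)
    # category confusion: any other category, uniformly
    if (any(cat_err)) {
      db$category[cat_err] <- vapply(which(cat_err), function(i) {
        sample(setdiff(cats, truth$category[i]), 1L)
      }, "")
    }
    db$name[name_err] <- sprintf("listing%06d", g[name_err])
    db$address[loc_err] <- sprintf("%d avenue %d", g[loc_err], g[loc_err])
    db$unit_id[shift] <- NA_character_
    db$x[shift] <- -10; db$y[shift] <- -10
    keep <- !omit

    truth_log <- tibble::tibble(
      record_id = truth$record_id, db_record_id = db$record_id,
      omitted = omit, category_error = cat_err, name_error = name_err,
      location_error = loc_err, cross_unit_shift = shift)

    listing <- db[keep, ]
    extracted <- listing[!is.na(listing$unit_id), ]
    outside <- listing[is.na(listing$unit_id), ]

    # phantoms: expected fraction phantom_rate of the final in-unit listing
    q <- params$phantom_rate
    phantoms <- NULL
    if (q > 0 && nrow(extracted) > 0) {
      per_unit <- table(factor(extracted$unit_id, levels = units$unit_id))
      n_ph <- rpois(length(per_unit), as.numeric(per_unit) * q / (1 - q))
      if (sum(n_ph) > 0) {
        ph_unit <- rep(seq_len(params$n_units), n_ph)
        pg <- n + seq_len(sum(n_ph))
        ph_pts <- t(vapply(seq_along(pg), function(i) {
          unit_point(ph_unit[i], pg[i], params$n_units)
        }, c(x = 0, y = 0)))
        phantoms <- tibble::tibble(
          record_id = sprintf("p%06d", pg),
          name = sprintf("phantom%06d", pg),
          address = sprintf("%d rue %d", pg, pg),
          category = sample(cats, length(pg), replace = TRUE,
                            prob = params$category_weights),
          unit_id = units$unit_id[ph_unit],
          x = ph_pts[, "x"], y = ph_pts[, "y"])
      }
    }
    extracted <- dplyr::bind_rows(extracted, phantoms)

    # duplicates: identical entry, or an administrative-suffix variant
    dup <- runif(nrow(extracted)) < params$duplicate_rate
    if (any(dup)) {
      dups <- extracted[dup, ]
      suffix <- runif(nrow(dups)) < params$admin_suffix_rate
      dups$name <- ifelse(suffix, paste(dups$name, "office"), dups$name)
      dups$record_id <- paste0(dups$record_id, "x")
      extracted <- dplyr::bind_rows(extracted, dups)
    }

    as_outlets <- function(tb, source) {
      outlet_table(record_id = tb$record_id, source = source,
                   name = tb$name, address = tb$address,
                   x = tb$x, y = tb$y,
                   codes = if (source == "database")
                     rep_len(list("5411"), nrow(tb)) else NULL,
                   category = tb$category, unit_id = tb$unit_id)
    }
    list(field_truth = as_outlets(truth, "field"),
         db_listing = as_outlets(extracted, "database"),
         full_db = as_outlets(dplyr::bind_rows(extracted, outside),
                              "database"),
         units = units,
         truth_log = truth_log)
  })
}

#' Closed-form expected metrics of a scenario
#'
#' Asymptotic expectations of the four validity measures under the
#' generator's error model, with omission rate `w`, phantom fraction `q`,
#' name-error rate `v`, within-unit location-error rate `l`, cross-unit
#' geocoding rate `g` and mean category-confusion mass `e` (weighted by the
#' category mix when per-category):
#' \itemize{
#'   \item traditional sensitivity `(1-w)(1-g)(1-e)(1-v)(1-l)` — a field
#'     outlet is a traditional TP iff listed, kept in its unit, and free of
#'     every error;
#'   \item relaxed sensitivity `(1-w)(1-g)(1-e)(1-v*l)` — name and
#'     within-unit location errors are forgiven, but a record with *both*
#'     (different name at a different address) can no longer be paired at
#'     all, hence the `(1-v*l)` term;
#'   \item traditional PPV `(1-q)(1-e)(1-v)(1-l)` and relaxed PPV
#'     `(1-q)(1-e)(1-v*l)` — the listing denominator keeps every in-unit
#'     entry, of which a fraction `q` are phantoms.
#' }
#' Duplicates are assumed removed by [deduplicate()] before matching.
#'
#' @param params A [scenario_params()].
#' @return Named numeric vector with `sensitivity_traditional`,
#'   `sensitivity_relaxed`, `ppv_traditional`, `ppv_relaxed`.
#' @export
#' @examples
#' p <- scenario_params(omission_rate = 0.2, phantom_rate = 0,
#'                      name_error_rate = 0, category_confusion = 0,
#'                      within_unit_location_error_rate = 0,
#'                      cross_unit_geocode_rate = 0)
#' expected_metrics(p)[["sensitivity_relaxed"]]  # 0.8
expected_metrics <- function(params) {
  w <- params$omission_rate
  q <- params$phantom_rate
  v <- params$name_error_rate
  l <- params$within_unit_location_error_rate
  g <- params$cross_unit_geocode_rate
  e <- params$category_confusion
  if (length(e) > 1L) {
    e <- sum(unname(e[names(params$category_weights)]) *
               params$category_weights)
  }
  c(sensitivity_traditional = (1 - w) * (1 - g) * (1 - e) * (1 - v) * (1 - l),
    sensitivity_relaxed = (1 - w) * (1 - g) * (1 - e) * (1 - v * l),
    ppv_traditional = (1 - q) * (1 - e) * (1 - v) * (1 - l),
    ppv_relaxed = (1 - q) * (1 - e) * (1 - v * l))
}
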