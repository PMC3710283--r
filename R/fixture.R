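# Deterministic nonnegative integer allocation with exact margins: each
# row is first split over the columns proportionally (largest-remainder
# rounding), then column sums are repaired by moving single units along
# rows in a fixed scan order. Spreads counts over all cells, unlike a
# northwest-corner rule which empties the tail cells.
prop_alloc <- function(rowsums, colsums) {
  stopifnot(sum(rowsums) == sum(colsums))
  nr <- length(rowsums); nc <- length(colsums)
  m <- matrix(0L, nr, nc)
  total <- sum(rowsums)
  if (total == 0L) return(m)
  for (i in seq_len(nr)) {
    if (rowsums[i] == 0L) next
    share <- rowsums[i] * colsums / total
    base <- floor(share)
    rem <- rowsums[i] - sum(base)
    if (rem > 0) {
      extra <- order(share - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    m[i, ] <- as.integer(base)
  }
  repeat {
    diff <- colSums(m) - colsums
    if (all(diff == 0)) break
    j_over <- which(diff > 0)[1]
    j_under <- which(diff < 0)[1]
    i <- which(m[, j_over] > 0)[1]
    m[i, j_over] <- m[i, j_over] - 1L
    m[i, j_under] <- m[i, j_under] + 1L
  }
  m
}

# disposition columns of the built-in demonstration foodscape
demo_disp_cols <- c("matched", "name_error", "location_error",
                    "category_error", "name_category_error", "not_found",
                    "unlisted", "ill_extracted")

demo_category_counts <- function() {
  m <- rbind(
    convenience_stores         = c(37,  9, 1, 1, 1,  2,  13, 1),
    chain_supermarkets         = c( 3,  0, 0, 0, 0,  0,   1, 0),
    grocery_stores             = c(16,  0, 0, 6, 2,  5,   5, 4),
    bakery_shops               = c(13,  2, 0, 3, 0,  3,   6, 3),
    specialty_markets          = c( 9,  0, 0, 0, 0,  4,   4, 1),
    fruit_and_vegetable_stores = c( 5,  2, 0, 0, 0,  2,   1, 3),
    natural_food_stores        = c( 7,  0, 0, 1, 0,  1,   6, 2),
    mega_markets               = c( 1,  0, 0, 0, 0,  0,   0, 0),
    fast_food_restaurants      = c(25,  0, 1, 1, 2,  3,  11, 2),
    cafes                      = c(18,  1, 1, 2, 3, 12,  19, 6),
    full_service_restaurants   = c(130, 36, 0, 2, 4, 33, 39, 12))
  colnames(m) <- demo_disp_cols
  m
}

demo_language_counts <- function() {
  m <- rbind(english = c(186, 41, 3, 13, 9, 43, 75, 22),
             french  = c( 78,  9, 0,  3, 3, 22, 30, 12))
  colnames(m) <- demo_disp_cols
  m
}

demo_ses_counts <- function() {
  m <- rbind(low    = c( 51,  5, 2, 1, 0, 14, 22,  9),
             medium = c(102, 29, 1, 7, 6, 19, 41,  6),
             high   = c(111, 16, 0, 8, 6, 32, 42, 19))
  colnames(m) <- demo_disp_cols
  m
}

next_category <- function(cat) {
  cats <- default_categories()
  cats[match(cat, cats) %% length(cats) + 1L]
}

#' Built-in demonstration foodscape
#'
#' A deterministic 12-unit fixture with a fully known error profile: 410
#' listed outlets against 484 field outlets, of which 264 match perfectly,
#' 50 trade under a different name, 3 sit at a different address within
#' their unit, 16 carry the wrong category, 12 err in both name and
#' category, 65 are listed but absent from the field, 105 are present in
#' the field but nowhere in the database, and 34 are in the database under
#' the correct name and address but geocoded outside their true unit
#' (ill-extracted). Counts are fixed per outlet category and per unit
#' grouping (socioeconomic tertile, predominant language): per-disposition
#' category totals are spread over the six (language, SES) unit cells with
#' nested proportional integer allocations so that every marginal rolls up
#' exactly, then split between the two units of each cell. Names and
#' addresses are synthesized unique tokens, so the staged matcher recovers
#' exactly the intended dispositions.
#'
#' @return List with `db_listing` (410 records), `field_truth` (484),
#'   `full_db` (the listing plus the 34 ill-extracted records geocoded
#'   outside every unit), and `units` (12 areal units with `ses` and
#'   `language` attributes).
#' @export
#' @examples
#' fx <- demo_foodscape()
#' nrow(fx$db_listing)   # 410
#' nrow(fx$field_truth)  # 484
demo_foodscape <- function() {
  cat_m <- demo_category_counts()
  lang_m <- demo_language_counts()
  ses_m <- demo_ses_counts()
  units <- make_grid_units(12)
  # cells in unit order: (english|french) x (low, medium, high), 2 units each
  cell_units <- split(units$unit_id,
                      rep(1:6, each = 2))

  db <- list(); field <- list(); outside <- list()
  gctr <- 0L
  fresh <- function() {
    gctr <<- gctr + 1L
    gctr
  }
  add_db <- function(unit, cat, name, addr, pt) {
    db[[length(db) + 1L]] <<- tibble::tibble(
      record_id = sprintf("d%04d", length(db) + 1L), name = name,
      address = addr, category = cat, unit_id = unit,
      x = pt["x"], y = pt["y"])
  }
  add_field <- function(unit, cat, name, addr, pt) {
    field[[length(field) + 1L]] <<- tibble::tibble(
      record_id = sprintf("f%04d", length(field) + 1L), name = name,
      address = addr, category = cat, unit_id = unit,
      x = pt["x"], y = pt["y"])
  }

  for (d in demo_disp_cols) {
    joint <- prop_alloc(lang_m[, d], ses_m[, d])        # 2 x 3 cells
    cell_tot <- as.integer(t(joint))                    # cell order 1..6
    alloc <- prop_alloc(cat_m[, d], cell_tot)           # 11 x 6
    for (ci in seq_len(nrow(alloc))) {
      cat <- rownames(cat_m)[ci]
      for (k in seq_len(6)) {
        m <- alloc[ci, k]
        if (m == 0L) next
        u1 <- cell_units[[k]][1]; u2 <- cell_units[[k]][2]
        n1 <- ceiling(m / 2)
        for (r in seq_len(m)) {
          unit <- if (r <= n1) u1 else u2
          uidx <- match(unit, units$unit_id)
          g <- fresh()
          pt <- unit_point(uidx, g, 12)
          nm <- sprintf("outlet%04d", g)
          ad <- sprintf("%d rue %d", g, g)
          switch(d,
            matched = {
              add_db(unit, cat, nm, ad, pt)
              add_field(unit, cat, nm, ad, pt)
            },
            name_error = {
              add_db(unit, cat, sprintf("listing%04d", g), ad, pt)
              add_field(unit, cat, nm, ad, pt)
            },
            location_error = {
              add_db(unit, cat, nm, sprintf("%d avenue %d", g, g), pt)
              add_field(unit, cat, nm, ad, pt)
            },
            category_error = {
              add_db(unit, cat, nm, ad, pt)
              add_field(unit, next_category(cat), nm, ad, pt)
            },
            name_category_error = {
              add_db(unit, cat, sprintf("listing%04d", g), ad, pt)
              add_field(unit, next_category(cat), nm, ad, pt)
            },
            not_found = add_db(unit, cat, nm, ad, pt),
            unlisted = add_field(unit, cat, nm, ad, pt),
            ill_extracted = {
              add_field(unit, cat, nm, ad, pt)
              outside[[length(outside) + 1L]] <- tibble::tibble(
                record_id = sprintf("e%04d", length(outside) + 1L),
                name = nm, address = ad, category = cat,
                unit_id = NA_character_, x = -10, y = -10)
            })
        }
      }
    }
  }

  to_outlets <- function(rows, source) {
    tb <- dplyr::bind_rows(rows)
    outlet_table(record_id = tb$record_id, source = source, name = tb$name,
                 address = tb$address, x = tb$x, y = tb$y,
                 codes = if (source == "database")
                   rep_len(list("5411"), nrow(tb)) else NULL,
                 category = tb$category, unit_id = tb$unit_id)
  }
  db_tb <- to_outlets(db, "database")
  field_tb <- to_outlets(field, "field")
  full_tb <- to_outlets(c(db, outside), "database")
  list(db_listing = db_tb, field_truth = field_tb, full_db = full_tb,
       units = units)
}

#' Write the demonstration foodscape to disk
#'
#' Exports the fixture in the same formats the readers consume: database
#' and field CSVs, the complete database CSV, and the areal units as
#' GeoJSON. Useful as command-line example input.
#'
#' @param dir Output directory (created if needed).
#' @return Named vector of the four file paths, invisibly.
#' @export
write_demo_foodscape <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fx <- demo_foodscape()
  paths <- c(db = file.path(dir, "db.csv"),
             field = file.path(dir, "field.csv"),
             full_db = file.path(dir, "full_db.csv"),
             units = file.path(dir, "units.geojson"))
  write_flat <- function(tb, path) {
    flat <- data.frame(record_id = tb$record_id, name = tb$name_raw,
                       address = tb$address_norm,
                       x = tb$x, y = tb$y,
                       codes = vapply(tb$codes, paste, "", collapse = ";"),
                       category = tb$category,
                       stringsAsFactors = FALSE)
    write.csv(flat, path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  write_flat(fx$db_listing, paths["db"])
  write_flat(fx$field_truth, paths["field"])
  write_flat(fx$full_db, paths["full_db"])
  write_areal_units(fx$units, paths["units"])
  invisible(paths)
}
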