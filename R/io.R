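#' Build an outlet table
#'
#' Constructs the tibble layout used for both database listings and field
#' censuses: one row per outlet record with a unique `record_id`, the raw
#' and normalized name and address, planar or lon/lat coordinates, the list
#' of 4-character industry classification codes (database records carry 1-6
#' codes; field records may carry none), an optional category, an optional
#' areal-unit id, and an optional geocoding-precision code.
#'
#' @param record_id Character; unique within a dataset (default `r1...rn`).
#' @param source `"database"` or `"field"`.
#' @param name Character vector of business names.
#' @param address Character vector of street addresses.
#' @param x,y Numeric coordinates (same CRS for every dataset in a run).
#' @param codes List of character vectors of 4-character codes, or a single
#'   delimiter-joined character vector (see `codes_delim`).
#' @param category Character or NA; must be one of `categories` once set.
#' @param unit_id Character or NA.
#' @param precision_code Character or NA.
#' @param codes_delim Delimiter used when `codes` is given as a character
#'   vector of joined tokens.
#' @param categories Allowed category names.
#' @return A tibble with class `poi_tbl`.
#' @export
#' @examples
#' outlet_table(source = "database", name = "Provigo",
#'              address = "123 Main St", x = 1, y = 1, codes = "5411;5461")
outlet_table <- function(record_id = NULL, source, name, address, x, y,
                         codes = NULL, category = NA_character_,
                         unit_id = NA_character_,
                         precision_code = NA_character_,
                         codes_delim = ";",
                         categories = default_categories()) {
  source <- match.arg(source, c("database", "field"))
  n <- length(name)
  if (is.null(record_id)) {
    record_id <- paste0(substr(source, 1, 1), seq_len(n))
  }
  if (anyDuplicated(record_id)) {
    abort("record_id values must be unique within a dataset",
          class = "poivalid_data_error")
  }
  codes <- parse_codes(codes, n, codes_delim)
  if (source == "database") {
    nc <- lengths(codes)
    if (any(nc < 1L | nc > 6L)) {
      abort("database records must carry between 1 and 6 codes",
            class = "poivalid_data_error")
    }
  }
  category <- rep_len(as.character(category), n)
  bad <- !is.na(category) & !category %in% categories
  if (any(bad)) {
    abort(paste0("unknown category: ", paste(unique(category[bad]), collapse = ", ")),
          class = "poivalid_config_error")
  }
  out <- tibble::tibble(
    record_id = as.character(record_id),
    source = source,
    name_raw = as.character(name),
    name_norm = normalize_text(name),
    address_norm = normalize_address(address),
    x = as.numeric(rep_len(x, n)),
    y = as.numeric(rep_len(y, n)),
    codes = codes,
    category = category,
    unit_id = rep_len(as.character(unit_id), n),
    precision_code = rep_len(as.character(precision_code), n)
  )
  class(out) <- c("poi_tbl", class(out))
  out
}

parse_codes <- function(codes, n, codes_delim) {
  if (is.null(codes)) return(rep_len(list(character(0)), n))
  if (!is.list(codes)) {
    codes <- strsplit(ifelse(is.na(codes), "", as.character(codes)),
                      codes_delim, fixed = TRUE)
  }
  codes <- lapply(codes, function(cc) {
    cc <- trimws(as.character(cc))
    cc[nzchar(cc)]
  })
  rep_len(codes, n)
}

#' Read an outlet table from a delimited file
#'
#' Reads a CSV (UTF-8, header row) into an outlet table. Column names are
#' supplied through `schema`, a named list mapping the roles `name`,
#' `address`, `x`, `y` (mandatory; plus `codes` for database sources) and
#' optionally `record_id`, `category`, `unit_id`, `precision_code` to the
#' file's column names. Rows whose coordinates do not parse as numbers are
#' returned in a separate `rejects` tibble carrying their row numbers —
#' validation studies require complete accounting, so nothing is silently
#' dropped.
#'
#' @param path Path to the file.
#' @param source `"database"` or `"field"`.
#' @param schema Named list of column names (see Details).
#' @param delim Field delimiter, default `","`.
#' @param codes_delim Delimiter inside the codes column, default `";"`.
#' @return A list with elements `records` (outlet table) and `rejects`
#'   (tibble with `row` and `reason` plus the raw columns).
#' @export
read_outlet_table <- function(path, source,
                              schema = list(name = "name", address = "address",
                                            x = "x", y = "y", codes = "codes"),
                              delim = ",", codes_delim = ";") {
  source <- match.arg(source, c("database", "field"))
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "poivalid_config_error")
  }
  raw <- read.csv(path, sep = delim, colClasses = "character",
                  check.names = FALSE, fileEncoding = "UTF-8")
  mandatory <- c("name", "address", "x", "y", if (source == "database") "codes")
  for (role in mandatory) {
    col <- schema[[role]]
    if (is.null(col)) {
      abort(paste0("schema does not map mandatory role '", role, "'"),
            class = "poivalid_config_error")
    }
    if (!col %in% names(raw)) {
      abort(paste0("missing mandatory column '", col, "' (role '", role, "')"),
            class = "poivalid_config_error")
    }
  }
  if (nrow(raw) == 0L) {
    return(list(records = outlet_table(character(0), source, character(0),
                                       character(0), numeric(0), numeric(0)),
                rejects = tibble::tibble(row = integer(0),
                                         reason = character(0))))
  }
  xs <- suppressWarnings(as.numeric(raw[[schema$x]]))
  ys <- suppressWarnings(as.numeric(raw[[schema$y]]))
  bad <- is.na(xs) | is.na(ys)
  rejects <- tibble::as_tibble(raw[bad, , drop = FALSE])
  rejects <- tibble::add_column(rejects, row = which(bad),
                                reason = "unparseable coordinates",
                                .before = 1)
  keep <- raw[!bad, , drop = FALSE]
  pick <- function(role, default = NULL) {
    col <- schema[[role]]
    if (is.null(col) || !col %in% names(keep)) return(default)
    keep[[col]]
  }
  records <- outlet_table(
    record_id = pick("record_id"),
    source = source,
    name = keep[[schema$name]],
    address = keep[[schema$address]],
    x = xs[!bad], y = ys[!bad],
    codes = pick("codes"),
    category = pick("category", NA_character_),
    unit_id = pick("unit_id", NA_character_),
    precision_code = pick("precision_code", NA_character_),
    codes_delim = codes_delim
  )
  list(records = records, rejects = rejects)
}

#' Write an outlet table to CSV
#'
#' Serializes with a stable column order (codes re-joined with the
#' delimiter) so outputs are diffable across runs.
#'
#' @param records Outlet table.
#' @param path Output path.
#' @param codes_delim Delimiter for the codes column.
#' @return `path`, invisibly.
#' @export
write_outlet_table <- function(records, path, codes_delim = ";") {
  flat <- as.data.frame(records[, c("record_id", "source", "name_raw",
                                    "name_norm", "address_norm", "x", "y",
                                    "category", "unit_id", "precision_code")])
  flat$codes <- vapply(records$codes, paste, "", collapse = codes_delim)
  flat <- flat[, c("record_id", "source", "name_raw", "name_norm",
                   "address_norm", "x", "y", "codes", "category", "unit_id",
                   "precision_code")]
  write.csv(flat, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read areal units from a GeoJSON FeatureCollection
#'
#' Each Feature must be a Polygon (outer ring used; holes are not supported)
#' with a `properties.unit_id`; all other properties are kept as grouping
#' attributes (e.g. `ses`, `language`). Ring validity is checked with the
#' shoelace area; duplicate unit ids and degenerate rings are errors.
#' Overlapping units are detected (vertex-in-other-polygon test) and produce
#' a warning, not an error.
#'
#' @param path Path to a GeoJSON file.
#' @return A tibble with `unit_id`, `ring` (list of two-column matrices) and
#'   one column per grouping attribute, classed `areal_units`.
#' @export
read_areal_units <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "poivalid_config_error")
  }
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) {
    abort("not a GeoJSON FeatureCollection", class = "poivalid_data_error")
  }
  feats <- gj$features
  ids <- character(length(feats))
  rings <- vector("list", length(feats))
  props <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    id <- f$properties$unit_id
    if (is.null(id)) {
      abort(paste0("feature ", i, " has no properties.unit_id"),
            class = "poivalid_data_error")
    }
    ids[i] <- as.character(id)
    if (!identical(f$geometry$type, "Polygon")) {
      abort(paste0("unit ", id, ": geometry must be Polygon"),
            class = "poivalid_data_error")
    }
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) c(p[[1]], p[[2]])))
    if (nrow(ring) < 4L || abs(shoelace_area(ring)) <= 0) {
      abort(paste0("unit ", id, ": invalid ring geometry"),
            class = "poivalid_data_error")
    }
    props[[i]] <- f$properties[setdiff(names(f$properties), "unit_id")]
  }
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate unit_id: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "poivalid_data_error")
  }
  for (i in seq_along(feats)) {
    ring <- do.call(rbind, lapply(feats[[i]]$geometry$coordinates[[1]],
                                  function(p) c(p[[1]], p[[2]])))
    rings[[i]] <- ring
  }
  attr_names <- unique(unlist(lapply(props, names)))
  units <- tibble::tibble(unit_id = ids, ring = rings)
  for (a in attr_names) {
    units[[a]] <- vapply(props, function(p) {
      v <- p[[a]]
      if (is.null(v)) NA_character_ else as.character(v)
    }, "")
  }
  class(units) <- c("areal_units", class(units))
  check_unit_overlap(units)
  units
}

#' @rdname read_areal_units
#' @param unit_id Character vector of unit ids.
#' @param ring List of closed rings (two-column matrices, first row == last).
#' @param ... Grouping attribute vectors (e.g. `ses = `, `language = `).
#' @export
areal_units <- function(unit_id, ring, ...) {
  if (anyDuplicated(unit_id)) {
    abort("duplicate unit_id", class = "poivalid_data_error")
  }
  units <- tibble::tibble(unit_id = as.character(unit_id), ring = ring, ...)
  class(units) <- c("areal_units", class(units))
  units
}

# signed area; 0 means degenerate ring
shoelace_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

check_unit_overlap <- function(units) {
  n <- nrow(units)
  if (n < 2L) return(invisible(FALSE))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      a <- units$ring[[i]]; b <- units$ring[[j]]
      # strict interior containment of any vertex flags an overlap
      hit <- any(point_in_ring(b[, 1], b[, 2], a, boundary = FALSE)) ||
        any(point_in_ring(a[, 1], a[, 2], b, boundary = FALSE))
      if (hit) {
        warn(paste0("areal units overlap: ", units$unit_id[i], " and ",
                    units$unit_id[j]))
        return(invisible(TRUE))
      }
    }
  }
  invisible(FALSE)
}

#' Write areal units to GeoJSON
#'
#' Inverse of [read_areal_units()]: one Polygon Feature per unit, grouping
#' attributes under `properties`.
#'
#' @param units Areal units tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_areal_units <- function(units, path) {
  attrs <- setdiff(names(units), c("unit_id", "ring"))
  feats <- lapply(seq_len(nrow(units)), function(i) {
    props <- c(list(unit_id = units$unit_id[i]),
               lapply(setNames(attrs, attrs), function(a) units[[a]][i]))
    ring <- units$ring[[i]]
    coords <- lapply(seq_len(nrow(ring)), function(k) c(ring[k, 1], ring[k, 2]))
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = list(coords)))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}
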