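#' Matching configuration
#'
#' @param name_similarity_threshold Names scoring at or above this
#'   token-set similarity (see [name_similarity()]) count as "the same
#'   name"; below it, as a name mismatch. Default 0.85.
#' @param spatial_tolerance `"same_unit"` (a location discrepancy is
#'   forgiven by the relaxed measures when the record stays in its areal
#'   unit) or a distance in meters. Matching itself always pairs records
#'   within the same unit; the distance form only changes which location
#'   errors the relaxed measures forgive downstream.
#' @param treat_ill_extracted_as `"fn"` (default: an ill-extracted outlet is
#'   a false negative in both modes, since relaxation only tolerates
#'   within-unit imprecision) or `"tp"` (the geocoding-correction
#'   counterfactual: what the metrics would be had cross-unit geocoding
#'   errors been repaired).
#' @param category_attribution For pairs with a category mismatch, the
#'   category cell that receives the false negative: `"listed"` (default,
#'   the database-listed category) or `"field"`.
#' @return A `match_config` list.
#' @export
match_config <- function(name_similarity_threshold = 0.85,
                         spatial_tolerance = "same_unit",
                         treat_ill_extracted_as = c("fn", "tp"),
                         category_attribution = c("listed", "field")) {
  stopifnot(name_similarity_threshold >= 0, name_similarity_threshold <= 1)
  structure(list(
    name_similarity_threshold = name_similarity_threshold,
    spatial_tolerance = spatial_tolerance,
    treat_ill_extracted_as = match.arg(treat_ill_extracted_as),
    category_attribution = match.arg(category_attribution)
  ), class = "match_config")
}

disposition_levels <- c("matched", "name_error", "location_error",
                        "category_error", "name_category_error",
                        "not_found", "unlisted", "ill_extracted")

# Greedy one-to-one pair selection in (stage, db_record_id,
# field_record_id) order, vectorized in rounds: each round keeps every row
# that is the first occurrence of both its ids, then discards rows
# conflicting with a kept pair. Fallback for components too large for the
# exact search; equivalent to walking the sorted candidate list row by row.
greedy_select <- function(cand) {
  cand <- cand[order(cand$stage, cand$db_record_id, cand$field_record_id), ,
               drop = FALSE]
  kept <- list()
  while (nrow(cand)) {
    take <- !duplicated(cand$db_record_id) & !duplicated(cand$field_record_id)
    sel <- cand[take, , drop = FALSE]
    kept[[length(kept) + 1L]] <- sel
    cand <- cand[!take, , drop = FALSE]
    cand <- cand[!(cand$db_record_id %in% sel$db_record_id) &
                   !(cand$field_record_id %in% sel$field_record_id), ,
                 drop = FALSE]
  }
  dplyr::bind_rows(kept)
}

# Exact lexicographic maximum matching for one connected component of the
# candidate-pair graph: maximizes the stage-count vector (matched first,
# then name errors, ...) over all one-to-one assignments, by dynamic
# programming over subsets of the smaller record side. Ties are broken by
# taking, at each record in id order, the optimal pair with the lowest
# stage and then the lowest partner id. Components whose smaller side
# exceeds `max_mask` records fall back to greedy_select.
solve_component <- function(pairs, max_mask = 12L) {
  if (nrow(pairs) == 1L) return(pairs)
  dbs <- sort(unique(pairs$db_record_id))
  fls <- sort(unique(pairs$field_record_id))
  swapped <- length(fls) > length(dbs)
  seq_ids <- if (swapped) fls else dbs      # iterated side
  mask_ids <- if (swapped) dbs else fls     # bitmask side
  if (length(mask_ids) > max_mask) return(greedy_select(pairs))
  i_of <- match(if (swapped) pairs$field_record_id else pairs$db_record_id,
                seq_ids)
  bit_of <- bitwShiftL(1L, match(
    if (swapped) pairs$db_record_id else pairs$field_record_id,
    mask_ids) - 1L)
  K <- min(length(dbs), length(fls))
  B <- K + 1
  w <- B^(5 - pairs$stage)
  n_seq <- length(seq_ids)
  n_mask <- bitwShiftL(1L, length(mask_ids))
  masks <- 0:(n_mask - 1L)
  f <- matrix(0, n_seq + 1L, n_mask)
  by_i <- split(seq_len(nrow(pairs)), i_of)
  for (i in n_seq:1) {
    vi <- f[i + 1L, ]
    for (j in by_i[[as.character(i)]] %||% integer(0)) {
      free <- bitwAnd(masks, bit_of[j]) == 0L
      cand <- w[j] + f[i + 1L, bitwOr(masks[free], bit_of[j]) + 1L]
      vi[free] <- pmax(vi[free], cand)
    }
    f[i, ] <- vi
  }
  # recover one optimal assignment deterministically
  chosen <- integer(0)
  mask <- 0L
  for (i in seq_len(n_seq)) {
    js <- by_i[[as.character(i)]] %||% integer(0)
    if (length(js)) {
      ord <- js[order(pairs$stage[js],
                      if (swapped) pairs$db_record_id[js] else
                        pairs$field_record_id[js])]
      hit <- FALSE
      for (j in ord) {
        if (bitwAnd(mask, bit_of[j]) == 0L &&
            isTRUE(all.equal(w[j] + f[i + 1L, bitwOr(mask, bit_of[j]) + 1L],
                             f[i, mask + 1L]))) {
          chosen <- c(chosen, j)
          mask <- bitwOr(mask, bit_of[j])
          hit <- TRUE
          break
        }
      }
    }
  }
  pairs[chosen, , drop = FALSE]
}

# union-find over the candidate pairs: pairs sharing a db or field record
# belong to one component and must be resolved together
pair_components <- function(pairs) {
  ids <- c(paste0("d.", pairs$db_record_id), paste0("f.", pairs$field_record_id))
  uid <- unique(ids)
  parent <- seq_along(uid)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  di <- match(paste0("d.", pairs$db_record_id), uid)
  fi <- match(paste0("f.", pairs$field_record_id), uid)
  for (k in seq_len(nrow(pairs))) {
    a <- find(di[k]); b <- find(fi[k])
    if (a != b) parent[a] <- b
  }
  vapply(di, find, 1L)
}

#' Classify the disposition of every database and field record
#'
#' Deterministic matching within each areal unit. Candidate pairs and
#' their error pattern are enumerated first: address+name+category agree
#' (stage 1, matched); address+category agree, names differ (stage 2, name
#' error); name+category agree, addresses differ within the unit (stage 3,
#' location error); address+name agree, categories differ (stage 4,
#' category error); address agrees, name and category differ (stage 5,
#' error in both name and category). Each record is then assigned at most
#' one partner by maximizing the stage-count vector lexicographically —
#' as many perfect matches as possible, then as many name errors, and so
#' on — exactly, per connected component of the candidate graph (ties
#' resolved per database record in id order by lowest stage, then lowest
#' field record id). Database records left over are "not found" (listed
#' but absent in the field); field records left over are "unlisted"
#' (present in the field but not on the extracted list). Every input
#' record appears in exactly one disposition row, and permuting input row
#' order never changes the result.
#'
#' @param db Outlet table (database side); `unit_id` and `category` set.
#' @param field Outlet table (field side); `unit_id` and `category` set.
#' @param cfg A [match_config()].
#' @return Tibble with columns `disposition`, `stage`, `db_record_id`,
#'   `field_record_id`, `unit_id`, `db_category`, `field_category`,
#'   `similarity`.
#' @export
classify_dispositions <- function(db, field, cfg = match_config()) {
  if (any(db$record_id %in% field$record_id)) {
    abort("record_id values duplicated across database and field inputs",
          class = "poivalid_data_error")
  }
  th <- cfg$name_similarity_threshold
  db <- dplyr::arrange(tibble::as_tibble(db), .data$record_id)
  field <- dplyr::arrange(tibble::as_tibble(field), .data$record_id)
  cand <- candidate_pairs(db, field, th)

  sel <- if (nrow(cand)) {
    comp <- pair_components(cand)
    single <- comp %in% which(tabulate(comp) == 1L)
    multi <- split(cand[!single, , drop = FALSE], comp[!single])
    dplyr::bind_rows(cand[single, , drop = FALSE],
                     purrr::map_dfr(multi, solve_component))
  } else cand

  stage_names <- c("matched", "name_error", "location_error",
                   "category_error", "name_category_error")
  paired <- tibble::tibble(
    disposition = stage_names[sel$stage], stage = sel$stage,
    db_record_id = sel$db_record_id, field_record_id = sel$field_record_id,
    unit_id = sel$unit_id, db_category = sel$db_category,
    field_category = sel$field_category, similarity = sel$similarity)
  leftover_db <- db[!db$record_id %in% sel$db_record_id, ]
  leftover_field <- field[!field$record_id %in% sel$field_record_id, ]
  out <- dplyr::bind_rows(
    paired,
    tibble::tibble(disposition = rep("not_found", nrow(leftover_db)),
                   stage = NA_integer_,
                   db_record_id = leftover_db$record_id,
                   field_record_id = NA_character_,
                   unit_id = leftover_db$unit_id,
                   db_category = leftover_db$category,
                   field_category = NA_character_,
                   similarity = NA_real_),
    tibble::tibble(disposition = rep("unlisted", nrow(leftover_field)),
                   stage = NA_integer_,
                   db_record_id = NA_character_,
                   field_record_id = leftover_field$record_id,
                   unit_id = leftover_field$unit_id,
                   db_category = NA_character_,
                   field_category = leftover_field$category,
                   similarity = NA_real_)
  )
  out <- out[order(out$stage, out$db_record_id, out$field_record_id,
                   na.last = TRUE), ]
  out$disposition <- factor(out$disposition, levels = disposition_levels)
  out
}

# Enumerate all candidate (db, field) pairs within units together with
# their stage. Equality joins carry the bulk; the fuzzy name-agreement
# pairs of stage 3 are found through a shared-token join (a similarity at
# or above a positive threshold requires at least one common name token).
candidate_pairs <- function(db, field, th) {
  d <- db[, c("record_id", "unit_id", "address_norm", "name_norm",
              "category")]
  f <- field[, c("record_id", "unit_id", "address_norm", "name_norm",
                 "category")]
  names(d) <- paste0("db_", names(d))
  names(f) <- paste0("field_", names(f))
  empty <- tibble::tibble(db_record_id = character(0),
                          field_record_id = character(0),
                          unit_id = character(0),
                          db_category = character(0),
                          field_category = character(0),
                          similarity = numeric(0), stage = integer(0))
  if (nrow(d) == 0L || nrow(f) == 0L) return(empty)

  join_on <- function(keys) {
    by <- setNames(paste0("field_", keys), paste0("db_", keys))
    out <- dplyr::inner_join(d, f, by = by, relationship = "many-to-many")
    for (k in keys) out[[paste0("field_", k)]] <- out[[paste0("db_", k)]]
    out
  }
  finish <- function(p, stage) {
    if (is.null(p) || nrow(p) == 0L) return(NULL)
    tibble::tibble(db_record_id = p$db_record_id,
                   field_record_id = p$field_record_id,
                   unit_id = p$db_unit_id,
                   db_category = p$db_category,
                   field_category = p$field_category,
                   similarity = p$similarity, stage = stage)
  }

  # same address, same category: stage 1 or 2 by name agreement
  ac <- join_on(c("unit_id", "address_norm", "category"))
  ac$similarity <- similarity_norm(ac$db_name_norm, ac$field_name_norm)
  p12 <- list(finish(ac[ac$similarity >= th, ], 1L),
              finish(ac[ac$similarity < th, ], 2L))

  # same name (exact or fuzzy), same category, address differs: stage 3
  nc <- join_on(c("unit_id", "category", "name_norm"))
  nc$similarity <- 1
  p3a <- finish(nc[nc$db_address_norm != nc$field_address_norm, ], 3L)
  p3b <- NULL
  if (th > 0) {
    tok_d <- tidyr::unnest(
      dplyr::mutate(d, tok = strsplit(.data$db_name_norm, " ", fixed = TRUE)),
      "tok")
    tok_f <- tidyr::unnest(
      dplyr::mutate(f, tok = strsplit(.data$field_name_norm, " ",
                                      fixed = TRUE)),
      "tok")
    fz <- dplyr::inner_join(
      tok_d, tok_f,
      by = c(db_unit_id = "field_unit_id", db_category = "field_category",
             tok = "tok"), relationship = "many-to-many")
    fz <- dplyr::distinct(fz, .data$db_record_id, .data$field_record_id,
                          .keep_all = TRUE)
    fz$field_unit_id <- fz$db_unit_id
    fz$field_category <- fz$db_category
    fz <- fz[fz$db_name_norm != fz$field_name_norm &
               fz$db_address_norm != fz$field_address_norm, ]
    if (nrow(fz)) {
      fz$similarity <- similarity_norm(fz$db_name_norm, fz$field_name_norm)
      p3b <- finish(fz[fz$similarity >= th, ], 3L)
    }
  } else {
    uc <- join_on(c("unit_id", "category"))
    uc$similarity <- similarity_norm(uc$db_name_norm, uc$field_name_norm)
    p3b <- finish(uc[uc$db_address_norm != uc$field_address_norm &
                       uc$similarity >= th &
                       uc$db_name_norm != uc$field_name_norm, ], 3L)
  }

  # same address, category differs: stage 4 or 5 by name agreement
  ad <- join_on(c("unit_id", "address_norm"))
  ad <- ad[ad$db_category != ad$field_category, ]
  ad$similarity <- similarity_norm(ad$db_name_norm, ad$field_name_norm)
  p45 <- list(finish(ad[ad$similarity >= th, ], 4L),
              finish(ad[ad$similarity < th, ], 5L))

  out <- dplyr::bind_rows(c(p12, list(p3a, p3b), p45))
  if (nrow(out) == 0L) return(empty)
  dplyr::distinct(out, .data$db_record_id, .data$field_record_id,
                  .keep_all = TRUE)
}

#' Split unlisted field records into ill-extracted and truly absent
#'
#' An unlisted field outlet that is present in the complete database under
#' the same street address and the same name (token-set similarity at or
#' above the threshold), but geocoded outside its true areal unit, was
#' missed by the spatial extraction rather than by the database: it is
#' "ill-extracted". The rest are truly absent.
#'
#' @param unlisted Outlet table of field records with disposition unlisted.
#' @param full_db The complete database listing (all units, not just the
#'   validated ones), with `unit_id` as geocoded (`NA` = outside all
#'   validated units).
#' @param cfg A [match_config()].
#' @return List with outlet tables `ill_extracted` and `truly_absent`;
#'   row counts always sum to `nrow(unlisted)`.
#' @export
find_ill_extracted <- function(unlisted, full_db, cfg = match_config()) {
  if (nrow(unlisted) == 0L || nrow(full_db) == 0L) {
    return(list(ill_extracted = unlisted[0, ], truly_absent = unlisted))
  }
  ill <- rep(FALSE, nrow(unlisted))
  for (i in seq_len(nrow(unlisted))) {
    cand <- full_db[full_db$address_norm == unlisted$address_norm[i], ]
    if (nrow(cand) == 0L) next
    sim <- similarity_norm(rep(unlisted$name_norm[i], nrow(cand)),
                           cand$name_norm)
    elsewhere <- is.na(cand$unit_id) | cand$unit_id != unlisted$unit_id[i]
    ill[i] <- any(sim >= cfg$name_similarity_threshold & elsewhere)
  }
  list(ill_extracted = unlisted[ill, ], truly_absent = unlisted[!ill, ])
}

#' Relabel ill-extracted rows in a disposition table
#'
#' @param dispositions Result of [classify_dispositions()].
#' @param ill_extracted Outlet table returned by [find_ill_extracted()].
#' @return The disposition table with the matching unlisted rows relabeled
#'   `ill_extracted`.
#' @export
mark_ill_extracted <- function(dispositions, ill_extracted) {
  hit <- dispositions$disposition == "unlisted" &
    dispositions$field_record_id %in% ill_extracted$record_id
  dispositions$disposition[hit] <- "ill_extracted"
  dispositions
}

#' Flag listed-but-absent records inappropriately included by geocoding
#'
#' For each not-found database record, compares the unit its coordinate
#' falls in (its `unit_id`) with the unit its street address belongs to,
#' looked up in a reference table of known addresses (e.g. built from the
#' field census). A mismatch means the record sits in the validated unit
#' only because of a geocoding error.
#'
#' @param not_found Outlet table of database records with disposition
#'   not_found.
#' @param address_units Tibble with columns `address_norm` and `unit_id`
#'   giving the true unit of known street addresses.
#' @return `not_found` with a logical `inappropriately_included` column
#'   (`NA` when the address is not in the reference table).
#' @export
check_inappropriately_included <- function(not_found, address_units) {
  if (nrow(not_found) == 0L) {
    not_found$inappropriately_included <- logical(0)
    return(not_found)
  }
  lookup <- address_units[!duplicated(address_units$address_norm), ]
  idx <- match(not_found$address_norm, lookup$address_norm)
  addr_unit <- lookup$unit_id[idx]
  not_found$inappropriately_included <-
    ifelse(is.na(addr_unit), NA, addr_unit != not_found$unit_id)
  not_found
}
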