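#' Remove duplicate listing entries
#'
#' Two records are duplicates when their normalized addresses are identical
#' and their normalized names are identical, or differ only by an
#' administrative-function token such as "office" or "fax" (head offices are
#' often listed at the retail address under an administrative variant of the
#' name). Within a duplicate group the record whose name lacks the
#' administrative token is kept; ties break on the lowest `record_id`.
#' Duplicate detection is identity-based: typo-level near-duplicates are
#' intentionally not collapsed here.
#'
#' @param records Outlet table.
#' @param admin_suffixes Administrative tokens (matched whole-token after
#'   normalization).
#' @return List with `kept` and `removed` outlet tables;
#'   `nrow(kept) + nrow(removed) == nrow(records)` always.
#' @export
#' @examples
#' tb <- outlet_table(source = "database",
#'                    name = c("Provigo", "Provigo office"),
#'                    address = c("123 Main St", "123 Main St"),
#'                    x = 0, y = 0, codes = "5411")
#' deduplicate(tb)$kept$name_raw  # "Provigo"
deduplicate <- function(records, admin_suffixes = c("office", "fax", "bureau",
                                                    "head office", "admin")) {
  n <- nrow(records)
  if (n == 0L) return(list(kept = records, removed = records))
  if (length(unique(records$source)) > 1L) {
    abort("deduplicate expects records from a single source",
          class = "poivalid_data_error")
  }
  admin_norm <- normalize_text(admin_suffixes)
  drop <- rep(FALSE, n)
  for (addr in unique(records$address_norm)) {
    idx <- which(records$address_norm == addr)
    if (length(idx) < 2L) next
    names_g <- records$name_norm[idx]
    # duplicate relation: equal names, or one name = the other +/- one
    # admin token; groups are connected components of that relation
    m <- length(idx)
    adj <- diag(TRUE, m)
    for (a in seq_len(m - 1L)) for (b in seq(a + 1L, m)) {
      adj[a, b] <- adj[b, a] <- names_match_dup(names_g[a], names_g[b], admin_norm)
    }
    comp <- connected_components(adj)
    for (g in unique(comp)) {
      members <- idx[comp == g]
      if (length(members) < 2L) next
      has_admin <- vapply(records$name_norm[members], has_admin_token, TRUE,
                          admin = admin_norm)
      pool <- if (any(!has_admin)) members[!has_admin] else members
      keep <- pool[order(records$record_id[pool])][1L]
      drop[setdiff(members, keep)] <- TRUE
    }
  }
  list(kept = records[!drop, ], removed = records[drop, ])
}

names_match_dup <- function(a, b, admin) {
  if (a == b) return(TRUE)
  strip_a <- strip_admin(a, admin)
  strip_b <- strip_admin(b, admin)
  # one name equals the other plus/minus an administrative token
  (strip_a == b) || (strip_b == a)
}

strip_admin <- function(x, admin) {
  for (tok in admin) {
    x <- gsub(paste0("\\b", tok, "\\b"), " ", x)
  }
  trimws(gsub(" +", " ", x))
}

has_admin_token <- function(x, admin) {
  any(vapply(admin, function(tok) grepl(paste0("\\b", tok, "\\b"), x), TRUE))
}

connected_components <- function(adj) {
  m <- nrow(adj)
  comp <- rep(NA_integer_, m)
  cur <- 0L
  for (s in seq_len(m)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    frontier <- s
    while (length(frontier)) {
      comp[frontier] <- cur
      nxt <- which(apply(adj[frontier, , drop = FALSE], 2L, any) & is.na(comp))
      frontier <- nxt
    }
  }
  comp
}
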