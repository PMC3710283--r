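# small builders used across the test files

mk_outlets <- function(src, name, address, category = NA_character_,
                       unit_id = "u1", x = 0.5, y = 0.5,
                       record_id = NULL) {
  outlet_table(
    record_id = record_id, source = src, name = name, address = address,
    x = x, y = y,
    codes = if (src == "database") rep_len(list("5411"), length(name)) else NULL,
    category = category, unit_id = unit_id)
}

square_ring <- function(x0, y0, side = 1) {
  cbind(c(x0, x0 + side, x0 + side, x0, x0),
        c(y0, y0, y0 + side, y0 + side, y0))
}

two_square_units <- function() {
  areal_units(c("u1", "u2"),
              list(square_ring(0, 0), square_ring(1, 0)),
              ses = c("low", "high"), language = c("english", "french"))
}

# random small matching case with collision-heavy names/addresses,
# stressing tie-breaks and cross-stage coupling
random_match_case <- function(nd, nf, cats = c("grocery_stores", "cafes",
                                               "bakery_shops")) {
  mk <- function(n, src) outlet_table(
    record_id = paste0(substr(src, 1, 1), seq_len(n)), source = src,
    name = sample(c("alpha", "beta", "gamma", "delta"), n, replace = TRUE),
    address = paste(sample(1:4, n, replace = TRUE), "main st"),
    x = 0, y = 0,
    codes = if (src == "database") rep_len(list("5411"), n) else NULL,
    category = sample(cats, n, replace = TRUE), unit_id = "u1")
  list(db = mk(nd, "database"), field = mk(nf, "field"))
}

# full pipeline on the built-in fixture, shared by several test files
demo_dispositions <- function() {
  fx <- demo_foodscape()
  disp <- classify_dispositions(fx$db_listing, fx$field_truth)
  unl <- fx$field_truth[fx$field_truth$record_id %in%
                          disp$field_record_id[disp$disposition == "unlisted"], ]
  ill <- find_ill_extracted(unl, fx$full_db)$ill_extracted
  list(fx = fx, disp = mark_ill_extracted(disp, ill))
}
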