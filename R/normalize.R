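#' Normalize free text for matching
#'
#' Case-folds, strips accents, collapses punctuation and runs of whitespace
#' to single spaces, and trims. Idempotent: applying it twice gives the same
#' result as applying it once. Used on both business names and street
#' addresses before any comparison, so that "Couche-Tard  " and "couche tard"
#' compare equal.
#'
#' @param raw Character vector (NA allowed, passed through as "").
#' @return Character vector of the same length, normalized.
#' @export
#' @examples
#' normalize_text("Couche-Tard  ")   # "couche tard"
#' normalize_text("Café Élève")  # "cafe eleve"
normalize_text <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  x <- ifelse(is.na(raw), "", as.character(raw))
  nonascii <- grepl("[^\\x01-\\x7F]", x, perl = TRUE, useBytes = TRUE)
  if (any(nonascii)) {
    x[nonascii] <- stringi::stri_trans_general(x[nonascii], "Latin-ASCII")
  }
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(gsub(" +", " ", x))
}

# apartment/suite designators stripped from addresses: the match key is
# street-number + street-name, not the unit within the building
address_unit_tokens <- c(
  "apt", "app", "appartement", "apartment", "suite", "ste", "unit",
  "bureau", "local", "no"
)

#' Normalize a street address for matching
#'
#' Applies [normalize_text()], then removes apartment/suite designators and
#' the token that follows them (e.g. "apt 4", "suite 200"), so the match key
#' is the street number plus street name.
#'
#' @param raw Character vector of raw addresses.
#' @return Character vector of normalized addresses.
#' @export
#' @examples
#' normalize_address("123 Main St., Apt 4")  # "123 main st"
normalize_address <- function(raw) {
  x <- normalize_text(raw)
  pat <- paste0("\\b(", paste(address_unit_tokens, collapse = "|"),
                ")( [0-9a-z]+)?\\b")
  trimws(gsub(" +", " ", gsub(pat, " ", x)))
}

#' Token-set name similarity
#'
#' Dice coefficient on the sets of normalized tokens of two names:
#' `2 * |A intersect B| / (|A| + |B|)`. 1 for identical token sets (in any
#' order), 0 for disjoint ones. Both inputs are normalized with
#' [normalize_text()] first; two empty names score 1.
#'
#' @param a,b Character vectors (recycled to common length).
#' @return Numeric vector of similarities in \[0, 1\].
#' @export
#' @examples
#' name_similarity("Provigo", "provigo")            # 1
#' name_similarity("Chez Luc", "Chez Marc")         # 0.5
name_similarity <- function(a, b) {
  n <- max(length(a), length(b))
  similarity_norm(rep_len(normalize_text(a), n),
                  rep_len(normalize_text(b), n))
}

# Dice on token sets of already-normalized strings (internal hot path)
similarity_norm <- function(a, b) {
  out <- rep(1, length(a))
  todo <- which(a != b)
  if (!length(todo)) return(out)
  ta <- strsplit(a[todo], " ", fixed = TRUE)
  tb <- strsplit(b[todo], " ", fixed = TRUE)
  for (j in seq_along(todo)) {
    x <- unique(ta[[j]]); y <- unique(tb[[j]])
    x <- x[nzchar(x)]; y <- y[nzchar(y)]
    out[todo[j]] <- if (length(x) == 0L && length(y) == 0L) 1 else
      2 * sum(x %in% y) / (length(x) + length(y))
  }
  out
}
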