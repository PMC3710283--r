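# independent oracles, kept free of the package's own algorithms

lex_gt <- function(a, b) {
  d <- a - b
  nz <- which(d != 0)
  length(nz) > 0 && d[nz[1]] > 0
}

# exhaustive assignment maximizing the stage-count vector (matched, name
# error, location error, category error, both) lexicographically; brute
# force over all one-to-one assignments, feasible for <= 6 records a side
oracle_stage_counts <- function(db, field, th = 0.85) {
  n_d <- nrow(db); n_f <- nrow(field)
  stage <- matrix(NA_integer_, max(n_d, 1), max(n_f, 1))
  for (i in seq_len(n_d)) for (j in seq_len(n_f)) {
    if (db$unit_id[i] != field$unit_id[j]) next
    addr <- db$address_norm[i] == field$address_norm[j]
    nm <- name_similarity(db$name_norm[i], field$name_norm[j]) >= th
    ceq <- db$category[i] == field$category[j]
    stage[i, j] <- if (addr && nm && ceq) 1L else if (addr && ceq) 2L else
      if (!addr && nm && ceq) 3L else if (addr && nm) 4L else
        if (addr) 5L else NA_integer_
  }
  best <- c(-1, 0, 0, 0, 0)
  rec <- function(i, used_f, counts) {
    if (i > n_d) {
      if (lex_gt(counts, best)) best <<- counts
      return()
    }
    rec(i + 1L, used_f, counts)
    for (j in seq_len(n_f)) {
      if (!used_f[j] && !is.na(stage[i, j])) {
        c2 <- counts
        c2[stage[i, j]] <- c2[stage[i, j]] + 1
        rec(i + 1L, replace(used_f, j, TRUE), c2)
      }
    }
  }
  rec(1L, rep(FALSE, n_f), c(0, 0, 0, 0, 0))
  best
}

# all compositions of n into k nonnegative parts
compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, 1))
  out <- NULL
  for (first in 0:n) {
    rest <- compositions(n - first, k - 1L)
    out <- rbind(out, cbind(first, rest))
  }
  unname(out)
}

# attainable values of the per-unit compensation sum when F false
# positives and N false negatives are spread over k units, for both the
# capped-min and absolute-difference forms; exhaustive over compositions
attainable_compensation <- function(F, N, k) {
  fp_all <- compositions(F, k)
  fn_all <- compositions(N, k)
  mins <- integer(0); abss <- integer(0)
  for (i in seq_len(nrow(fp_all))) {
    for (j in seq_len(nrow(fn_all))) {
      mins <- c(mins, sum(pmin(fp_all[i, ], fn_all[j, ])))
      abss <- c(abss, sum(abs(fp_all[i, ] - fn_all[j, ])))
    }
  }
  list(compensated_min = sort(unique(mins)),
       as_printed_abs = sort(unique(abss)))
}

# shoelace polygon area
shoelace <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]; n <- nrow(ring)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2)
}
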