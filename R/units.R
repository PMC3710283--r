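# Point-in-polygon with an explicit boundary rule. Interior membership comes
# from mgcv::in.out (even-odd ray crossing); points on an edge or vertex are
# decided by an on-segment test because ray-crossing algorithms are not
# reliable exactly on the boundary. Boundary counts as inside by default so
# records sitting on a shared tract edge are never dropped.
point_in_ring <- function(px, py, ring, boundary = TRUE, eps = 1e-9) {
  stopifnot(length(px) == length(py))
  if (length(px) == 0L) return(logical(0))
  on_b <- point_on_ring(px, py, ring, eps)
  inside <- as.logical(mgcv::in.out(ring, cbind(px, py)))
  if (boundary) inside | on_b else inside & !on_b
}

point_on_ring <- function(px, py, ring, eps = 1e-9) {
  n <- nrow(ring)
  scale <- max(abs(ring), 1)
  tol <- eps * scale
  out <- rep(FALSE, length(px))
  for (k in seq_len(n - 1L)) {
    x1 <- ring[k, 1]; y1 <- ring[k, 2]
    x2 <- ring[k + 1L, 1]; y2 <- ring[k + 1L, 2]
    cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    within <- px >= pmin(x1, x2) - tol & px <= pmax(x1, x2) + tol &
      py >= pmin(y1, y2) - tol & py <= pmax(y1, y2) + tol
    out <- out | (abs(cross) <= tol * max(abs(x2 - x1), abs(y2 - y1), 1) & within)
  }
  out
}

#' Assign outlet records to areal units
#'
#' Point-in-polygon assignment of each record's coordinate to a unit.
#' Boundary points count as inside. If overlapping polygons both contain a
#' point, the first unit in file order wins and a warning is emitted. Points
#' inside no unit get `NA`.
#'
#' @param records Outlet table (see [outlet_table()]).
#' @param units Areal units (see [read_areal_units()]).
#' @return `records` with `unit_id` filled in.
#' @export
assign_units <- function(records, units) {
  n <- nrow(records)
  if (n == 0L) return(records)
  hits <- matrix(FALSE, n, nrow(units))
  for (j in seq_len(nrow(units))) {
    hits[, j] <- point_in_ring(records$x, records$y, units$ring[[j]])
  }
  nhit <- rowSums(hits)
  if (any(nhit > 1L)) {
    warn(paste0(sum(nhit > 1L), " record(s) fall in more than one unit; ",
                "first unit in file order used"))
  }
  first <- apply(hits, 1L, function(h) if (any(h)) which(h)[1L] else NA_integer_)
  records$unit_id <- ifelse(is.na(first), NA_character_,
                            units$unit_id[first])
  records
}

#' @rdname assign_units
#' @param x,y A single coordinate.
#' @return `assign_unit()`: a single unit id or `NA`.
#' @export
assign_unit <- function(x, y, units) {
  fake <- tibble::tibble(x = x, y = y, unit_id = NA_character_)
  assign_units(fake, units)$unit_id
}

#' Grouping attributes of areal units
#'
#' @param units Areal units.
#' @return Tibble of `unit_id` plus every grouping attribute column.
#' @export
unit_attributes <- function(units) {
  units[, setdiff(names(units), "ring")]
}
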