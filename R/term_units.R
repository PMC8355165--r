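## Grouping hairpins into cluster/single termination units; selecting the
## identified (nearest the stop codon) and RNA-seq derived (nearest pos^st)
## units; zone assignment and +-n distances.

#' Group hairpins into cluster/single termination units
#'
#' Hairpins are first reduced for subsumption (a hairpin wholly contained in
#' an earlier-starting, larger hairpin is dropped: the first-occurring larger
#' hairpin participates), then chained left to right: consecutive hairpins
#' whose gap (`next.start - prev.end`) is strictly below `gap_max` merge into
#' the same unit; overlapping hairpins (negative gap) merge too. A unit of
#' two or more hairpins is a `cluster`, an isolated hairpin a `single`. Every
#' surviving hairpin belongs to exactly one unit.
#'
#' @param hairpins A `data.frame` with `start` and `end` columns (0-based
#'   half-open, one shared coordinate system), plus any extra columns.
#' @param gap_max Gap threshold in bases (default 15; gaps of exactly 15 do
#'   not cluster). The threshold mirrors the nascent-RNA length sequestered in
#'   the RNA exit channel (~5 nt) plus the DNA-RNA hybrid (9-10 bp).
#' @return A `data.frame` of units: `kind` (`cluster`/`single`), `span_start`,
#'   `span_end`, `n_hairpins`, and a list-column `hairpins` holding the member
#'   rows (sorted 5'->3').
#' @export
group_units <- function(hairpins, gap_max = 15L) {
  empty <- data.frame(kind = character(0), span_start = integer(0),
                      span_end = integer(0), n_hairpins = integer(0))
  empty$hairpins <- list()
  if (is.null(hairpins) || nrow(hairpins) == 0L) return(empty)
  hp <- hairpins[order(hairpins$start, -hairpins$end), , drop = FALSE]
  ## subsumption: drop rows contained in an earlier (or equal-start larger) row
  keep <- rep(TRUE, nrow(hp))
  max_end <- -Inf
  for (i in seq_len(nrow(hp))) {
    if (hp$end[i] <= max_end) keep[i] <- FALSE else max_end <- hp$end[i]
  }
  hp <- hp[keep, , drop = FALSE]
  n <- nrow(hp)
  gaps <- if (n > 1L) hp$start[-1L] - hp$end[-n] else numeric(0)
  unit_id <- cumsum(c(1L, as.integer(gaps >= gap_max)))
  out <- lapply(split(seq_len(n), unit_id), function(ix) {
    m <- hp[ix, , drop = FALSE]
    rownames(m) <- NULL
    data.frame(kind = if (length(ix) >= 2L) "cluster" else "single",
               span_start = min(m$start), span_end = max(m$end),
               n_hairpins = length(ix), hairpins = I(list(m)),
               stringsAsFactors = FALSE)
  })
  units <- do.call(rbind, out)
  units <- units[order(units$span_start), , drop = FALSE]
  rownames(units) <- NULL
  units
}

#' The identified termination unit (nearest the stop codon)
#'
#' @param units A unit `data.frame` from [group_units()] (coordinates relative
#'   to the IR start).
#' @param stop_rel Position of the stop codon's first base in the units'
#'   coordinate system (with IR-relative coordinates this is -3; only units
#'   starting at or after it are eligible). Default -3.
#' @return The row index of the unit with minimal `span_start` downstream of
#'   the stop codon (ties broken toward the larger unit), or `NA_integer_`
#'   when no unit qualifies.
#' @export
identified_unit <- function(units, stop_rel = -3L) {
  if (nrow(units) == 0L) return(NA_integer_)
  elig <- which(units$span_start >= stop_rel)
  if (!length(elig)) return(NA_integer_)
  s <- units$span_start[elig]
  cand <- elig[s == min(s)]
  if (length(cand) > 1L) {
    sz <- units$span_end[cand] - units$span_start[cand]
    cand <- cand[which.max(sz)]
  }
  cand[1L]
}

#' Zone and +-n distance of a termination unit
#'
#' The zone follows the unit's start: before `pos_st` is Zone 1, inside
#' `[pos_st, pos_end)` Zone 2, at or after `pos_end` Zone 3. The distance `n`
#' to the positive-slope start is measured from the last hairpin base for
#' Zone 1 (`pos_st - span_end`) and the first for Zone 2
#' (`span_start - pos_st`); a unit straddling `pos_st` has `n = 0`.
#'
#' @param span_start,span_end Unit span, IR-relative 0-based half-open.
#' @param pos A `pos_st`/`pos_end` list (IR-relative).
#' @param ir_len IR length; units starting at or beyond it are an error.
#' @return A list: `zone` (1/2/3), `n` (bases; `NA` for Zone 3) and
#'   `distance_to_stop` (`span_start`, i.e. bases from the 3' CDS end).
#' @export
unit_distance <- function(span_start, span_end, pos, ir_len = Inf) {
  if (span_start >= ir_len) stopf("unit outside IR")
  if (span_start < pos$pos_st) {
    if (span_end > pos$pos_st) {
      list(zone = 1L, n = 0L, distance_to_stop = span_start)  # straddle
    } else {
      list(zone = 1L, n = as.integer(pos$pos_st - span_end),
           distance_to_stop = span_start)
    }
  } else if (span_start < pos$pos_end) {
    list(zone = 2L, n = as.integer(span_start - pos$pos_st),
         distance_to_stop = span_start)
  } else {
    list(zone = 3L, n = NA_integer_, distance_to_stop = span_start)
  }
}

#' The RNA-seq derived termination unit (nearest pos^st)
#'
#' Restricted to Zone 1 and Zone 2 units; Zone 3 units are excluded. Returns
#' the unit minimising the +-n distance of [unit_distance()]; ties between a
#' Zone 1 and a Zone 2 unit at equal `n` break toward the upstream (Zone 1)
#' unit.
#'
#' @param units A unit `data.frame` from [group_units()], IR-relative.
#' @param pos A `pos_st`/`pos_end` list.
#' @param ir_len IR length in bases.
#' @return The selected row index, or `NA_integer_` when no Zone 1/2 unit
#'   exists.
#' @export
derived_unit <- function(units, pos, ir_len = Inf) {
  if (nrow(units) == 0L || is.null(pos)) return(NA_integer_)
  d <- lapply(seq_len(nrow(units)), function(i) {
    unit_distance(units$span_start[i], units$span_end[i], pos, ir_len)
  })
  zone <- vapply(d, `[[`, integer(1), "zone")
  n <- vapply(d, function(x) as.integer(x$n %||% NA_integer_), integer(1))
  elig <- which(zone %in% c(1L, 2L))
  if (!length(elig)) return(NA_integer_)
  best_n <- min(n[elig])
  cand <- elig[n[elig] == best_n]
  if (length(cand) > 1L) {
    z1 <- cand[zone[cand] == 1L]
    cand <- if (length(z1)) z1 else cand
  }
  cand[1L]
}
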