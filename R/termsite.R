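## Cumulative-depth slopes and positive-slope-region (termination) detection.

#' Slope-calculation settings
#'
#' @param w Window size in bases for the first difference of the cumulative
#'   curve (default 10; the supported range in practice is 5..30).
#' @param zero_tolerance Numeric tolerance for classifying a slope difference
#'   as positive/negative/zero. `NULL` (default) resolves at run time: 0 when
#'   the depth values are integral, otherwise `1e-9 * max(sl1)` for
#'   replicate-averaged real depth.
#' @return A list of class `slope_config`.
#' @export
slope_config <- function(w = 10L, zero_tolerance = NULL) {
  stopifnot(w >= 1L)
  structure(list(w = as.integer(w), zero_tolerance = zero_tolerance),
            class = "slope_config")
}

#' Cumulative read-depth curve over a region
#'
#' @param track A [depth_track()].
#' @param region `c(start, end)` 0-based half-open genomic; for `-` strand
#'   tracks the depth is accumulated in transcript orientation (genomically
#'   right to left).
#' @return Numeric nondecreasing series `F`, `F[i] = sum(depth[1..i])` over
#'   the oriented region.
#' @export
cumulative_curve <- function(track, region) {
  s <- as.integer(region[1L]); e <- as.integer(region[2L])
  if (e <= s) stopf("empty region")
  if (s < 0L || e > length(track$depth)) stopf("region outside genome")
  d <- track$depth[(s + 1L):e]
  if (track$strand == "-") d <- rev(d)
  cumsum(d)
}

#' Windowed first difference of a cumulative curve (sl1)
#'
#' `sl1[i] = (F[i + w] - F[i]) / w`; nonnegative whenever `F` is
#' nondecreasing. Positions are 0-based: the value at index `i` (1-based R
#' index) describes series position `i - 1`.
#'
#' @param F Numeric series (cumulative depth).
#' @param cfg A [slope_config()] or a window size.
#' @return Numeric vector of length `length(F) - w` (empty, with a warning,
#'   when `F` is too short).
#' @export
slope_sl1 <- function(F, cfg = slope_config()) {
  w <- if (inherits(cfg, "slope_config")) cfg$w else as.integer(cfg)
  n <- length(F)
  if (n <= w) {
    warnf("series length %d <= window %d; empty sl1", n, w)
    return(numeric(0))
  }
  (F[(1L + w):n] - F[1L:(n - w)]) / w
}

#' Successive differences of sl1 (sl2)
#'
#' The discrete second difference of the cumulative curve at lag `w`:
#' `sl2[i] = sl1[i + 1] - sl1[i]`.
#'
#' @param sl1 Numeric vector from [slope_sl1()].
#' @return Numeric vector of length `length(sl1) - 1` (empty, with a warning,
#'   when `sl1` has fewer than 2 values).
#' @export
slope_sl2 <- function(sl1) {
  if (length(sl1) < 2L) {
    warnf("sl1 has fewer than 2 values; empty sl2")
    return(numeric(0))
  }
  diff(sl1)
}

## resolve the zero tolerance: 0 for integral depth, scaled otherwise
resolve_eps <- function(cfg, depth, sl1) {
  if (!is.null(cfg$zero_tolerance)) return(cfg$zero_tolerance)
  if (max(abs(depth - round(depth))) < 1e-12) 0 else 1e-9 * max(sl1, 1)
}

#' Find the first positive-slope region of an IR
#'
#' Scans `sl2` left to right from the IR start: locates the first index with
#' `sl2 < -eps` (the post-stop-codon drop), then the first later index with
#' `sl2 > +eps`; that position is `pos_st`. The region extends while
#' `sl2 >= -eps` and ends (`pos_end`) at the next index with `sl2 < -eps`, or
#' at the IR end if none. Each sl2 value is attributed to the base entering
#' its sliding window (`sl2[j]` compares the depth `w` bases apart, so it
#' describes span position `j + w`); a drop exactly at the CDS/IR boundary is
#' therefore part of the scanned support. When depth is already zero at the
#' IR start the drop happened further upstream, outside the support; a
#' leading zero run of sl2 then counts as the post-drop saddle (set
#' `zero_at_ir_start`). Absence of any positive-slope region is a valid
#' outcome (`NULL`).
#'
#' @param sl2 Numeric vector over the unit span (CDS + IR).
#' @param ir_offset 0-based span position of the IR start.
#' @param ir_len IR length in bases.
#' @param w The sl1 window size the series was computed with.
#' @param eps Sign-classification tolerance (see [slope_config()]).
#' @param zero_at_ir_start Logical; depth at the first IR base is zero.
#' @return `NULL`, or a list with `pos_st`, `pos_end` (0-based half-open,
#'   relative to the IR start).
#' @name find_pos_region
NULL

## Core scanner. j0 is the first scanned 1-based sl2 index; sl2 index j is
## attributed to 0-based span position j + w (the base entering the window).
## Returns IR-relative pos_st/pos_end plus end_idx, the 1-based sl2 index of
## the drop that closed the region (NA when the region runs to the IR end).
scan_pos_region <- function(sl2, j0, ir_offset, ir_len, eps,
                            allow_leading_zero, w) {
  n <- length(sl2)
  if (j0 > n) return(NULL)
  idx <- j0:n
  sig <- idx[abs(sl2[idx]) > eps]
  p <- NA_integer_
  if (allow_leading_zero) {
    if (!length(sig)) return(NULL)
    if (sl2[sig[1L]] > eps) {
      ## drop happened at the CDS boundary; the leading zero run is the saddle
      p <- sig[1L]
    } else {
      d <- sig[1L]
      after <- idx[idx > d & sl2[idx] > eps]
      if (length(after)) p <- after[1L]
    }
  } else {
    neg <- idx[sl2[idx] < -eps]
    if (!length(neg)) return(NULL)
    d <- neg[1L]
    after <- idx[idx > d & sl2[idx] > eps]
    if (length(after)) p <- after[1L]
  }
  if (is.na(p)) return(NULL)
  pos_st <- p + w - ir_offset
  if (pos_st >= ir_len) return(NULL)
  ends <- which(sl2 < -eps)
  ends <- ends[ends > p]
  end_idx <- if (length(ends)) ends[1L] else NA_integer_
  pos_end <- if (is.na(end_idx)) ir_len else min(end_idx + w - ir_offset, ir_len)
  if (pos_end <= pos_st) return(NULL)
  list(pos_st = as.integer(pos_st), pos_end = as.integer(pos_end),
       end_idx = end_idx)
}

scan_start <- function(ir_offset, w) max(1L, as.integer(ir_offset) - as.integer(w))

#' @rdname find_pos_region
#' @export
find_pos_region <- function(sl2, ir_offset, ir_len, w = 10L, eps = 0,
                            zero_at_ir_start = FALSE) {
  r <- scan_pos_region(sl2, scan_start(ir_offset, w), ir_offset, ir_len, eps,
                       zero_at_ir_start, w)
  if (is.null(r)) return(NULL)
  list(pos_st = r$pos_st, pos_end = r$pos_end)
}

#' All successive positive-slope regions of an IR
#'
#' Repeats the detection of [find_pos_region()] after each region end; the
#' first element always equals the [find_pos_region()] result.
#'
#' @inheritParams find_pos_region
#' @return A list (possibly empty) of `pos_st`/`pos_end` lists, ordered by
#'   position.
#' @export
alternate_pos_regions <- function(sl2, ir_offset, ir_len, w = 10L, eps = 0,
                                  zero_at_ir_start = FALSE) {
  out <- list()
  j0 <- scan_start(ir_offset, w)
  allow0 <- zero_at_ir_start
  repeat {
    r <- scan_pos_region(sl2, j0, ir_offset, ir_len, eps, allow0, w)
    if (is.null(r)) break
    out[[length(out) + 1L]] <- list(pos_st = r$pos_st, pos_end = r$pos_end)
    if (is.na(r$end_idx)) break
    ## the drop that closed this region doubles as the next saddle's precursor
    j0 <- r$end_idx
    allow0 <- FALSE
  }
  out
}

#' Partition an IR into zones around the positive-slope region
#'
#' Zone 1: IR start to `pos_st` (transcript tail); Zone 2: the positive-slope
#' region itself (buffer); Zone 3: `pos_end` to the IR end. Lengths always sum
#' to the IR length.
#'
#' @param ir_len IR length in bases.
#' @param pos `NULL` or a `pos_st`/`pos_end` list (IR-relative, from
#'   [find_pos_region()]).
#' @return `NULL` when `pos` is `NULL`; otherwise a list of half-open
#'   IR-relative intervals `zone1`, `zone2`, `zone3`.
#' @export
segment_zones <- function(ir_len, pos) {
  if (is.null(pos)) return(NULL)
  if (pos$pos_st < 0L || pos$pos_end > ir_len || pos$pos_st >= pos$pos_end) {
    stopf("positive-slope region outside IR")
  }
  list(zone1 = c(0L, pos$pos_st),
       zone2 = c(pos$pos_st, pos$pos_end),
       zone3 = c(pos$pos_end, as.integer(ir_len)))
}

#' Detect the termination region of one IR from a depth track
#'
#' Convenience wrapper: builds the cumulative curve over the unit span
#' (CDS + IR, transcript orientation), computes sl1/sl2, resolves the sign
#' tolerance, and runs [find_pos_region()] and [segment_zones()].
#'
#' @param unit One row of an `itt_units` data.frame.
#' @param ir The matching row of an `itt_irs` data.frame.
#' @param track The [depth_track()] for the unit's strand.
#' @param cfg A [slope_config()].
#' @return A list: `pos` (or `NULL`), `zones` (or `NULL`), `eps`, `sl2`,
#'   `ir_offset`, and `alternates` (all successive positive-slope regions).
#' @export
detect_termination <- function(unit, ir, track, cfg = slope_config()) {
  if (unit$strand == "+") {
    region <- c(unit$cds_start, ir$ir_end)
  } else {
    region <- c(ir$ir_start, unit$cds_end)
  }
  s <- as.integer(region[1L]); e <- as.integer(region[2L])
  d <- track$depth[(s + 1L):e]
  if (track$strand == "-") d <- rev(d)
  F <- cumsum(d)
  sl1 <- slope_sl1(F, cfg)
  sl2 <- slope_sl2(sl1)
  ir_len <- ir$ir_end - ir$ir_start
  ir_offset <- length(d) - ir_len
  eps <- resolve_eps(cfg, d, sl1)
  zero0 <- length(d) >= ir_offset + 1L && d[ir_offset + 1L] <= eps
  pos <- if (length(sl2)) {
    find_pos_region(sl2, ir_offset, ir_len, cfg$w, eps, zero0)
  } else NULL
  alts <- if (length(sl2)) {
    alternate_pos_regions(sl2, ir_offset, ir_len, cfg$w, eps, zero0)
  } else list()
  list(pos = pos, zones = segment_zones(ir_len, pos), eps = eps,
       sl2 = sl2, ir_offset = ir_offset, alternates = alts)
}
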