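## Mismatch-tolerant poly-U/A (and poly-G/C) trail search downstream of
## hairpin ends.

#' Find the nearest poly-U/A (or poly-G/C) pattern in a downstream sequence
#'
#' Works on the transcript-orientation sequence with T read as U. A pattern
#' is a run of at least `min_len` bases of the class (`AU` = \{A, U\},
#' `GC` = \{G, C\}) that may contain up to `max_mismatch` out-of-class bases
#' in its interior; it always begins and ends in-class (leading/trailing
#' out-of-class bases are trimmed). Search is seed-and-extend from each
#' in-class base left to right, greedily consuming mismatches, and the
#' leftmost (nearest) qualifying pattern is reported.
#'
#' @param seq_downstream Character scalar, transcript orientation, position 0
#'   at the search origin (typically the hairpin 3' end).
#' @param base_class `"AU"` or `"GC"`.
#' @param min_len Minimum pattern length (default 3).
#' @param max_mismatch Maximum interior out-of-class bases (default 0).
#' @param max_search Only patterns starting strictly before this offset are
#'   reported (default: the whole sequence).
#' @return `NULL`, or a list: `start` (0-based offset), `length`,
#'   `mismatches`, `base_class`.
#' @export
find_poly <- function(seq_downstream, base_class = c("AU", "GC"),
                      min_len = 3L, max_mismatch = 0L, max_search = NULL) {
  base_class <- match.arg(base_class)
  v <- strsplit(toupper(seq_downstream), "", fixed = TRUE)[[1L]]
  v[v == "T"] <- "U"
  L <- length(v)
  if (L == 0L) return(NULL)
  inc <- v %in% (if (base_class == "AU") c("A", "U") else c("G", "C"))
  lim <- if (is.null(max_search)) L else min(L, as.integer(max_search))
  starts <- which(inc)
  starts <- starts[starts <= lim]
  for (s in starts) {
    t <- s; mism <- 0L
    while (t < L) {
      if (inc[t + 1L]) {
        t <- t + 1L
      } else if (mism < max_mismatch) {
        mism <- mism + 1L; t <- t + 1L
      } else break
    }
    while (t > s && !inc[t]) { t <- t - 1L; mism <- mism - 1L }
    len <- t - s + 1L
    if (len >= min_len) {
      return(list(start = s - 1L, length = as.integer(len),
                  mismatches = as.integer(mism), base_class = base_class))
    }
  }
  NULL
}

#' Distance from a hairpin 3' end to a downstream pattern
#'
#' @param hairpin_end 0-based half-open end of the hairpin (the coordinate at
#'   which the downstream search began).
#' @param pattern A pattern from [find_poly()], whose `start` is an offset
#'   from `hairpin_end`.
#' @return Distance in bases (>= 0; the search domain starts at the hairpin
#'   end, so a negative distance is an error).
#' @export
pattern_distance <- function(hairpin_end, pattern) {
  d <- pattern$start
  if (d < 0) stopf("pattern upstream of hairpin end")
  as.integer(d)
}
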