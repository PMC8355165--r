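## Stem-loop (inverted repeat) enumeration, additive free-energy scoring,
## and the 2-D stem/loop histogram rejection.

#' Default base-pair stack table (kcal/mol)
#'
#' Nearest-neighbor style stacking free energies at 37 C for every ordered
#' step of two pairs over \{AU, UA, GC, CG, GU, UG\}. Keys are
#' `"P1/P2"` where each pair is written 5'-arm base then its partner, e.g.
#' `"GC/AU"` is a G:C pair stacked on an A:U pair. Values for Watson-Crick
#' steps follow the standard RNA nearest-neighbor parameter set; wobble steps
#' use the corresponding published G:U values.
#'
#' @return Named numeric vector of 36 stack energies.
#' @export
default_stack_table <- function() {
  c(
    "AU/AU" = -0.93, "AU/CG" = -2.24, "AU/GC" = -2.08, "AU/UA" = -1.10,
    "AU/GU" = -0.55, "AU/UG" = -1.36,
    "CG/AU" = -2.11, "CG/CG" = -3.26, "CG/GC" = -2.36, "CG/UA" = -2.08,
    "CG/GU" = -1.41, "CG/UG" = -2.11,
    "GC/AU" = -2.35, "GC/CG" = -3.42, "GC/GC" = -3.26, "GC/UA" = -2.24,
    "GC/GU" = -1.53, "GC/UG" = -2.51,
    "UA/AU" = -1.33, "UA/CG" = -2.35, "UA/GC" = -2.11, "UA/UA" = -0.93,
    "UA/GU" = -1.00, "UA/UG" = -1.27,
    "GU/AU" = -1.27, "GU/CG" = -2.51, "GU/GC" = -2.11, "GU/UA" = -1.36,
    "GU/GU" = -0.50, "GU/UG" = +1.29,
    "UG/AU" = -1.00, "UG/CG" = -1.53, "UG/GC" = -1.41, "UG/UA" = -0.55,
    "UG/GU" = +0.30, "UG/UG" = -0.50
  )
}

#' Default hairpin-loop initiation penalties (kcal/mol)
#'
#' Penalties for loop lengths 3..9; longer loops are extrapolated
#' logarithmically as `dG(n) = dG(9) + 1.0785 * ln(n / 9)`
#' (1.75 * R * T at 310.15 K).
#'
#' @return Named numeric vector indexed by loop length.
#' @export
default_loop_penalty <- function() {
  c("3" = 5.4, "4" = 5.6, "5" = 5.7, "6" = 5.4, "7" = 6.0, "8" = 5.5,
    "9" = 6.4)
}

#' Hairpin scan settings
#'
#' @param stem_min,stem_max Stem length bounds in base pairs (defaults 3 and
#'   20). The short-stem mode observed in matched terminators is 3 bp.
#' @param loop_min,loop_max Loop length bounds in bases (defaults 3 and 15).
#' @param allow_gu_wobble Allow G:U (G:T on DNA input) pairs (default TRUE).
#' @param delta_g_max Retain hairpins with score at or below this, kcal/mol
#'   (default +5: weakly positive-scoring short hairpins are kept).
#' @param stack_table,loop_penalty_table Scoring tables; see
#'   [default_stack_table()] and [default_loop_penalty()].
#' @return A list of class `hairpin_scan_config`.
#' @export
hairpin_scan_config <- function(stem_min = 3L, stem_max = 20L,
                                loop_min = 3L, loop_max = 15L,
                                allow_gu_wobble = TRUE, delta_g_max = 5,
                                stack_table = default_stack_table(),
                                loop_penalty_table = default_loop_penalty()) {
  stopifnot(stem_min <= stem_max, loop_min <= loop_max, is.finite(delta_g_max))
  structure(list(stem_min = as.integer(stem_min), stem_max = as.integer(stem_max),
                 loop_min = as.integer(loop_min), loop_max = as.integer(loop_max),
                 allow_gu_wobble = isTRUE(allow_gu_wobble),
                 delta_g_max = delta_g_max,
                 stack_table = stack_table,
                 loop_penalty_table = loop_penalty_table),
            class = "hairpin_scan_config")
}

## encode A,C,G,T/U,N -> 1..5; anything else 5 (never pairs)
encode_seq <- function(seq) {
  v <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  v[v == "U"] <- "T"
  code <- match(v, c("A", "C", "G", "T"))
  code[is.na(code)] <- 5L
  code
}

## 5x5 pair-validity matrix (A,C,G,T,N); T stands for T or U
pair_matrix <- function(allow_gu) {
  m <- matrix(FALSE, 5L, 5L)
  m[1L, 4L] <- m[4L, 1L] <- TRUE   # A:T
  m[2L, 3L] <- m[3L, 2L] <- TRUE   # C:G
  if (allow_gu) m[3L, 4L] <- m[4L, 3L] <- TRUE  # G:T wobble
  m
}

#' Enumerate candidate stem-loop hairpins in a scan window
#'
#' Finds every maximal perfect-complement inverted repeat with stem length in
#' `[stem_min, stem_max]` and loop length in `[loop_min, loop_max]`. For a
#' fixed apex (loop placement) the stem grows outward from the loop-closing
#' pair as far as pairing allows (up to `stem_max`); only that maximal stem is
#' reported, so a candidate subsumed by a larger one with the same apex never
#' appears. `N` never pairs. Each hairpin is scored with [score_hairpin()]
#' and retained iff its score is at most `delta_g_max`.
#'
#' @param window_seq Character scalar over A/C/G/T/U/N, transcript
#'   orientation (from [extract_scan_window()]).
#' @param cfg A [hairpin_scan_config()].
#' @return A `data.frame`: `start`, `end` (0-based half-open, window-relative,
#'   covering the full 5'-arm..3'-arm extent), `stem_len`, `loop_len`,
#'   `delta_g`; sorted by `start` then `end`.
#' @export
enumerate_hairpins <- function(window_seq, cfg = hairpin_scan_config()) {
  code <- encode_seq(window_seq)
  L <- length(code)
  empty <- data.frame(start = integer(0), end = integer(0),
                      stem_len = integer(0), loop_len = integer(0),
                      delta_g = numeric(0))
  if (L < 2L * cfg$stem_min + cfg$loop_min) return(empty)
  pm <- pair_matrix(cfg$allow_gu_wobble)
  res_start <- integer(0); res_stem <- integer(0); res_loop <- integer(0)
  for (l in cfg$loop_min:cfg$loop_max) {
    ## loop occupies 0-based [q, q + l); stem pair k (1-based) joins
    ## positions q - k and q + l - 1 + k
    qmax <- L - l - 1L
    if (qmax < 1L) next
    q <- seq_len(qmax)                      # 0-based loop starts 1..qmax
    kmax <- pmin(q, L - l - q, cfg$stem_max)
    valid_run <- integer(length(q))
    alive <- rep(TRUE, length(q))
    for (k in seq_len(min(max(kmax), cfg$stem_max))) {
      can <- alive & kmax >= k
      if (!any(can)) break
      i <- q[can] - k + 1L                  # 1-based index of 5' base
      j <- q[can] + l + k                   # 1-based index of 3' base
      ok <- pm[cbind(code[i], code[j])]
      valid_run[can][ok] <- k
      alive[can][!ok] <- FALSE
      alive[!can] <- FALSE
    }
    hit <- valid_run >= cfg$stem_min
    if (any(hit)) {
      res_start <- c(res_start, q[hit] - valid_run[hit])
      res_stem <- c(res_stem, valid_run[hit])
      res_loop <- c(res_loop, rep(l, sum(hit)))
    }
  }
  if (!length(res_start)) return(empty)
  hp <- data.frame(start = as.integer(res_start),
                   end = as.integer(res_start + 2L * res_stem + res_loop),
                   stem_len = as.integer(res_stem),
                   loop_len = as.integer(res_loop))
  hp$delta_g <- vapply(seq_len(nrow(hp)), function(i) {
    score_hairpin(hp$start[i], hp$stem_len[i], hp$loop_len[i], window_seq, cfg)
  }, numeric(1))
  hp <- hp[hp$delta_g <= cfg$delta_g_max, , drop = FALSE]
  hp <- hp[order(hp$start, hp$end), , drop = FALSE]
  rownames(hp) <- NULL
  hp
}

#' Score a hairpin with the additive stack + loop-penalty model
#'
#' The score is the sum over adjacent stem pair steps of the stack table plus
#' the loop penalty for the loop length (lengths beyond the table are
#' extrapolated logarithmically). Deterministic; lower is more stable.
#'
#' @param start 0-based window-relative start of the hairpin's 5' arm.
#' @param stem_len Stem length in base pairs.
#' @param loop_len Loop length in bases.
#' @param window_seq The window sequence the hairpin lives in.
#' @param cfg A [hairpin_scan_config()].
#' @return Score in kcal/mol.
#' @export
score_hairpin <- function(start, stem_len, loop_len, window_seq,
                          cfg = hairpin_scan_config()) {
  v <- strsplit(toupper(window_seq), "", fixed = TRUE)[[1L]]
  v[v == "T"] <- "U"
  end <- start + 2L * stem_len + loop_len          # half-open
  if (start < 0L || end > length(v)) stopf("hairpin outside window")
  top <- v[(start + 1L):(start + stem_len)]
  bot <- v[end:(end - stem_len + 1L)]              # partner of top[k]
  pairs <- paste0(top, bot)
  dg <- 0
  if (stem_len >= 2L) {
    steps <- paste0(pairs[-stem_len], "/", pairs[-1L])
    vals <- cfg$stack_table[steps]
    if (anyNA(vals)) {
      stopf("missing stack-table entry: %s",
            paste(unique(steps[is.na(vals)]), collapse = ", "))
    }
    dg <- sum(vals)
  }
  dg + loop_penalty(loop_len, cfg$loop_penalty_table)
}

loop_penalty <- function(loop_len, table = default_loop_penalty()) {
  key <- as.character(loop_len)
  if (key %in% names(table)) return(unname(table[key]))
  lens <- as.integer(names(table))
  lmax <- max(lens)
  if (loop_len < min(lens)) stopf("loop length %d below penalty table", loop_len)
  unname(table[as.character(lmax)]) + 1.0785 * log(loop_len / lmax)
}

#' Reject rare stem/loop combinations via the 2-D histogram tail
#'
#' Counts hairpins per (stem length, loop length) cell across the whole
#' genome, sorts cells ascending by count (ties broken by lexicographic
#' (stem, loop)), and removes cells greedily while the cumulative removed
#' hairpin count stays at or below `tail_fraction` of the total. Never removes
#' more than that fraction of hairpins.
#'
#' @param hairpins A `data.frame` with `stem_len` and `loop_len` columns
#'   (typically all hairpins pooled across IRs).
#' @param tail_fraction Fraction of total hairpins the removed cells may hold
#'   (default 0.05).
#' @return A list: `kept` (surviving rows), `removed_cells` (`data.frame` of
#'   rejected `stem_len`/`loop_len`/`count`).
#' @export
histogram_filter <- function(hairpins, tail_fraction = 0.05) {
  if (nrow(hairpins) == 0L) {
    return(list(kept = hairpins,
                removed_cells = data.frame(stem_len = integer(0),
                                           loop_len = integer(0),
                                           count = integer(0))))
  }
  tab <- as.data.frame(table(stem_len = hairpins$stem_len,
                             loop_len = hairpins$loop_len),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, , drop = FALSE]
  tab$stem_len <- as.integer(tab$stem_len)
  tab$loop_len <- as.integer(tab$loop_len)
  tab <- tab[order(tab$Freq, tab$stem_len, tab$loop_len), , drop = FALSE]
  budget <- tail_fraction * nrow(hairpins)
  rm_idx <- which(cumsum(tab$Freq) <= budget)
  removed <- tab[rm_idx, , drop = FALSE]
  names(removed)[names(removed) == "Freq"] <- "count"
  rownames(removed) <- NULL
  if (nrow(removed)) {
    key <- paste(hairpins$stem_len, hairpins$loop_len)
    drop <- key %in% paste(removed$stem_len, removed$loop_len)
    kept <- hairpins[!drop, , drop = FALSE]
  } else {
    kept <- hairpins
  }
  rownames(kept) <- NULL
  list(kept = kept, removed_cells = removed)
}
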