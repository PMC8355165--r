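## Independent reference implementations used as oracles. Structured
## deliberately differently from the package code paths they check.

## Brute-force inverted-repeat enumerator: all (start, stem, loop) triples,
## vectorised per (stem, loop) combination, with explicit outward-maximality.
oracle_hairpins <- function(seq, stem_min = 3L, stem_max = 20L,
                            loop_min = 3L, loop_max = 15L, gu = TRUE) {
  v <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  v[v == "U"] <- "T"
  code <- match(v, c("A", "C", "G", "T"))
  code[is.na(code)] <- 5L
  L <- length(code)
  ok_pair <- matrix(FALSE, 5L, 5L)
  ok_pair[1L, 4L] <- ok_pair[4L, 1L] <- TRUE
  ok_pair[2L, 3L] <- ok_pair[3L, 2L] <- TRUE
  if (gu) ok_pair[3L, 4L] <- ok_pair[4L, 3L] <- TRUE
  rows <- list()
  for (s in stem_min:stem_max) {
    for (l in loop_min:loop_max) {
      span <- 2L * s + l
      if (span > L) next
      starts <- 0:(L - span)                      # 0-based
      all_ok <- rep(TRUE, length(starts))
      for (k in 0:(s - 1L)) {
        a <- code[starts + k + 1L]
        b <- code[starts + span - k]
        all_ok <- all_ok & ok_pair[cbind(a, b)]
      }
      ## maximal: cannot add an outward pair within stem_max
      ext <- rep(FALSE, length(starts))
      if (s < stem_max) {
        can <- starts > 0L & (starts + span) < L
        a <- rep(5L, length(starts)); b <- rep(5L, length(starts))
        a[can] <- code[starts[can]]              # 0-based starts - 1
        b[can] <- code[starts[can] + span + 1L]  # 0-based starts + span
        ext <- can & ok_pair[cbind(a, b)]
      }
      hit <- all_ok & !ext
      if (any(hit)) {
        rows[[length(rows) + 1L]] <- data.frame(
          start = starts[hit], end = starts[hit] + span,
          stem_len = s, loop_len = l)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0),
                      stem_len = integer(0), loop_len = integer(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$end, out$stem_len), , drop = FALSE]
}

## Transitive closure of the symmetric "gap < gap_max" relation on intervals
## (after the same containment pre-reduction the grouping applies), computed
## by label propagation on an explicit adjacency matrix.
oracle_unit_groups <- function(starts, ends, gap_max = 15L) {
  o <- order(starts, -ends)
  starts <- starts[o]; ends <- ends[o]
  n <- length(starts)
  contained <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j &&
          (starts[j] < starts[i] || (starts[j] == starts[i] && ends[j] > ends[i])) &&
          starts[j] <= starts[i] && ends[i] <= ends[j]) {
        contained[i] <- TRUE
      }
    }
  }
  starts <- starts[!contained]; ends <- ends[!contained]
  n <- length(starts)
  if (n == 0L) return(list())
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      gap <- max(starts[i], starts[j]) - min(ends[i], ends[j])
      if (i != j && gap < gap_max) adj[i, j] <- TRUE
    }
  }
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(adj[i, ])
      if (length(nb) && min(lab[c(i, nb)]) < lab[i]) {
        lab[i] <- min(lab[c(i, nb)]); changed <- TRUE
      }
      if (length(nb)) {
        m <- min(lab[c(i, nb)])
        if (any(lab[nb] > m)) { lab[nb] <- m; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  unname(lapply(split(seq_len(n), lab), function(ix) {
    list(span_start = min(starts[ix]), span_end = max(ends[ix]),
         size = length(ix))
  }))
}

## Direct second difference of F at lag w, elementwise loop.
oracle_second_diff <- function(F, w) {
  n <- length(F)
  m <- n - w - 1L
  if (m < 1L) return(numeric(0))
  out <- numeric(m)
  for (i in seq_len(m)) {
    out[i] <- (F[i + 1L + w] - F[i + 1L] - F[i + w] + F[i]) / w
  }
  out
}

## Exhaustive window scan for the poly-pattern search: every window with
## in-class endpoints and at most k interior out-of-class bases; leftmost
## start, then longest.
oracle_find_poly <- function(seq, base_class = "AU", min_len = 3L, k = 0L,
                             max_search = NULL) {
  v <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  v[v == "T"] <- "U"
  L <- length(v)
  inc <- v %in% (if (base_class == "AU") c("A", "U") else c("G", "C"))
  lim <- if (is.null(max_search)) L else min(L, max_search)
  for (s in seq_len(lim)) {
    if (!inc[s]) next
    best <- NULL
    for (e in s:L) {
      if (!inc[e]) next
      mm <- sum(!inc[s:e])
      if (mm <= k && (e - s + 1L) >= min_len) {
        best <- list(start = s - 1L, length = e - s + 1L, mismatches = mm)
      }
    }
    if (!is.null(best)) return(best)
  }
  NULL
}

## Per-base depth by naive counting over kept records (1-based pos/width).
oracle_depth <- function(pos, width, glen) {
  d <- numeric(glen)
  for (i in seq_along(pos)) {
    for (p in pos[i]:(pos[i] + width[i] - 1L)) {
      if (p >= 1L && p <= glen) d[p] <- d[p] + 1
    }
  }
  d
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

## canonical key for comparing hairpin tables
hp_key <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  sort(paste(df$start, df$end, df$stem_len, df$loop_len, sep = ":"))
}
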