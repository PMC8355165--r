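test_that("alignment filter applies flag, MAPQ and TLEN rules in order", {
  recs <- data.frame(
    flag  = c(99L, 99L, 0L, 147L, 83L, 99L),
    mapq  = c(40L, 20L, 40L, 40L, 30L, NA),
    tlen  = c(250L, 250L, 250L, -80L, -150L, 200L),
    width = c(100L, 100L, 100L, 100L, 100L, 100L),
    pos = 1L, rname = "chr")
  out <- filter_alignments(recs)
  ## kept: proper flag, mapq >= 30, |TLEN| >= read length
  expect_equal(nrow(out$kept), 2L)          # rows 1 and 5
  expect_equal(out$kept$flag, c(99L, 83L))
  expect_equal(unname(out$tally),
               c(2L, 1L, 1L, 1L, 1L))       # kept/flag/mapq/tlen/unreadable
})

test_that("depth from SAM records matches per-base counting", {
  sam <- write_sam(c(
    sam_line("r1", 99L, 11L, 60L, 100L, 250L, 161L),
    sam_line("r1", 147L, 161L, 60L, 100L, -250L, 11L),
    sam_line("r2", 83L, 51L, 60L, 50L, -200L, 201L),
    sam_line("r3", 99L, 301L, 10L, 50L, 200L, 401L)   # fails MAPQ
  ))
  recs <- read_alignments(sam)
  expect_equal(nrow(recs), 4L)
  kept <- filter_alignments(recs)$kept
  expect_equal(nrow(kept), 3L)

  gen <- Biostrings::DNAStringSet(structure(paste(rep("A", 500), collapse = ""),
                                            names = "chr"))
  tp <- build_depth(kept, "+", gen, "chr")
  tm <- build_depth(kept, "-", gen, "chr")
  ## '+' fragment: r1 both mates; '-' fragment: r2
  expect_equal(tp$depth, oracle_depth(c(11L, 161L), c(100L, 100L), 500L))
  expect_equal(tm$depth, oracle_depth(51L, 50L, 500L))
  ## single read covering [10, 110): depth 1 there, 0 elsewhere
  one <- build_depth(kept[1, ], "+", gen, "chr")
  expect_equal(sum(one$depth), 100)
  expect_equal(unname(one$depth[11:110]), rep(1, 100))
  ## empty input -> all-zero track
  empty <- build_depth(kept[0, ], "+", gen, "chr")
  expect_equal(empty$depth, numeric(500))
})

test_that("depth equals brute-force counting on random read sets", {
  set.seed(42)
  gen <- Biostrings::DNAStringSet(structure(random_dna(400), names = "chr"))
  for (rep in 1:5) {
    n <- sample(20:100, 1)
    pos <- sample(1:300, n, replace = TRUE)
    w <- sample(20:80, n, replace = TRUE)
    recs <- data.frame(flag = 99L, mapq = 60L, tlen = 300L,
                       pos = pos, width = w, rname = "chr")
    tr <- build_depth(recs, "+", gen, "chr")
    expect_equal(tr$depth, oracle_depth(pos, w, 400L))
  }
})

test_that("replicate averaging is elementwise and idempotent on copies", {
  a <- flat_track("+", c(2, 2, 0, 4))
  b <- flat_track("+", c(4, 0, 0, 4))
  avg <- average_tracks(list(a, b))
  expect_equal(avg$depth, c(3, 1, 0, 4))
  expect_equal(avg$n_replicates, 2L)
  same <- average_tracks(list(a, a, a))
  expect_equal(same$depth, a$depth)
  expect_error(average_tracks(list(a, flat_track("-", c(1, 1, 1, 1)))),
               "share")
})

test_that("bedGraph input round-trips into a depth track and is bounds-checked", {
  gen <- Biostrings::DNAStringSet(structure(random_dna(100), names = "chr"))
  bg <- tempfile(fileext = ".bedGraph")
  writeLines(c("chr\t0\t10\t5", "chr\t50\t60\t2"), bg)
  tr <- build_depth(bg, "+", gen, "chr")
  expect_equal(unname(tr$depth[1:10]), rep(5, 10))
  expect_equal(unname(tr$depth[51:60]), rep(2, 10))
  expect_equal(sum(tr$depth), 70)
  bad <- tempfile(fileext = ".bedGraph")
  writeLines("chr\t90\t120\t1", bad)
  expect_error(build_depth(bad, "+", gen, "chr"), "outside genome")
})

test_that("coverage fraction counts bases at or above the covered threshold", {
  d <- numeric(100); d[1:95] <- 2
  tr <- flat_track("+", d)
  expect_equal(coverage_fraction(c(0L, 100L), tr), 0.95)
  expect_equal(coverage_fraction(c(95L, 100L), tr), 0)
  ## replicate-averaged 0.5 never reaches the default threshold of 1
  half <- flat_track("+", rep(0.5, 100))
  expect_equal(coverage_fraction(c(0L, 100L), half), 0)
  expect_equal(coverage_fraction(c(0L, 100L), half, covered_min = 0.5), 1)
  expect_error(coverage_fraction(c(10L, 10L), tr), "zero-length")
})

test_that("IR screening: Stage 2 removes the strict upper mean-depth tail", {
  ## 100 IRs of 10 bases each, coverage 1.0, mean depths 1..100
  n <- 100L
  depth <- rep(1:n, each = 10L)
  tr <- flat_track("+", depth)
  irs <- data.frame(unit_id = sprintf("ir%03d", 1:n), seqid = "chr",
                    strand = "+", ir_start = seq(0L, by = 10L, length.out = n),
                    ir_end = seq(10L, by = 10L, length.out = n),
                    length = 10L, terminal = FALSE, seq_tx = "",
                    stringsAsFactors = FALSE)
  out <- screen_irs(irs, list("+" = tr, "-" = tr),
                    screen_config(apply_to = "IR"))
  removed2 <- irs$unit_id[which(out$audit$removed_stage == 2L)]
  expect_equal(removed2, sprintf("ir%03d", 96:100))
  expect_equal(nrow(out$kept), 95L)

  ## coverage below 90% is removed at Stage 1
  d2 <- depth; d2[1:2] <- 0                    # ir001 coverage 0.8
  out2 <- screen_irs(irs, list("+" = flat_track("+", d2), "-" = tr),
                     screen_config(apply_to = "IR"))
  expect_equal(out2$audit$removed_stage[1], 1L)

  ## degenerate: identical means -> nothing strictly above the quantile
  out3 <- screen_irs(irs, list("+" = flat_track("+", rep(5, 1000)), "-" = tr),
                     screen_config(apply_to = "IR"))
  expect_equal(sum(out3$audit$removed_stage == 2L, na.rm = TRUE), 0L)

  ## too few IRs: Stage 2 skipped with a warning
  expect_warning(
    screen_irs(irs[1:5, ], list("+" = tr, "-" = tr),
               screen_config(apply_to = "IR")),
    "skipped")
})

test_that("screening removals are disjoint and exhaustive across stages", {
  set.seed(9)
  n <- 60L
  depth <- rep(sample(0:50, n, replace = TRUE), each = 20L)
  tr <- flat_track("+", depth)
  irs <- data.frame(unit_id = sprintf("r%02d", 1:n), seqid = "chr",
                    strand = "+", ir_start = seq(0L, by = 20L, length.out = n),
                    ir_end = seq(20L, by = 20L, length.out = n),
                    length = 20L, terminal = FALSE, seq_tx = "",
                    stringsAsFactors = FALSE)
  out <- screen_irs(irs, list("+" = tr, "-" = tr),
                    screen_config(apply_to = "IR"))
  s1 <- sum(out$audit$removed_stage == 1L, na.rm = TRUE)
  s2 <- sum(out$audit$removed_stage == 2L, na.rm = TRUE)
  expect_equal(s1 + s2 + nrow(out$kept), n)
  expect_gte(n - s1, nrow(out$kept))           # |stage1 kept| >= |final kept|
})
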