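test_that("cumulative curve accumulates in transcript orientation", {
  tr <- flat_track("+", c(1, 1, 1, 0, 5, 0, 2))
  expect_equal(cumulative_curve(tr, c(0L, 3L)), c(1, 2, 3))
  expect_equal(cumulative_curve(tr, c(3L, 7L)), c(0, 5, 5, 7))
  tm <- flat_track("-", c(1, 2, 3, 4))
  expect_equal(cumulative_curve(tm, c(0L, 4L)), c(4, 7, 9, 10))
  zero <- flat_track("+", numeric(5))
  expect_equal(cumulative_curve(zero, c(0L, 5L)), rep(0, 5))
  expect_error(cumulative_curve(tr, c(3L, 3L)), "empty")
})

test_that("sl1 is the windowed first difference of F", {
  expect_equal(slope_sl1(cumsum(rep(1, 30)), slope_config(w = 10)),
               rep(1, 20))
  expect_equal(slope_sl1(rep(7, 30), slope_config(w = 10)), rep(0, 20))
  expect_equal(slope_sl1(c(0, 0, 5, 5, 9), slope_config(w = 2)),
               c(2.5, 2.5, 2.0))
  expect_warning(out <- slope_sl1(1:5, slope_config(w = 10)), "empty")
  expect_length(out, 0)
})

test_that("sl2 equals the independent second difference of F", {
  expect_equal(slope_sl2(c(1, 3, 2)), c(2, -1))
  expect_equal(slope_sl2(rep(4, 10)), rep(0, 9))
  expect_warning(out <- slope_sl2(1), "empty")
  expect_length(out, 0)
  set.seed(11)
  for (rep in 1:10) {
    F <- cumsum(sample(0:5, 50, replace = TRUE))
    w <- sample(c(5L, 10L, 15L), 1)
    expect_equal(slope_sl2(slope_sl1(F, slope_config(w = w))),
                 oracle_second_diff(F, w))
  }
  ## sl1 is nonnegative whenever F is nondecreasing
  F <- cumsum(rpois(100, 2))
  expect_true(all(slope_sl1(F, slope_config(w = 10)) >= 0))
})

## helper: depth profile -> (sl2, ir_offset) as detect_termination builds them
profile_sl2 <- function(depth, ir_offset, w = 10L) {
  sl1 <- slope_sl1(cumsum(depth), slope_config(w = w))
  slope_sl2(sl1)
}

test_that("the first positive-slope region lands at a planted ramp", {
  ## CDS plateau 100, IR: flat zero for 200 bases, then ramp 1,2,3,...
  w <- 10L
  cds <- rep(100, 120)
  ramp_start <- 200L
  ir <- c(rep(0, ramp_start), seq_len(80))
  depth <- c(cds, ir)
  sl2 <- profile_sl2(depth, 120L, w)
  pos <- find_pos_region(sl2, 120L, length(ir), w = w, eps = 0,
                         zero_at_ir_start = TRUE)
  expect_false(is.null(pos))
  expect_lte(abs(pos$pos_st - ramp_start), w)

  ## entirely flat zero IR: no region
  flat <- c(cds, rep(0, 300))
  expect_null(find_pos_region(profile_sl2(flat, 120L, w), 120L, 300L,
                              w = w, eps = 0, zero_at_ir_start = TRUE))
})

test_that("drop at IR start with immediate ramp: pos_st at the sl2 sign change", {
  w <- 10L
  depth <- c(rep(100, 120), c(rep(0, 3), seq_len(100)))
  ir_offset <- 120L
  sl2 <- profile_sl2(depth, ir_offset, w)
  pos <- find_pos_region(sl2, ir_offset, 103L, w = w, eps = 0)
  ## oracle: enumerate sl2 signs directly on the constructed profile; sl2[j]
  ## is attributed to the base entering its window, span position j + w
  sgn <- sign(sl2)
  scan <- max(1L, ir_offset - w):length(sl2)
  d <- scan[sgn[scan] < 0][1]
  p <- scan[scan > d & sgn[scan] > 0][1]
  expect_equal(pos$pos_st, p + w - ir_offset)
})

test_that("leading zero depth at the IR start satisfies the drop precondition", {
  w <- 10L
  ir <- c(rep(0, 150), seq_len(60))
  sl2 <- profile_sl2(ir, 0L, w)
  ## without the boundary rule there is no negative sl2 anywhere: no region
  expect_null(find_pos_region(sl2, 0L, length(ir), w = w, eps = 0))
  pos <- find_pos_region(sl2, 0L, length(ir), w = w, eps = 0,
                         zero_at_ir_start = TRUE)
  expect_false(is.null(pos))
  expect_lte(abs(pos$pos_st - 150L), w)
})

test_that("zones partition the IR exactly", {
  z <- segment_zones(1000L, list(pos_st = 200L, pos_end = 240L))
  expect_equal(diff(z$zone1), 200L)
  expect_equal(diff(z$zone2), 40L)
  expect_equal(diff(z$zone3), 760L)
  ## empty Zone 1 at the boundary
  z0 <- segment_zones(1000L, list(pos_st = 0L, pos_end = 40L))
  expect_equal(diff(z0$zone1), 0L)
  ## property: lengths sum to IR length, zones abut
  set.seed(13)
  for (rep in 1:25) {
    len <- sample(50:2000, 1)
    st <- sample(0:(len - 2L), 1)
    en <- sample((st + 1L):len, 1)
    z <- segment_zones(len, list(pos_st = st, pos_end = en))
    expect_equal(diff(z$zone1) + diff(z$zone2) + diff(z$zone3), len)
    expect_equal(z$zone1[2], z$zone2[1])
    expect_equal(z$zone2[2], z$zone3[1])
  }
  expect_null(segment_zones(1000L, NULL))
  expect_error(segment_zones(100L, list(pos_st = 50L, pos_end = 200L)),
               "outside IR")
})

test_that("alternate regions enumerate successive ramps in order", {
  w <- 10L
  ## two ramps separated by a flat stretch and a drop back to the floor
  ir <- c(rep(0, 100), seq_len(40), rep(40, 5), rep(0, 100), seq_len(50))
  depth <- c(rep(100, 120), ir)
  sl2 <- profile_sl2(depth, 120L, w)
  alts <- alternate_pos_regions(sl2, 120L, length(ir), w = w, eps = 0)
  expect_equal(length(alts), 2L)
  expect_lte(abs(alts[[1]]$pos_st - 100L), w)
  expect_lte(abs(alts[[2]]$pos_st - 245L), w)
  expect_true(alts[[1]]$pos_end <= alts[[2]]$pos_st)
  ## first element always equals the single-region detector
  first <- find_pos_region(sl2, 120L, length(ir), w = w, eps = 0)
  expect_equal(alts[[1]], first)
  ## flat IR: empty collection
  expect_equal(length(alternate_pos_regions(
    profile_sl2(c(rep(100, 120), rep(0, 200)), 120L, w), 120L, 200L,
    w = w, eps = 0)), 0L)
})

test_that("smaller windows never detect a later first region on step-ramps", {
  cds <- rep(100, 150)
  ir <- c(rep(0, 180), seq_len(90))
  depth <- c(cds, ir)
  found <- sapply(c(5L, 10L, 15L, 20L, 25L, 30L), function(w) {
    sl2 <- profile_sl2(depth, 150L, w)
    p <- find_pos_region(sl2, 150L, length(ir), w = w, eps = 0)
    if (is.null(p)) NA_integer_ else p$pos_st
  })
  found <- found[!is.na(found)]
  expect_true(all(diff(found) >= 0))
})

test_that("detect_termination works end-to-end on both strands", {
  set.seed(21)
  sim <- simulate_genome(sim_config(n_units = 6, seed = 21))
  tracks <- simulate_depth(sim)
  irs <- compute_irs(sim$units, sim$genome)
  for (i in seq_len(nrow(sim$units))) {
    u <- sim$units[i, ]
    ir <- irs[match(u$unit_id, irs$unit_id), ]
    tr <- sim$truth[match(u$unit_id, sim$truth$unit_id), ]
    det <- detect_termination(u, ir, tracks[[u$strand]])
    expect_false(is.null(det$pos), info = u$unit_id)
    expect_lte(abs(det$pos$pos_st - tr$ramp_start), 10L)
    z <- det$zones
    expect_equal(diff(z$zone1) + diff(z$zone2) + diff(z$zone3), ir$length)
  }
})
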