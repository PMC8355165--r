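write_fasta <- function(lines) {
  f <- tempfile(fileext = ".fa")
  writeLines(lines, f)
  f
}

test_that("load_genome reads, uppercases and preserves record order", {
  g <- load_genome(write_fasta(c(">g", "ACGT")))
  expect_equal(length(g), 1L)
  expect_equal(Biostrings::width(g), 4L)
  expect_equal(names(g), "g")

  g2 <- load_genome(write_fasta(c(">g", "acgt")))
  expect_equal(as.character(g2[[1]]), "ACGT")

  g3 <- load_genome(write_fasta(c(">a desc", "ACGTN", ">b", "GGCC")))
  expect_equal(names(g3), c("a", "b"))

  expect_error(load_genome(write_fasta(character(0))), "empty|malformed")
  expect_error(load_genome(tempfile()), "not found")
})

test_that("transcription units load from TSV and GFF3 with 1-based conversion", {
  fa <- write_fasta(c(">chr", paste(rep("ACGTTGCA", 2000), collapse = "")))
  gen <- load_genome(fa)

  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr\ttest\tgene\t3687\t9675\t.\t+\t.\tID=opA",
    "chr\ttest\tgene\t10901\t12000\t.\t+\t.\tID=opB",
    "chr\ttest\tgene\t13000\t14000\t.\t-\t.\tID=opC"
  ), gff)
  u <- load_transcription_units(gff, gen)
  a <- u[u$unit_id == "opA", ]
  expect_equal(c(a$cds_start, a$cds_end), c(3686L, 9675L))  # [3686, 9675)
  expect_equal(a$stop_site, 9675L - 3L)
  cc <- u[u$unit_id == "opC", ]
  expect_equal(cc$stop_site, cc$cds_start + 2L)  # leftmost codon, tx-first base

  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("unit_id\tstrand\tstart\tend",
               "t1\t+\t101\t400", "t2\t+\t601\t1000"), tsv)
  ut <- load_transcription_units(tsv, gen)
  expect_equal(ut$cds_start, c(100L, 600L))
  expect_equal(ut$stop_site, c(397L, 997L))

  dup <- tempfile(fileext = ".tsv")
  writeLines(c("unit_id\tstrand\tstart\tend",
               "t1\t+\t101\t400", "t1\t+\t601\t1000"), dup)
  expect_error(load_transcription_units(dup, gen), "duplicate")

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("unit_id\tstrand\tstart\tend", "t1\t?\t101\t400"), bad)
  expect_error(load_transcription_units(bad, gen), "strand")

  over <- tempfile(fileext = ".tsv")
  writeLines(c("unit_id\tstrand\tstart\tend", "t1\t+\t101\t99999"), over)
  expect_error(load_transcription_units(over, gen), "past genome end")
})

test_that("IRs span the 3' end of a unit to the next same-strand 5' start", {
  set.seed(1)
  fa <- write_fasta(c(">chr", random_dna(12000)))
  gen <- load_genome(fa)
  units <- validate_units_for_test(data.frame(
    unit_id = c("u1", "u2"), seqid = "chr", strand = "+",
    cds_start = c(3686L, 10900L), cds_end = c(9675L, 11800L),
    stringsAsFactors = FALSE))
  irs <- compute_irs(units, gen, terminal_max = 100L)
  internal <- irs[!irs$terminal, ]
  expect_equal(nrow(internal), 1L)
  expect_equal(c(internal$ir_start, internal$ir_end), c(9675L, 10900L))
  expect_equal(internal$length, 1225L)
  expect_equal(nchar(internal$seq_tx), 1225L)
})

test_that("minus-strand IRs mirror coordinates and reverse-complement seq_tx", {
  set.seed(2)
  fa <- write_fasta(c(">chr", random_dna(6000)))
  gen <- load_genome(fa)
  units <- validate_units_for_test(data.frame(
    unit_id = c("m1", "m2"), seqid = "chr", strand = "-",
    cds_start = c(500L, 3000L), cds_end = c(1500L, 4000L),
    stringsAsFactors = FALSE))
  irs <- compute_irs(units, gen, terminal_max = 200L)
  ## transcript-downstream neighbour of m2 is m1 (genomically leftward)
  internal <- irs[!irs$terminal, ]
  expect_equal(internal$unit_id, "m2")
  expect_equal(c(internal$ir_start, internal$ir_end), c(1500L, 3000L))
  plus_slice <- as.character(Biostrings::subseq(gen[[1]], 1501L, 3000L))
  expect_equal(internal$seq_tx,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(plus_slice))))
})

test_that("IR count per strand equals consecutive pairs plus terminal IRs", {
  set.seed(3)
  fa <- write_fasta(c(">chr", random_dna(20000)))
  gen <- load_genome(fa)
  ## brute-force pairing oracle over random unit layouts
  for (rep in 1:20) {
    npl <- sample(1:4, 1); nmn <- sample(1:4, 1)
    mk <- function(n, strand, offset) {
      if (n == 0) return(NULL)
      s <- sort(sample(seq(offset, 18000, by = 40), n))
      data.frame(unit_id = paste0(strand, seq_len(n), "_", rep),
                 seqid = "chr", strand = strand,
                 cds_start = s, cds_end = s + 30L, stringsAsFactors = FALSE)
    }
    units <- validate_units_for_test(rbind(mk(npl, "+", 1), mk(nmn, "-", 21)))
    irs <- suppressWarnings(compute_irs(units, gen, terminal_max = 50L))
    expect_equal(sum(irs$strand == "+" & !irs$terminal), npl - 1L)
    expect_equal(sum(irs$strand == "-" & !irs$terminal), nmn - 1L)
    expect_lte(sum(irs$terminal), 2L)
  }
})

test_that("overlapping adjacent units yield a skipped zero-length IR", {
  fa <- write_fasta(c(">chr", random_dna(3000)))
  gen <- load_genome(fa)
  units <- validate_units_for_test(data.frame(
    unit_id = c("o1", "o2"), seqid = "chr", strand = "+",
    cds_start = c(100L, 400L), cds_end = c(500L, 900L),
    stringsAsFactors = FALSE))
  expect_warning(irs <- compute_irs(units, gen, terminal_max = 100L),
                 "zero-length")
  expect_false("o1" %in% irs$unit_id[!irs$terminal])
})

test_that("scan window covers [stop-20, stop+270) and clips at boundaries", {
  set.seed(4)
  fa <- write_fasta(c(">chr", random_dna(1000)))
  gen <- load_genome(fa)
  u <- list(unit_id = "w1", seqid = "chr", strand = "+", stop_site = 100L)
  win <- extract_scan_window(u, gen)
  expect_equal(range(win$offsets), c(80L, 369L))
  expect_equal(win$anchor, 20L)
  expect_equal(nchar(win$seq), 290L)

  u2 <- list(unit_id = "w2", seqid = "chr", strand = "+", stop_site = 10L)
  win2 <- extract_scan_window(u2, gen)
  expect_equal(win2$offsets[1], 0L)   # upstream clipped to 10 bases
  expect_equal(win2$anchor, 10L)
  expect_true(win2$clipped)
})

test_that("minus-strand window offset map round-trips every position", {
  set.seed(5)
  fa <- write_fasta(c(">chr", random_dna(1000)))
  gen <- load_genome(fa)
  u <- list(unit_id = "wm", seqid = "chr", strand = "-", stop_site = 600L)
  win <- extract_scan_window(u, gen)
  ## bijective: all distinct, decreasing for '-', and the window base equals
  ## the complement of the genomic base at the mapped coordinate
  expect_equal(length(unique(win$offsets)), length(win$offsets))
  expect_true(all(diff(win$offsets) == -1L))
  gseq <- strsplit(as.character(gen[[1]]), "")[[1]]
  wseq <- strsplit(win$seq, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  expect_equal(wseq, unname(comp[gseq[win$offsets + 1L]]))
  expect_equal(win$offsets[win$anchor + 1L], 600L)
  expect_error(extract_scan_window(
    list(unit_id = "x", seqid = "chr", strand = "+", stop_site = 5000L), gen),
    "outside genome")
})
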