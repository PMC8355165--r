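## Seeded generator for genomes, annotations and strand-specific depth tracks
## with planted intrinsic-termination structure.

#' Simulation settings
#'
#' Defaults emulate the structure of bulk bacterial RNA-seq around
#' terminators: high plateau coverage over the CDS, a sharp post-terminator
#' decay, a near-zero IR floor, a short positive-slope bump shortly after the
#' planted termination end, and a 5'-UTR ascent into the next same-strand
#' unit (the source of alternate positive-slope regions).
#'
#' @param n_units Number of transcription units, tiled on alternating strands.
#' @param gc_fraction Background GC (default 0.5; bacterial genomes span
#'   roughly 0.27-0.68).
#' @param cds_len_mean,cds_len_sd CDS length distribution (bases).
#' @param ir_len_mean,ir_len_sd Same-strand IR length distribution (bases);
#'   the inter-CDS gap is derived as `(ir_len_mean - cds_len_mean) / 2`.
#' @param terminator_offset_max Maximum terminator offset downstream of the
#'   stop codon (default 80); offsets are geometric with mean
#'   `terminator_offset_mean`, reflecting that most units terminate within
#'   ~20 bases.
#' @param terminator_offset_mean Mean of the sampled offset (default 20).
#' @param cluster_prob Probability a planted unit is a cluster of >= 2
#'   hairpins (default 2/3).
#' @param cluster_size_p Geometric decay of cluster sizes beyond 2
#'   (default 0.45; sizes decrease roughly exponentially).
#' @param stem_range,loop_range Planted hairpin stem/loop length ranges.
#' @param gap_range Planted intra-cluster gap range (default 0..14, always
#'   below the 15-base cluster threshold).
#' @param polyU_prob Probability of a 3-8 base U trail after the last hairpin
#'   (default 0.5; roughly half of IRs carry a short trail).
#' @param depth_cds_lambda Expected CDS coverage (default 100).
#' @param depth_ir_floor Post-termination background coverage (default 3).
#' @param readthrough_decay Bases over which the expected excess depth decays
#'   from the CDS plateau to ~1 (default 5).
#' @param ramp_delay Bases between the planted termination end and the
#'   positive-slope bump (default 15).
#' @param ramp_len,ramp_slope Length (default 35) and slope (default 0.4
#'   depth/base) of the bump's rising flank.
#' @param utr_len 5'-UTR ascent length before each CDS (default 50).
#' @param noise `"none"` (expected values) or `"poisson"`.
#' @param seed Mandatory RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_units = 20L, gc_fraction = 0.5,
                       cds_len_mean = 900, cds_len_sd = 150,
                       ir_len_mean = 1700, ir_len_sd = 200,
                       terminator_offset_max = 80L,
                       terminator_offset_mean = 20L,
                       cluster_prob = 2 / 3, cluster_size_p = 0.45,
                       stem_range = c(4L, 8L), loop_range = c(4L, 8L),
                       gap_range = c(0L, 14L), polyU_prob = 0.5,
                       depth_cds_lambda = 100, depth_ir_floor = 3,
                       readthrough_decay = 5, ramp_delay = 15L,
                       ramp_len = 35L, ramp_slope = 0.4, utr_len = 50L,
                       noise = c("none", "poisson"), seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(gc_fraction >= 0, gc_fraction <= 1,
            cluster_prob >= 0, cluster_prob <= 1,
            polyU_prob >= 0, polyU_prob <= 1,
            !is.null(seed), is.finite(seed))
  structure(as.list(environment()), class = "sim_config")
}

sample_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

## one planted termination unit in transcript orientation; returns the
## character vector plus hairpin spans (0-based, relative to the unit start)
build_term_unit <- function(cfg) {
  m <- if (runif(1) < cfg$cluster_prob) {
    2L + rgeom(1L, cfg$cluster_size_p)
  } else 1L
  m <- min(m, 6L)
  seq <- character(0)
  spans <- matrix(0L, nrow = m, ncol = 2L)
  for (h in seq_len(m)) {
    if (h > 1L) {
      g <- sample(cfg$gap_range[1L]:cfg$gap_range[2L], 1L)
      seq <- c(seq, sample_bases(g, cfg$gc_fraction))
    }
    s <- sample(cfg$stem_range[1L]:cfg$stem_range[2L], 1L)
    l <- sample(cfg$loop_range[1L]:cfg$loop_range[2L], 1L)
    ## stems follow the background composition so the emitted genome's GC
    ## stays at gc_fraction (a stem plus its complement is GC-neutral)
    stem <- sample_bases(s, cfg$gc_fraction)
    loop <- sample_bases(l, cfg$gc_fraction)
    hp <- c(stem, loop, rev(unname(COMP[stem])))
    spans[h, ] <- c(length(seq), length(seq) + length(hp))
    seq <- c(seq, hp)
  }
  polyu <- 0L
  if (runif(1) < cfg$polyU_prob) {
    off <- sample(0:2, 1L)
    run <- sample(3:8, 1L)
    seq <- c(seq, sample_bases(off, cfg$gc_fraction), rep("T", run))
    polyu <- run
  }
  list(seq = seq, spans = spans, kind = if (m >= 2L) "cluster" else "single",
       m = m, polyu = polyu)
}

#' Simulate a genome with planted terminators
#'
#' Tiles `n_units` transcription units on alternating strands over an i.i.d.
#' background of the configured GC content. Each unit receives a planted
#' termination unit (cluster or single of perfect stem-loops, GC-enriched
#' stems) at a geometric offset downstream of its stop codon, optionally
#' followed by a short U trail. Deterministic under `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `itt_sim`: `genome` (a
#'   [Biostrings::DNAStringSet] with one sequence `synth_chr`), `units` (an
#'   `itt_units` data.frame) and `truth`, one row per unit: planted `kind`,
#'   `n_hairpins`, IR-relative `term_unit_start`/`term_unit_end` (hairpin
#'   span), `term_end` (including the U trail), `polyu_len`, `ramp_start`
#'   (IR-relative planted bump start) and `hairpin_spans`
#'   (`"s1-e1;s2-e2;..."`, IR-relative).
#' @export
simulate_genome <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_units
  gap_mean <- max(350, (cfg$ir_len_mean - cfg$cds_len_mean) / 2)
  gap_sd <- cfg$ir_len_sd / 2
  margin <- 400L
  cds_len <- pmax(300L, as.integer(round(rnorm(n, cfg$cds_len_mean, cfg$cds_len_sd))))
  gap_len <- pmax(350L, as.integer(round(rnorm(n, gap_mean, gap_sd))))
  strand <- rep(c("+", "-"), length.out = n)
  cds_start <- integer(n); cds_end <- integer(n)
  pos <- margin
  for (i in seq_len(n)) {
    cds_start[i] <- pos
    cds_end[i] <- pos + cds_len[i]
    pos <- cds_end[i] + gap_len[i]
  }
  glen <- pos + margin
  gseq <- sample_bases(glen, cfg$gc_fraction)

  ## stop codons (transcript orientation TAA)
  for (i in seq_len(n)) {
    if (strand[i] == "+") {
      gseq[(cds_end[i] - 2L):cds_end[i]] <- c("T", "A", "A")
    } else {
      gseq[(cds_start[i] + 1L):(cds_start[i] + 3L)] <- c("T", "T", "A")
    }
  }

  sample_offset <- function() {
    min(cfg$terminator_offset_max,
        5L + rgeom(1L, 1 / max(1L, cfg$terminator_offset_mean - 5L)))
  }
  truth_row <- function(i, off, tu) {
    data.frame(
      unit_id = sprintf("unit_%03d", i), strand = strand[i],
      kind = tu$kind, n_hairpins = tu$m,
      term_unit_start = off + tu$spans[1L, 1L],
      term_unit_end = off + tu$spans[tu$m, 2L],
      term_end = off + length(tu$seq),
      polyu_len = tu$polyu,
      ramp_start = off + length(tu$seq) + cfg$ramp_delay,
      hairpin_spans = paste(off + tu$spans[, 1L], off + tu$spans[, 2L],
                            sep = "-", collapse = ";"),
      stringsAsFactors = FALSE
    )
  }

  ## plant terminators; the gap after a '+' unit also holds, at its far end,
  ## the terminator of the following '-' unit, so the pair is placed jointly
  truth <- vector("list", n)
  for (i in seq(1L, n, by = 2L)) {             # '+' units
    gap <- gap_len[i]
    has_partner <- i + 1L <= n
    placed <- FALSE
    for (attempt in 1:100) {
      off_p <- sample_offset(); tu_p <- build_term_unit(cfg)
      if (has_partner) {
        off_m <- sample_offset(); tu_m <- build_term_unit(cfg)
        need <- off_p + length(tu_p$seq) + 5L + length(tu_m$seq) + off_m
      } else {
        need <- off_p + length(tu_p$seq)
      }
      if (need <= gap) { placed <- TRUE; break }
    }
    if (!placed) stopf("could not place terminator(s) in gap after unit %d", i)
    at <- cds_end[i] + off_p                   # 0-based genomic start
    gseq[(at + 1L):(at + length(tu_p$seq))] <- tu_p$seq
    truth[[i]] <- truth_row(i, off_p, tu_p)
    if (has_partner) {
      at <- cds_start[i + 1L] - off_m - length(tu_m$seq)
      gseq[(at + 1L):(at + length(tu_m$seq))] <- rev(unname(COMP[tu_m$seq]))
      truth[[i + 1L]] <- truth_row(i + 1L, off_m, tu_m)
    }
  }
  truth <- do.call(rbind, truth)

  units <- data.frame(
    unit_id = truth$unit_id, seqid = "synth_chr", strand = strand,
    cds_start = cds_start, cds_end = cds_end,
    stop_site = derive_stop_site(strand, cds_start, cds_end),
    stringsAsFactors = FALSE
  )
  units <- validate_units(units)
  genome <- Biostrings::DNAStringSet(paste(gseq, collapse = ""))
  names(genome) <- "synth_chr"
  structure(list(genome = genome, units = units, truth = truth, config = cfg),
            class = "itt_sim")
}

#' Simulate strand-specific depth tracks for a planted genome
#'
#' Expected coverage per unit: a plateau of `depth_cds_lambda` over the CDS
#' and the transcribed IR head, exponential decay to `depth_ir_floor` after
#' the planted termination end (reaching ~1 excess after `readthrough_decay`
#' bases), a linear bump of slope `ramp_slope` starting `ramp_delay` bases
#' after the termination end (the planted positive-slope region), and a
#' linear 5'-UTR ascent over the `utr_len` bases before each CDS. With
#' `noise = "poisson"` each base is an independent Poisson draw around the
#' expected value. Deterministic under `cfg$seed`.
#'
#' @param sim An `itt_sim` from [simulate_genome()].
#' @param cfg The same [sim_config()] (defaults to `sim$config`).
#' @return Named list of [depth_track()]s (`"+"`, `"-"`).
#' @export
simulate_depth <- function(sim, cfg = sim$config) {
  set.seed(cfg$seed + 1L)
  glen <- Biostrings::width(sim$genome)[1L]
  units <- sim$units
  irs <- compute_irs(units, sim$genome, terminal_max = 3000L)
  lam <- cfg$depth_cds_lambda
  floor_ <- cfg$depth_ir_floor
  exp_depth <- list("+" = numeric(glen), "-" = numeric(glen))

  tx_positions <- function(strand, start0, len, origin) {
    ## genomic 0-based positions of len transcript-orientation bases
    if (strand == "+") origin + start0 + seq_len(len) - 1L
    else origin - start0 - seq_len(len) + 1L
  }

  for (i in seq_len(nrow(units))) {
    u <- units[i, ]
    tr <- sim$truth[match(u$unit_id, sim$truth$unit_id), ]
    ir <- irs[match(u$unit_id, irs$unit_id), ]
    st <- u$strand
    ## CDS plateau
    exp_depth[[st]][(u$cds_start + 1L):u$cds_end] <-
      exp_depth[[st]][(u$cds_start + 1L):u$cds_end] + lam
    if (is.na(ir$ir_start)) next
    ir_len <- ir$length
    k <- seq_len(ir_len) - 1L                      # IR-relative 0-based
    prof <- numeric(ir_len) + floor_
    head_ <- k < tr$term_end
    prof[head_] <- lam
    decay <- (lam - floor_) * lam^(-(k[!head_] - tr$term_end) / cfg$readthrough_decay)
    prof[!head_] <- floor_ + decay
    ## positive-slope bump
    rs <- tr$ramp_start
    rise <- k >= rs & k < rs + cfg$ramp_len
    prof[rise] <- prof[rise] + cfg$ramp_slope * (k[rise] - rs + 1L)
    peak <- cfg$ramp_slope * cfg$ramp_len
    aft <- k >= rs + cfg$ramp_len
    prof[aft] <- prof[aft] + peak * exp(-(k[aft] - rs - cfg$ramp_len + 1L) / 20)
    ## place (transcript orientation)
    origin <- if (st == "+") ir$ir_start else ir$ir_end - 1L
    gpos <- tx_positions(st, 0L, ir_len, origin)
    exp_depth[[st]][gpos + 1L] <- pmax(exp_depth[[st]][gpos + 1L], prof)
    ## 5'-UTR ascent into this unit's own CDS (lies in the upstream IR)
    utr <- cfg$utr_len
    five_prime <- if (st == "+") u$cds_start else u$cds_end - 1L
    j <- seq_len(utr)
    upos <- if (st == "+") five_prime - j else five_prime + j
    okp <- upos >= 0L & upos < glen
    exp_depth[[st]][upos[okp] + 1L] <-
      pmax(exp_depth[[st]][upos[okp] + 1L], (lam * (1 - j / (utr + 1)))[okp])
  }
  mk <- function(st) {
    d <- exp_depth[[st]]
    if (cfg$noise == "poisson") d <- rpois(length(d), d)
    depth_track("synth_chr", st, d)
  }
  list("+" = mk("+"), "-" = mk("-"))
}

#' Write a simulated dataset to disk
#'
#' Emits the genome FASTA, annotations (GFF3 and TSV), per-strand bedGraphs
#' and the truth table.
#'
#' @param sim An `itt_sim`.
#' @param tracks Optional list of [depth_track()]s to export as bedGraph.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, tracks = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  u <- sim$units
  gr <- GenomicRanges::GRanges(u$seqid,
                               IRanges::IRanges(u$cds_start + 1L, u$cds_end),
                               strand = u$strand)
  gr$type <- "gene"; gr$ID <- u$unit_id
  rtracklayer::export(gr, file.path(dir, "annotations.gff3"), format = "gff3")
  tsv <- data.frame(unit_id = u$unit_id, strand = u$strand,
                    start = u$cds_start + 1L, end = u$cds_end,
                    stop_site = u$stop_site + 1L, seqid = u$seqid)
  write.table(tsv, file.path(dir, "annotations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(tracks)) {
    for (st in names(tracks)) {
      d <- tracks[[st]]$depth
      r <- rle(d)
      ends <- cumsum(r$lengths)
      gr <- GenomicRanges::GRanges("synth_chr",
        IRanges::IRanges(ends - r$lengths + 1L, ends), score = r$values)
      gr <- gr[gr$score > 0]
      nm <- if (st == "+") "depth_plus.bedGraph" else "depth_minus.bedGraph"
      rtracklayer::export(gr, file.path(dir, nm), format = "bedGraph")
    }
  }
  invisible(dir)
}
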