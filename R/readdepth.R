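## Alignment filtering, strand-specific depth tracks, IR coverage screening.

#' Alignment filter settings
#'
#' Proper-pair SAM flags, minimum mapping quality and the TLEN rule
#' (|TLEN| must be at least the read length).
#'
#' @param proper_pair_flags Integer SAM flag values accepted (default
#'   83/163 and 99/147, the two proper-pair orientations).
#' @param min_mapq Minimum MAPQ (default 30).
#' @return A list of class `alignment_filter_config`.
#' @export
alignment_filter_config <- function(proper_pair_flags = c(83L, 163L, 99L, 147L),
                                    min_mapq = 30L) {
  stopifnot(all(proper_pair_flags >= 0L), all(proper_pair_flags < 4096L))
  structure(list(proper_pair_flags = as.integer(proper_pair_flags),
                 min_mapq = as.integer(min_mapq)),
            class = "alignment_filter_config")
}

#' Screening settings for IR coverage filtering
#'
#' @param min_coverage_fraction Keep regions with coverage fraction strictly
#'   above this (default 0.90).
#' @param outlier_tail_fraction Upper tail of the mean-depth distribution
#'   removed as outliers (default 0.05).
#' @param apply_to Where the coverage rule applies: the source unit's CDS, the
#'   IR, or both (default).
#' @param covered_min A base counts as covered when its (replicate-averaged)
#'   depth is at least this value (default 1).
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(min_coverage_fraction = 0.90,
                          outlier_tail_fraction = 0.05,
                          apply_to = c("both", "IR", "CDS"),
                          covered_min = 1) {
  stopifnot(min_coverage_fraction > 0, min_coverage_fraction < 1,
            outlier_tail_fraction > 0, outlier_tail_fraction < 1)
  structure(list(min_coverage_fraction = min_coverage_fraction,
                 outlier_tail_fraction = outlier_tail_fraction,
                 apply_to = match.arg(apply_to),
                 covered_min = covered_min),
            class = "screen_config")
}

#' Read paired-end alignment records from SAM/BAM
#'
#' Plain-text SAM is converted on the fly with [Rsamtools::asBam()]. Only the
#' fields needed by [filter_alignments()] and [build_depth()] are retained.
#'
#' @param path SAM or BAM file.
#' @return A `data.frame` with columns `flag`, `mapq`, `tlen`, `pos` (1-based
#'   leftmost), `width` (read length on the reference) and `rname`.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stopf("alignment file not found: %s", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("flag", "mapq", "isize", "pos", "qwidth", "rname")))[[1L]]
  data.frame(flag = res$flag, mapq = res$mapq, tlen = res$isize,
             pos = res$pos, width = res$qwidth,
             rname = as.character(res$rname), stringsAsFactors = FALSE)
}

#' Filter alignment records by flag, MAPQ and TLEN
#'
#' A record is kept iff its flag is one of the configured proper-pair flags,
#' MAPQ >= `min_mapq`, and |TLEN| >= read length. Records with missing fields
#' are tallied as `unreadable` and dropped, never fatal.
#'
#' @param records A `data.frame` as from [read_alignments()].
#' @param cfg An [alignment_filter_config()].
#' @return A list: `kept` (the surviving records) and `tally`, a named integer
#'   vector of counts per rejection reason (`kept`, `flag`, `mapq`, `tlen`,
#'   `unreadable`). A record is tallied under its first failing criterion.
#' @export
filter_alignments <- function(records, cfg = alignment_filter_config()) {
  need <- c("flag", "mapq", "tlen", "width")
  stopifnot(all(need %in% names(records)))
  unread <- Reduce(`|`, lapply(records[need], is.na))
  ok_flag <- !unread & records$flag %in% cfg$proper_pair_flags
  ok_mapq <- !unread & records$mapq >= cfg$min_mapq
  ok_tlen <- !unread & abs(records$tlen) >= records$width
  keep <- ok_flag & ok_mapq & ok_tlen
  reason <- rep("kept", nrow(records))
  reason[!ok_tlen] <- "tlen"
  reason[!ok_mapq] <- "mapq"
  reason[!ok_flag] <- "flag"
  reason[unread]   <- "unreadable"
  tally <- vapply(c("kept", "flag", "mapq", "tlen", "unreadable"),
                  function(r) sum(reason == r), integer(1))
  list(kept = records[keep, , drop = FALSE], tally = tally)
}

## fragment strand from the SAM flag: strand of the first-in-pair mate
fragment_strand <- function(flag) {
  first <- bitwAnd(flag, 64L) > 0L
  rev   <- bitwAnd(flag, 16L) > 0L
  ifelse(first, ifelse(rev, "-", "+"), ifelse(rev, "+", "-"))
}

#' Construct a strand-specific depth track
#'
#' @param genome_id Sequence name the track refers to.
#' @param strand `"+"` or `"-"`.
#' @param depth Numeric vector, one non-negative value per genome base
#'   (real-valued after replicate averaging).
#' @param n_replicates Number of replicates averaged into `depth`.
#' @return A list of class `depth_track`.
#' @export
depth_track <- function(genome_id, strand, depth, n_replicates = 1L) {
  stopifnot(strand %in% c("+", "-"), all(depth >= 0))
  structure(list(genome_id = genome_id, strand = strand,
                 depth = as.numeric(depth),
                 n_replicates = as.integer(n_replicates)),
            class = "depth_track")
}

#' @export
print.depth_track <- function(x, ...) {
  cat(sprintf("depth_track %s(%s): %d bases, mean %.3f, %d replicate(s)\n",
              x$genome_id, x$strand, length(x$depth), mean(x$depth),
              x$n_replicates))
  invisible(x)
}

#' Build a per-base depth track from filtered records or a bedGraph
#'
#' Every reference base of a kept read contributes one count; replicate tracks
#' are averaged elementwise with [average_tracks()]. With record input the
#' fragment strand is inferred from the flag (strand of the first-in-pair
#' mate), and only fragments on `strand` are counted.
#'
#' @param x A `data.frame` of (already filtered) records, or the path of a
#'   pre-split 4-column bedGraph for one strand.
#' @param strand `"+"` or `"-"`.
#' @param genome A [Biostrings::DNAStringSet] (for the track length).
#' @param genome_id Sequence to build the track for (default: first).
#' @return A [depth_track()].
#' @export
build_depth <- function(x, strand, genome, genome_id = names(genome)[1L]) {
  glen <- Biostrings::width(genome)[match(genome_id, names(genome))]
  if (is.na(glen)) stopf("genome_id %s not in genome", genome_id)
  if (is.character(x) && length(x) == 1L) {
    gr <- rtracklayer::import(x, format = "bedGraph")
    gr <- gr[as.character(GenomicRanges::seqnames(gr)) == genome_id]
    if (length(gr) &&
        (min(GenomicRanges::start(gr)) < 1L || max(GenomicRanges::end(gr)) > glen)) {
      stopf("bedGraph interval outside genome [1, %d]", glen)
    }
    depth <- numeric(glen)
    if (length(gr)) {
      for (i in seq_along(gr)) {
        depth[GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]] <- gr$score[i]
      }
    }
    return(depth_track(genome_id, strand, depth))
  }
  stopifnot(is.data.frame(x))
  recs <- x[!is.na(x$pos) & x$rname == genome_id &
              fragment_strand(x$flag) == strand, , drop = FALSE]
  if (nrow(recs) == 0L) return(depth_track(genome_id, strand, numeric(glen)))
  ir <- IRanges::IRanges(start = recs$pos, width = recs$width)
  depth <- as.numeric(IRanges::coverage(ir, width = glen))
  depth_track(genome_id, strand, depth)
}

#' Average replicate depth tracks elementwise
#'
#' @param tracks A list of [depth_track()] objects on the same strand/genome.
#' @return A single [depth_track()] with `n_replicates` set to the count.
#' @export
average_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1L)
  strands <- unique(vapply(tracks, `[[`, "", "strand"))
  ids <- unique(vapply(tracks, `[[`, "", "genome_id"))
  lens <- unique(vapply(tracks, function(t) length(t$depth), integer(1)))
  if (length(strands) != 1L || length(ids) != 1L || length(lens) != 1L) {
    stopf("replicate tracks must share genome, strand and length")
  }
  depth <- Reduce(`+`, lapply(tracks, `[[`, "depth")) / length(tracks)
  depth_track(ids, strands, depth, n_replicates = length(tracks))
}

#' Fraction of covered bases in a region
#'
#' @param region Integer vector `c(start, end)`, 0-based half-open genomic.
#' @param track A [depth_track()].
#' @param covered_min Depth at or above which a base counts as covered
#'   (default 1; note that replicate averaging can push integer depths below
#'   this threshold).
#' @return A real in `[0, 1]`.
#' @export
coverage_fraction <- function(region, track, covered_min = 1) {
  s <- as.integer(region[1L]); e <- as.integer(region[2L])
  if (e <= s) stopf("zero-length region")
  if (s < 0L || e > length(track$depth)) stopf("region outside genome")
  mean(track$depth[(s + 1L):e] >= covered_min)
}

#' Screen IRs by coverage and depth-outlier rules
#'
#' Stage 1 keeps IRs whose coverage fraction exceeds
#' `min_coverage_fraction` (on the IR, the source unit's CDS, or both,
#' per `cfg$apply_to`). Stage 2 removes surviving IRs whose mean depth lies
#' strictly above the upper `outlier_tail_fraction` quantile of the mean-depth
#' distribution over survivors; with fewer than `ceiling(1/tail)` survivors
#' Stage 2 is skipped with a warning.
#'
#' @param irs An `itt_irs` data.frame.
#' @param tracks Named list of [depth_track()] objects, names `"+"` and `"-"`.
#' @param cfg A [screen_config()].
#' @param units The `itt_units` data.frame (required when `apply_to` involves
#'   the CDS).
#' @return A list: `kept` (surviving IRs) and `audit`, one row per input IR
#'   with its coverage, mean depth and `removed_stage` (NA, 1 or 2).
#' @export
screen_irs <- function(irs, tracks, cfg = screen_config(), units = NULL) {
  stopifnot(all(c("+", "-") %in% names(tracks)))
  n <- nrow(irs)
  cov_ir <- cov_cds <- mean_depth <- numeric(n)
  for (i in seq_len(n)) {
    tr <- tracks[[irs$strand[i]]]
    cov_ir[i] <- coverage_fraction(c(irs$ir_start[i], irs$ir_end[i]), tr,
                                   covered_min = cfg$covered_min)
    mean_depth[i] <- mean(tr$depth[(irs$ir_start[i] + 1L):irs$ir_end[i]])
    if (cfg$apply_to %in% c("both", "CDS")) {
      if (is.null(units)) stopf("units required when apply_to includes CDS")
      u <- units[match(irs$unit_id[i], units$unit_id), ]
      cov_cds[i] <- coverage_fraction(c(u$cds_start, u$cds_end), tr,
                                      covered_min = cfg$covered_min)
    } else {
      cov_cds[i] <- NA_real_
    }
  }
  pass1 <- switch(cfg$apply_to,
    IR   = cov_ir > cfg$min_coverage_fraction,
    CDS  = cov_cds > cfg$min_coverage_fraction,
    both = cov_ir > cfg$min_coverage_fraction &
           cov_cds > cfg$min_coverage_fraction)
  removed <- rep(NA_integer_, n)
  removed[!pass1] <- 1L
  surv <- which(pass1)
  if (length(surv) < ceiling(1 / cfg$outlier_tail_fraction)) {
    if (length(surv) > 0L) {
      warnf("too few IRs (%d) for the %.0f%% outlier tail; Stage 2 skipped",
            length(surv), 100 * cfg$outlier_tail_fraction)
    }
  } else {
    cut <- quantile(mean_depth[surv], 1 - cfg$outlier_tail_fraction,
                    names = FALSE, type = 7)
    removed[surv[mean_depth[surv] > cut]] <- 2L
  }
  audit <- data.frame(unit_id = irs$unit_id, strand = irs$strand,
                      coverage_ir = cov_ir, coverage_cds = cov_cds,
                      mean_depth = mean_depth, removed_stage = removed,
                      stringsAsFactors = FALSE)
  list(kept = irs[is.na(removed), , drop = FALSE], audit = audit)
}
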