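## Genome + transcription-unit input, inter-operonic regions, scan windows.

#' Load a genome from a FASTA file
#'
#' Reads one or more DNA sequences. Sequences are uppercased; `N` is allowed
#' and never pairs in hairpin stems downstream.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] with one entry per record, in file
#'   order. Names are the first whitespace-delimited token of each header.
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stopf("genome FASTA not found: %s", path)
  gen <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stopf("malformed FASTA '%s': %s", path, conditionMessage(e))
  )
  if (length(gen) == 0L) stopf("empty FASTA: %s", path)
  names(gen) <- sub("\\s.*$", "", names(gen))
  Biostrings::DNAStringSet(toupper(gen))
}

## stop_site (0-based genomic) of the transcript-orientation first base of the
## stop codon: '+' -> cds_end - 3; '-' -> cds_start + 2.
derive_stop_site <- function(strand, cds_start, cds_end) {
  ifelse(strand == "+", cds_end - 3L, cds_start + 2L)
}

#' Load transcription-unit (gene/operon) annotations
#'
#' Accepts GFF3 (features of type `gene` or `operon`; the unit id is taken
#' from the `ID`, `Name` or `locus_tag` attribute) or a TSV with 1-based
#' inclusive coordinates and columns `unit_id`, `strand`, `start`, `end` and
#' optionally `stop_site` (genomic position of the transcript-first base of
#' the stop codon) and `seqid`. Coordinates are converted to 0-based
#' half-open; when `stop_site` is absent it is derived from the strand as the
#' terminal codon of the unit.
#'
#' @param path Annotation file.
#' @param genome Optional [Biostrings::DNAStringSet]; when supplied, units
#'   extending past the genome end are an error and seqids are checked.
#' @param format `"auto"` (by extension), `"gff3"` or `"tsv"`.
#' @return A `data.frame` (class `itt_units`) with columns `unit_id`, `seqid`,
#'   `strand`, `cds_start`, `cds_end`, `stop_site` (all coordinates 0-based
#'   half-open), sorted by seqid, strand, then start.
#' @export
load_transcription_units <- function(path, genome = NULL,
                                     format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    keep <- as.character(gr$type) %in% c("gene", "operon")
    gr <- gr[keep]
    if (length(gr) == 0L) stopf("no gene/operon features in %s", path)
    ids <- gr$ID
    if (is.null(ids)) ids <- gr$Name
    if (is.null(ids)) ids <- gr$locus_tag
    if (is.null(ids) || anyNA(ids)) {
      stopf("gene/operon features in %s lack ID/Name/locus_tag attributes", path)
    }
    units <- data.frame(
      unit_id   = as.character(ids),
      seqid     = as.character(GenomicRanges::seqnames(gr)),
      strand    = as.character(GenomicRanges::strand(gr)),
      cds_start = GenomicRanges::start(gr) - 1L,
      cds_end   = GenomicRanges::end(gr),
      stringsAsFactors = FALSE
    )
    units$stop_site <- derive_stop_site(units$strand, units$cds_start, units$cds_end)
  } else {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("unit_id", "strand", "start", "end")
    if (!all(need %in% names(tab))) {
      stopf("TSV %s must have columns: %s", path, paste(need, collapse = ", "))
    }
    units <- data.frame(
      unit_id   = as.character(tab$unit_id),
      seqid     = if ("seqid" %in% names(tab)) as.character(tab$seqid)
                  else if (!is.null(genome)) names(genome)[1L] else "chr",
      strand    = as.character(tab$strand),
      cds_start = as.integer(tab$start) - 1L,
      cds_end   = as.integer(tab$end),
      stringsAsFactors = FALSE
    )
    units$stop_site <- if ("stop_site" %in% names(tab)) {
      as.integer(tab$stop_site) - 1L
    } else {
      derive_stop_site(units$strand, units$cds_start, units$cds_end)
    }
  }
  validate_units(units, genome)
}

validate_units <- function(units, genome = NULL) {
  units$strand <- sub("−", "-", units$strand)  # tolerate unicode minus
  bad <- !units$strand %in% c("+", "-")
  if (any(bad)) stopf("unknown strand symbol(s): %s",
                      paste(unique(units$strand[bad]), collapse = ", "))
  if (anyDuplicated(units$unit_id)) {
    stopf("duplicate unit_id(s): %s",
          paste(unique(units$unit_id[duplicated(units$unit_id)]), collapse = ", "))
  }
  if (any(units$cds_start >= units$cds_end)) stopf("unit with cds_start >= cds_end")
  if (any(units$stop_site < units$cds_start | units$stop_site >= units$cds_end)) {
    stopf("stop_site outside [cds_start, cds_end) for some unit")
  }
  if (!is.null(genome)) {
    miss <- setdiff(units$seqid, names(genome))
    if (length(miss)) stopf("seqid(s) not in genome: %s", paste(miss, collapse = ", "))
    glen <- Biostrings::width(genome)[match(units$seqid, names(genome))]
    if (any(units$cds_end > glen | units$cds_start < 0L)) {
      stopf("unit extends past genome end")
    }
  }
  units <- units[order(units$seqid, units$strand, units$cds_start), , drop = FALSE]
  rownames(units) <- NULL
  class(units) <- c("itt_units", "data.frame")
  units
}

#' Compute inter-operonic regions (IRs)
#'
#' One IR per consecutive same-strand unit pair, running (in transcript
#' orientation) from the 3' end of the upstream unit to the 5' start of the
#' next same-strand unit. Terminal units with no downstream neighbour yield an
#' IR capped at `terminal_max` bases (or the genome edge). Adjacent units that
#' touch or overlap yield no IR (a warning is raised).
#'
#' @param units An `itt_units` data.frame (see [load_transcription_units()]).
#' @param genome A [Biostrings::DNAStringSet].
#' @param terminal_max Maximum length of chromosome-end IRs (default 3000).
#' @return A `data.frame` (class `itt_irs`): `unit_id` (the upstream /
#'   provenance unit), `seqid`, `strand`, `ir_start`, `ir_end` (0-based
#'   half-open genomic), `length`, `terminal`, and `seq_tx`, the IR sequence in
#'   transcript orientation (reverse-complemented for `-` strand units).
#' @export
compute_irs <- function(units, genome, terminal_max = 3000L) {
  stopifnot(is.data.frame(units))
  out <- list()
  for (sq in unique(units$seqid)) {
    glen <- Biostrings::width(genome)[match(sq, names(genome))]
    for (st in c("+", "-")) {
      u <- units[units$seqid == sq & units$strand == st, , drop = FALSE]
      if (nrow(u) == 0L) next
      ## order in transcript direction: '+' left-to-right, '-' right-to-left
      u <- u[order(u$cds_start, decreasing = (st == "-")), , drop = FALSE]
      n <- nrow(u)
      for (i in seq_len(n)) {
        if (i < n) {
          if (st == "+") {
            s <- u$cds_end[i]; e <- u$cds_start[i + 1L]
          } else {
            s <- u$cds_end[i + 1L]; e <- u$cds_start[i]
          }
          terminal <- FALSE
        } else {
          if (st == "+") {
            s <- u$cds_end[i]; e <- min(glen, u$cds_end[i] + terminal_max)
          } else {
            s <- max(0L, u$cds_start[i] - terminal_max); e <- u$cds_start[i]
          }
          terminal <- TRUE
        }
        if (e <= s) {
          warnf("zero-length IR for unit %s skipped (adjacent units overlap)",
                u$unit_id[i])
          next
        }
        sq_chr <- as.character(Biostrings::subseq(genome[[sq]], s + 1L, e))
        if (st == "-") sq_chr <- revcomp(sq_chr)
        out[[length(out) + 1L]] <- data.frame(
          unit_id = u$unit_id[i], seqid = sq, strand = st,
          ir_start = as.integer(s), ir_end = as.integer(e),
          length = as.integer(e - s), terminal = terminal,
          seq_tx = sq_chr, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) stopf("no IRs could be computed")
  irs <- do.call(rbind, out)
  rownames(irs) <- NULL
  class(irs) <- c("itt_irs", "data.frame")
  irs
}

#' Export IRs as BED6
#'
#' @param irs An `itt_irs` data.frame.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
export_irs_bed <- function(irs, path) {
  bed <- data.frame(irs$seqid, irs$ir_start, irs$ir_end, irs$unit_id,
                    0L, irs$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extract the hairpin scan window around a stop codon
#'
#' Returns the transcript-orientation subsequence spanning `up` bases upstream
#' of the stop-codon site through `down` bases downstream (position +1 of the
#' window convention is the first base of the stop codon). The window is
#' clipped at the genome boundary and, when `max_down` is given, at
#' `stop_site + max_down` in transcript orientation (used to stop at the next
#' same-strand CDS).
#'
#' @param unit One row of an `itt_units` data.frame (or an equivalent list).
#' @param genome A [Biostrings::DNAStringSet].
#' @param up,down Bases upstream/downstream of the stop-codon site (defaults
#'   20 and 270).
#' @param max_down Optional cap on the downstream extent, in bases from the
#'   stop site.
#' @return A list: `seq` (character, transcript orientation), `offsets`
#'   (integer vector, genomic 0-based coordinate of every window position; a
#'   bijective map), `anchor` (0-based window index of the stop site),
#'   `clipped` (logical).
#' @export
extract_scan_window <- function(unit, genome, up = 20L, down = 270L,
                                max_down = NULL) {
  ss <- as.integer(unit$stop_site)
  sq <- as.character(unit$seqid)
  glen <- Biostrings::width(genome)[match(sq, names(genome))]
  if (is.na(glen)) stopf("seqid %s not in genome", sq)
  if (ss < 0L || ss >= glen) stopf("stop_site outside genome for unit %s", unit$unit_id)
  down_eff <- if (is.null(max_down)) down else min(down, as.integer(max_down))
  if (unit$strand == "+") {
    g0 <- max(0L, ss - up)
    g1 <- min(glen, ss + down_eff)
    if (g1 <= g0) stopf("scan window empty for unit %s", unit$unit_id)
    offsets <- seq.int(g0, g1 - 1L)
    seq <- as.character(Biostrings::subseq(genome[[sq]], g0 + 1L, g1))
  } else {
    ## transcript runs genomically leftward; window pos i -> g = ghigh - i
    ghigh <- min(glen - 1L, ss + up)                  # most-upstream base
    glow  <- max(0L, ss - down_eff + 1L)              # most-downstream base
    if (ghigh < glow) stopf("scan window empty for unit %s", unit$unit_id)
    offsets <- seq.int(ghigh, glow)
    seq <- revcomp(as.character(Biostrings::subseq(genome[[sq]], glow + 1L, ghigh + 1L)))
  }
  anchor <- match(ss, offsets) - 1L
  clipped <- length(offsets) < up + down_eff
  list(seq = seq, offsets = as.integer(offsets), anchor = anchor,
       clipped = clipped)
}
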