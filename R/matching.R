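## Identified-vs-derived matching, per-genome accounting, and the pipeline
## orchestrator.

unit_key <- function(units, i) {
  m <- units$hairpins[[i]]
  paste(sort(paste(m$start, m$end, sep = "-")), collapse = ";")
}

#' Classify an identified-vs-derived unit pair
#'
#' `full` when the two units have identical hairpin membership; `part` when
#' their spans overlap by at least `min_overlap` bases but membership
#' differs; `ahead` when the spans are disjoint with the identified unit
#' upstream (nearer the stop codon). The symmetric disjoint case cannot occur
#' for a minimal-start identified unit and raises an internal consistency
#' error.
#'
#' @param units A unit `data.frame` from [group_units()] for one IR.
#' @param identified,derived Row indices into `units`.
#' @param min_overlap Minimum shared bases for a `part` match (default 1).
#' @return `"full"`, `"part"` or `"ahead"`.
#' @export
match_units <- function(units, identified, derived, min_overlap = 1L) {
  if (identical(identified, derived) ||
      unit_key(units, identified) == unit_key(units, derived)) {
    return("full")
  }
  s1 <- units$span_start[identified]; e1 <- units$span_end[identified]
  s2 <- units$span_start[derived];    e2 <- units$span_end[derived]
  overlap <- min(e1, e2) - max(s1, s2)
  if (overlap >= min_overlap) return("part")
  if (s1 < s2) return("ahead")
  stopf("internal inconsistency: identified unit downstream of derived unit")
}

#' Does any unit of the IR co-locate with the derived unit?
#'
#' Alternate-site matching: TRUE iff any unit (not only the identified one)
#' fully or partially overlaps the derived unit's span. Implied by a
#' full/part primary match, so the alternate match rate is never below the
#' primary rate.
#'
#' @inheritParams match_units
#' @param derived Row index of the derived unit.
#' @return Logical.
#' @export
alternate_match <- function(units, derived, min_overlap = 1L) {
  if (is.na(derived) || nrow(units) == 0L) return(FALSE)
  s2 <- units$span_start[derived]; e2 <- units$span_end[derived]
  any(pmin(units$span_end, e2) - pmax(units$span_start, s2) >= min_overlap)
}

#' Percent of derived units matched (full or part), half-up rounding
#'
#' @param ahead,part,full Counts of the three match categories (their sum is
#'   the number of IRs with both an identified and a derived unit).
#' @return Integer percent `round(100 * (part + full) / (ahead + part +
#'   full))` with half-up rounding, or `NA` when the denominator is zero.
#' @export
match_percent <- function(ahead, part, full) {
  derived <- ahead + part + full
  ifelse(derived > 0, round_half_up(100 * (part + full) / derived), NA_real_)
}

#' Aggregate per-IR results into a genome report
#'
#' Produces the three accounting tables: identified-unit counts by kind,
#' derived-unit counts by strand, kind and zone (Zone 3 excluded upstream),
#' and the ahead/part/full match accounting with the percent of correctly
#' matched sites.
#'
#' @param per_ir A `data.frame` with one row per analysed IR, columns
#'   `strand`, `identified_kind`, `derived_kind`, `derived_zone`,
#'   `match_category` (NA where a unit is absent).
#' @param genome_id Label for the report rows.
#' @return A list of class `itt_report`: `identified`, `zonal`, `matching`.
#' @export
summarize_matches <- function(per_ir, genome_id = "genome") {
  ident <- per_ir$identified_kind
  identified <- data.frame(
    genome = genome_id,
    identified = sum(!is.na(ident)),
    cluster = sum(ident == "cluster", na.rm = TRUE),
    single = sum(ident == "single", na.rm = TRUE)
  )
  dk <- !is.na(per_ir$derived_kind)
  zonal <- as.data.frame(table(
    strand = per_ir$strand[dk],
    kind = per_ir$derived_kind[dk],
    zone = per_ir$derived_zone[dk]), stringsAsFactors = FALSE)
  names(zonal)[names(zonal) == "Freq"] <- "count"
  mc <- per_ir$match_category
  ahead <- sum(mc == "ahead", na.rm = TRUE)
  part <- sum(mc == "part", na.rm = TRUE)
  full <- sum(mc == "full", na.rm = TRUE)
  matching <- data.frame(
    genome = genome_id,
    filtered = nrow(per_ir),
    identified = sum(!is.na(ident)),
    derived = ahead + part + full,
    ahead = ahead, part = part, full = full,
    percent_correct = match_percent(ahead, part, full)
  )
  structure(list(identified = identified, zonal = zonal, matching = matching),
            class = "itt_report")
}

#' @export
print.itt_report <- function(x, ...) {
  cat("Identified termination units:\n"); print(x$identified)
  cat("\nRNA-seq derived units by strand/kind/zone:\n"); print(x$zonal)
  cat("\nMatch accounting:\n"); print(x$matching)
  invisible(x)
}

#' Run the full termination-site inference pipeline
#'
#' Orchestrates: IR computation, coverage screening, hairpin scanning with the
#' genome-wide stem/loop histogram rejection, positive-slope-region detection,
#' unit grouping, identified/derived selection, matching, and poly-U/A trail
#' search downstream of the identified unit.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param units An `itt_units` data.frame.
#' @param tracks Named list of [depth_track()]s (`"+"`, `"-"`).
#' @param slope_cfg,scan_cfg,screen_cfg Stage configurations.
#' @param gap_max Cluster gap threshold in bases (default 15).
#' @param up,down Scan-window extent around the stop site (defaults 20/270).
#' @param terminal_max Terminal IR cap (default 3000).
#' @param genome_id Report label.
#' @param out_dir Optional directory; when given, the IR audit, per-IR table,
#'   hairpin table and a run log of every parameter are written as TSV/text.
#' @return A list of class `itt_result`: `irs`, `audit`, `hairpins` (all
#'   retained hairpins, window coordinates plus genomic), `per_ir` (one row
#'   per screened IR), `report` (an `itt_report`), `params`.
#' @export
run_pipeline <- function(genome, units, tracks,
                         slope_cfg = slope_config(),
                         scan_cfg = hairpin_scan_config(),
                         screen_cfg = screen_config(),
                         gap_max = 15L, up = 20L, down = 270L,
                         terminal_max = 3000L,
                         genome_id = names(genome)[1L], out_dir = NULL) {
  irs <- compute_irs(units, genome, terminal_max = terminal_max)
  scr <- screen_irs(irs, tracks, screen_cfg, units)
  kept <- scr$kept
  if (nrow(kept) == 0L) stopf("screening removed every IR")

  ## pass 1: windows + hairpin enumeration, pooled for the histogram filter
  windows <- vector("list", nrow(kept))
  hp_all <- vector("list", nrow(kept))
  for (i in seq_len(nrow(kept))) {
    u <- units[match(kept$unit_id[i], units$unit_id), ]
    win <- extract_scan_window(u, genome, up = up, down = down,
                               max_down = kept$length[i] + 3L)
    hp <- enumerate_hairpins(win$seq, scan_cfg)
    if (nrow(hp)) hp$unit_id <- kept$unit_id[i]
    windows[[i]] <- win
    hp_all[[i]] <- hp
  }
  pooled <- do.call(rbind, hp_all[vapply(hp_all, nrow, 1L) > 0])
  if (is.null(pooled)) pooled <- enumerate_hairpins("", scan_cfg)
  hf <- histogram_filter(pooled, tail_fraction = 0.05)
  retained <- hf$kept

  ## pass 2: per-IR units, pos region, matching, trails
  rows <- vector("list", nrow(kept))
  for (i in seq_len(nrow(kept))) {
    ir <- kept[i, ]
    u <- units[match(ir$unit_id, units$unit_id), ]
    win <- windows[[i]]
    hp <- retained[retained$unit_id == ir$unit_id, , drop = FALSE]
    ## window -> IR-relative coordinates (0 at the 3' CDS end); hairpins
    ## starting upstream of the stop codon lie in the CDS and are not
    ## termination-unit candidates
    if (nrow(hp)) {
      shift <- win$anchor + 3L
      hp$start <- hp$start - shift
      hp$end <- hp$end - shift
      hp <- hp[hp$start >= -3L, , drop = FALSE]
    }
    tu <- group_units(hp, gap_max = gap_max)
    ident <- identified_unit(tu, stop_rel = -3L)
    det <- detect_termination(u, ir, tracks[[ir$strand]], slope_cfg)
    der <- if (!is.null(det$pos)) derived_unit(tu, det$pos, ir$length) else NA_integer_
    cat_ <- if (!is.na(ident) && !is.na(der)) {
      match_units(tu, ident, der)
    } else NA_character_
    alt <- if (!is.na(der)) alternate_match(tu, der) else NA
    dinfo <- if (!is.na(der)) {
      unit_distance(tu$span_start[der], tu$span_end[der], det$pos, ir$length)
    } else NULL
    ## poly-U/A trails downstream of the identified unit's last hairpin
    poly <- rep(NA_integer_, 3L)
    if (!is.na(ident) && tu$span_end[ident] >= 0L &&
        tu$span_end[ident] < ir$length) {
      downstream <- substring(ir$seq_tx, tu$span_end[ident] + 1L, ir$length)
      for (k in 0:2) {
        pat <- find_poly(downstream, "AU", min_len = 3L, max_mismatch = k)
        if (!is.null(pat)) poly[k + 1L] <- pattern_distance(tu$span_end[ident], pat)
      }
    }
    rows[[i]] <- data.frame(
      unit_id = ir$unit_id, strand = ir$strand,
      ir_start = ir$ir_start, ir_end = ir$ir_end, ir_len = ir$length,
      n_hairpins = nrow(hp), n_units = nrow(tu),
      pos_detected = !is.null(det$pos),
      pos_st = if (!is.null(det$pos)) det$pos$pos_st else NA_integer_,
      pos_end = if (!is.null(det$pos)) det$pos$pos_end else NA_integer_,
      n_alternate_pos = length(det$alternates),
      identified_kind = if (!is.na(ident)) tu$kind[ident] else NA_character_,
      identified_start = if (!is.na(ident)) tu$span_start[ident] else NA_integer_,
      identified_end = if (!is.na(ident)) tu$span_end[ident] else NA_integer_,
      derived_kind = if (!is.na(der)) tu$kind[der] else NA_character_,
      derived_start = if (!is.na(der)) tu$span_start[der] else NA_integer_,
      derived_end = if (!is.na(der)) tu$span_end[der] else NA_integer_,
      derived_zone = if (!is.null(dinfo)) dinfo$zone else NA_integer_,
      derived_n = if (!is.null(dinfo)) dinfo$n else NA_integer_,
      match_category = cat_, alternate_match = alt,
      poly_au_k0 = poly[1L], poly_au_k1 = poly[2L], poly_au_k2 = poly[3L],
      stringsAsFactors = FALSE
    )
  }
  per_ir <- do.call(rbind, rows)
  report <- summarize_matches(per_ir, genome_id)
  params <- list(slope = unclass(slope_cfg),
                 scan = unclass(scan_cfg)[c("stem_min", "stem_max", "loop_min",
                                            "loop_max", "allow_gu_wobble",
                                            "delta_g_max")],
                 screen = unclass(screen_cfg), gap_max = gap_max,
                 up = up, down = down, terminal_max = terminal_max)
  res <- structure(list(irs = irs, audit = scr$audit, hairpins = retained,
                        removed_cells = hf$removed_cells, per_ir = per_ir,
                        report = report, params = params),
                   class = "itt_result")
  if (!is.null(out_dir)) write_result(res, out_dir)
  res
}

#' @export
print.itt_result <- function(x, ...) {
  cat(sprintf("ittscan result: %d IRs screened in, %d hairpins retained\n",
              nrow(x$per_ir), nrow(x$hairpins)))
  print(x$report)
  invisible(x)
}

write_result <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) write.table(d, file.path(out_dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wt(res$audit, "ir_audit.tsv")
  wt(res$per_ir, "per_ir.tsv")
  wt(res$hairpins, "hairpins.tsv")
  wt(res$report$matching, "match_report.tsv")
  p <- unlist(res$params)
  writeLines(paste(names(p), p, sep = "\t"), file.path(out_dir, "run_log.tsv"))
  invisible(out_dir)
}

#' Score pipeline output against planted synthetic truth
#'
#' For every analysed IR whose unit has a planted terminator, the prediction
#' counts as recovered when the identified-vs-derived match category is full
#' or part AND the identified unit's span overlaps the planted span or lies
#' within `tol` bases of it.
#'
#' @param result An `itt_result` from [run_pipeline()].
#' @param truth The truth `data.frame` from [simulate_genome()].
#' @param tol Span tolerance in bases (default 25).
#' @return A list: `n` (IRs evaluated), `recovered`, `rate`, and the per-IR
#'   logical vector `hit`.
#' @export
evaluate_against_truth <- function(result, truth, tol = 25L) {
  per <- result$per_ir
  m <- match(per$unit_id, truth$unit_id)
  ok <- !is.na(m)
  per <- per[ok, , drop = FALSE]
  tr <- truth[m[ok], , drop = FALSE]
  matched <- !is.na(per$match_category) & per$match_category %in% c("full", "part")
  gap <- pmax(per$identified_start, tr$term_unit_start) -
         pmin(per$identified_end, tr$term_unit_end)
  hit <- matched & !is.na(gap) & gap <= tol
  list(n = nrow(per), recovered = sum(hit),
       rate = if (nrow(per)) sum(hit) / nrow(per) else NA_real_, hit = hit)
}
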