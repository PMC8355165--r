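## Published 13-genome benchmark accounting table shipped with the package.

#' Benchmark match-count table for 13 bacterial genomes
#'
#' Per-genome counts of screened (filtered) IRs, IRs with an identified unit,
#' IRs with an RNA-seq derived unit, and the ahead/part/full match split,
#' from a published 13-genome survey of bacterial intrinsic terminators,
#' together with the printed percent-correct column. Used as a worked
#' arithmetic example for [match_percent()] and in the acceptance checks; the
#' `Sigma` row holds the column totals.
#'
#' @return A `data.frame` with columns `organism`, `label`, `filtered_irs`,
#'   `identified`, `derived`, `ahead`, `part_match`, `full_match`,
#'   `percent_printed`.
#' @export
benchmark_match_counts <- function() {
  path <- system.file("extdata", "bacterial_itt_match_counts.tsv",
                      package = "ittscan", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Benchmark hairpin totals
#'
#' Genome-wide hairpin accounting from the same survey: total stable hairpins
#' predicted across all screened IRs, the number of cluster units they form,
#' the hairpins left as singles, and the identified-cluster figures (units
#' and member hairpins). The average hairpins per cluster follow by division.
#'
#' @return A named list of counts.
#' @export
benchmark_hairpin_totals <- function() {
  list(total_hairpins = 677943L,
       cluster_units = 131610L,
       single_hairpins = 25696L,
       identified_cluster_units = 7394L,
       identified_cluster_hairpins = 22519L)
}
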