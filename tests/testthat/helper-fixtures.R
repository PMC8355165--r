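## Shared fixture builders.

validate_units_for_test <- function(df) {
  if (is.null(df$stop_site)) {
    df$stop_site <- ifelse(df$strand == "+", df$cds_end - 3L, df$cds_start + 2L)
  }
  ittscan:::validate_units(df)
}

## constant depth track helper
flat_track <- function(strand, depth) {
  depth_track("chr", strand, depth)
}

## a tiny SAM file: header plus supplied alignment lines
write_sam <- function(lines, ln = 500L) {
  f <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:chr\tLN:%d", ln), lines), f)
  f
}

sam_line <- function(qname, flag, pos, mapq, len, tlen, mpos = pos) {
  sprintf("%s\t%d\tchr\t%d\t%d\t%dM\t=\t%d\t%d\t%s\t*",
          qname, flag, pos, mapq, len, mpos, tlen,
          paste(rep("A", len), collapse = ""))
}
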