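# Internal microsatellite / simple-repeat detector, used by the SNP
# filter when no RepeatMasker annotation supplies Simple_repeat
# intervals.

#' Detect perfect tandem repeats and homopolymer runs
#'
#' Finds maximal perfect tandem repeats with unit length up to
#' `unit_max` spanning at least `min_span` bp, plus homopolymer runs of
#' at least 8 bp, and returns the merged intervals.
#'
#' @param sequence DNA text.
#' @param unit_max maximum repeat unit length (default 6).
#' @param min_span minimum tandem span in bp (default 12).
#' @return Data frame of 0-based half-open intervals (`start`, `end`),
#'   merged and sorted.
#' @export
detect_simple_repeats <- function(sequence, unit_max = 6L,
                                  min_span = 12L) {
  n <- nchar(sequence)
  s <- charToRaw(sequence)
  out_s <- integer(0); out_e <- integer(0)
  for (u in seq_len(min(unit_max, max(n - 1L, 0L)))) {
    need <- if (u == 1L) max(8L, u + 1L) else min_span
    if (n < need) next
    eq <- s[seq_len(n - u)] == s[(u + 1L):n]  # s[i] == s[i+u]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & (r$lengths + u) >= need)
    for (k in hit) {
      span_start <- starts[k] - 1L             # 0-based
      span_end <- ends[k] + u                  # half-open
      out_s <- c(out_s, span_start)
      out_e <- c(out_e, span_end)
    }
  }
  merge_intervals(out_s, out_e)
}
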