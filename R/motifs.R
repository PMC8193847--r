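# PRDM9-style motif scanning and repeat-overlap classification.
# Motifs are literal or IUPAC-degenerate DNA patterns searched
# strand-explicitly on the forward strand; `N` in the subject never
# matches.  Overlapping occurrences are all reported.

#' Scan a sequence for motif occurrences
#'
#' @param sequence DNA text (may contain `N`; `N` matches nothing).
#' @param motifs data frame with columns `id` and `pattern` (IUPAC DNA
#'   text), e.g. [prdm9_motifs()].
#' @return Data frame of hits sorted by position, with columns `id`,
#'   `position` (0-based start), `matched` (the matched text).
#' @export
scan_motifs <- function(sequence, motifs) {
  stopifnot(all(c("id", "pattern") %in% names(motifs)))
  subj <- Biostrings::DNAString(sequence)
  out <- lapply(seq_len(nrow(motifs)), function(i) {
    m <- Biostrings::matchPattern(motifs$pattern[i], subj,
                                  fixed = "subject")
    if (length(m) == 0)
      return(data.frame(id = character(), position = integer(),
                        matched = character(), stringsAsFactors = FALSE))
    txt <- as.character(m)
    keep <- !grepl("N", txt, fixed = TRUE)
    data.frame(id = motifs$id[i],
               position = IRanges::start(m)[keep] - 1L,
               matched = txt[keep], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$position, out$id), , drop = FALSE]
}

#' Assign motif hits to overlapping repeat features
#'
#' Each hit is assigned to the feature covering the majority of its
#' span; ties go to the feature with the lower start, and hits with no
#' overlapping feature are labelled `"Non-repeat region"`.
#'
#' @param hits data frame from [scan_motifs()].
#' @param features annotation data frame (needs `q_start`, `q_end`,
#'   `rep_name`, `rep_class_family`).
#' @return List with `hits` (the input plus `category` and
#'   `rep_class_family` columns) and `matrix`, a category x motif count
#'   matrix whose column sums equal the per-motif hit counts.
#' @export
classify_motif_overlap <- function(hits, features) {
  n <- nrow(hits)
  cat_name <- rep("Non-repeat region", n)
  cat_cf <- rep("", n)
  if (n && nrow(features)) {
    fo <- order(features$q_start)
    fs <- features$q_start[fo]; fe <- features$q_end[fo]
    for (i in seq_len(n)) {
      h0 <- hits$position[i]
      h1 <- h0 + nchar(hits$matched[i])
      ov <- pmin(fe, h1) - pmax(fs, h0)
      if (any(ov > 0)) {
        # largest overlap wins; ties go to the lower-start feature
        # (features are sorted by start, so which.max picks it)
        b <- which.max(ov)
        cat_name[i] <- features$rep_name[fo[b]]
        cat_cf[i] <- features$rep_class_family[fo[b]]
      }
    }
  }
  hits$category <- cat_name
  hits$rep_class_family <- cat_cf
  motifs <- unique(hits$id)
  cats <- unique(cat_name)
  mat <- matrix(0L, nrow = length(cats), ncol = length(motifs),
                dimnames = list(cats, motifs))
  if (n) for (i in seq_len(n))
    mat[cat_name[i], hits$id[i]] <- mat[cat_name[i], hits$id[i]] + 1L
  list(hits = hits, matrix = mat)
}

#' Survey motifs over a genomic interval with repeat classification
#'
#' Scans `sequence[start, end)` for all motifs and tabulates hits by
#' the repeat feature they fall in, in the style of a motif-by-repeat
#' count table with a `"Non-repeat region"` row and per-motif totals.
#'
#' @param sequence DNA text (full sequence; coordinates below refer to
#'   it).
#' @param features annotation data frame on the same coordinates.
#' @param motifs motif data frame (default [prdm9_motifs()] minus the
#'   degenerate 13-mer).
#' @param start,end 0-based half-open interval to survey (default:
#'   whole sequence).
#' @return List with `hits`, `matrix` and `totals` (named per-motif hit
#'   counts).
#' @export
motif_survey <- function(sequence, features,
                         motifs = prdm9_motifs()[1:4, ],
                         start = 0L, end = nchar(sequence)) {
  stopifnot(start >= 0, end <= nchar(sequence), start < end)
  sub <- substr(sequence, start + 1L, end)
  hits <- scan_motifs(sub, motifs)
  hits$position <- hits$position + start
  keep <- features$q_end > start & features$q_start < end
  cl <- classify_motif_overlap(hits, features[keep, , drop = FALSE])
  totals <- vapply(motifs$id, function(m) sum(cl$hits$id == m),
                   integer(1))
  list(hits = cl$hits, matrix = cl$matrix, totals = totals)
}
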