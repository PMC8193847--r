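# File-format boundaries: FASTA (via Biostrings), BED (0-based
# half-open), plain TSV with header.  Internal coordinates are always
# 0-based half-open; conversions happen here and in read_repeatmasker().

#' Read and write FASTA files
#'
#' Thin wrappers around Biostrings that present sequences as named
#' character vectors, the representation used throughout the package.
#'
#' @param path file path.
#' @param seqs named character vector of DNA sequences.
#' @return `read_fasta()` returns a named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read and write BED intervals
#'
#' Coordinates are 0-based half-open on disk and in memory.  Only the
#' first four/five columns are used: chrom, start, end, name, score.
#'
#' @param df data frame with columns `chrom`, `start`, `end` and
#'   optionally `name`, `score`.
#' @param path file path.
#' @return `read_bed()` returns a data frame.
#' @export
write_bed <- function(df, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  cols <- intersect(c("chrom", "start", "end", "name", "score"), names(df))
  write.table(df[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character()))
  x <- read.table(path, sep = "\t", header = FALSE,
                  colClasses = "character", fill = TRUE)
  names(x)[1:3] <- c("chrom", "start", "end")
  if (ncol(x) >= 4) names(x)[4] <- "name"
  if (ncol(x) >= 5) names(x)[5] <- "score"
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  x
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, comment.char = "", quote = "", ...)
}
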