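# RepeatMasker .out dialect: 3 header lines, then whitespace-delimited
# rows of 14-15 columns (plus an optional trailing '*' overlap flag).
# Query coordinates are 1-based inclusive on disk and converted to
# 0-based half-open on parse.  Strand 'C' denotes the minus strand; it
# is preserved verbatim in the `strand` column.

#' Parse a RepeatMasker .out annotation file
#'
#' @param path path to a `.out` file (or a connection).
#' @return Data frame with columns `sw_score`, `pct_div`, `pct_del`,
#'   `pct_ins`, `query`, `q_start`, `q_end` (0-based half-open),
#'   `strand` (`+`/`C`), `rep_name`, `rep_class_family`, `rep_start`,
#'   `rep_end`, `rep_left`, `feature_id`, in file order.
#' @export
read_repeatmasker <- function(path) {
  lines <- readLines(path)
  empty_cols <- function() data.frame(
    sw_score = integer(), pct_div = numeric(), pct_del = numeric(),
    pct_ins = numeric(), query = character(), q_start = integer(),
    q_end = integer(), strand = character(), rep_name = character(),
    rep_class_family = character(), rep_start = character(),
    rep_end = integer(), rep_left = character(), feature_id = integer(),
    stringsAsFactors = FALSE)
  if (length(lines) <= 3) return(empty_cols())
  body <- lines[-(1:3)]
  body_no <- which(nzchar(trimws(body)))
  if (!length(body_no)) return(empty_cols())
  rows <- lapply(body_no, function(i) {
    f <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(f) == 16L && f[16] == "*") f <- f[1:15]
    if (length(f) == 15L && f[15] == "*") f <- f[1:14]
    if (length(f) < 14L)
      stop("malformed RepeatMasker row at line ", i + 3L, ": ",
           body[i])
    f
  })
  n <- length(rows)
  get <- function(k) vapply(rows, function(f)
    if (length(f) >= k) f[k] else NA_character_, "")
  suppress <- function(x) suppressWarnings(as.numeric(x))
  qs <- as.integer(get(6)); qe <- as.integer(get(7))
  if (any(is.na(qs) | is.na(qe) | qs > qe)) {
    bad <- which(is.na(qs) | is.na(qe) | qs > qe)[1]
    stop("malformed RepeatMasker coordinates at line ",
         body_no[bad] + 3L)
  }
  data.frame(
    sw_score = as.integer(get(1)),
    pct_div = suppress(get(2)), pct_del = suppress(get(3)),
    pct_ins = suppress(get(4)),
    query = get(5),
    q_start = qs - 1L, q_end = qe,
    strand = get(9),
    rep_name = get(10), rep_class_family = get(11),
    rep_start = get(12),
    rep_end = as.integer(get(13)),
    rep_left = get(14),
    feature_id = {
      id <- suppressWarnings(as.integer(get(15)))
      ifelse(is.na(id), seq_len(n), id)
    },
    stringsAsFactors = FALSE)
}

#' Write features in the RepeatMasker .out dialect
#'
#' Inverse of [read_repeatmasker()]: coordinates are converted back to
#' 1-based inclusive and a standard 3-line header is emitted.
#'
#' @param features data frame as returned by [read_repeatmasker()]
#'   (missing numeric columns are filled with placeholders).
#' @param path output path.
#' @export
write_repeatmasker <- function(features, path) {
  n <- nrow(features)
  fill <- function(col, default) {
    if (!is.null(features[[col]])) features[[col]] else rep(default, n)
  }
  hdr <- c(
    paste("  SW  perc perc perc  query     position in query    ",
          "matching   repeat          position in repeat"),
    paste("score  div. del. ins.  sequence  begin end    (left) ",
          "repeat     class/family    begin  end (left)   ID"),
    "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (n == 0) return(invisible(path))
  qleft <- paste0("(", fill("q_left", 0L), ")")
  lines <- sprintf("%5s %5.1f %4.1f %4.1f %-10s %8d %8d %8s %s %-15s %-18s %6s %6d %6s %4d",
                   as.character(fill("sw_score", 1000L)),
                   as.numeric(fill("pct_div", 0)),
                   as.numeric(fill("pct_del", 0)),
                   as.numeric(fill("pct_ins", 0)),
                   as.character(features$query),
                   features$q_start + 1L, features$q_end, qleft,
                   as.character(fill("strand", "+")),
                   as.character(features$rep_name),
                   as.character(features$rep_class_family),
                   as.character(fill("rep_start", 1L)),
                   as.integer(fill("rep_end",
                                   features$q_end - features$q_start)),
                   as.character(fill("rep_left", "(0)")),
                   as.integer(fill("feature_id", seq_len(n))))
  writeLines(lines, con)
  invisible(path)
}
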