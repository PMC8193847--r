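# Small shared helpers: local RNG scope, coordinate maps, interval math.

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's
# RNG state afterwards so simulation calls do not perturb user code.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a per-stage child seed from a global seed; keeps values < 2^31.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  (as.integer(seed) %% 1000003L) * 1009L + sum(utf8ToInt(stage)) %% 1000L
}

## ---- coordinate maps -------------------------------------------------

#' Convert positions between the base frame and a haplotype frame
#'
#' The simulator builds every haplotype on a common base coordinate frame
#' and then applies insertions/deletions.  A coordinate map is a data
#' frame of copied segments (`base_start`, `base_end`, `hap_start`) with
#' strictly increasing starts; it defines a monotone partial mapping
#' between the two frames.
#'
#' @param map coordinate map data frame as stored in a
#'   [simulate_panel()] truth set (`truth$coord_maps[[hap]]`).
#' @param pos integer vector of 0-based positions.
#' @return Integer vector of mapped 0-based positions; `NA` where the
#'   position falls in sequence absent from the target frame (deleted
#'   span, or inserted sequence when mapping back to base).
#' @export
map_to_hap <- function(map, pos) {
  idx <- findInterval(pos, map$base_start)
  out <- rep(NA_integer_, length(pos))
  ok <- idx >= 1
  ok[ok] <- pos[ok] < map$base_end[idx[ok]]
  out[ok] <- map$hap_start[idx[ok]] + (pos[ok] - map$base_start[idx[ok]])
  out
}

#' @rdname map_to_hap
#' @export
map_to_base <- function(map, pos) {
  hap_end <- map$hap_start + (map$base_end - map$base_start)
  idx <- findInterval(pos, map$hap_start)
  out <- rep(NA_integer_, length(pos))
  ok <- idx >= 1
  ok[ok] <- pos[ok] < hap_end[idx[ok]]
  out[ok] <- map$base_start[idx[ok]] + (pos[ok] - map$hap_start[idx[ok]])
  out
}

# identity coordinate map for a sequence of length n
identity_map <- function(n) {
  data.frame(base_start = 0L, base_end = as.integer(n), hap_start = 0L)
}

## ---- intervals (0-based half-open, plain matrices) -------------------

# merge overlapping/adjacent intervals; x is a 2-col matrix [start, end)
merge_intervals <- function(starts, ends) {
  if (length(starts) == 0)
    return(data.frame(start = integer(), end = integer()))
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  out_s <- starts[1]; out_e <- ends[1]; k <- 1L
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= out_e[k]) {
      out_e[k] <- max(out_e[k], ends[i])
    } else {
      k <- k + 1L
      out_s[k] <- starts[i]; out_e[k] <- ends[i]
    }
  }
  data.frame(start = out_s, end = out_e)
}

# TRUE for positions lying in any [start, end) interval
in_intervals <- function(pos, starts, ends) {
  if (length(starts) == 0) return(rep(FALSE, length(pos)))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  idx <- findInterval(pos, starts)
  ok <- idx >= 1
  ok[ok] <- pos[ok] < ends[idx[ok]]
  ok
}

# distance from positions to nearest point of any interval (0 if inside)
dist_to_intervals <- function(pos, starts, ends) {
  if (length(starts) == 0) return(rep(Inf, length(pos)))
  vapply(pos, function(p) {
    d <- ifelse(p < starts, starts - p, ifelse(p >= ends, p - ends + 1L, 0L))
    min(d)
  }, numeric(1))
}

## ---- sequence helpers ------------------------------------------------

# random DNA of length n as a character scalar (uses current RNG stream)
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

seq_to_raw <- function(s) charToRaw(s)
raw_to_seq <- function(r) rawToChar(r)

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
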