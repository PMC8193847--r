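# MUM-style anchoring for near-identical long sequences: exact matches
# seeded by k-mers unique in both sequences, extended maximally, then
# chained co-linearly by weighted longest-increasing-subsequence.

#' Find maximal unique exact matches between two sequences
#'
#' Seeds are k-mers that occur exactly once in each sequence and
#' contain no `N`; each seed is extended maximally left and right
#' (stopping at a mismatch, an `N`, or a sequence end) and duplicate
#' extensions are collapsed.
#'
#' @param seq_a,seq_b DNA text over `A,C,G,T,N`.
#' @param k k-mer size (default 31; must be >= 16).
#' @return Data frame of anchors sorted by `a_pos`: columns `a_pos`,
#'   `b_pos` (0-based starts) and `length`.  Empty when either
#'   sequence is shorter than `k`.
#' @export
find_anchors <- function(seq_a, seq_b, k = 31L) {
  stopifnot(k >= 16L)
  na <- nchar(seq_a); nb <- nchar(seq_b)
  empty <- data.frame(a_pos = integer(), b_pos = integer(),
                      length = integer())
  if (na < k || nb < k) return(empty)
  ra <- charToRaw(seq_a); rb <- charToRaw(seq_b)
  rawN <- charToRaw("N")

  kmer_info <- function(s, r, n) {
    starts <- 1:(n - k + 1L)
    km <- substring(s, starts, starts + k - 1L)
    # k-mers containing N, via cumulative N counts
    cn <- cumsum(r == rawN)
    nfree <- (cn[starts + k - 1L] -
                c(0L, cn)[starts]) == 0L
    uni <- !(duplicated(km) | duplicated(km, fromLast = TRUE))
    list(km = km, ok = nfree & uni)
  }
  ia <- kmer_info(seq_a, ra, na)
  ib <- kmer_info(seq_b, rb, nb)
  cand <- which(ia$ok)
  hit <- match(ia$km[cand], ib$km)
  keep <- !is.na(hit) & ib$ok[ifelse(is.na(hit), 1L, hit)]
  a0 <- cand[keep] - 1L          # 0-based seed starts
  b0 <- hit[keep] - 1L
  if (!length(a0)) return(empty)

  # merge overlapping seeds on the same diagonal
  diag <- b0 - a0
  o <- order(diag, a0)
  a0 <- a0[o]; b0 <- b0[o]; diag <- diag[o]
  new_run <- c(TRUE, diff(a0) > k | diff(diag) != 0)
  grp <- cumsum(new_run)
  run_a <- tapply(a0, grp, min)
  run_e <- tapply(a0, grp, max) + k
  run_d <- tapply(diag, grp, function(x) x[1])

  # maximal extension (chunked raw comparison)
  ext <- function(apos, bpos, step) {
    # returns number of equal non-N chars extending from (apos,bpos)
    # in direction `step` (+1 right of given pos, -1 left), 1-based
    total <- 0L
    repeat {
      w <- 256L
      if (step > 0) {
        la <- na - apos + 1L; lb <- nb - bpos + 1L
      } else {
        la <- apos; lb <- bpos
      }
      w <- min(w, la, lb)
      if (w <= 0L) return(total)
      idx_a <- apos + step * (0:(w - 1L))
      idx_b <- bpos + step * (0:(w - 1L))
      ok <- ra[idx_a] == rb[idx_b] & ra[idx_a] != rawN
      bad <- which(!ok)
      if (length(bad)) return(total + bad[1] - 1L)
      total <- total + w
      apos <- apos + step * w; bpos <- bpos + step * w
    }
  }
  n_runs <- length(run_a)
  out_a <- integer(n_runs); out_b <- integer(n_runs)
  out_l <- integer(n_runs)
  for (i in seq_len(n_runs)) {
    s <- run_a[[i]]; e <- run_e[[i]]; d <- run_d[[i]]
    left <- ext(s, s + d, -1L)            # chars before 0-based s
    right <- ext(e + 1L, e + d + 1L, +1L) # chars from 0-based e on
    out_a[i] <- s - left
    out_b[i] <- s + d - left
    out_l[i] <- (e - s) + left + right
  }
  anch <- unique(data.frame(a_pos = out_a, b_pos = out_b,
                            length = out_l))
  anch <- anch[order(anch$a_pos, anch$b_pos), , drop = FALSE]
  rownames(anch) <- NULL
  anch
}

#' Chain anchors into a co-linear set
#'
#' Selects the maximum-total-length subset of anchors that is strictly
#' increasing in both coordinates (weighted longest increasing
#' subsequence on anchor lengths), then trims any residual overlap
#' between consecutive chained anchors so they are disjoint in both
#' sequences.
#'
#' @param anchors data frame from [find_anchors()].
#' @return Data frame of disjoint chained anchors (`a_pos`, `b_pos`,
#'   `length`), sorted.
#' @export
chain_anchors <- function(anchors) {
  n <- nrow(anchors)
  if (n == 0) return(anchors)
  o <- order(anchors$a_pos, anchors$b_pos)
  a <- anchors$a_pos[o]; b <- anchors$b_pos[o]
  len <- anchors$length[o]
  score <- numeric(n); prev <- integer(n)
  for (i in seq_len(n)) {
    score[i] <- len[i]; prev[i] <- 0L
    if (i > 1) {
      ok <- which(a[1:(i - 1)] < a[i] & b[1:(i - 1)] < b[i])
      if (length(ok)) {
        j <- ok[which.max(score[ok])]
        if (score[j] + len[i] > score[i]) {
          score[i] <- score[j] + len[i]
          prev[i] <- j
        }
      }
    }
  }
  i <- which.max(score)
  path <- integer(0)
  while (i != 0L) { path <- c(i, path); i <- prev[i] }
  ca <- a[path]; cb <- b[path]; cl <- len[path]
  # trim overlaps against the previous (already trimmed) anchor
  if (length(path) > 1) {
    for (i in 2:length(path)) {
      shift <- max(0L, ca[i - 1] + cl[i - 1] - ca[i],
                   cb[i - 1] + cl[i - 1] - cb[i])
      ca[i] <- ca[i] + shift; cb[i] <- cb[i] + shift
      cl[i] <- cl[i] - shift
    }
    keep <- cl > 0L
    ca <- ca[keep]; cb <- cb[keep]; cl <- cl[keep]
  }
  out <- data.frame(a_pos = ca, b_pos = cb, length = cl)
  # total anchor length of the selected (untrimmed) chain, for
  # comparison against exhaustive search
  attr(out, "untrimmed_weight") <- max(score)
  out
}
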