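# Global affine-gap alignment (match +1, mismatch -1, gap open -4,
# extension -1 per gapped position) used to close inter-anchor gaps,
# plus co-linear map construction and variant extraction.
#
# Op codes: M = aligned equal, X = aligned mismatch, I = bases present
# only in A (insertion relative to B), D = bases present only in B.

GAP_OPEN <- 4
GAP_EXT <- 1
NEG <- -1e9

# cached +1/-1 substitution matrix for Biostrings calls
sub_matrix <- local({
  m <- NULL
  function() {
    if (is.null(m))
      m <<- Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = FALSE)
    m
  }
})

#' Global affine-gap alignment of two short sequences
#'
#' Needleman-Wunsch with affine gaps (gap of length L costs
#' `4 + L`), vectorised row-wise.  `N` scores as a mismatch against
#' anything.  Intended for inter-anchor gaps; refuses problems over
#' 25e6 cells.
#'
#' @param a,b DNA text.
#' @return List with `score` and `ops`, a run-length encoded data
#'   frame (`op` in `M,X,I,D`, `len`).
#' @export
align_global <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  if (la == 0 && lb == 0)
    return(list(score = 0, ops = data.frame(op = character(),
                                            len = integer())))
  if (la == 0)
    return(list(score = -(GAP_OPEN + GAP_EXT * lb),
                ops = data.frame(op = "D", len = lb)))
  if (lb == 0)
    return(list(score = -(GAP_OPEN + GAP_EXT * la),
                ops = data.frame(op = "I", len = la)))
  if (as.double(la) * lb > 25e6)
    stop("alignment problem too large: ", la, " x ", lb)
  ra <- charToRaw(a); rb <- charToRaw(b)
  rawN <- charToRaw("N")
  ncol <- lb + 1L
  M <- matrix(NEG, la + 1L, ncol)
  I <- matrix(NEG, la + 1L, ncol)
  D <- matrix(NEG, la + 1L, ncol)
  M[1, 1] <- 0
  if (lb) D[1, 2:ncol] <- -(GAP_OPEN + GAP_EXT * (1:lb))
  jj <- 0:lb
  for (i in 1:la) {
    sj <- ifelse(rb == ra[i] & rb != rawN & ra[i] != rawN, 1, -1)
    prevM <- M[i, ]; prevI <- I[i, ]; prevD <- D[i, ]
    curM <- rep(NEG, ncol)
    curM[2:ncol] <- pmax(prevM[1:lb], prevI[1:lb], prevD[1:lb]) + sj
    curI <- pmax(prevM, prevD, prevI + GAP_OPEN) -
      (GAP_OPEN + GAP_EXT)
    curI[curI < NEG] <- NEG
    # horizontal (D) state via prefix max of max(M, I) + column index
    V <- pmax(curM, curI)
    Tv <- cummax(V + jj * GAP_EXT)
    curD <- rep(NEG, ncol)
    # D[i,j] = max_{k<j} (V[k] - open - ext*(j-k)) = cummax(V+k) - open - j
    curD[2:ncol] <- Tv[1:lb] - GAP_EXT * (1:lb) - GAP_OPEN
    curD[curD < NEG / 2] <- NEG
    M[i + 1L, ] <- curM; I[i + 1L, ] <- curI; D[i + 1L, ] <- curD
  }
  ## traceback
  i <- la + 1L; j <- ncol
  fin <- c(M = M[i, j], D = D[i, j], I = I[i, j])
  state <- names(fin)[which.max(fin)]
  score <- max(fin)
  ops <- character(0)
  eps <- 1e-7
  while (i > 1L || j > 1L) {
    if (state == "M") {
      sij <- if (ra[i - 1L] == rb[j - 1L] && ra[i - 1L] != rawN) 1 else -1
      ops <- c(ops, if (sij > 0) "M" else "X")
      tgt <- M[i, j] - sij
      prev <- c(M = M[i - 1L, j - 1L], D = D[i - 1L, j - 1L],
                I = I[i - 1L, j - 1L])
      state <- names(prev)[which(abs(prev - tgt) < eps)[1]]
      i <- i - 1L; j <- j - 1L
    } else if (state == "I") {
      ops <- c(ops, "I")
      if (abs(I[i - 1L, j] - GAP_EXT - I[i, j]) < eps) state <- "I"
      else if (abs(M[i - 1L, j] - GAP_OPEN - GAP_EXT - I[i, j]) < eps)
        state <- "M"
      else state <- "D"
      i <- i - 1L
    } else {
      ops <- c(ops, "D")
      if (abs(D[i, j - 1L] - GAP_EXT - D[i, j]) < eps) state <- "D"
      else if (abs(M[i, j - 1L] - GAP_OPEN - GAP_EXT - D[i, j]) < eps)
        state <- "M"
      else state <- "I"
      j <- j - 1L
    }
  }
  r <- rle(rev(ops))
  list(score = score,
       ops = data.frame(op = r$values, len = r$lengths,
                        stringsAsFactors = FALSE))
}

# run-length op encoding (M/X/I/D) from two gapped aligned strings
ops_from_gapped <- function(al_a, al_b) {
  ca <- strsplit(al_a, "")[[1]]
  cb <- strsplit(al_b, "")[[1]]
  op <- ifelse(cb == "-", "I", ifelse(ca == "-", "D",
                                      ifelse(ca == cb & ca != "N",
                                             "M", "X")))
  r <- rle(op)
  data.frame(op = r$values, len = r$lengths, stringsAsFactors = FALSE)
}

# affine-gap global alignment of one inter-anchor gap; the DP itself is
# delegated to Biostrings (same scoring as align_global)
gap_align <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  if (la == lb) {
    # ungapped optimality shortcut: any gapped alignment of
    # equal-length strings scores <= L - 11, the ungapped one
    # L - 2m, so m <= 5 guarantees ungapped is optimal; and when one
    # side is a pure N run no alignment can create matches at all
    ra <- charToRaw(a); rb <- charToRaw(b)
    rawN <- charToRaw("N")
    m <- sum(ra != rb | ra == rawN | rb == rawN)
    if (m <= 5 || all(ra == rawN) || all(rb == rawN))
      return(ops_from_gapped(a, b))
  }
  mat <- sub_matrix()
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = mat,
    gapOpening = 4, gapExtension = 1)
  ops_from_gapped(as.character(Biostrings::alignedPattern(pa)),
                  as.character(Biostrings::alignedSubject(pa)))
}

#' Close inter-anchor gaps into a co-linear map
#'
#' Gaps between chained anchors are globally aligned when both sides
#' are at most `max_gap` bp (or when one side is empty, which needs no
#' alignment) and labelled `aligned_gap`; larger two-sided gaps are
#' labelled `unaligned`.  The resulting map covers both sequences.
#'
#' @param seq_a,seq_b the sequences.
#' @param chain chained anchors from [chain_anchors()].
#' @param max_gap maximum gap side for alignment (default 5000).
#' @return An object of class `collinear_map`: list with `blocks`
#'   (data frame `a_start`, `a_end`, `b_start`, `b_end`, `kind`),
#'   `ops` (per-block alignment operations, `NULL` for matched /
#'   unaligned blocks) and `a_len`, `b_len`.
#' @export
close_gaps <- function(seq_a, seq_b, chain, max_gap = 5000L) {
  la <- nchar(seq_a); lb <- nchar(seq_b)
  blocks <- list(); ops <- list()
  add_block <- function(a0, a1, b0, b1, kind, op = NULL) {
    blocks[[length(blocks) + 1L]] <<- data.frame(
      a_start = a0, a_end = a1, b_start = b0, b_end = b1, kind = kind,
      stringsAsFactors = FALSE)
    ops[[length(blocks)]] <<- op
  }
  emit_gap <- function(a0, a1, b0, b1) {
    ga <- a1 - a0; gb <- b1 - b0
    if (ga == 0 && gb == 0) return(invisible())
    if (ga == 0) {
      add_block(a0, a1, b0, b1, "aligned_gap",
                data.frame(op = "D", len = gb))
    } else if (gb == 0) {
      add_block(a0, a1, b0, b1, "aligned_gap",
                data.frame(op = "I", len = ga))
    } else if (ga <= max_gap && gb <= max_gap) {
      ops <- gap_align(substr(seq_a, a0 + 1L, a1),
                       substr(seq_b, b0 + 1L, b1))
      add_block(a0, a1, b0, b1, "aligned_gap", ops)
    } else {
      add_block(a0, a1, b0, b1, "unaligned")
    }
  }
  pa <- 0L; pb <- 0L
  for (i in seq_len(nrow(chain))) {
    emit_gap(pa, chain$a_pos[i], pb, chain$b_pos[i])
    add_block(chain$a_pos[i], chain$a_pos[i] + chain$length[i],
              chain$b_pos[i], chain$b_pos[i] + chain$length[i],
              "matched")
    pa <- chain$a_pos[i] + chain$length[i]
    pb <- chain$b_pos[i] + chain$length[i]
  }
  emit_gap(pa, la, pb, lb)
  blocks <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(a_start = integer(), a_end = integer(),
               b_start = integer(), b_end = integer(),
               kind = character(), stringsAsFactors = FALSE)
  structure(list(blocks = blocks, ops = ops, a_len = la, b_len = lb),
            class = "collinear_map")
}

# left-align an indel (VCF-style): shift while the base preceding the
# indel equals its last base, rotating the indel text
normalize_indel <- function(ctx_raw, pos, txt) {
  # ctx_raw: raw vector of the sequence carrying the extra bases;
  # pos: 0-based start of the extra bases in that sequence
  len <- nchar(txt)
  t <- strsplit(txt, "")[[1]]
  shift <- 0L
  while (pos > 0L && rawToChar(ctx_raw[pos]) == t[len]) {
    t <- c(t[len], t[-len])
    pos <- pos - 1L
    shift <- shift + 1L
  }
  list(pos = pos, txt = paste(t, collapse = ""), shift = shift)
}

#' Extract variants from a co-linear map
#'
#' Walks the map: every mismatched aligned column becomes a SNP, every
#' gap run one insertion/deletion record (left-normalised against its
#' local sequence context), every maximal `N` run in either sequence
#' one `N_run` record, and every unaligned block a deletion/insertion
#' pair record flagged `within_aligned_gap = FALSE`.  Aligned columns
#' where either base is `N` are never reported as SNPs.
#'
#' @param map a [close_gaps()] result.
#' @param seq_a,seq_b the sequences the map was built from.
#' @return Data frame sorted by `a_pos` with columns `kind` (`SNP`,
#'   `insertion`, `deletion`, `N_run`), `a_pos`, `b_pos` (0-based),
#'   `ref`, `alt`, `length`, `within_aligned_gap`.
#' @export
extract_variants <- function(map, seq_a, seq_b) {
  if (nchar(seq_a) != map$a_len || nchar(seq_b) != map$b_len)
    stop("map/sequence length mismatch")
  ra <- charToRaw(seq_a); rb <- charToRaw(seq_b)
  rawN <- charToRaw("N")
  rec <- list()
  add <- function(kind, a_pos, b_pos, ref = "", alt = "", length = 1L,
                  gapflag = TRUE) {
    rec[[length(rec) + 1L]] <<- data.frame(
      kind = kind, a_pos = a_pos, b_pos = b_pos, ref = ref, alt = alt,
      length = length, within_aligned_gap = gapflag,
      stringsAsFactors = FALSE)
  }
  bl <- map$blocks
  for (bi in seq_len(nrow(bl))) {
    kind <- bl$kind[bi]
    if (kind == "matched") next
    if (kind == "unaligned") {
      ga <- bl$a_end[bi] - bl$a_start[bi]
      gb <- bl$b_end[bi] - bl$b_start[bi]
      if (ga > 0)
        add("insertion", bl$a_start[bi], bl$b_start[bi],
            length = ga, gapflag = FALSE)
      if (gb > 0)
        add("deletion", bl$a_start[bi], bl$b_start[bi],
            length = gb, gapflag = FALSE)
      next
    }
    ops <- map$ops[[bi]]
    ai <- bl$a_start[bi]; bi2 <- bl$b_start[bi]
    for (oi in seq_len(nrow(ops))) {
      op <- ops$op[oi]; len <- ops$len[oi]
      if (op == "M") {
        ai <- ai + len; bi2 <- bi2 + len
      } else if (op == "X") {
        for (t in seq_len(len)) {
          ca <- ra[ai + t]; cb <- rb[bi2 + t]
          if (ca != rawN && cb != rawN)
            add("SNP", ai + t - 1L, bi2 + t - 1L,
                ref = rawToChar(ca), alt = rawToChar(cb))
        }
        ai <- ai + len; bi2 <- bi2 + len
      } else if (op == "I") {
        txt <- substr(seq_a, ai + 1L, ai + len)
        nm <- normalize_indel(ra, ai, txt)
        add("insertion", nm$pos, bi2 - nm$shift, alt = nm$txt,
            length = len)
        ai <- ai + len
      } else if (op == "D") {
        txt <- substr(seq_b, bi2 + 1L, bi2 + len)
        nm <- normalize_indel(rb, bi2, txt)
        add("deletion", ai - nm$shift, nm$pos, ref = nm$txt,
            length = len)
        bi2 <- bi2 + len
      }
    }
  }
  ## maximal N runs in either sequence
  n_runs <- function(r) {
    v <- r == rawN
    rl <- rle(as.vector(v))
    e <- cumsum(rl$lengths); s <- e - rl$lengths
    data.frame(start = s[rl$values], end = e[rl$values])
  }
  nra <- n_runs(ra)
  for (i in seq_len(nrow(nra)))
    add("N_run", nra$start[i], NA_integer_,
        length = nra$end[i] - nra$start[i])
  nrb <- n_runs(rb)
  if (nrow(nrb)) {
    proj <- project_b_to_a(map, nrb$start)
    for (i in seq_len(nrow(nrb)))
      add("N_run", proj[i], nrb$start[i],
          length = nrb$end[i] - nrb$start[i])
  }
  out <- if (length(rec)) do.call(rbind, rec) else
    data.frame(kind = character(), a_pos = integer(),
               b_pos = integer(), ref = character(), alt = character(),
               length = integer(), within_aligned_gap = logical(),
               stringsAsFactors = FALSE)
  out <- out[order(out$a_pos, out$kind), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' End-to-end co-linear comparison of two haplotype sequences
#'
#' Runs [find_anchors()], [chain_anchors()], [close_gaps()] and
#' [extract_variants()].
#'
#' @param seq_a,seq_b DNA text.
#' @param k anchor k-mer size (default 31).
#' @param max_gap see [close_gaps()].
#' @return List with `anchors`, `chain`, `map` and `variants`.
#' @export
compare_haplotypes <- function(seq_a, seq_b, k = 31L, max_gap = 5000L) {
  anchors <- find_anchors(seq_a, seq_b, k = k)
  chain <- chain_anchors(anchors)
  map <- close_gaps(seq_a, seq_b, chain, max_gap = max_gap)
  variants <- extract_variants(map, seq_a, seq_b)
  list(anchors = anchors, chain = chain, map = map,
       variants = variants)
}

#' Variants from an externally produced pairwise alignment
#'
#' Entry point that bypasses anchoring: takes two aligned, equal-length
#' gapped sequences (`-` for gaps, e.g. from an aligned-FASTA pair) and
#' extracts the same variant table as [extract_variants()].
#'
#' @param aligned_a,aligned_b gapped DNA text of equal length.
#' @return List with `map` (a synthetic one-block co-linear map) and
#'   `variants`.
#' @export
variants_from_alignment <- function(aligned_a, aligned_b) {
  if (nchar(aligned_a) != nchar(aligned_b))
    stop("aligned sequences must have equal length")
  if (any(strsplit(aligned_a, "")[[1]] == "-" &
            strsplit(aligned_b, "")[[1]] == "-"))
    stop("column with gaps in both sequences")
  ops <- ops_from_gapped(aligned_a, aligned_b)
  seq_a <- gsub("-", "", aligned_a, fixed = TRUE)
  seq_b <- gsub("-", "", aligned_b, fixed = TRUE)
  map <- structure(list(
    blocks = data.frame(a_start = 0L, a_end = nchar(seq_a),
                        b_start = 0L, b_end = nchar(seq_b),
                        kind = "aligned_gap", stringsAsFactors = FALSE),
    ops = list(ops), a_len = nchar(seq_a), b_len = nchar(seq_b)),
    class = "collinear_map")
  list(map = map, variants = extract_variants(map, seq_a, seq_b))
}
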