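# Independent oracles used across the suite.  These re-derive expected
# results from first principles (brute force, exhaustive enumeration,
# or an established external implementation) and never share code with
# the package paths they check.

# ---- brute-force maximal-unique-match enumeration -------------------

# all k-mers unique in both sequences, extended maximally, deduplicated
oracle_mums <- function(seq_a, seq_b, k) {
  na <- nchar(seq_a); nb <- nchar(seq_b)
  if (na < k || nb < k)
    return(data.frame(a_pos = integer(), b_pos = integer(),
                      length = integer()))
  ca <- strsplit(seq_a, "")[[1]]
  cb <- strsplit(seq_b, "")[[1]]
  kms_a <- vapply(1:(na - k + 1), function(i)
    substr(seq_a, i, i + k - 1), "")
  kms_b <- vapply(1:(nb - k + 1), function(i)
    substr(seq_b, i, i + k - 1), "")
  ta <- table(kms_a); tb <- table(kms_b)
  out <- list()
  for (i in seq_along(kms_a)) {
    km <- kms_a[i]
    if (grepl("N", km, fixed = TRUE)) next
    if (ta[[km]] != 1) next
    j <- match(km, kms_b)
    if (is.na(j) || tb[[km]] != 1) next
    # extend maximally
    s_a <- i; s_b <- j
    while (s_a > 1 && s_b > 1 && ca[s_a - 1] == cb[s_b - 1] &&
           ca[s_a - 1] != "N") { s_a <- s_a - 1; s_b <- s_b - 1 }
    e_a <- i + k - 1; e_b <- j + k - 1
    while (e_a < na && e_b < nb && ca[e_a + 1] == cb[e_b + 1] &&
           ca[e_a + 1] != "N") { e_a <- e_a + 1; e_b <- e_b + 1 }
    out[[length(out) + 1L]] <- c(s_a - 1L, s_b - 1L, e_a - s_a + 1L)
  }
  if (!length(out))
    return(data.frame(a_pos = integer(), b_pos = integer(),
                      length = integer()))
  m <- unique(do.call(rbind, out))
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  data.frame(a_pos = m[, 1], b_pos = m[, 2], length = m[, 3])
}

# ---- exhaustive co-linear chain search ------------------------------

oracle_chain_weight <- function(anchors) {
  n <- nrow(anchors)
  if (n == 0) return(0)
  best <- 0
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) < 2) {
      w <- sum(anchors$length[idx])
      best <- max(best, w)
      next
    }
    o <- idx[order(anchors$a_pos[idx])]
    ok <- all(diff(anchors$a_pos[o]) > 0) &&
      all(diff(anchors$b_pos[o]) > 0)
    if (ok) best <- max(best, sum(anchors$length[o]))
  }
  best
}

# ---- full-DP global alignment oracle (Biostrings) -------------------

# align the complete pair with the same scoring scheme and extract the
# variant table from the explicit alignment
oracle_dp_variants <- function(seq_a, seq_b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                  mismatch = -1,
                                                  baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b),
    type = "global", substitutionMatrix = mat,
    gapOpening = 4, gapExtension = 1)
  al_a <- as.character(Biostrings::alignedPattern(pa))
  al_b <- as.character(Biostrings::alignedSubject(pa))
  variants_from_alignment(al_a, al_b)$variants
}

oracle_dp_score <- function(seq_a, seq_b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                  mismatch = -1,
                                                  baseOnly = FALSE)
  Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b),
    type = "global", substitutionMatrix = mat,
    gapOpening = 4, gapExtension = 1))
}

# ---- brute-force motif scan -----------------------------------------

iupac_sets <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

oracle_scan <- function(sequence, pattern) {
  chars <- strsplit(sequence, "")[[1]]
  pat <- strsplit(pattern, "")[[1]]
  L <- length(chars); k <- length(pat)
  if (L < k) return(integer(0))
  ok <- rep(TRUE, L - k + 1)
  for (j in seq_len(k))
    ok <- ok & chars[j:(L - k + j)] %in% iupac_sets[[pat[j]]]
  which(ok) - 1L
}

# ---- brute-force simple-repeat scan ---------------------------------

oracle_simple_repeats <- function(sequence, unit_max = 6, min_span = 12) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  covered <- rep(FALSE, n)
  for (u in 1:unit_max) {
    need <- if (u == 1) 8 else min_span
    i <- 1
    while (i + u <= n) {
      j <- i
      while (j + u <= n && chars[j + u] == chars[j]) j <- j + 1
      span <- (j - i) + u
      if (j > i && span >= need) covered[i:(i + span - 1)] <- TRUE
      i <- if (j > i) j else i + 1
    }
  }
  r <- rle(covered)
  e <- cumsum(r$lengths); s <- e - r$lengths
  data.frame(start = s[r$values], end = e[r$values])
}

# ---- random additive trees ------------------------------------------

# random unrooted binary tree with positive branch lengths; returns the
# ape phylo and its exact pairwise path-length (additive) matrix
oracle_random_additive <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(n) stats::runif(n, 0.05, 1))
  labs <- sort(tr$tip.label)
  d <- ape::cophenetic.phylo(tr)[labs, labs]
  list(tree = tr, d = d)
}

# ---- exact two-rate Poisson change-point ----------------------------

# ML change point for SNP positions on [0, span) with one rate switch
oracle_changepoint <- function(pos, span) {
  pos <- sort(pos)
  cands <- unique(sort(c(pos, pos + 1L)))
  cands <- cands[cands > 0 & cands < span]
  best <- NA_integer_; best_ll <- -Inf
  n <- length(pos)
  for (c in cands) {
    nl <- sum(pos < c); nr <- n - nl
    ll <- 0
    if (nl > 0) ll <- ll + nl * log(nl / c)
    if (nr > 0) ll <- ll + nr * log(nr / (span - c))
    ll <- ll - n
    if (ll > best_ll) { best_ll <- ll; best <- c }
  }
  best
}

# ---- small utilities -------------------------------------------------

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
        collapse = "")
}

mutate_seq <- function(s, rate) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  k <- rbinom(1, n, rate)
  if (k > 0) {
    pos <- sample.int(n, k)
    for (p in pos)
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

# snp/indel perturbed copy used by the aligner-oracle suites
perturb_pair <- function(n = 2000, sub_rate = 0.01, n_indels = 2,
                         max_indel = 50) {
  a <- random_seq(n)
  b <- mutate_seq(a, sub_rate)
  for (i in seq_len(n_indels)) {
    len <- sample.int(max_indel, 1)
    if (stats::runif(1) < 0.5) {
      pos <- sample.int(nchar(b) - 1, 1)
      b <- paste0(substr(b, 1, pos), random_seq(len),
                  substr(b, pos + 1, nchar(b)))
    } else {
      pos <- sample.int(nchar(b) - len - 1, 1)
      b <- paste0(substr(b, 1, pos), substr(b, pos + len + 1, nchar(b)))
    }
  }
  list(a = a, b = b)
}

variant_key <- function(v) {
  v <- v[order(v$a_pos, v$kind, v$length), , drop = FALSE]
  paste(v$kind, v$a_pos, v$b_pos, v$ref, v$alt, v$length,
        sep = ":", collapse = ";")
}
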