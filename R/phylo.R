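# p-distances without evolutionary-model correction and a
# deterministic Saitou-Nei neighbor-joining implementation.

#' p-distance and percent-identity matrices
#'
#' For each pair of equal-length aligned sequences, columns where
#' either sequence has a gap (`-`) or `N` are skipped; the p-distance
#' is the proportion of differing compared columns.
#'
#' @param seqs named character vector of aligned sequences of equal
#'   length.
#' @return List with `taxa`, `p` (symmetric p-distance matrix, zero
#'   diagonal) and `identity` (percent identity, `100 * (1 - p)`).
#' @export
p_distance_matrix <- function(seqs) {
  n <- length(seqs)
  stopifnot(n >= 2, !is.null(names(seqs)))
  if (length(unique(nchar(seqs))) != 1)
    stop("sequences must have equal (aligned) lengths")
  raws <- lapply(seqs, charToRaw)
  skip_chars <- c(charToRaw("-"), charToRaw("N"))
  bad <- lapply(raws, function(r) r %in% skip_chars)
  p <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    use <- !(bad[[i]] | bad[[j]])
    comp <- sum(use)
    if (comp == 0)
      stop("no comparable sites between ", names(seqs)[i], " and ",
           names(seqs)[j])
    d <- sum(raws[[i]][use] != raws[[j]][use]) / comp
    p[i, j] <- p[j, i] <- d
  }
  list(taxa = names(seqs), p = p, identity = 100 * (1 - p))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration minimising the Q criterion.  Ties
#' are broken deterministically towards the lexicographically smallest
#' taxon pair (each node is keyed by its smallest leaf label).
#' Negative branch lengths are clamped to zero and the deficit
#' reported.  Exact on additive matrices.
#'
#' @param d symmetric distance matrix with row/column names (or the
#'   `p` element of [p_distance_matrix()]).
#' @return List with `tree` (an [ape][ape::read.tree] `phylo`,
#'   unrooted), `newick` (text) and `clamped` (data frame of edges
#'   whose negative lengths were clamped).
#' @export
neighbor_joining <- function(d) {
  if (is.list(d) && !is.null(d$p)) d <- d$p
  n <- nrow(d)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(d))) stop("distance matrix must be labelled")
  labels <- rownames(d)
  sub <- labels            # newick fragment per active node
  key <- labels            # smallest leaf label per active node
  D <- d
  clamped <- data.frame(node = character(), deficit = numeric(),
                        stringsAsFactors = FALSE)
  clamp <- function(x, node) {
    if (x < 0) {
      clamped <<- rbind(clamped,
                        data.frame(node = node, deficit = -x,
                                   stringsAsFactors = FALSE))
      0
    } else x
  }
  fmt <- function(x) sprintf("%.12g", x)
  while (nrow(D) > 3) {
    m <- nrow(D)
    R <- rowSums(D)
    Q <- (m - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    best <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    pk <- apply(best, 1, function(ij) {
      k <- sort(c(key[ij[1]], key[ij[2]]))
      paste(k, collapse = "\r")
    })
    sel <- best[order(pk)[1], ]
    i <- sel[1]; j <- sel[2]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    li <- clamp(li, key[i]); lj <- clamp(lj, key[j])
    new_sub <- paste0("(", sub[i], ":", fmt(li), ",", sub[j], ":",
                      fmt(lj), ")")
    new_key <- min(key[i], key[j])
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    sub <- c(sub[keep], new_sub)
    key <- c(key[keep], new_key)
    rownames(D2) <- colnames(D2) <- key
    D <- D2
  }
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  la <- clamp(la, key[1]); lb <- clamp(lb, key[2])
  lc <- clamp(lc, key[3])
  newick <- paste0("(", sub[1], ":", fmt(la), ",", sub[2], ":",
                   fmt(lb), ",", sub[3], ":", fmt(lc), ");")
  tree <- ape::read.tree(text = newick)
  list(tree = tree, newick = newick, clamped = clamped)
}

#' Write a percent-identity / distance matrix as TSV
#'
#' @param pd a [p_distance_matrix()] result.
#' @param path output path.
#' @param what `"identity"` (PIM-style percent identities) or `"p"`.
#' @export
write_distance_tsv <- function(pd, path, what = c("identity", "p")) {
  what <- match.arg(what)
  m <- pd[[what]]
  df <- data.frame(taxon = rownames(m), as.data.frame(m),
                   check.names = FALSE)
  write_tsv(df, path)
}
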