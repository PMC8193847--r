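# Dimorphic (presence/absence) transposable-element locus calling from
# per-haplotype repeat annotations.  Features of two haplotypes are
# paired by name/strand and projected position; unmatched features are
# merged into candidate insertion loci, anchored by paired flanking
# features, and unified across a panel.

#' Pair repeat annotations of two haplotypes
#'
#' Features are paired by identical `rep_name` and `strand`.  When
#' `map` (a [close_gaps()] co-linear map) is given, positions of
#' `ann_b` are projected through it and features pair greedily, nearest
#' projected distance first, within `tol`.  Without a map, pairing is
#' the maximum co-linear chain over all same-name/strand candidate
#' pairs (weighted longest increasing subsequence in both coordinates),
#' which absorbs the arbitrary coordinate drift caused by indels
#' between the haplotypes.
#'
#' @param ann_a,ann_b annotation data frames ([read_repeatmasker()]
#'   layout) for haplotypes A and B.
#' @param map optional co-linear map from [close_gaps()] with A as the
#'   first sequence; `NULL` for co-linear chain matching.
#' @param tol maximum projected-position distance in bp when a map is
#'   given (default 500).
#' @return List with `pairs` (data frame of indices `a`, `b` into the
#'   two inputs), `unmatched_a`, `unmatched_b` (row indices).
#' @export
match_annotations <- function(ann_a, ann_b, map = NULL, tol = 500L) {
  na <- nrow(ann_a); nb <- nrow(ann_b)
  empty <- list(pairs = data.frame(a = integer(), b = integer()),
                unmatched_a = seq_len(na), unmatched_b = seq_len(nb))
  if (na == 0 || nb == 0) return(empty)
  key_a <- paste(ann_a$rep_name, ann_a$strand)
  key_b <- paste(ann_b$rep_name, ann_b$strand)
  shared <- intersect(key_a, key_b)
  if (!length(shared)) return(empty)
  cand <- do.call(rbind, lapply(shared, function(k)
    expand.grid(a = which(key_a == k), b = which(key_b == k))))
  if (!is.null(map)) {
    proj <- project_b_to_a(map, ann_b$q_start)
    cand$d <- abs(proj[cand$b] - ann_a$q_start[cand$a])
    cand <- cand[cand$d <= tol, , drop = FALSE]
    cand <- cand[order(cand$d), , drop = FALSE]
    used_a <- rep(FALSE, na); used_b <- rep(FALSE, nb)
    pa <- integer(0); pb <- integer(0)
    for (i in seq_len(nrow(cand))) {
      ai <- cand$a[i]; bi <- cand$b[i]
      if (used_a[ai] || used_b[bi]) next
      used_a[ai] <- TRUE; used_b[bi] <- TRUE
      pa <- c(pa, ai); pb <- c(pb, bi)
    }
  } else {
    ## maximum co-linear chain: longest subsequence strictly
    ## increasing in both coordinates (each feature used once, which
    ## strictness guarantees); patience LIS, O(n log n)
    ordc <- order(ann_a$q_start[cand$a], -ann_b$q_start[cand$b])
    cand <- cand[ordc, , drop = FALSE]
    v <- ann_b$q_start[cand$b]
    n <- nrow(cand)
    tails <- numeric(0)       # smallest tail value per chain length
    tails_idx <- integer(0)   # candidate index achieving it
    parent <- integer(n)
    for (i in seq_len(n)) {
      pos <- findInterval(v[i] - 0.5, tails)  # chains extendable
      parent[i] <- if (pos > 0) tails_idx[pos] else 0L
      tails[pos + 1L] <- v[i]
      tails_idx[pos + 1L] <- i
    }
    i <- tails_idx[length(tails_idx)]
    path <- integer(0)
    while (i != 0L) { path <- c(i, path); i <- parent[i] }
    pa <- cand$a[path]; pb <- cand$b[path]
  }
  o <- order(ann_a$q_start[pa])
  list(pairs = data.frame(a = pa[o], b = pb[o]),
       unmatched_a = setdiff(seq_len(na), pa),
       unmatched_b = setdiff(seq_len(nb), pb))
}

# project B coordinates into the A frame through a co-linear map
project_b_to_a <- function(map, pos) {
  blocks <- map$blocks
  out <- rep(NA_integer_, length(pos))
  for (i in seq_along(pos)) {
    p <- pos[i]
    hit <- which(blocks$b_start <= p & p < blocks$b_end)
    if (length(hit)) {
      b <- hit[1]
      if (blocks$kind[b] == "matched") {
        out[i] <- blocks$a_start[b] + (p - blocks$b_start[b])
      } else {
        # inside a gap: clamp to the gap's a-side start
        out[i] <- blocks$a_start[b]
      }
    } else {
      # beyond the map: extrapolate from the final block
      nb <- nrow(blocks)
      out[i] <- blocks$a_end[nb] + (p - blocks$b_end[nb])
    }
  }
  out
}

#' Call dimorphic TE loci between one haplotype pair
#'
#' Unmatched features within `merge_gap` of each other are merged into
#' one candidate locus (so a multi-member mosaic indel is one locus,
#' not many); candidates of at least `min_len` bp with paired flanking
#' features on both sides within `flank_window` become calls.
#'
#' @param matched result of [match_annotations()].
#' @param ann_a,ann_b the annotation data frames used for matching.
#' @param hap_a,hap_b haplotype names used in the output.
#' @param min_len minimum insertion length in bp (default 100).
#' @param merge_gap maximum gap between unmatched features merged into
#'   one locus (default 200).
#' @param flank_window maximum distance to a paired flanking feature
#'   (default 10000).
#' @return Data frame of candidate loci: `carrier`, `other`, `start`,
#'   `end` (carrier frame), `length`, `members` (comma-separated
#'   rep_names), `flank_left`, `flank_right` (rep_names),
#'   `flank_left_pos_carrier`, `flank_left_pos_other` (0-based).
#' @export
call_dimorphic_te <- function(matched, ann_a, ann_b,
                              hap_a = "A", hap_b = "B",
                              min_len = 100L, merge_gap = 200L,
                              flank_window = 10000L) {
  one_side <- function(unm, ann_c, ann_o, pairs, c_col, o_col,
                       hap_c, hap_o) {
    if (!length(unm) || !nrow(pairs))
      return(NULL)
    unm <- unm[order(ann_c$q_start[unm])]
    gaps <- ann_c$q_start[unm][-1] - ann_c$q_end[unm][-length(unm)]
    grp <- cumsum(c(1L, as.integer(gaps > merge_gap)))
    out <- lapply(split(unm, grp), function(idx) {
      s <- min(ann_c$q_start[idx]); e <- max(ann_c$q_end[idx])
      if (e - s < min_len) return(NULL)
      pc <- pairs[[c_col]]
      lefts <- pc[ann_c$q_end[pc] <= s]
      rights <- pc[ann_c$q_start[pc] >= e]
      if (!length(lefts) || !length(rights)) return(NULL)
      fl <- lefts[which.max(ann_c$q_end[lefts])]
      fr <- rights[which.min(ann_c$q_start[rights])]
      if (s - ann_c$q_end[fl] > flank_window ||
          ann_c$q_start[fr] - e > flank_window) return(NULL)
      fl_o <- pairs[[o_col]][match(fl, pc)]
      data.frame(carrier = hap_c, other = hap_o, start = s, end = e,
                 length = e - s,
                 members = paste(ann_c$rep_name[idx], collapse = ","),
                 flank_left = ann_c$rep_name[fl],
                 flank_right = ann_c$rep_name[fr],
                 flank_left_pos_carrier = ann_c$q_start[fl],
                 flank_left_pos_other = ann_o$q_start[fl_o],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  rbind(
    one_side(matched$unmatched_a, ann_a, ann_b, matched$pairs, "a", "b",
             hap_a, hap_b),
    one_side(matched$unmatched_b, ann_b, ann_a, matched$pairs, "b", "a",
             hap_b, hap_a))
}

#' Call dimorphic TE loci across a haplotype panel
#'
#' Runs [match_annotations()] and [call_dimorphic_te()] for every
#' haplotype pair, then unifies candidates whose flank anchors coincide
#' into panel-level loci with a presence/absence flag per haplotype.
#' Elements present in every haplotype are monomorphic and yield no
#' call.
#'
#' @param annotations named list of annotation data frames, one per
#'   haplotype.
#' @param tol,min_len,merge_gap,flank_window see
#'   [match_annotations()] and [call_dimorphic_te()].
#' @param unify_tol candidates are treated as one locus when their
#'   left-flank anchors share a haplotype frame within this distance
#'   (default 1000 bp).
#' @return List with `loci` (data frame: `locus`, `length`, `members`,
#'   `flank_left`, `flank_right`) and `presence`, a haplotype x locus
#'   0/1 matrix.
#' @export
call_dimorphic_panel <- function(annotations, tol = 500L,
                                 min_len = 100L, merge_gap = 200L,
                                 flank_window = 10000L,
                                 unify_tol = 1000L) {
  haps <- names(annotations)
  nh <- length(haps)
  stopifnot(nh >= 2)
  cands <- list()
  for (i in 1:(nh - 1)) for (j in (i + 1):nh) {
    m <- match_annotations(annotations[[i]], annotations[[j]],
                           tol = tol)
    cd <- call_dimorphic_te(m, annotations[[i]], annotations[[j]],
                            hap_a = haps[i], hap_b = haps[j],
                            min_len = min_len, merge_gap = merge_gap,
                            flank_window = flank_window)
    if (!is.null(cd) && nrow(cd)) cands[[length(cands) + 1L]] <- cd
  }
  empty <- list(loci = data.frame(locus = character(),
                                  length = integer(),
                                  members = character(),
                                  flank_left = character(),
                                  flank_right = character(),
                                  stringsAsFactors = FALSE),
                presence = matrix(0L, nrow = nh, ncol = 0,
                                  dimnames = list(haps, NULL)))
  if (!length(cands)) return(empty)
  cd <- do.call(rbind, cands)
  n <- nrow(cd)
  # union-find over candidates sharing flank names and a close anchor
  # position in a shared frame (carrier-carrier or other-other)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    if (cd$flank_left[a] != cd$flank_left[b] ||
        cd$flank_right[a] != cd$flank_right[b]) next
    close_anchor <-
      (cd$carrier[a] == cd$carrier[b] &&
       abs(cd$flank_left_pos_carrier[a] -
           cd$flank_left_pos_carrier[b]) <= unify_tol) ||
      (cd$other[a] == cd$other[b] &&
       abs(cd$flank_left_pos_other[a] -
           cd$flank_left_pos_other[b]) <= unify_tol) ||
      (cd$carrier[a] == cd$other[b] &&
       abs(cd$flank_left_pos_carrier[a] -
           cd$flank_left_pos_other[b]) <= unify_tol) ||
      (cd$other[a] == cd$carrier[b] &&
       abs(cd$flank_left_pos_other[a] -
           cd$flank_left_pos_carrier[b]) <= unify_tol)
    if (close_anchor) parent[find(a)] <- find(b)
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), comp)
  loci <- list(); pres <- list()
  for (k in seq_along(groups)) {
    g <- groups[[k]]
    present <- unique(cd$carrier[g])
    absent <- setdiff(unique(cd$other[g]), present)
    p <- rep(NA_integer_, nh); names(p) <- haps
    p[present] <- 1L; p[absent] <- 0L
    pres[[k]] <- p
    gi <- g[which.max(cd$length[g])]
    loci[[k]] <- data.frame(
      locus = paste0("DIM_", k), length = cd$length[gi],
      members = paste(cd$members[gi], collapse = ","),
      n_members = length(strsplit(cd$members[gi], ",")[[1]]),
      flank_left = cd$flank_left[gi], flank_right = cd$flank_right[gi],
      stringsAsFactors = FALSE)
  }
  loci <- do.call(rbind, loci)
  presence <- do.call(cbind, pres)
  colnames(presence) <- loci$locus
  o <- order(loci$flank_left)
  list(loci = loci[o, , drop = FALSE],
       presence = presence[, o, drop = FALSE])
}
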