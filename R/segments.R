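# Windowed SNP densities, SNP-poor / SNP-rich segmentation and
# crossover (XO) calling at segment junctions.

#' Segmentation parameters
#'
#' Densities are expressed per 100 kb.  SNP-poor means fewer than
#' `poor_max` and SNP-rich more than `rich_min` kept SNPs per 100 kb;
#' intermediate densities are not a third class, they are absorbed into
#' a neighbouring run.
#'
#' @param poor_max density upper bound for SNP-poor (default 10).
#' @param rich_min density lower bound for SNP-rich (default 50).
#' @param scan_window sliding window size in bp (default 10000).
#' @param scan_step window step in bp (default 1000).
#' @param min_segment minimum reported segment length in bp (default
#'   20000); shorter runs are absorbed into the longer neighbour.
#' @return An object of class `segment_params`.
#' @export
segment_params <- function(poor_max = 10, rich_min = 50,
                           scan_window = 10000L, scan_step = 1000L,
                           min_segment = 20000L) {
  stopifnot(poor_max < rich_min, scan_window > 0, scan_step > 0,
            min_segment >= scan_window)
  structure(list(poor_max = poor_max, rich_min = rich_min,
                 scan_window = as.integer(scan_window),
                 scan_step = as.integer(scan_step),
                 min_segment = as.integer(min_segment)),
            class = "segment_params")
}

#' SNP-density profile in non-overlapping windows
#'
#' Counts kept SNPs in consecutive non-overlapping windows tiling
#' `[0, span)`; windows overlapping a masked interval (unaligned
#' blocks, N-runs) are flagged.
#'
#' @param filtered a [filter_snps()] result (or a sorted numeric
#'   vector of positions).
#' @param window window size in nt (default 500).
#' @param span length of the analysed region in bp.
#' @param mask optional data frame of intervals (`start`, `end`) whose
#'   overlapping windows are flagged.
#' @return Data frame with `window_start`, `count`, `masked`.
#' @export
density_profile <- function(filtered, window = 500L, span,
                            mask = NULL) {
  p <- if (inherits(filtered, "filtered_variants")) filtered$positions
       else sort(filtered)
  starts <- seq(0L, max(span - 1L, 0L), by = window)
  ends <- pmin(starts + window, span)
  cnt <- findInterval(ends - 0.5, p) - findInterval(starts - 0.5, p)
  masked <- rep(FALSE, length(starts))
  if (!is.null(mask) && nrow(mask))
    masked <- vapply(seq_along(starts), function(i)
      any(mask$start < ends[i] & mask$end > starts[i]), logical(1))
  data.frame(window_start = starts, count = cnt, masked = masked)
}

# exact two-rate Poisson maximum-likelihood change point between two
# adjacent segments.  Two passes: a profile-likelihood split (rates
# re-estimated at every candidate), then rates re-estimated from the
# two segment cores (excluding the boundary neighbourhood, where
# assignment is uncertain) and an exact fixed-rate ML split.  The
# fixed-rate pass bridges SNP-sparse stretches at a rich-block edge up
# to log(r1/r2)/(r1-r2) bp, which the contaminated profile estimates
# systematically under-bridge.
refine_boundary <- function(p, lo, hi, b0, core_margin = 5000L) {
  inner <- p[p > lo & p < hi]
  cand <- unique(sort(c(inner, inner + 1L)))
  cand <- cand[cand > lo & cand < hi]
  if (!length(cand)) return(b0)
  count <- function(a, b) findInterval(b - 0.5, p) -
    findInterval(a - 0.5, p)
  nTot <- count(lo, hi)
  nL <- count(lo, cand)
  nR <- nTot - nL
  ll <- ifelse(nL > 0, nL * log(nL / (cand - lo)), 0) +
    ifelse(nR > 0, nR * log(nR / (hi - cand)), 0)
  c0 <- cand[which.max(ll)]
  ## pass 2: fixed rates from the segment cores
  core_l <- c(lo, max(lo + 1L, c0 - core_margin))
  core_r <- c(min(hi - 1L, c0 + core_margin), hi)
  len_l <- core_l[2] - core_l[1]; len_r <- core_r[2] - core_r[1]
  if (len_l < core_margin || len_r < core_margin) return(c0)
  rate_l <- max(count(core_l[1], core_l[2]), 0.5) / len_l
  rate_r <- max(count(core_r[1], core_r[2]), 0.5) / len_r
  if (abs(log(rate_l / rate_r)) < 1e-9) return(c0)
  ll2 <- nL * log(rate_l) - rate_l * (cand - lo) +
    nR * log(rate_r) - rate_r * (hi - cand)
  cand[which.max(ll2)]
}

#' Classify a span into SNP-poor and SNP-rich segments
#'
#' Sliding windows are labelled rich/poor/intermediate by scaled
#' density; runs are merged, intermediate runs absorbed into the
#' adjacent run with the nearer density (ties to the preceding run),
#' runs shorter than `min_segment` absorbed into the longer neighbour,
#' and each surviving rich/poor boundary refined by an exact local
#' two-rate Poisson maximum-likelihood change point over the kept SNP
#' positions.
#'
#' @param filtered a [filter_snps()] result or sorted positions.
#' @param params a [segment_params()].
#' @param span analysed span in bp (A frame).
#' @return Data frame of segments tiling `[0, span)`: `start`, `end`,
#'   `label` (`poor`/`rich`), `snp_count`, `density` (per 100 kb).
#' @export
classify_segments <- function(filtered, params = segment_params(),
                              span) {
  p <- if (inherits(filtered, "filtered_variants")) filtered$positions
       else sort(filtered)
  W <- params$scan_window; step <- params$scan_step
  seg_out <- function(starts, ends, labels) {
    cnt <- findInterval(ends - 0.5, p) - findInterval(starts - 0.5, p)
    data.frame(start = starts, end = ends, label = labels,
               snp_count = cnt,
               density = cnt / (ends - starts) * 1e5,
               stringsAsFactors = FALSE)
  }
  if (length(p) == 0)
    return(seg_out(0L, as.integer(span), "poor"))
  if (span <= W) {
    dens <- length(p) / span * 1e5
    lab <- if (dens > params$rich_min) "rich" else "poor"
    return(seg_out(0L, as.integer(span), lab))
  }
  starts <- seq(0L, span - W, by = step)
  ends <- starts + W
  cnt <- findInterval(ends - 0.5, p) - findInterval(starts - 0.5, p)
  dens <- cnt / W * 1e5
  lab <- ifelse(dens > params$rich_min, "rich",
                ifelse(dens < params$poor_max, "poor", "mid"))
  ## collapse to runs of window labels
  r <- rle(lab)
  run_end_i <- cumsum(r$lengths)
  run_start_i <- run_end_i - r$lengths + 1L
  runs <- data.frame(label = r$values,
                     w_from = run_start_i, w_to = run_end_i,
                     stringsAsFactors = FALSE)
  run_density <- function(i) {
    s <- starts[runs$w_from[i]]; e <- ends[runs$w_to[i]]
    (findInterval(e - 0.5, p) - findInterval(s - 0.5, p)) / (e - s) * 1e5
  }
  ## absorb intermediate runs into the nearer-density neighbour
  while (any(runs$label == "mid")) {
    i <- which(runs$label == "mid")[1]
    d <- run_density(i)
    dl <- if (i > 1) abs(d - run_density(i - 1)) else Inf
    dr <- if (i < nrow(runs)) abs(d - run_density(i + 1)) else Inf
    if (is.infinite(dl) && is.infinite(dr)) {
      runs$label[i] <- if (d > params$rich_min) "rich" else "poor"
    } else if (dl <= dr) {
      runs$label[i] <- runs$label[i - 1]
    } else {
      runs$label[i] <- runs$label[i + 1]
    }
    r2 <- rle(runs$label)
    to <- cumsum(r2$lengths)
    from <- to - r2$lengths + 1L
    runs <- data.frame(label = r2$values,
                       w_from = runs$w_from[from],
                       w_to = runs$w_to[to], stringsAsFactors = FALSE)
  }
  ## provisional segment boundaries at window-run midpoints
  seg_bounds <- function(runs) {
    nb <- nrow(runs) - 1L
    if (nb <= 0) return(integer(0))
    vapply(seq_len(nb), function(i) {
      left_end <- ends[runs$w_to[i]]
      right_start <- starts[runs$w_from[i + 1]]
      as.integer((left_end + right_start) %/% 2L)
    }, integer(1))
  }
  bounds <- seg_bounds(runs)
  seg <- data.frame(start = c(0L, bounds),
                    end = c(bounds, as.integer(span)),
                    label = runs$label, stringsAsFactors = FALSE)
  merge_same <- function(seg) {
    k <- 1L
    while (k < nrow(seg)) {
      if (seg$label[k] == seg$label[k + 1]) {
        seg$end[k] <- seg$end[k + 1]
        seg <- seg[-(k + 1L), , drop = FALSE]
      } else k <- k + 1L
    }
    rownames(seg) <- NULL
    seg
  }
  ## absorb segments shorter than min_segment into the longer neighbour
  absorb_short <- function(seg) {
    repeat {
      len <- seg$end - seg$start
      short <- which(len < params$min_segment)
      if (!length(short) || nrow(seg) == 1) break
      i <- short[which.min(len[short])]
      nl <- if (i > 1) len[i - 1] else -1L
      nr <- if (i < nrow(seg)) len[i + 1] else -1L
      j <- if (nl >= nr) i - 1L else i + 1L
      lo <- min(seg$start[i], seg$start[j])
      hi <- max(seg$end[i], seg$end[j])
      seg$start[j] <- lo; seg$end[j] <- hi
      seg <- merge_same(seg[-i, , drop = FALSE])
    }
    seg
  }
  seg <- absorb_short(seg)
  ## refine each boundary with the exact two-rate ML change point
  ## over the two adjacent segments
  if (nrow(seg) > 1) {
    for (i in seq_len(nrow(seg) - 1L)) {
      b <- refine_boundary(p, seg$start[i], seg$end[i + 1],
                           seg$end[i])
      seg$end[i] <- b; seg$start[i + 1] <- b
    }
  }
  ## final labels reflect realized segment densities (guards against
  ## window-level noise promoting an intermediate-density region)
  dens <- (findInterval(seg$end - 0.5, p) -
             findInterval(seg$start - 0.5, p)) /
    (seg$end - seg$start) * 1e5
  seg$label <- ifelse(dens > params$rich_min, "rich", "poor")
  seg <- merge_same(seg)
  ## refinement can carve segments below min_segment; absorb again
  seg <- absorb_short(seg)
  seg_out(seg$start, seg$end, seg$label)
}

#' Call SNP-density crossovers at segment junctions
#'
#' One XO per rich/poor adjacency.  The XO position is the kept SNP
#' inside the SNP-rich segment nearest the junction (the "last
#' identifiable SNP" of the rich block); `side = "poor"` reports the
#' poor-side boundary SNP instead.
#'
#' @param segments data frame from [classify_segments()].
#' @param filtered a [filter_snps()] result or sorted positions.
#' @param pair optional pair identifier carried into the output.
#' @param side which side's boundary SNP defines the XO position.
#' @return Data frame with `position` (a kept SNP), `left_label`,
#'   `right_label`, `junction` (the segment boundary) and `pair`.
#' @export
call_xos <- function(segments, filtered, pair = NA_character_,
                     side = c("rich", "poor")) {
  side <- match.arg(side)
  p <- if (inherits(filtered, "filtered_variants")) filtered$positions
       else sort(filtered)
  out <- list()
  if (nrow(segments) > 1) {
    for (i in seq_len(nrow(segments) - 1L)) {
      if (segments$label[i] == segments$label[i + 1]) next
      junction <- segments$end[i]
      want <- if (side == "rich") "rich" else "poor"
      left_is_want <- segments$label[i] == want
      if (left_is_want) {
        cand <- p[p >= segments$start[i] & p < junction]
        pos <- if (length(cand)) max(cand) else NA_integer_
      } else {
        cand <- p[p >= junction & p < segments$end[i + 1]]
        pos <- if (length(cand)) min(cand) else NA_integer_
      }
      if (is.na(pos) && length(p))  # degenerate: nearest kept SNP
        pos <- p[which.min(abs(p - junction))]
      out[[length(out) + 1L]] <- data.frame(
        position = pos, left_label = segments$label[i],
        right_label = segments$label[i + 1], junction = junction,
        pair = pair, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(position = integer(), left_label = character(),
                      right_label = character(), junction = integer(),
                      pair = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Summarise XO calls across haplotype pairs
#'
#' @param xos either a list of per-pair XO data frames / position
#'   vectors, or one data frame with a `pair` column.
#' @param merge_radius positions within this distance (bp) are counted
#'   as one unique XO site (default 1000).
#' @return List with `n_pairs`, `total`, `by_multiplicity` (named
#'   counts of pairs with 0,1,2,3,4+ XOs) and `unique_sites`.
#' @export
xo_summary <- function(xos, merge_radius = 1000L) {
  if (is.data.frame(xos))
    xos <- split(xos$position, xos$pair)
  pos_of <- function(x) if (is.data.frame(x)) x$position else x
  counts <- vapply(xos, function(x) length(pos_of(x)), integer(1))
  mult <- c(`0` = sum(counts == 0), `1` = sum(counts == 1),
            `2` = sum(counts == 2), `3` = sum(counts == 3),
            `4+` = sum(counts >= 4))
  all_pos <- sort(unlist(lapply(xos, pos_of), use.names = FALSE))
  uniq <- if (length(all_pos))
    sum(diff(all_pos) > merge_radius) + 1L else 0L
  list(n_pairs = length(xos), total = sum(counts),
       by_multiplicity = mult, unique_sites = uniq)
}

#' Write segments or XO calls as BED
#'
#' Segments become `chrom start end label`; XOs become 1-bp intervals
#' named `left>right`.
#'
#' @param segments,xos data frames from [classify_segments()] /
#'   [call_xos()].
#' @param path output path.
#' @param chrom chromosome/sequence name for the BED `chrom` column.
#' @export
write_segments_bed <- function(segments, path, chrom = "A") {
  write_bed(data.frame(chrom = rep(chrom, nrow(segments)),
                       start = segments$start,
                       end = segments$end, name = segments$label),
            path)
}

#' @rdname write_segments_bed
#' @export
write_xo_bed <- function(xos, path, chrom = "A") {
  write_bed(data.frame(chrom = rep(chrom, nrow(xos)),
                       start = xos$position,
                       end = xos$position + 1L,
                       name = sprintf("%s>%s", xos$left_label,
                                      xos$right_label)),
            path)
}
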