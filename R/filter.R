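# Deterministic codification of the manual SNP-counting exclusion
# rules: clustered SNPs (> 5 in any sliding 50-nt span), SNPs within
# 50 bp of N-runs or long deletion strings, SNPs inside simple
# microsatellite repeats, SNPs in unaligned blocks.  Indel and N-run
# records are never counted as SNPs.

#' SNP filter parameters
#'
#' @param cluster_max maximum SNPs tolerated in a cluster window;
#'   strictly more triggers exclusion (default 5).
#' @param cluster_window cluster window size in nt (default 50).
#' @param proximity_exclude inclusive distance in bp around N-runs and
#'   long deletions within which SNPs are excluded (default 50).
#' @param n_run_min minimum N-run length treated as an artifact
#'   (default 5).
#' @param long_del_min minimum indel length treated as a long-deletion
#'   artifact (default 100).
#' @param microsat_source where microsatellite intervals come from:
#'   `"annotation"` (Simple_repeat features) or `"internal"`
#'   ([detect_simple_repeats()]).
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(cluster_max = 5L, cluster_window = 50L,
                          proximity_exclude = 50L, n_run_min = 5L,
                          long_del_min = 100L,
                          microsat_source = c("annotation", "internal")) {
  stopifnot(cluster_max > 0, cluster_window >= cluster_max,
            proximity_exclude > 0, n_run_min > 0, long_del_min > 0)
  structure(list(cluster_max = as.integer(cluster_max),
                 cluster_window = as.integer(cluster_window),
                 proximity_exclude = as.integer(proximity_exclude),
                 n_run_min = as.integer(n_run_min),
                 long_del_min = as.integer(long_del_min),
                 microsat_source = match.arg(microsat_source)),
            class = "filter_params")
}

#' Collect artifact intervals for SNP filtering
#'
#' Gathers, in A-frame coordinates, the artifact classes the filter
#' excludes around: N-runs (from the variant table), long indels,
#' unaligned blocks (from the co-linear map) and microsatellite
#' intervals — either Simple_repeat annotation features or the internal
#' detector run on both sequences.
#'
#' @param variants variant table from [extract_variants()].
#' @param map the [close_gaps()] co-linear map (or `NULL`).
#' @param params a [filter_params()].
#' @param annotation optional annotation data frame whose
#'   `Simple_repeat` features supply microsatellite intervals.
#' @param seq_a,seq_b optional sequences for the internal
#'   microsatellite detector (B intervals are projected through `map`).
#' @return Data frame with columns `kind` (`n_run`, `long_deletion`,
#'   `microsatellite`, `unaligned`), `start`, `end` (A frame; long
#'   deletions with no A-side extent are zero-width).
#' @export
collect_artifacts <- function(variants, map = NULL,
                              params = filter_params(),
                              annotation = NULL,
                              seq_a = NULL, seq_b = NULL) {
  art <- list()
  add <- function(kind, start, end) {
    if (length(start))
      art[[length(art) + 1L]] <<- data.frame(
        kind = kind, start = as.integer(start), end = as.integer(end),
        stringsAsFactors = FALSE)
  }
  nr <- variants[variants$kind == "N_run" &
                   variants$length >= params$n_run_min, , drop = FALSE]
  add("n_run", nr$a_pos, nr$a_pos + nr$length)
  ins <- variants[variants$kind == "insertion" &
                    variants$length >= params$long_del_min, ,
                  drop = FALSE]
  add("long_deletion", ins$a_pos, ins$a_pos + ins$length)
  del <- variants[variants$kind == "deletion" &
                    variants$length >= params$long_del_min, ,
                  drop = FALSE]
  add("long_deletion", del$a_pos, del$a_pos)  # zero-width in A
  if (!is.null(map)) {
    un <- map$blocks[map$blocks$kind == "unaligned", , drop = FALSE]
    add("unaligned", un$a_start, un$a_end)
  }
  if (params$microsat_source == "annotation") {
    if (!is.null(annotation)) {
      ms <- annotation[grepl("Simple_repeat", annotation$rep_class_family),
                       , drop = FALSE]
      add("microsatellite", ms$q_start, ms$q_end)
    }
  } else {
    if (!is.null(seq_a)) {
      sr <- detect_simple_repeats(seq_a)
      add("microsatellite", sr$start, sr$end)
    }
    if (!is.null(seq_b) && !is.null(map)) {
      sr <- detect_simple_repeats(seq_b)
      if (nrow(sr)) {
        s <- project_b_to_a(map, sr$start)
        add("microsatellite", s, s + (sr$end - sr$start))
      }
    }
  }
  if (!length(art))
    return(data.frame(kind = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  do.call(rbind, art)
}

#' Apply the SNP exclusion rules
#'
#' A SNP is excluded iff it (i) lies in any sliding `cluster_window`-nt
#' span containing more than `cluster_max` SNPs, (ii) lies within
#' `proximity_exclude` bp (inclusive) of an N-run of at least
#' `n_run_min` bp or an indel of at least `long_del_min` bp, (iii)
#' falls inside a microsatellite interval, or (iv) falls inside an
#' unaligned block.  Indel and N-run records are never counted as SNPs.
#'
#' @param variants variant table from [extract_variants()] (or any data
#'   frame with `kind` and `a_pos`).
#' @param artifacts artifact intervals from [collect_artifacts()].
#' @param params a [filter_params()].
#' @return An object of class `filtered_variants`: list with `kept`
#'   (data frame of retained SNP records), `excluded` (SNP records plus
#'   `reason`), and `positions` (sorted kept A-frame positions).
#' @export
filter_snps <- function(variants, artifacts = NULL,
                        params = filter_params()) {
  if (is.null(artifacts))
    artifacts <- data.frame(kind = character(), start = integer(),
                            end = integer())
  snps <- variants[variants$kind == "SNP", , drop = FALSE]
  snps <- snps[order(snps$a_pos), , drop = FALSE]
  n <- nrow(snps)
  reason <- rep("", n)
  if (n) {
    p <- snps$a_pos
    ## (i) cluster rule: windows anchored at each SNP suffice to cover
    ## every integer-offset window
    w <- params$cluster_window
    j2 <- findInterval(p + (w - 1L) + 0.5, p)
    for (i in seq_len(n)) {
      if (j2[i] - i + 1L > params$cluster_max)
        reason[i:j2[i]] <- ifelse(reason[i:j2[i]] == "", "cluster",
                                  reason[i:j2[i]])
    }
    prox <- params$proximity_exclude
    flag <- function(kinds, label, pad) {
      a <- artifacts[artifacts$kind %in% kinds, , drop = FALSE]
      if (!nrow(a)) return(invisible())
      d <- dist_to_intervals(p, a$start, a$end)
      hit <- reason == "" & d <= pad
      reason[hit] <<- label
      invisible()
    }
    flag("n_run", "near_N", prox)
    flag("long_deletion", "near_long_deletion", prox)
    flag("microsatellite", "microsatellite", 0L)
    flag("unaligned", "unaligned", 0L)
  }
  kept <- snps[reason == "", , drop = FALSE]
  excluded <- snps[reason != "", , drop = FALSE]
  excluded$reason <- reason[reason != ""]
  rownames(kept) <- rownames(excluded) <- NULL
  structure(list(kept = kept, excluded = excluded,
                 positions = sort(kept$a_pos), params = params),
            class = "filtered_variants")
}

#' @export
print.filtered_variants <- function(x, ...) {
  cat("filtered_variants:", nrow(x$kept), "kept,",
      nrow(x$excluded), "excluded\n")
  if (nrow(x$excluded))
    print(table(x$excluded$reason))
  invisible(x)
}

#' Per-SNP filter report
#'
#' @param filtered a [filter_snps()] result.
#' @return Data frame with one row per input SNP (`a_pos`, `b_pos`,
#'   `ref`, `alt`, `kept`, `reason`), sorted by position.
#' @export
filter_report <- function(filtered) {
  k <- filtered$kept
  e <- filtered$excluded
  cols <- c("a_pos", "b_pos", "ref", "alt")
  cols_k <- intersect(cols, names(k))
  out <- rbind(
    if (nrow(k)) cbind(k[, cols_k, drop = FALSE], kept = TRUE,
                       reason = "") else NULL,
    if (nrow(e)) cbind(e[, cols_k, drop = FALSE], kept = FALSE,
                       reason = e$reason) else NULL)
  if (is.null(out))
    return(data.frame(a_pos = integer(), kept = logical(),
                      reason = character()))
  out <- out[order(out$a_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
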