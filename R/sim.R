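# Mosaic-haplotype simulator.
#
# Haplotypes are mosaics of ancestral blocks over a shared "base"
# coordinate frame.  All length-preserving edits (ancestral and private
# substitutions, planted SNP clusters, N-runs, microsatellite tracts,
# motif copies) are applied in the base frame; insertions (TE
# presence/absence) and long deletions are applied afterwards, with an
# explicit monotone coordinate map per haplotype.  Truth is exact: SNP
# truth is derived by direct comparison of the final base-frame
# sequences, never from the sampling intentions.

DECOY_CATALOG <- data.frame(
  rep_name = c("AluSx", "AluY", "L1M5", "L2a", "MIRb", "MLT1E", "MER20"),
  rep_class = c("SINE/Alu", "SINE/Alu", "LINE/L1", "LINE/L2", "SINE/MIR",
                "LTR/ERVL-MaLR", "DNA/hAT-Charlie"),
  min_len = c(150L, 280L, 400L, 300L, 150L, 350L, 200L),
  max_len = c(310L, 310L, 1500L, 900L, 260L, 600L, 400L),
  stringsAsFactors = FALSE
)

#' Synthetic transposable-element library
#'
#' Fixed small library of synthetic TE consensus-like sequences used by
#' the simulator: an Alu-sized element, an SVA-sized element, a solitary
#' LTR, and a 7-kb mosaic element composed of ten sub-element parts
#' (emulating composite indels whose RepeatMasker annotation is a run of
#' several family members).  Sequences are generated from a fixed
#' internal seed, so the library is identical across sessions.
#'
#' @return A list of entries; each entry has `name`, `sequence`,
#'   `class_family` and (for the mosaic) `member_parts`, a data frame of
#'   `(name, offset, length)` tiling the entry without overlap.
#' @export
te_library <- function() {
  with_seed(990001L, {
    mk <- function(name, len, cf) {
      list(name = name, sequence = random_dna(len), class_family = cf,
           member_parts = NULL)
    }
    alu <- mk("AluYs1", 300L, "SINE/Alu")
    sva <- mk("SVAs1", 1600L, "Retroposon/SVA")
    ltr <- mk("LTRs42", 480L, "LTR/ERVK")
    part_names <- c("LTR9s", "AluSxs", "HUERSP3s", "MER51s", "MER58s",
                    "MER61s", "MER63s", "LTR33s", "MLT1Es", "MSTCs")
    part_cf <- c("LTR/ERV1", "SINE/Alu", "LTR/ERV1", "LTR/ERV1",
                 "DNA/hAT-Charlie", "LTR/ERV1", "LTR/ERV1", "LTR/ERVL",
                 "LTR/ERVL-MaLR", "LTR/ERVL-MaLR")
    part_len <- c(660L, 300L, 1800L, 500L, 340L, 700L, 620L, 480L,
                  800L, 800L)
    mosaic <- list(name = "MOSAIC7K", sequence = random_dna(sum(part_len)),
                   class_family = "Mosaic/composite",
                   member_parts = data.frame(
                     name = part_names,
                     class_family = part_cf,
                     offset = cumsum(c(0L, part_len[-length(part_len)])),
                     length = part_len,
                     stringsAsFactors = FALSE))
    out <- list(alu, sva, ltr, mosaic)
    names(out) <- vapply(out, `[[`, "", "name")
    out
  })
}

#' PRDM9-associated motif set
#'
#' The recombination-activating partial binding 8-mer `CCTCCCCT`, the
#' recombination-suppressing 7-mer `ATCCATG`, their reverse complements
#' `AGGGGAGG` and `CATGGAT`, and the degenerate 13-mer PRDM9 binding
#' motif `CCNCCNTNNCCNC`.  Each motif is searched strand-explicitly on
#' the forward strand; a motif and its reverse complement are distinct
#' entries and their hits are never merged.
#'
#' @return Data frame with columns `id` and `pattern` (IUPAC DNA text).
#' @export
prdm9_motifs <- function() {
  data.frame(
    id = c("CCTCCCCT", "AGGGGAGG", "ATCCATG", "CATGGAT", "PRDM9-13mer"),
    pattern = c("CCTCCCCT", "AGGGGAGG", "ATCCATG", "CATGGAT",
                "CCNCCNTNNCCNC"),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Defines a panel of mosaic haplotypes.  Defaults reproduce the study
#' conditions the package is aimed at: pairs of ~0.6 Mb haplotypes whose
#' unshared ancestral blocks diverge at 2 x 4e-4 substitutions per bp
#' (SNP-rich, 80 SNPs/100 kb between different ancestors) and whose
#' shared blocks retain a residual 2 x 2e-5 divergence (SNP-poor,
#' 4 SNPs/100 kb).
#'
#' @param seed integer RNG seed; the whole panel is a deterministic
#'   function of the configuration including this seed.
#' @param length base-frame sequence length in bp.
#' @param haplotypes character vector of haplotype names.
#' @param branch_divergence substitutions per bp per ancestor branch;
#'   a pair with different block ancestors has expected SNP density
#'   `2 * branch_divergence` there.
#' @param background_divergence private substitutions per bp per
#'   haplotype; same-ancestor blocks show `2 * background_divergence`.
#' @param block_plan data frame with columns `start`, `end` and one
#'   column per haplotype giving the ancestor label of that block; the
#'   blocks must tile `[0, length)`.  `NULL` means one block shared by
#'   all haplotypes (ancestor "A1").
#' @param te_plan data frame with columns `entry` (a [te_library()]
#'   name), `position` (base-frame insertion point) and one logical
#'   column per haplotype (presence).  `NULL` for none.
#' @param noise_plan data frame with columns `kind` (one of `n_run`,
#'   `snp_cluster`, `microsat`, `deletion`), `hap`, `position`, and
#'   optional `length` (defaults 200 / 40 / 60 / 1000 by kind) and
#'   `unit` (microsatellite unit, default "CA").  SNP clusters plant 8
#'   substitutions inside a 40-bp window (violating the >5-in-50-nt
#'   rule); microsatellite tracts are overwritten in every haplotype and
#'   receive 2 substitutions in the named haplotype.
#' @param motif_plan data frame with columns `id`, `pattern`, optional
#'   `position` (`NA` = place automatically) and `inside_repeat`
#'   (logical: place inside a decoy repeat feature).  Planted copies are
#'   written into every haplotype; spurious copies of any planted
#'   pattern arising elsewhere are screened out, so the truth hit set is
#'   exact.
#' @param decoy_rate expected decoy repeat features per bp emitted in
#'   every haplotype's annotation (default 1/1500, matching the
#'   observed density of roughly 1200 interspersed repeats per Mb in
#'   the MHC class II region; decoys also supply the flank anchors for
#'   dimorphic-TE calling).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed, length = 600000L, haplotypes = c("h1", "h2"),
                       branch_divergence = 4e-4,
                       background_divergence = 2e-5,
                       block_plan = NULL, te_plan = NULL,
                       noise_plan = NULL, motif_plan = NULL,
                       decoy_rate = 1 / 1500) {
  length <- as.integer(length)
  stopifnot(length > 0, length(haplotypes) >= 1,
            branch_divergence >= 0, background_divergence >= 0,
            branch_divergence >= background_divergence)
  if (is.null(block_plan)) {
    block_plan <- data.frame(start = 0L, end = length)
    for (h in haplotypes) block_plan[[h]] <- "A1"
  }
  stopifnot(all(haplotypes %in% names(block_plan)))
  o <- order(block_plan$start)
  block_plan <- block_plan[o, , drop = FALSE]
  if (block_plan$start[1] != 0L ||
      block_plan$end[nrow(block_plan)] != length ||
      (nrow(block_plan) > 1 &&
       any(block_plan$start[-1] != block_plan$end[-nrow(block_plan)])))
    stop("block_plan must tile [0, length) without gaps or overlap")
  if (!is.null(noise_plan) && nrow(noise_plan)) {
    defaults <- c(n_run = 200L, snp_cluster = 40L, microsat = 60L,
                  deletion = 1000L)
    if (is.null(noise_plan$length)) noise_plan$length <- NA_integer_
    miss <- is.na(noise_plan$length)
    noise_plan$length[miss] <- defaults[noise_plan$kind[miss]]
    if (is.null(noise_plan$unit)) noise_plan$unit <- NA_character_
    noise_plan$unit[noise_plan$kind == "microsat" &
                    is.na(noise_plan$unit)] <- "CA"
    bad <- setdiff(noise_plan$kind, names(defaults))
    if (length(bad)) stop("unknown noise kind: ", paste(bad, collapse = ", "))
  }
  if (!is.null(motif_plan) && nrow(motif_plan)) {
    if (is.null(motif_plan$position)) motif_plan$position <- NA_integer_
    if (is.null(motif_plan$inside_repeat)) motif_plan$inside_repeat <- FALSE
  }
  structure(list(seed = as.integer(seed), length = length,
                 haplotypes = haplotypes,
                 branch_divergence = branch_divergence,
                 background_divergence = background_divergence,
                 block_plan = block_plan, te_plan = te_plan,
                 noise_plan = noise_plan, motif_plan = motif_plan,
                 decoy_rate = decoy_rate),
            class = "sim_config")
}

#' Random two-haplotype mosaic block plan
#'
#' Draws `n_breakpoints` breakpoints (uniform, at least `min_segment`
#' apart and from the ends) and assigns ancestors so the pair alternates
#' between shared (SNP-poor) and unshared (SNP-rich) blocks, starting
#' from a random state.
#'
#' @param length sequence length (bp).
#' @param n_breakpoints number of ancestor switches between the pair.
#' @param min_segment minimum block length (bp).
#' @param haplotypes two haplotype names.
#' @return A block plan data frame suitable for [sim_config()].
#' @export
random_pair_plan <- function(length, n_breakpoints,
                             min_segment = 50000L,
                             haplotypes = c("h1", "h2")) {
  stopifnot(length(haplotypes) == 2, n_breakpoints >= 0,
            (n_breakpoints + 1) * min_segment <= length)
  repeat {
    bp <- sort(sample.int(length - 1L, n_breakpoints))
    gaps <- diff(c(0L, bp, length))
    if (all(gaps >= min_segment)) break
  }
  starts <- c(0L, bp)
  ends <- c(bp, as.integer(length))
  shared_first <- sample(c(TRUE, FALSE), 1)
  shared <- rep(c(shared_first, !shared_first),
                length.out = n_breakpoints + 1)
  plan <- data.frame(start = starts, end = ends)
  plan[[haplotypes[1]]] <- "A1"
  plan[[haplotypes[2]]] <- ifelse(shared, "A1", "A2")
  plan
}

## ---- internal helpers ------------------------------------------------

# throw if any two planted intervals overlap; `what` names each row
check_overlaps <- function(starts, ends, what) {
  if (length(starts) < 2) return(invisible())
  o <- order(starts)
  s <- starts[o]; e <- ends[o]; w <- what[o]
  hit <- which(s[-1] < e[-length(e)])
  if (length(hit))
    stop("planted features overlap: ", w[hit[1]], " collides with ",
         w[hit[1] + 1L])
  invisible()
}

# draw a concrete instance of an IUPAC pattern
concrete_motif <- function(pattern) {
  amb <- Biostrings::IUPAC_CODE_MAP
  paste(vapply(strsplit(pattern, "")[[1]], function(ch) {
    opts <- strsplit(amb[[ch]], "")[[1]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, ""), collapse = "")
}

# independent sliding-window cluster flag used for truth bookkeeping:
# TRUE for every position lying in some 50-nt span holding > maxn of them
truth_cluster_flag <- function(pos, window = 50L, maxn = 5L) {
  if (length(pos) == 0) return(logical(0))
  pos <- as.integer(pos)
  flag <- rep(FALSE, length(pos))
  n <- length(pos)
  j <- 1L
  for (i in seq_len(n)) {
    while (pos[i] - pos[j] >= window) j <- j + 1L
    if (i - j + 1L > maxn) flag[j:i] <- TRUE
  }
  flag
}

# build one haplotype's post-indel sequence + coordinate map
apply_indels <- function(seq_raw, events) {
  # events: data.frame(position, del_len, ins_seq) sorted by position;
  # del_len > 0 removes [position, position+del_len); ins_seq inserted
  # before base `position`
  n <- length(seq_raw)
  if (nrow(events) == 0) {
    return(list(seq = seq_raw,
                map = identity_map(n)))
  }
  pieces <- list()
  map_bs <- integer(0); map_be <- integer(0); map_hs <- integer(0)
  cur_base <- 0L; cur_hap <- 0L
  for (i in seq_len(nrow(events))) {
    p <- events$position[i]
    if (p > cur_base) {
      pieces[[length(pieces) + 1L]] <- seq_raw[(cur_base + 1L):p]
      map_bs <- c(map_bs, cur_base); map_be <- c(map_be, p)
      map_hs <- c(map_hs, cur_hap)
      cur_hap <- cur_hap + (p - cur_base)
      cur_base <- p
    }
    ins <- events$ins_seq[i]
    if (nzchar(ins)) {
      pieces[[length(pieces) + 1L]] <- charToRaw(ins)
      cur_hap <- cur_hap + nchar(ins)
    }
    cur_base <- cur_base + events$del_len[i]
  }
  if (cur_base < n) {
    pieces[[length(pieces) + 1L]] <- seq_raw[(cur_base + 1L):n]
    map_bs <- c(map_bs, cur_base); map_be <- c(map_be, n)
    map_hs <- c(map_hs, cur_hap)
  }
  list(seq = do.call(c, pieces),
       map = data.frame(base_start = map_bs, base_end = map_be,
                        hap_start = map_hs))
}

# RepeatMasker-like feature row(s) for a planted TE entry at hap coords
te_feature_rows <- function(entry, hap_start) {
  if (is.null(entry$member_parts)) {
    data.frame(rep_name = entry$name,
               rep_class_family = entry$class_family,
               q_start = hap_start,
               q_end = hap_start + nchar(entry$sequence),
               strand = "+", stringsAsFactors = FALSE)
  } else {
    mp <- entry$member_parts
    data.frame(rep_name = mp$name,
               rep_class_family = mp$class_family,
               q_start = hap_start + mp$offset,
               q_end = hap_start + mp$offset + mp$length,
               strand = "+", stringsAsFactors = FALSE)
  }
}

## ---- the generator ---------------------------------------------------

#' Simulate a mosaic haplotype panel with an exact truth set
#'
#' Generates the panel described by a [sim_config()]: haplotype
#' sequences (post-indel, each in its own coordinate frame),
#' RepeatMasker-style annotations per haplotype (planted TEs, planted
#' microsatellite tracts, and shared decoy repeat features), and a truth
#' set recording, per haplotype pair, the ancestor-switch breakpoints
#' and the exact SNP list with its expected filter outcome, plus planted
#' TE loci, motif copies, noise artifacts and per-haplotype coordinate
#' maps.
#'
#' @param config a [sim_config()].
#' @return A list of class `hap_panel` with elements `sequences` (named
#'   character vector), `annotations` (named list of feature data
#'   frames, 0-based half-open), `truth` (see Details) and `config`.
#' @details The truth element contains: `breakpoints` and `snps` (lists
#'   keyed `"hapA|hapB"`), `te_loci`, `motifs`, `noise`, `decoys` and
#'   `coord_maps`.  Truth SNP positions are reported in the base frame
#'   and in both haplotype frames.  Expected filter outcomes are derived
#'   from the planted artifact geometry (cluster membership, proximity
#'   to N-runs/long deletions, microsatellite tracts), independently of
#'   the package's own filtering code.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_panel_impl(config))
}

simulate_panel_impl <- function(config) {
  L <- config$length
  haps <- config$haplotypes
  nh <- length(haps)
  lib <- te_library()
  tp <- config$te_plan
  np <- config$noise_plan
  mp <- config$motif_plan

  ## -- planted feature geometry (base frame) --
  feat_s <- integer(0); feat_e <- integer(0); feat_w <- character(0)
  if (!is.null(tp) && nrow(tp)) {
    for (i in seq_len(nrow(tp))) {
      if (!tp$entry[i] %in% names(lib))
        stop("unknown TE library entry: ", tp$entry[i])
      feat_s <- c(feat_s, tp$position[i])
      feat_e <- c(feat_e, tp$position[i] + 1L)  # zero-width insertion point
      feat_w <- c(feat_w, paste0("te:", tp$entry[i], "@", tp$position[i]))
    }
  }
  if (!is.null(np) && nrow(np)) {
    feat_s <- c(feat_s, np$position)
    feat_e <- c(feat_e, np$position + np$length)
    feat_w <- c(feat_w, paste0("noise:", np$kind, "@", np$position))
  }
  explicit_motifs <- !is.null(mp) && nrow(mp) && any(!is.na(mp$position))
  if (explicit_motifs) {
    em <- which(!is.na(mp$position))
    feat_s <- c(feat_s, mp$position[em])
    feat_e <- c(feat_e, mp$position[em] + nchar(mp$pattern[em]))
    feat_w <- c(feat_w, paste0("motif:", mp$id[em], "@", mp$position[em]))
  }
  if (length(feat_s)) {
    if (any(feat_s < 0 | feat_e > L))
      stop("planted feature outside [0, length)")
    check_overlaps(feat_s, feat_e, feat_w)
  }

  ## -- decoy repeat features, avoiding planted spans --
  n_decoy <- stats::rpois(1, L * config$decoy_rate)
  dec <- data.frame(rep_name = character(), rep_class = character(),
                    start = integer(), end = integer(),
                    strand = character(), stringsAsFactors = FALSE)
  occupied_s <- feat_s; occupied_e <- feat_e
  tries <- 0L
  while (nrow(dec) < n_decoy && tries < n_decoy * 60L) {
    tries <- tries + 1L
    ci <- sample.int(nrow(DECOY_CATALOG), 1)
    len <- sample(DECOY_CATALOG$min_len[ci]:DECOY_CATALOG$max_len[ci], 1)
    s <- sample.int(L - len, 1) - 1L
    if (any(s < occupied_e + 50L & s + len + 50L > occupied_s)) next
    dec <- rbind(dec, data.frame(
      rep_name = DECOY_CATALOG$rep_name[ci],
      rep_class = DECOY_CATALOG$rep_class[ci],
      start = s, end = s + len,
      strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE))
    occupied_s <- c(occupied_s, s); occupied_e <- c(occupied_e, s + len)
  }
  dec <- dec[order(dec$start), , drop = FALSE]
  rownames(dec) <- NULL

  ## -- motif auto-placement --
  if (!is.null(mp) && nrow(mp)) {
    for (i in seq_len(nrow(mp))) {
      if (!is.na(mp$position[i])) next
      mlen <- nchar(mp$pattern[i])
      pos <- NA_integer_
      for (try in 1:200) {
        if (isTRUE(mp$inside_repeat[i])) {
          if (!nrow(dec)) stop("no decoy features to host an inside-repeat motif")
          di <- sample.int(nrow(dec), 1)
          if (dec$end[di] - dec$start[di] < mlen + 8L) next
          cand <- dec$start[di] +
            sample.int(dec$end[di] - dec$start[di] - mlen - 7L, 1) + 3L
        } else {
          cand <- sample.int(L - mlen - 40L, 1) + 19L
          if (any(cand < dec$end + 20L & cand + mlen + 20L > dec$start)) next
        }
        if (any(cand < occupied_e + 20L & cand + mlen + 20L > occupied_s) &&
            !isTRUE(mp$inside_repeat[i])) next
        # never overlap another planted motif / noise / TE span
        if (any(cand < feat_e + 5L & cand + mlen + 5L > feat_s)) next
        pos <- cand
        break
      }
      if (is.na(pos)) stop("could not auto-place motif ", mp$id[i])
      mp$position[i] <- pos
      feat_s <- c(feat_s, pos); feat_e <- c(feat_e, pos + mlen)
      feat_w <- c(feat_w, paste0("motif:", mp$id[i], "@", pos))
    }
    check_overlaps(feat_s, feat_e, feat_w)
  }

  ## -- protected positions (no random substitutions) --
  protected <- rep(FALSE, L)
  if (length(feat_s)) {
    for (i in seq_along(feat_s))
      if (feat_e[i] > feat_s[i])
        protected[(feat_s[i] + 1L):feat_e[i]] <- TRUE
  }
  allowed <- which(!protected)  # 1-based

  ## -- base sequence and substitution sets --
  base_raw <- charToRaw(random_dna(L))
  others <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                 G = c("A", "C", "T"), T = c("A", "C", "G"))
  draw_subs <- function(rate) {
    n <- rbinom(1, L, rate)
    n <- min(n, length(allowed))
    pos <- sort(sample(allowed, n))  # 1-based
    ref <- strsplit(rawToChar(base_raw[pos]), "")[[1]]
    alt <- vapply(ref, function(b) sample(others[[b]], 1), "",
                  USE.NAMES = FALSE)
    list(pos = pos, alt = alt)
  }
  anc_labels <- unique(unlist(config$block_plan[haps]))
  anc_rate <- config$branch_divergence - config$background_divergence
  anc_subs <- lapply(setNames(anc_labels, anc_labels),
                     function(a) draw_subs(anc_rate))

  ## -- assemble base-frame haplotypes --
  hap_raw <- list()
  for (h in haps) {
    s <- base_raw
    for (b in seq_len(nrow(config$block_plan))) {
      a <- config$block_plan[[h]][b]
      sub <- anc_subs[[a]]
      inblk <- sub$pos > config$block_plan$start[b] &
        sub$pos <= config$block_plan$end[b]
      if (any(inblk))
        s[sub$pos[inblk]] <- charToRaw(paste(sub$alt[inblk], collapse = ""))
    }
    priv <- draw_subs(config$background_divergence)
    if (length(priv$pos))
      s[priv$pos] <- charToRaw(paste(priv$alt, collapse = ""))
    hap_raw[[h]] <- s
  }

  ## -- planted noise (length-preserving part) --
  noise_truth <- data.frame(kind = character(), hap = character(),
                            start = integer(), end = integer(),
                            stringsAsFactors = FALSE)
  cluster_spans <- list()
  if (!is.null(np) && nrow(np)) {
    for (i in seq_len(nrow(np))) {
      kind <- np$kind[i]; h <- np$hap[i]
      s0 <- np$position[i]; len <- np$length[i]
      if (kind == "n_run") {
        hap_raw[[h]][(s0 + 1L):(s0 + len)] <- charToRaw(
          paste(rep("N", len), collapse = ""))
      } else if (kind == "snp_cluster") {
        off <- sort(sample.int(len, 8L)) - 1L
        pos <- s0 + off + 1L
        ref <- strsplit(rawToChar(hap_raw[[h]][pos]), "")[[1]]
        alt <- vapply(ref, function(b) sample(others[[b]], 1), "",
                      USE.NAMES = FALSE)
        hap_raw[[h]][pos] <- charToRaw(paste(alt, collapse = ""))
        cluster_spans[[length(cluster_spans) + 1L]] <- c(s0, s0 + len)
      } else if (kind == "microsat") {
        unit <- np$unit[i]
        tract <- substr(paste(rep(unit, ceiling(len / nchar(unit))),
                              collapse = ""), 1L, len)
        for (hh in haps)
          hap_raw[[hh]][(s0 + 1L):(s0 + len)] <- charToRaw(tract)
        # two substitutions inside the tract in the named haplotype
        pos <- s0 + sort(sample(seq(5L, len - 5L), 2L))
        ref <- strsplit(rawToChar(hap_raw[[h]][pos]), "")[[1]]
        alt <- vapply(ref, function(b) sample(others[[b]], 1), "",
                      USE.NAMES = FALSE)
        hap_raw[[h]][pos] <- charToRaw(paste(alt, collapse = ""))
      }
      # deletions handled in the indel phase
      noise_truth <- rbind(noise_truth, data.frame(
        kind = kind, hap = h, start = s0, end = s0 + len,
        stringsAsFactors = FALSE))
    }
  }

  ## -- planted motifs (all haplotypes; identical copies) --
  motif_truth <- data.frame(id = character(), pattern = character(),
                            position = integer(), matched = character(),
                            category = character(),
                            stringsAsFactors = FALSE)
  if (!is.null(mp) && nrow(mp)) {
    for (i in seq_len(nrow(mp))) {
      inst <- concrete_motif(mp$pattern[i])
      s0 <- mp$position[i]
      for (h in haps)
        hap_raw[[h]][(s0 + 1L):(s0 + nchar(inst))] <- charToRaw(inst)
      cat_i <- "Non-repeat region"
      cover <- which(dec$start <= s0 & dec$end >= s0 + nchar(inst))
      if (length(cover))
        cat_i <- paste0(dec$rep_name[cover[1]], "|", dec$rep_class[cover[1]])
      motif_truth <- rbind(motif_truth, data.frame(
        id = mp$id[i], pattern = mp$pattern[i], position = s0,
        matched = inst, category = cat_i, stringsAsFactors = FALSE))
    }
    ## screen spurious copies of every planted pattern
    pats <- unique(mp[, c("id", "pattern")])
    for (iter in 1:25) {
      dirty <- FALSE
      for (pi in seq_len(nrow(pats))) {
        want <- motif_truth$position[motif_truth$pattern == pats$pattern[pi]]
        for (h in haps) {
          hits <- scan_motifs(rawToChar(hap_raw[[h]]),
                              data.frame(id = pats$id[pi],
                                         pattern = pats$pattern[pi]))
          spur <- setdiff(hits$position, want)
          for (sp in spur) {
            mlen <- nchar(pats$pattern[pi])
            cand <- (sp + 1L):(sp + mlen)
            free <- cand[!protected[cand]]
            if (!length(free)) free <- cand
            j <- free[ceiling(length(free) / 2)]
            b <- rawToChar(hap_raw[[haps[1]]][j])
            if (b == "N") next
            nb <- sample(others[[b]], 1)
            for (hh in haps) hap_raw[[hh]][j] <- charToRaw(nb)
            dirty <- TRUE
          }
        }
      }
      if (!dirty) break
      if (iter == 25L) stop("motif screening failed to converge")
    }
  }

  ## -- truth SNPs per pair (direct comparison, base frame) --
  nrun_by_hap <- split(noise_truth[noise_truth$kind == "n_run", ],
                       noise_truth$hap[noise_truth$kind == "n_run"])
  del_rows <- noise_truth[noise_truth$kind == "deletion", , drop = FALSE]
  ms_rows <- noise_truth[noise_truth$kind == "microsat", , drop = FALSE]
  pair_key <- function(a, b) paste(a, b, sep = "|")
  breakpoints <- list(); snp_truth <- list()
  if (nh >= 2) {
    for (ai in 1:(nh - 1)) for (bi in (ai + 1):nh) {
      a <- haps[ai]; b <- haps[bi]
      ra <- hap_raw[[a]]; rb <- hap_raw[[b]]
      isN <- ra == charToRaw("N") | rb == charToRaw("N")
      diffp <- which(ra != rb & !isN)  # 1-based
      pos0 <- diffp - 1L               # 0-based
      ## expected filter outcome from planted geometry
      reason <- rep("", length(pos0))
      cl <- truth_cluster_flag(pos0)
      reason[cl] <- "cluster"
      prox <- 50L
      nr <- rbind(nrun_by_hap[[a]], nrun_by_hap[[b]])
      if (!is.null(nr) && nrow(nr)) {
        d <- dist_to_intervals(pos0, nr$start, nr$end)
        reason[reason == "" & d <= prox] <- "near_N"
      }
      dl <- del_rows[del_rows$hap %in% c(a, b), , drop = FALSE]
      drop_snp <- rep(FALSE, length(pos0))
      if (nrow(dl)) {
        inside <- in_intervals(pos0, dl$start, dl$end)
        drop_snp <- drop_snp | inside
        d <- dist_to_intervals(pos0, dl$start, dl$end)
        reason[reason == "" & d <= prox] <- "near_long_deletion"
      }
      if (nrow(ms_rows)) {
        inms <- in_intervals(pos0, ms_rows$start, ms_rows$end)
        reason[reason == "" & inms] <- "microsatellite"
      }
      keep <- !drop_snp
      st <- data.frame(base_pos = pos0[keep],
                       expect_kept = reason[keep] == "",
                       reason = reason[keep], stringsAsFactors = FALSE)
      snp_truth[[pair_key(a, b)]] <- st
      ## breakpoints: transitions of ancestor-identity between the pair
      same <- config$block_plan[[a]] == config$block_plan[[b]]
      if (nrow(config$block_plan) > 1) {
        tr <- which(same[-1] != same[-length(same)])
        breakpoints[[pair_key(a, b)]] <- config$block_plan$end[tr]
      } else breakpoints[[pair_key(a, b)]] <- integer(0)
    }
  }

  ## -- indel phase --
  sequences <- character(0)
  coord_maps <- list()
  te_loci <- NULL
  if (!is.null(tp) && nrow(tp)) {
    te_loci <- data.frame(locus = paste0("TE_", seq_len(nrow(tp))),
                          entry = tp$entry, base_pos = tp$position,
                          length = vapply(tp$entry, function(e)
                            nchar(lib[[e]]$sequence), integer(1)),
                          stringsAsFactors = FALSE)
    for (h in haps) te_loci[[paste0("present.", h)]] <- tp[[h]]
    for (h in haps) te_loci[[paste0("pos.", h)]] <- NA_integer_
  }
  for (h in haps) {
    ev <- data.frame(position = integer(), del_len = integer(),
                     ins_seq = character(), stringsAsFactors = FALSE)
    if (!is.null(tp) && nrow(tp)) {
      pres <- which(as.logical(tp[[h]]))
      if (length(pres))
        ev <- rbind(ev, data.frame(
          position = tp$position[pres], del_len = 0L,
          ins_seq = vapply(tp$entry[pres],
                           function(e) lib[[e]]$sequence, ""),
          stringsAsFactors = FALSE))
    }
    dl <- del_rows[del_rows$hap == h, , drop = FALSE]
    if (nrow(dl))
      ev <- rbind(ev, data.frame(position = dl$start, del_len =
                                   dl$end - dl$start, ins_seq = "",
                                 stringsAsFactors = FALSE))
    ev <- ev[order(ev$position), , drop = FALSE]
    res <- apply_indels(hap_raw[[h]], ev)
    sequences[h] <- rawToChar(res$seq)
    coord_maps[[h]] <- res$map
    if (!is.null(te_loci)) {
      for (i in seq_len(nrow(te_loci))) {
        if (te_loci[[paste0("present.", h)]][i]) {
          # insertion point: hap coordinate where the insertion begins
          hp <- map_to_hap(res$map, te_loci$base_pos[i])
          te_loci[[paste0("pos.", h)]][i] <- hp - te_loci$length[i] +
            0L  # placeholder, fixed below
        }
      }
    }
  }
  # insertion start in hap frame: base position p maps to the first base
  # *after* the insertion, so subtract the insertion length
  # (computed above); recompute cleanly here for correctness:
  if (!is.null(te_loci)) {
    for (h in haps) {
      for (i in seq_len(nrow(te_loci))) {
        if (!te_loci[[paste0("present.", h)]][i]) next
        m <- coord_maps[[h]]
        after <- map_to_hap(m, te_loci$base_pos[i])
        te_loci[[paste0("pos.", h)]][i] <- after - te_loci$length[i]
      }
    }
  }

  ## -- annotations per haplotype --
  annotations <- list()
  for (h in haps) {
    m <- coord_maps[[h]]
    rows <- list()
    if (nrow(dec)) {
      qs <- map_to_hap(m, dec$start)
      qe_last <- map_to_hap(m, dec$end - 1L)
      ok <- !is.na(qs) & !is.na(qe_last)
      if (any(ok))
        rows[[length(rows) + 1L]] <- data.frame(
          rep_name = dec$rep_name[ok], rep_class_family = dec$rep_class[ok],
          q_start = qs[ok], q_end = qe_last[ok] + 1L,
          strand = dec$strand[ok], stringsAsFactors = FALSE)
    }
    if (nrow(ms_rows)) {
      qs <- map_to_hap(m, ms_rows$start)
      qe <- map_to_hap(m, ms_rows$end - 1L)
      ok <- !is.na(qs) & !is.na(qe)
      if (any(ok))
        rows[[length(rows) + 1L]] <- data.frame(
          rep_name = "(CA)n", rep_class_family = "Simple_repeat",
          q_start = qs[ok], q_end = qe[ok] + 1L, strand = "+",
          stringsAsFactors = FALSE)
    }
    if (!is.null(te_loci)) {
      for (i in seq_len(nrow(te_loci))) {
        if (!te_loci[[paste0("present.", h)]][i]) next
        rows[[length(rows) + 1L]] <-
          te_feature_rows(lib[[te_loci$entry[i]]],
                          te_loci[[paste0("pos.", h)]][i])
      }
    }
    ann <- if (length(rows)) do.call(rbind, rows) else
      data.frame(rep_name = character(), rep_class_family = character(),
                 q_start = integer(), q_end = integer(),
                 strand = character(), stringsAsFactors = FALSE)
    ann <- ann[order(ann$q_start), , drop = FALSE]
    n <- nrow(ann)
    ann <- data.frame(
      sw_score = if (n) sample(250:8000, n, replace = TRUE) else integer(),
      pct_div = if (n) round(runif(n, 0, 25), 1) else numeric(),
      pct_del = if (n) round(runif(n, 0, 5), 1) else numeric(),
      pct_ins = if (n) round(runif(n, 0, 5), 1) else numeric(),
      query = if (n) rep(h, n) else character(),
      q_start = ann$q_start, q_end = ann$q_end,
      strand = ifelse(ann$strand == "-", "C", ann$strand),
      rep_name = ann$rep_name,
      rep_class_family = ann$rep_class_family,
      rep_start = if (n) rep(1L, n) else integer(),
      rep_end = if (n) ann$q_end - ann$q_start else integer(),
      rep_left = if (n) rep(0L, n) else integer(),
      feature_id = if (n) seq_len(n) else integer(),
      stringsAsFactors = FALSE)
    annotations[[h]] <- ann
  }

  ## -- per-frame truth positions --
  if (nh >= 2) {
    for (key in names(snp_truth)) {
      ab <- strsplit(key, "|", fixed = TRUE)[[1]]
      st <- snp_truth[[key]]
      st$a_pos <- map_to_hap(coord_maps[[ab[1]]], st$base_pos)
      st$b_pos <- map_to_hap(coord_maps[[ab[2]]], st$base_pos)
      snp_truth[[key]] <- st
    }
  }
  motif_truth_frames <- motif_truth
  if (nrow(motif_truth)) {
    for (h in haps)
      motif_truth_frames[[paste0("pos.", h)]] <-
        map_to_hap(coord_maps[[h]], motif_truth$position)
  }

  structure(list(
    sequences = sequences,
    annotations = annotations,
    truth = list(breakpoints = breakpoints, snps = snp_truth,
                 te_loci = te_loci, motifs = motif_truth_frames,
                 noise = noise_truth, decoys = dec,
                 coord_maps = coord_maps),
    config = config), class = "hap_panel")
}

#' @export
print.hap_panel <- function(x, ...) {
  cat("hap_panel:", length(x$sequences), "haplotypes of base length",
      x$config$length, "bp\n")
  for (h in names(x$sequences))
    cat(sprintf("  %s: %d bp, %d annotation rows\n", h,
                nchar(x$sequences[[h]]), nrow(x$annotations[[h]])))
  invisible(x)
}

## ---- truth evaluation helpers ---------------------------------------

#' Rich-side boundary SNPs implied by a truth set
#'
#' For each planted ancestor-switch breakpoint of a pair, returns the
#' expected crossover position: the truth SNP (expected to be kept by
#' the filters) inside the SNP-rich flank nearest to the breakpoint.
#'
#' @param panel a `hap_panel`.
#' @param pair pair key `"hapA|hapB"` (default: first pair).
#' @return Data frame with `breakpoint` (base frame) and `boundary_snp`
#'   (A-frame position of the expected XO SNP; `NA` if the rich flank
#'   holds no kept SNP).
#' @export
truth_boundary_snps <- function(panel, pair = NULL) {
  tr <- panel$truth
  if (is.null(pair)) pair <- names(tr$breakpoints)[1]
  ab <- strsplit(pair, "|", fixed = TRUE)[[1]]
  bp <- tr$breakpoints[[pair]]
  st <- tr$snps[[pair]]
  kept <- st[st$expect_kept, , drop = FALSE]
  plan <- panel$config$block_plan
  same <- plan[[ab[1]]] == plan[[ab[2]]]
  out <- data.frame(breakpoint = bp, boundary_snp = NA_integer_)
  for (i in seq_along(bp)) {
    b <- bp[i]
    blk_left <- max(which(plan$end == b))
    rich_left <- !same[blk_left]
    if (rich_left) {
      lo <- plan$start[blk_left]
      cand <- kept$base_pos[kept$base_pos >= lo & kept$base_pos < b]
      if (length(cand)) out$boundary_snp[i] <- max(cand)
    } else {
      hi <- plan$end[blk_left + 1L]
      cand <- kept$base_pos[kept$base_pos >= b & kept$base_pos < hi]
      if (length(cand)) out$boundary_snp[i] <- min(cand)
    }
  }
  # report in the A frame of the pair
  m <- tr$coord_maps[[ab[1]]]
  out$boundary_snp_a <- map_to_hap(m, out$boundary_snp)
  out
}

## ---- truth serialization --------------------------------------------

#' Write and read a truth set
#'
#' Breakpoints are written as BED (0-based half-open, one 1-bp record
#' per breakpoint, chrom = pair key); all other tables as TSV with a
#' header.  `read_truth()` round-trips the files written by
#' `write_truth()` losslessly.
#'
#' @param truth the `truth` element of a [simulate_panel()] result.
#' @param dir output/input directory.
#' @return `write_truth()` returns `dir` invisibly; `read_truth()` a
#'   truth list.
#' @export
write_truth <- function(truth, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory: ", dir)
  bp <- data.frame(chrom = character(), start = integer(),
                   end = integer())
  for (key in names(truth$breakpoints)) {
    p <- truth$breakpoints[[key]]
    if (length(p))
      bp <- rbind(bp, data.frame(chrom = key, start = p, end = p + 1L))
  }
  bp <- bp[order(bp$chrom, bp$start), , drop = FALSE]
  write_bed(bp, file.path(dir, "breakpoints.bed"))
  snps <- do.call(rbind, lapply(names(truth$snps), function(key) {
    st <- truth$snps[[key]]
    if (nrow(st)) cbind(pair = key, st) else NULL
  }))
  if (is.null(snps))
    snps <- data.frame(pair = character(), base_pos = integer(),
                       expect_kept = logical(), reason = character(),
                       a_pos = integer(), b_pos = integer())
  write_tsv(snps, file.path(dir, "snp_truth.tsv"))
  write_tsv(truth$te_loci %||%
              data.frame(locus = character(), entry = character(),
                         base_pos = integer(), length = integer()),
            file.path(dir, "te_loci.tsv"))
  write_tsv(truth$motifs, file.path(dir, "motif_truth.tsv"))
  write_tsv(truth$noise, file.path(dir, "noise_truth.tsv"))
  maps <- do.call(rbind, lapply(names(truth$coord_maps), function(h)
    cbind(hap = h, truth$coord_maps[[h]])))
  if (is.null(maps))
    maps <- data.frame(hap = character(), base_start = integer(),
                       base_end = integer(), hap_start = integer())
  write_tsv(maps, file.path(dir, "coord_maps.tsv"))
  invisible(dir)
}

#' @rdname write_truth
#' @export
read_truth <- function(dir) {
  bed <- read_bed(file.path(dir, "breakpoints.bed"))
  snps <- read_tsv(file.path(dir, "snp_truth.tsv"))
  te <- read_tsv(file.path(dir, "te_loci.tsv"))
  motifs <- read_tsv(file.path(dir, "motif_truth.tsv"))
  noise <- read_tsv(file.path(dir, "noise_truth.tsv"))
  maps <- read_tsv(file.path(dir, "coord_maps.tsv"))
  pairs <- unique(c(bed$chrom, snps$pair))
  breakpoints <- lapply(setNames(pairs, pairs), function(k)
    as.integer(bed$start[bed$chrom == k]))
  snp_truth <- lapply(setNames(pairs, pairs), function(k) {
    st <- snps[snps$pair == k, setdiff(names(snps), "pair"), drop = FALSE]
    rownames(st) <- NULL
    st
  })
  coord_maps <- lapply(setNames(unique(maps$hap), unique(maps$hap)),
                       function(h) {
    m <- maps[maps$hap == h, c("base_start", "base_end", "hap_start")]
    rownames(m) <- NULL
    m
  })
  list(breakpoints = breakpoints, snps = snp_truth,
       te_loci = if (nrow(te)) te else NULL, motifs = motifs,
       noise = noise, coord_maps = coord_maps)
}

#' Write panel sequences, annotations and truth to a directory
#'
#' Writes `haplotypes.fasta`, one RepeatMasker-dialect `.out` file per
#' haplotype, and the truth files of [write_truth()] under
#' `truth/`.
#'
#' @param panel a `hap_panel`.
#' @param dir output directory (created if needed).
#' @export
write_panel <- function(panel, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory: ", dir)
  write_fasta(panel$sequences, file.path(dir, "haplotypes.fasta"))
  for (h in names(panel$annotations))
    write_repeatmasker(panel$annotations[[h]],
                       file.path(dir, paste0(h, ".out")))
  write_truth(panel$truth, file.path(dir, "truth"))
  invisible(dir)
}
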