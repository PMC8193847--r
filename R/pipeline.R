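# End-to-end orchestration: simulate -> compare -> filter -> segment ->
# XO -> dimorphic TE -> motifs -> linkage -> phylogeny, with all
# intermediate files written to an output directory.

#' Packaged demonstration simulation configuration
#'
#' A three-haplotype panel at study scale: 0.6 Mb haplotypes, three
#' ancestor-switch breakpoints between the first pair, four planted TE
#' loci (including the 7-kb ten-member mosaic), one artifact of each
#' noise class, and six planted PRDM9 motif copies (half inside decoy
#' repeats).
#'
#' @param seed integer seed.
#' @param length base-frame length in bp (default 600000).
#' @return A [sim_config()].
#' @export
demo_sim_config <- function(seed, length = 600000L) {
  haps <- c("h1", "h2", "h3")
  with_seed(derive_seed(seed, "demo-plan"), {
    min_seg <- max(5000L, min(50000L, length %/% 8L))
    plan <- random_pair_plan(length, 3L, min_segment = min_seg,
                             haplotypes = c("h1", "h2"))
    plan$h3 <- plan$h2
    lib <- te_library()
    n_te <- 4L
    entries <- c("AluYs1", "SVAs1", "LTRs42", "MOSAIC7K")
    te_pos <- sort(sample(seq(20000L, length - 20000L), n_te))
    te <- data.frame(entry = entries, position = te_pos,
                     stringsAsFactors = FALSE)
    te$h1 <- c(TRUE, TRUE, FALSE, TRUE)
    te$h2 <- c(FALSE, TRUE, TRUE, FALSE)
    te$h3 <- c(FALSE, FALSE, TRUE, FALSE)
    gap_ok <- function(pos, len) {
      all(abs(pos - te$position) > len + 2000L)
    }
    place <- function(len) {
      repeat {
        pos <- sample(seq(15000L, length - 15000L), 1)
        if (gap_ok(pos, len)) return(pos)
      }
    }
    noise <- data.frame(
      kind = c("n_run", "snp_cluster", "microsat", "deletion"),
      hap = c("h1", "h2", "h1", "h2"),
      position = c(place(200L), place(40L), place(60L), place(1000L)),
      stringsAsFactors = FALSE)
    motifs <- prdm9_motifs()
    motif_plan <- data.frame(
      id = motifs$id[c(1, 2, 3, 4, 5, 1)],
      pattern = motifs$pattern[c(1, 2, 3, 4, 5, 1)],
      position = NA_integer_,
      inside_repeat = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
      stringsAsFactors = FALSE)
    sim_config(seed = derive_seed(seed, "demo-sim"), length = length,
               haplotypes = haps, block_plan = plan, te_plan = te,
               noise_plan = noise, motif_plan = motif_plan)
  })
}

#' Run the XO-calling stage on two sequences
#'
#' Compare, collect artifacts, filter SNPs, profile densities,
#' segment, and call crossovers.
#'
#' @param seq_a,seq_b haplotype sequences.
#' @param fparams,sparams filter and segmentation parameters.
#' @param annotation optional annotation (A frame) supplying
#'   `Simple_repeat` microsatellite intervals; without it the internal
#'   detector is used.
#' @param pair pair label for the outputs.
#' @param density_window window for the density profile (default 500).
#' @return List with `comparison`, `artifacts`, `filtered`, `profile`,
#'   `segments`, `xos`.
#' @export
xo_stage <- function(seq_a, seq_b, fparams = filter_params(),
                     sparams = segment_params(), annotation = NULL,
                     pair = "A|B", density_window = 500L) {
  cmp <- compare_haplotypes(seq_a, seq_b)
  use_ann <- !is.null(annotation) &&
    fparams$microsat_source == "annotation"
  art <- collect_artifacts(
    cmp$variants, cmp$map, fparams,
    annotation = if (use_ann) annotation else NULL,
    seq_a = if (!use_ann) seq_a else NULL,
    seq_b = if (!use_ann) seq_b else NULL)
  if (!use_ann && fparams$microsat_source == "annotation") {
    # no annotation available: fall back to the internal detector
    art <- collect_artifacts(cmp$variants, cmp$map,
                             filter_params(microsat_source = "internal"),
                             seq_a = seq_a, seq_b = seq_b)
  }
  filt <- filter_snps(cmp$variants, art, fparams)
  span <- nchar(seq_a)
  mask <- art[art$kind %in% c("unaligned", "n_run"), , drop = FALSE]
  prof <- density_profile(filt, window = density_window, span = span,
                          mask = mask)
  seg <- classify_segments(filt, sparams, span)
  xos <- call_xos(seg, filt, pair = pair)
  list(comparison = cmp, artifacts = art, filtered = filt,
       profile = prof, segments = seg, xos = xos)
}

#' Run the full demonstration pipeline
#'
#' Simulates the packaged demo panel, runs the comparison/XO stage on
#' the first haplotype pair, calls dimorphic TE loci across the panel,
#' scans and classifies PRDM9 motifs, tabulates marker linkage, and
#' builds a p-distance NJ tree of simulated allele sequences.  All
#' declared outputs are written under `out_dir`.
#'
#' @param out_dir output directory.
#' @param seed integer seed; the run is fully deterministic given the
#'   seed.
#' @param length simulated haplotype length (default 600000 bp).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with every stage's results.
#' @export
run_pipeline <- function(out_dir, seed = 1L, length = 600000L,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create directory: ", out_dir)
  say("simulate: building demo panel (", length, " bp)")
  cfg <- demo_sim_config(seed, length = length)
  panel <- simulate_panel(cfg)
  write_panel(panel, file.path(out_dir, "panel"))
  say("compare/xo: h1 vs h2")
  st <- xo_stage(panel$sequences[["h1"]], panel$sequences[["h2"]],
                 annotation = panel$annotations[["h1"]],
                 pair = "h1|h2")
  write_tsv(st$comparison$variants, file.path(out_dir, "variants.tsv"))
  write_tsv(filter_report(st$filtered),
            file.path(out_dir, "filter_report.tsv"))
  write_tsv(st$profile, file.path(out_dir, "density_profile.tsv"))
  write_segments_bed(st$segments, file.path(out_dir, "segments.bed"),
                     chrom = "h1")
  write_xo_bed(st$xos, file.path(out_dir, "xos.bed"), chrom = "h1")
  say("te: dimorphic loci across the panel")
  dim_calls <- call_dimorphic_panel(panel$annotations)
  write_tsv(dim_calls$loci, file.path(out_dir, "dimorphic_loci.tsv"))
  pres <- data.frame(haplotype = rownames(dim_calls$presence),
                     dim_calls$presence, check.names = FALSE)
  write_tsv(pres, file.path(out_dir, "dimorphic_presence.tsv"))
  say("motifs: scan + repeat-overlap classification on h1")
  sv <- motif_survey(panel$sequences[["h1"]],
                     panel$annotations[["h1"]],
                     motifs = prdm9_motifs())
  write_tsv(sv$hits, file.path(out_dir, "motif_hits.tsv"))
  mat <- data.frame(category = rownames(sv$matrix), sv$matrix,
                    check.names = FALSE)
  write_tsv(mat, file.path(out_dir, "motif_matrix.tsv"))
  say("linkage: TE presence vs ancestry blocks")
  records <- pipeline_records(panel, dim_calls)
  link <- if (length(unique(records$locus)) >= 2) {
    loci <- unique(records$locus)
    linkage_percentages(records, loci[1], loci[2])
  } else NULL
  if (!is.null(link))
    write_tsv(link$table, file.path(out_dir, "linkage.tsv"))
  tab <- tabulate_haplotypes(records, unique(records$locus))
  write_tsv(tab$table, file.path(out_dir, "haplotype_table.tsv"))
  say("phylo: p-distance NJ of simulated allele panel")
  alleles <- simulate_allele_panel(derive_seed(seed, "alleles"))
  pd <- p_distance_matrix(alleles)
  nj <- neighbor_joining(pd)
  write_distance_tsv(pd, file.path(out_dir, "identity_matrix.tsv"))
  writeLines(nj$newick, file.path(out_dir, "tree.nwk"))
  invisible(list(panel = panel, xo = st, dimorphic = dim_calls,
                 motifs = sv, records = records, linkage = link,
                 haplotypes = tab, distances = pd, tree = nj))
}

# long-form marker records for the demo panel: TE presence plus the
# block-plan ancestor at each breakpointed block treated as loci
pipeline_records <- function(panel, dim_calls) {
  haps <- names(panel$sequences)
  rec <- list()
  pres <- dim_calls$presence
  for (l in colnames(pres)) {
    v <- pres[, l]
    rec[[length(rec) + 1L]] <- data.frame(
      haplotype = rownames(pres), locus = l,
      allele = ifelse(is.na(v), "GAP",
                      ifelse(v == 1, "present", "absent")),
      stringsAsFactors = FALSE)
  }
  plan <- panel$config$block_plan
  for (b in seq_len(nrow(plan))) {
    rec[[length(rec) + 1L]] <- data.frame(
      haplotype = haps, locus = sprintf("block_%d", b),
      allele = vapply(haps, function(h) plan[[h]][b], ""),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rec)
}

#' Simulate a small allele library panel
#'
#' Ten 660-bp allele sequences derived from a common base sequence by
#' seeded substitutions — a stand-in, synthetic allele panel shaped
#' like a processed-pseudogene allele library (10 alleles of 660 bp).
#'
#' @param seed integer seed.
#' @param n_alleles number of alleles (default 10).
#' @param length allele length in bp (default 660).
#' @param divergence per-branch substitution rate (default 0.01).
#' @return Named character vector (`*01` ... `*10`).
#' @export
simulate_allele_panel <- function(seed, n_alleles = 10L,
                                  length = 660L, divergence = 0.01) {
  with_seed(seed, {
    base <- charToRaw(random_dna(length))
    others <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                   G = c("A", "C", "T"), T = c("A", "C", "G"))
    out <- vapply(seq_len(n_alleles), function(i) {
      s <- base
      n <- rbinom(1, length, divergence)
      if (n > 0) {
        pos <- sample.int(length, n)
        for (p in pos) {
          b <- rawToChar(s[p])
          s[p] <- charToRaw(sample(others[[b]], 1))
        }
      }
      rawToChar(s)
    }, "")
    names(out) <- sprintf("*%02d", seq_len(n_alleles))
    out
  })
}
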