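# RepeatMasker parsing, simple-repeat detection, annotation matching,
# dimorphic TE calling, motif scanning and classification.

random_features <- function(n, query = "hap", L = 100000) {
  starts <- sort(sample.int(L - 2000, n))
  data.frame(
    query = rep(query, n),
    sw_score = sample(200:5000, n, replace = TRUE),
    pct_div = round(runif(n, 0, 30), 1),
    pct_del = round(runif(n, 0, 5), 1),
    pct_ins = round(runif(n, 0, 5), 1),
    q_start = starts,
    q_end = starts + sample(100:1500, n, replace = TRUE),
    strand = sample(c("+", "C"), n, replace = TRUE),
    rep_name = sample(c("AluSx", "AluY", "L1M5", "MIRb", "MER20"),
                      n, replace = TRUE),
    rep_class_family = rep("SINE/Alu", n),
    rep_start = rep("1", n),
    rep_end = rep(300L, n),
    rep_left = rep("(0)", n),
    feature_id = seq_len(n),
    stringsAsFactors = FALSE)
}

test_that("a header-only RepeatMasker file parses to an empty table", {
  f <- tempfile(fileext = ".out")
  write_repeatmasker(random_features(0), f)
  expect_equal(nrow(read_repeatmasker(f)), 0)
})

test_that("RepeatMasker coordinates convert to 0-based half-open", {
  f <- tempfile(fileext = ".out")
  feats <- random_features(1)
  feats$q_start <- 1000L; feats$q_end <- 1300L  # internal half-open
  write_repeatmasker(feats, f)
  lines <- readLines(f)
  expect_match(lines[4], " 1001 ")   # 1-based inclusive on disk
  back <- read_repeatmasker(f)
  expect_equal(back$q_start, 1000L)
  expect_equal(back$q_end, 1300L)
})

test_that("RepeatMasker write/parse round-trips 50 random features", {
  set.seed(61)
  feats <- random_features(50)
  f <- tempfile(fileext = ".out")
  write_repeatmasker(feats, f)
  back <- read_repeatmasker(f)
  for (col in c("sw_score", "q_start", "q_end", "strand", "rep_name",
                "rep_class_family", "feature_id"))
    expect_equal(back[[col]], feats[[col]], info = col)
})

test_that("malformed RepeatMasker rows fail with a line number", {
  f <- tempfile(fileext = ".out")
  writeLines(c("h1", "h2", "", "too few fields here"), f)
  expect_error(read_repeatmasker(f), "line 4")
})

test_that("simple tandem repeats and homopolymers are detected", {
  got <- detect_simple_repeats("ACACACACACAC")
  expect_equal(nrow(got), 1)
  expect_equal(c(got$start, got$end), c(0, 12))
  hp <- detect_simple_repeats("GGGTAAAAAAAATGC")
  expect_true(any(hp$start <= 4 & hp$end >= 12))
  none <- detect_simple_repeats("ACGTTGCAAGCTTGACGATC")
  expect_equal(nrow(none), 0)
})

test_that("simple-repeat detection matches the brute-force scan", {
  set.seed(62)
  for (rep in 1:8) {
    s <- random_seq(500)
    # plant one tandem tract half the time
    if (rep %% 2 == 0) {
      unit <- random_seq(sample(1:6, 1))
      tract <- strrep(unit, ceiling(30 / nchar(unit)))
      pos <- sample.int(400, 1)
      s <- paste0(substr(s, 1, pos), tract,
                  substr(s, pos + nchar(tract) + 1, nchar(s)))
    }
    got <- detect_simple_repeats(s)
    want <- oracle_simple_repeats(s)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("identical annotations pair fully with no leftovers", {
  set.seed(63)
  ann <- random_features(20)
  m <- match_annotations(ann, ann)
  expect_equal(nrow(m$pairs), 20)
  expect_equal(length(m$unmatched_a), 0)
  expect_equal(length(m$unmatched_b), 0)
})

test_that("an extra element between shared features is left unmatched", {
  ann_b <- data.frame(q_start = c(1000L, 20000L),
                      q_end = c(7000L, 21000L),
                      rep_name = c("L1M5", "L1M5"),
                      rep_class_family = "LINE/L1",
                      strand = "+", stringsAsFactors = FALSE)
  extra <- data.frame(q_start = 10000L, q_end = 10300L,
                      rep_name = "AluY", rep_class_family = "SINE/Alu",
                      strand = "+", stringsAsFactors = FALSE)
  ann_a <- rbind(ann_b[1, ], extra, ann_b[2, ])
  m <- match_annotations(ann_a, ann_b)
  expect_equal(nrow(m$pairs), 2)
  expect_equal(m$unmatched_a, 2L)
  expect_equal(length(m$unmatched_b), 0)
})

test_that("jittered annotations pair like the optimal assignment", {
  set.seed(64)
  for (rep in 1:6) {
    n <- sample(4:8, 1)
    starts <- sort(sample(seq(2000, 80000, by = 2500), n))
    ann_a <- data.frame(q_start = starts, q_end = starts + 300L,
                        rep_name = sample(c("AluSx", "MIRb"), n,
                                          replace = TRUE),
                        rep_class_family = "x", strand = "+",
                        stringsAsFactors = FALSE)
    ann_b <- ann_a
    ann_b$q_start <- ann_b$q_start + sample(-400:400, n, replace = TRUE)
    ann_b$q_end <- ann_b$q_start + 300L
    o <- order(ann_b$q_start)
    ann_b <- ann_b[o, , drop = FALSE]
    m <- match_annotations(ann_a, ann_b)
    # optimal: every feature pairs with its jittered copy
    expect_equal(nrow(m$pairs), n)
    expect_equal(ann_b$rep_name[m$pairs$b], ann_a$rep_name[m$pairs$a])
  }
})

test_that("a planted panel recovers every dimorphic locus exactly once", {
  lib <- te_library()
  te <- data.frame(entry = c("AluYs1", "SVAs1", "MOSAIC7K"),
                   position = c(40000L, 90000L, 140000L),
                   h1 = c(TRUE, FALSE, TRUE),
                   h2 = c(FALSE, TRUE, FALSE),
                   h3 = c(TRUE, TRUE, FALSE))
  cfg <- sim_config(seed = 65, length = 200000,
                    haplotypes = c("h1", "h2", "h3"), te_plan = te)
  p <- simulate_panel(cfg)
  calls <- call_dimorphic_panel(p$annotations)
  expect_equal(ncol(calls$presence), 3)
  # mosaic appears as one locus with 10 members
  mos <- which(calls$loci$n_members == 10)
  expect_equal(length(mos), 1)
  expect_equal(calls$loci$length[mos], 7000)
  # presence flags match the plan for each locus (match by length)
  for (i in seq_len(nrow(te))) {
    len <- nchar(lib[[te$entry[i]]]$sequence)
    j <- which(calls$loci$length == len)
    expect_equal(length(j), 1)
    got <- calls$presence[, calls$loci$locus[j]]
    expect_equal(unname(got[c("h1", "h2", "h3")]),
                 as.integer(unlist(te[i, c("h1", "h2", "h3")])))
  }
})

test_that("monomorphic planted elements yield zero dimorphic calls", {
  te <- data.frame(entry = "SVAs1", position = 50000L,
                   h1 = TRUE, h2 = TRUE, h3 = TRUE)
  cfg <- sim_config(seed = 66, length = 100000,
                    haplotypes = c("h1", "h2", "h3"), te_plan = te)
  p <- simulate_panel(cfg)
  calls <- call_dimorphic_panel(p$annotations)
  expect_equal(ncol(calls$presence), 0)
})

test_that("dimorphism calls are symmetric in haplotype order", {
  te <- data.frame(entry = "AluYs1", position = 30000L,
                   h1 = TRUE, h2 = FALSE)
  cfg <- sim_config(seed = 67, length = 60000, te_plan = te)
  p <- simulate_panel(cfg)
  c12 <- call_dimorphic_panel(p$annotations[c("h1", "h2")])
  c21 <- call_dimorphic_panel(p$annotations[c("h2", "h1")])
  expect_equal(unname(c12$presence[c("h1", "h2"), 1]),
               unname(c21$presence[c("h1", "h2"), 1]))
})

test_that("literal motif scanning finds planted and no spurious hits", {
  hits <- scan_motifs("CCTCCCCT",
                      data.frame(id = c("CCTCCCCT", "AGGGGAGG"),
                                 pattern = c("CCTCCCCT", "AGGGGAGG")))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$id, "CCTCCCCT")
  expect_equal(hits$position, 0)
})

test_that("reverse complement swaps the paired motif hit counts", {
  set.seed(68)
  for (rep in 1:5) {
    s <- random_seq(10000)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(s)))
    motifs <- data.frame(id = c("f", "r"),
                         pattern = c("CCTCCCCT", "AGGGGAGG"))
    h_fwd <- scan_motifs(s, motifs)
    h_rev <- scan_motifs(rc, motifs)
    expect_equal(sum(h_fwd$id == "f"), sum(h_rev$id == "r"))
    expect_equal(sum(h_fwd$id == "r"), sum(h_rev$id == "f"))
  }
})

test_that("motif scanning equals the brute-force oracle incl. IUPAC", {
  set.seed(69)
  pats <- c("CCTCCCCT", "AGGGGAGG", "ATCCATG", "CATGGAT",
            "CCNCCNTNNCCNC", "RYSWKM")
  for (rep in 1:4) {
    s <- random_seq(5000)
    # splice in N runs to check that N matches nothing
    s <- paste0(substr(s, 1, 2000), strrep("N", 30),
                substr(s, 2031, 5000))
    for (pat in pats) {
      got <- scan_motifs(s, data.frame(id = pat, pattern = pat))
      expect_equal(got$position, oracle_scan(s, pat), info = pat)
    }
  }
})

test_that("motif overlap classification assigns majority feature", {
  feats <- data.frame(q_start = c(100L, 200L), q_end = c(204L, 400L),
                      rep_name = c("L1", "AluY"),
                      rep_class_family = c("LINE/L1", "SINE/Alu"),
                      stringsAsFactors = FALSE)
  hits <- data.frame(id = "m", position = c(150L, 500L, 201L),
                     matched = "CCTCCCCT", stringsAsFactors = FALSE)
  cl <- classify_motif_overlap(hits, feats)
  expect_equal(cl$hits$category, c("L1", "Non-repeat region", "AluY"))
  # column sums equal per-motif hit counts
  expect_equal(unname(colSums(cl$matrix)), 3L)
})

test_that("motif survey matrix equals the simulator's motif truth", {
  motifs <- prdm9_motifs()
  mp <- data.frame(id = motifs$id[c(1, 1, 2, 3, 4, 5)],
                   pattern = motifs$pattern[c(1, 1, 2, 3, 4, 5)],
                   inside_repeat = c(TRUE, FALSE, TRUE, FALSE, TRUE,
                                     FALSE))
  cfg <- sim_config(seed = 70, length = 120000, motif_plan = mp)
  p <- simulate_panel(cfg)
  sv <- motif_survey(p$sequences[["h1"]], p$annotations[["h1"]],
                     motifs = motifs)
  truth <- p$truth$motifs
  expect_equal(nrow(sv$hits), nrow(truth))
  expect_setequal(sv$hits$position, truth$pos.h1)
  # per-motif totals match the plan
  for (id in unique(mp$id))
    expect_equal(unname(sv$totals[id]), sum(mp$id == id), info = id)
  # count-matrix marginals
  expect_equal(unname(colSums(sv$matrix)[names(sv$totals)]),
               unname(as.integer(sv$totals)))
  # planted inside-repeat copies are classified into their repeat
  inside <- truth$category != "Non-repeat region"
  got_cat <- sv$hits$category[match(truth$pos.h1, sv$hits$position)]
  expect_equal(got_cat[inside] != "Non-repeat region", rep(TRUE, sum(inside)))
})
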