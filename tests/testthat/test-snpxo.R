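# SNP exclusion rules, density profiles, segmentation, XO calling.

snp_variants <- function(pos) {
  data.frame(kind = "SNP", a_pos = as.integer(pos),
             b_pos = as.integer(pos), ref = "A", alt = "C",
             length = 1L, within_aligned_gap = TRUE,
             stringsAsFactors = FALSE)
}

test_that("cluster rule triggers above, not at, the threshold", {
  # 6 SNPs inside a 50-nt span: all excluded
  v6 <- snp_variants(c(100, 105, 110, 120, 130, 145))
  f6 <- filter_snps(v6)
  expect_equal(nrow(f6$kept), 0)
  expect_true(all(f6$excluded$reason == "cluster"))
  # exactly 5 SNPs in the span: all kept
  v5 <- snp_variants(c(100, 105, 110, 120, 145))
  f5 <- filter_snps(v5)
  expect_equal(nrow(f5$kept), 5)
  # 6 SNPs spread over more than 50 nt: kept
  v_sp <- snp_variants(c(100, 160, 220, 280, 340, 400))
  expect_equal(nrow(filter_snps(v_sp)$kept), 6)
})

test_that("proximity to N-runs is excluded inclusively at 50 bp", {
  art <- data.frame(kind = "n_run", start = 1000L, end = 1200L)
  # last N base is 1199; distances 50 and 51
  v <- snp_variants(c(1249, 1250, 949, 950))
  f <- filter_snps(v, art)
  expect_setequal(f$positions, c(1250, 949))
  expect_setequal(f$excluded$a_pos, c(1249, 950))
  expect_true(all(f$excluded$reason == "near_N"))
})

test_that("indels and N-runs are never counted as SNPs", {
  v <- rbind(snp_variants(500),
             data.frame(kind = c("insertion", "deletion", "N_run"),
                        a_pos = c(600L, 700L, 800L),
                        b_pos = c(600L, 700L, 800L),
                        ref = "", alt = "", length = c(10L, 10L, 20L),
                        within_aligned_gap = TRUE,
                        stringsAsFactors = FALSE))
  f <- filter_snps(v)
  expect_equal(nrow(f$kept) + nrow(f$excluded), 1)
  expect_equal(f$positions, 500)
})

test_that("microsatellite and unaligned intervals exclude SNPs inside", {
  art <- data.frame(kind = c("microsatellite", "unaligned"),
                    start = c(100L, 1000L), end = c(160L, 2000L))
  v <- snp_variants(c(99, 100, 159, 160, 1500, 2000))
  f <- filter_snps(v, art)
  expect_setequal(f$positions, c(99, 160, 2000))
  expect_setequal(f$excluded$reason[f$excluded$a_pos == 1500],
                  "unaligned")
})

test_that("filtering is idempotent", {
  set.seed(31)
  pos <- sort(sample.int(50000, 300))
  art <- data.frame(kind = "n_run", start = 20000L, end = 20100L)
  f1 <- filter_snps(snp_variants(pos), art)
  f2 <- filter_snps(snp_variants(f1$positions), art)
  expect_equal(f2$positions, f1$positions)
  expect_equal(nrow(f2$excluded), 0)
})

test_that("filter agrees with simulator truth on noisy pairs", {
  noise <- data.frame(
    kind = c("n_run", "snp_cluster", "microsat"),
    hap = c("h2", "h2", "h1"),
    position = c(20000L, 40000L, 60000L))
  plan <- data.frame(start = 0L, end = 80000L, h1 = "A1", h2 = "A2")
  for (s in c(41, 42)) {
    cfg <- sim_config(seed = s, length = 80000, block_plan = plan,
                      noise_plan = noise)
    p <- simulate_panel(cfg)
    st <- xo_stage(p$sequences[["h1"]], p$sequences[["h2"]],
                   annotation = p$annotations[["h1"]])
    truth <- p$truth$snps[["h1|h2"]]
    expect_setequal(st$filtered$positions,
                    truth$a_pos[truth$expect_kept])
  }
})

test_that("density profile windows are half-open and complete", {
  prof0 <- density_profile(numeric(0), window = 500, span = 2000)
  expect_equal(prof0$count, rep(0, 4))
  prof <- density_profile(c(10, 499, 500), window = 500, span = 1000)
  expect_equal(prof$count, c(2, 1))
  # Poisson-planted SNPs at 8e-4/bp: mean 0.4 per 500-nt window
  set.seed(32)
  span <- 600000
  pos <- which(runif(span) < 8e-4) - 1
  pr <- density_profile(pos, window = 500, span = span)
  expect_equal(sum(pr$count), length(pos))
  mu <- 0.4
  se <- sqrt(mu / nrow(pr))
  expect_lt(abs(mean(pr$count) - mu), 4 * se)
})

test_that("uniform spans classify as a single segment", {
  set.seed(33)
  span <- 300000
  rich <- sort(sample.int(span, round(80 * span / 1e5))) - 1
  seg_r <- classify_segments(rich, span = span)
  expect_equal(nrow(seg_r), 1)
  expect_equal(seg_r$label, "rich")
  poor <- sort(sample.int(span, round(2 * span / 1e5))) - 1
  seg_p <- classify_segments(poor, span = span)
  expect_equal(nrow(seg_p), 1)
  expect_equal(seg_p$label, "poor")
  seg_0 <- classify_segments(numeric(0), span = span)
  expect_equal(seg_0$label, "poor")
})

test_that("a two-rate span is split near the truth and the ML change point", {
  set.seed(34)
  span <- 600000
  bp <- 300000
  pos <- sort(c(which(runif(bp) < 80 / 1e5) - 1,
                bp + which(runif(span - bp) < 2 / 1e5) - 1))
  seg <- classify_segments(pos, span = span)
  expect_equal(seg$label, c("rich", "poor"))
  expect_lt(abs(seg$end[1] - bp), 2000)
  cp <- oracle_changepoint(pos, span)
  expect_lt(abs(seg$end[1] - cp), 2000)
})

test_that("raising rich_min never increases the rich span", {
  set.seed(35)
  span <- 400000
  pos <- sort(sample.int(span, 150)) - 1
  rich_span <- function(rich_min) {
    seg <- classify_segments(pos, segment_params(rich_min = rich_min),
                             span = span)
    sum(seg$end[seg$label == "rich"] - seg$start[seg$label == "rich"])
  }
  spans <- vapply(c(30, 50, 80, 120), rich_span, numeric(1))
  expect_true(all(diff(spans) <= 0))
})

test_that("XO calls sit on the boundary SNP and count label changes", {
  set.seed(36)
  span <- 600000
  bp <- 300000
  pos <- sort(c(which(runif(bp) < 80 / 1e5) - 1,
                bp + which(runif(span - bp) < 2 / 1e5) - 1))
  seg <- classify_segments(pos, span = span)
  xos <- call_xos(seg, pos, pair = "t")
  expect_equal(nrow(xos), sum(diff(as.integer(factor(seg$label))) != 0))
  # rich side: last kept SNP of the rich block
  last_rich <- max(pos[pos < seg$end[1]])
  expect_equal(xos$position[1], last_rich)
  # single segment: no XOs (same-haplotype pairs give none)
  expect_equal(nrow(call_xos(seg[1, ], pos)), 0)
  # poor-side alternative
  xos_p <- call_xos(seg, pos, side = "poor")
  expect_equal(xos_p$position[1], min(pos[pos >= seg$end[1]]))
})

test_that("xo_summary reproduces totals, multiplicities, unique sites", {
  xos <- c(lapply(1:3, function(i) c(1000 * i)),
           list(c(5000, 9000)), list(integer(0)))
  s <- xo_summary(xos)
  expect_equal(s$total, 5)
  expect_equal(unname(s$by_multiplicity["0"]), 1)
  expect_equal(unname(s$by_multiplicity["1"]), 3)
  expect_equal(unname(s$by_multiplicity["2"]), 1)
  # two pairs sharing an XO position merge into one unique site
  s2 <- xo_summary(list(a = 1000, b = 1000))
  expect_equal(s2$unique_sites, 1)
  s3 <- xo_summary(list(a = 1000, b = 2500))
  expect_equal(s3$unique_sites, 2)
  s0 <- xo_summary(list(a = integer(0), b = integer(0)))
  expect_equal(s0$total, 0)
  expect_equal(unname(s0$by_multiplicity["0"]), 2)
})

test_that("segment boundaries agree with the exact ML change point", {
  # on simulated two-rate pairs, every called boundary must agree with
  # the single-switch two-rate Poisson ML change point computed over
  # the two adjacent segments
  for (s in c(51, 52)) {
    plan <- local({
      set.seed(s)
      random_pair_plan(600000, 3, min_segment = 60000)
    })
    cfg <- sim_config(seed = s, length = 600000, block_plan = plan,
                      decoy_rate = 0)
    p <- simulate_panel(cfg)
    st <- xo_stage(p$sequences[["h1"]], p$sequences[["h2"]])
    truth <- truth_boundary_snps(p, "h1|h2")
    seg <- st$segments
    expect_equal(nrow(st$xos), nrow(truth))
    kept <- st$filtered$positions
    for (i in seq_len(nrow(seg) - 1)) {
      lo <- seg$start[i]; hi <- seg$end[i + 1]
      loc <- kept[kept >= lo & kept < hi] - lo
      cp <- oracle_changepoint(loc, hi - lo) + lo
      expect_lt(abs(seg$end[i] - cp), 2000)
    }
  }
})

test_that("breakpoints are recovered exactly at high rich density", {
  # at rich densities typical of observed density-plot peaks (a few
  # hundred SNPs per 100 kb) the boundary SNP is identifiable and the
  # called XO must hit the truth SNP
  for (s in c(61, 62)) {
    plan <- local({
      set.seed(s)
      random_pair_plan(600000, 2, min_segment = 60000)
    })
    cfg <- sim_config(seed = s, length = 600000, block_plan = plan,
                      branch_divergence = 1.5e-3, decoy_rate = 0)
    p <- simulate_panel(cfg)
    st <- xo_stage(p$sequences[["h1"]], p$sequences[["h2"]])
    truth <- truth_boundary_snps(p, "h1|h2")
    expect_equal(nrow(st$xos), nrow(truth))
    for (b in truth$boundary_snp_a)
      expect_true(any(abs(st$xos$position - b) <= 2000))
  }
})
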