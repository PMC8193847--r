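# Mosaic haplotype simulator: determinism, planted-feature geometry,
# exact truth bookkeeping, serialization round trips.

test_that("zero divergence yields identical haplotypes and empty truth", {
  cfg <- sim_config(seed = 1, length = 20000, branch_divergence = 0,
                    background_divergence = 0)
  p <- simulate_panel(cfg)
  expect_identical(p$sequences[["h1"]], p$sequences[["h2"]])
  expect_equal(nrow(p$truth$snps[["h1|h2"]]), 0)
})

test_that("simulation is a deterministic function of the config", {
  plan <- data.frame(start = 0L, end = 50000L, h1 = "A1", h2 = "A2")
  cfg <- sim_config(seed = 99, length = 50000, block_plan = plan)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1$sequences, p2$sequences)
  expect_identical(p1$annotations, p2$annotations)
  expect_identical(p1$truth, p2$truth)
})

test_that("unshared-block SNP counts follow the binomial expectation", {
  # one 100-kb block with different ancestors at branch divergence
  # 4e-4: expected pair divergence 8e-4, i.e. Binomial(1e5, 8e-4)
  plan <- data.frame(start = 0L, end = 100000L, h1 = "A1", h2 = "A2")
  counts <- vapply(1:6, function(s) {
    cfg <- sim_config(seed = 1000 + s, length = 100000,
                      block_plan = plan, decoy_rate = 0)
    nrow(simulate_panel(cfg)$truth$snps[["h1|h2"]])
  }, numeric(1))
  mu <- 1e5 * 8e-4
  sigma <- sqrt(mu)
  expect_true(all(abs(counts - mu) < 4 * sigma))
  # and over the seeds the mean is close to the nominal rate
  expect_lt(abs(mean(counts) - mu) / mu, 0.05 * sqrt(6))
})

test_that("TE insertion changes length by the planted amount", {
  te <- data.frame(entry = "AluYs1", position = 5000L,
                   h1 = TRUE, h2 = FALSE)
  cfg <- sim_config(seed = 7, length = 20000, te_plan = te,
                    branch_divergence = 0, background_divergence = 0)
  p <- simulate_panel(cfg)
  expect_equal(nchar(p$sequences[["h1"]]),
               nchar(p$sequences[["h2"]]) + 300L)
  tl <- p$truth$te_loci
  expect_equal(nrow(tl), 1)
  expect_true(tl$present.h1)
  expect_false(tl$present.h2)
  # coordinate maps: positions downstream of the insertion shift by
  # the TE length in h1 and not in h2
  m1 <- p$truth$coord_maps[["h1"]]
  m2 <- p$truth$coord_maps[["h2"]]
  expect_equal(map_to_hap(m1, 10000L), 10300L)
  expect_equal(map_to_hap(m2, 10000L), 10000L)
  expect_equal(map_to_base(m1, 10300L), 10000L)
})

test_that("overlapping planted features are rejected with a message", {
  noise <- data.frame(kind = c("n_run", "microsat"),
                      hap = c("h1", "h1"),
                      position = c(1000L, 1100L))
  cfg <- sim_config(seed = 1, length = 10000, noise_plan = noise)
  expect_error(simulate_panel(cfg), "overlap")
})

test_that("block plans must tile the sequence", {
  bad <- data.frame(start = c(0L, 6000L), end = c(5000L, 10000L),
                    h1 = c("A1", "A1"), h2 = c("A1", "A2"))
  expect_error(sim_config(seed = 1, length = 10000, block_plan = bad),
               "tile")
})

test_that("planted noise shows up in truth with expected filter fate", {
  noise <- data.frame(
    kind = c("n_run", "snp_cluster", "microsat", "deletion"),
    hap = c("h2", "h2", "h1", "h2"),
    position = c(10000L, 20000L, 30000L, 40000L))
  plan <- data.frame(start = 0L, end = 60000L, h1 = "A1", h2 = "A2")
  cfg <- sim_config(seed = 3, length = 60000, block_plan = plan,
                    noise_plan = noise)
  p <- simulate_panel(cfg)
  st <- p$truth$snps[["h1|h2"]]
  expect_true(any(st$reason == "cluster"))
  expect_true(any(st$reason == "microsatellite"))
  # every cluster-planted SNP lies inside the planted window
  cl <- st$base_pos[st$reason == "cluster"]
  expect_true(all(cl >= 20000 - 50 & cl < 20040 + 50))
  # no truth SNP inside the deleted span (unobservable)
  expect_false(any(st$base_pos >= 40000 & st$base_pos < 41000))
  # N-run positions never appear as SNPs
  expect_false(any(st$base_pos >= 10000 & st$base_pos < 10200))
})

test_that("truth files round-trip through write_truth/read_truth", {
  cfg <- demo_sim_config(5, length = 60000)
  p <- simulate_panel(cfg)
  dir <- tempfile("truth")
  write_truth(p$truth, dir)
  back <- read_truth(dir)
  expect_equal(back$breakpoints[["h1|h2"]],
               p$truth$breakpoints[["h1|h2"]])
  st0 <- p$truth$snps[["h1|h2"]]
  st1 <- back$snps[["h1|h2"]]
  expect_equal(st1$base_pos, st0$base_pos)
  expect_equal(st1$expect_kept, st0$expect_kept)
  expect_equal(back$coord_maps[["h1"]], p$truth$coord_maps[["h1"]])
  expect_equal(nrow(back$te_loci), nrow(p$truth$te_loci))
})

test_that("an empty truth set writes valid empty files", {
  cfg <- sim_config(seed = 2, length = 5000, branch_divergence = 0,
                    background_divergence = 0, decoy_rate = 0)
  p <- simulate_panel(cfg)
  dir <- tempfile("truth-empty")
  write_truth(p$truth, dir)
  expect_true(file.exists(file.path(dir, "breakpoints.bed")))
  back <- read_truth(dir)
  expect_equal(sum(vapply(back$snps, nrow, integer(1))), 0L)
})

test_that("haplotype length conservation under insertions and deletions", {
  te <- data.frame(entry = c("SVAs1", "LTRs42"),
                   position = c(20000L, 60000L),
                   h1 = c(TRUE, FALSE), h2 = c(FALSE, TRUE))
  noise <- data.frame(kind = "deletion", hap = "h1",
                      position = 40000L)
  cfg <- sim_config(seed = 4, length = 100000, te_plan = te,
                    noise_plan = noise)
  p <- simulate_panel(cfg)
  expect_equal(nchar(p$sequences[["h1"]]), 100000 + 1600 - 1000)
  expect_equal(nchar(p$sequences[["h2"]]), 100000 + 480)
})
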