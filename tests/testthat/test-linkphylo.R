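# Allele assignment, haplotype tabulation, linkage percentages,
# p-distances and neighbor joining.

test_that("allele assignment distinguishes exact, novel and GAP", {
  lib <- simulate_allele_panel(81)
  q_exact <- lib[["*01"]]
  expect_equal(assign_allele(q_exact, lib)$status, "exact")
  # one substitution in 660 bp: identity 99.85% -> novel, same label
  chars <- strsplit(q_exact, "")[[1]]
  # find a diagnostic site where *01 differs from every other allele,
  # otherwise mutate any site and only check the status
  chars[5] <- setdiff(c("A", "C", "G", "T"), chars[5])[1]
  q_novel <- paste(chars, collapse = "")
  got <- assign_allele(q_novel, lib)
  expect_equal(got$status, "novel")
  expect_gte(got$identity, 0.99)
  q_gap <- strrep("N", 660)
  expect_equal(assign_allele(q_gap, lib)$status, "GAP")
  expect_error(assign_allele(q_exact, character(0)), "empty")
})

test_that("haplotype tabulation groups label tuples and drops incomplete", {
  rec <- rbind(
    data.frame(haplotype = rep(c("s1", "s2", "s3"), each = 2),
               locus = rep(c("L1", "L2"), 3),
               allele = c("a", "x", "a", "x", "b", "y")),
    data.frame(haplotype = "s4", locus = "L1", allele = "a"))
  tab <- tabulate_haplotypes(rec, c("L1", "L2"))
  expect_equal(tab$total, 3)
  expect_equal(nrow(tab$table), 2)
  expect_equal(tab$table$count, c(2, 1))
  expect_equal(tab$dropped, "s4")
  expect_error(tabulate_haplotypes(rec, character(0)), "loci")
  # all identical records collapse to one combination
  rec1 <- data.frame(haplotype = paste0("s", 1:5), locus = "L1",
                     allele = "a")
  expect_equal(nrow(tabulate_haplotypes(rec1, "L1")$table), 1)
})

test_that("perfectly linked markers give 100% rows", {
  rec <- rbind(
    data.frame(haplotype = paste0("s", 1:6), locus = "A",
               allele = rep(c("a1", "a2"), each = 3)),
    data.frame(haplotype = paste0("s", 1:6), locus = "B",
               allele = rep(c("b1", "b2"), each = 3)))
  link <- linkage_percentages(rec, "A", "B")
  expect_true(all(link$table$percent == 100))
  expect_equal(sum(link$table$count), 6)
})

test_that("GAP records are excluded from linkage and reported", {
  rec <- rbind(
    data.frame(haplotype = c("s1", "s2"), locus = "A",
               allele = c("a1", "GAP")),
    data.frame(haplotype = c("s1", "s2"), locus = "B",
               allele = c("b1", "b2")))
  link <- linkage_percentages(rec, "A", "B")
  expect_equal(link$excluded, "s2")
  expect_equal(sum(link$table$count), 1)
})

test_that("independent markers have row percentages near the marginals", {
  set.seed(82)
  n <- 1000
  a <- sample(c("a1", "a2"), n, replace = TRUE)
  b <- sample(c("b1", "b2"), n, replace = TRUE, prob = c(0.3, 0.7))
  rec <- rbind(
    data.frame(haplotype = paste0("s", 1:n), locus = "A", allele = a),
    data.frame(haplotype = paste0("s", 1:n), locus = "B", allele = b))
  link <- linkage_percentages(rec, "A", "B")
  for (av in c("a1", "a2")) {
    row <- link$table[link$table$a_value == av &
                        link$table$b_value == "b1", ]
    nA <- sum(a == av)
    se <- sqrt(0.3 * 0.7 / nA) * 100
    expect_lt(abs(row$percent - 30), 4 * se)
  }
})

test_that("p-distances equal brute-force column counting", {
  expect_equal(p_distance_matrix(c(x = "ACGT", y = "ACGT"))$p[1, 2], 0)
  pd1 <- p_distance_matrix(c(x = strrep("A", 660),
                             y = paste0(strrep("A", 659), "C")))
  expect_equal(pd1$p[1, 2], 1 / 660)
  expect_equal(pd1$identity[1, 2], 100 * (1 - 1 / 660))
  set.seed(83)
  for (rep in 1:5) {
    n <- 5
    L <- 200
    seqs <- setNames(vapply(1:n, function(i) {
      s <- random_seq(L)
      # sprinkle gaps and Ns
      chars <- strsplit(s, "")[[1]]
      chars[sample.int(L, 6)] <- sample(c("-", "N"), 6, replace = TRUE)
      paste(chars, collapse = "")
    }, ""), paste0("t", 1:n))
    pd <- p_distance_matrix(seqs)
    # brute force on a random pair
    i <- 1; j <- sample(2:n, 1)
    ci <- strsplit(seqs[i], "")[[1]]
    cj <- strsplit(seqs[[j]], "")[[1]]
    use <- !(ci %in% c("-", "N") | cj %in% c("-", "N"))
    expect_equal(pd$p[i, j], sum(ci[use] != cj[use]) / sum(use))
    expect_equal(pd$p, t(pd$p))
    expect_equal(unname(diag(pd$p)), rep(0, n))
  }
  expect_error(p_distance_matrix(c(a = "NNNN", b = "ACGT")),
               "comparable")
})

test_that("three-taxon NJ solves the pairwise equations exactly", {
  d <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.6,
                0.5, 0.6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  nj <- neighbor_joining(d)
  el <- setNames(nj$tree$edge.length,
                 nj$tree$tip.label[nj$tree$edge[, 2]])
  expect_equal(unname(el["A"] + el["B"]), 0.3, tolerance = 1e-12)
  expect_equal(unname(el["A"] + el["C"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(el["B"] + el["C"]), 0.6, tolerance = 1e-12)
})

test_that("the symmetric quartet resolves into its two cherries", {
  labs <- c("A", "B", "C", "D")
  d <- matrix(0.6, 4, 4, dimnames = list(labs, labs))
  diag(d) <- 0
  d["A", "B"] <- d["B", "A"] <- 0.2
  d["C", "D"] <- d["D", "C"] <- 0.2
  nj <- neighbor_joining(d)
  # unrooted quartet ((A,B),(C,D)): A and B form a cherry
  tr <- nj$tree
  pair_of <- function(x) {
    edge <- tr$edge
    tip <- which(tr$tip.label == x)
    parent <- edge[edge[, 2] == tip, 1]
    sibs <- edge[edge[, 1] == parent, 2]
    sort(tr$tip.label[sibs[sibs <= length(tr$tip.label)]])
  }
  expect_equal(pair_of("A"), c("A", "B"))
  expect_equal(pair_of("C"), c("C", "D"))
})

test_that("NJ reconstructs random additive trees exactly", {
  set.seed(84)
  for (rep in 1:25) {
    n <- sample(4:10, 1)
    gen <- oracle_random_additive(n)
    nj <- neighbor_joining(gen$d)
    # topology: RF distance 0 against the generating tree
    expect_equal(ape::dist.topo(ape::unroot(gen$tree), nj$tree), 0,
                 ignore_attr = TRUE)
    # branch lengths: path distances reproduced to 1e-9
    got <- ape::cophenetic.phylo(nj$tree)[rownames(gen$d),
                                          colnames(gen$d)]
    expect_lt(max(abs(got - gen$d)), 1e-9)
    # cross-check against the established NJ implementation
    ref <- ape::nj(gen$d)
    expect_equal(ape::dist.topo(ref, nj$tree), 0, ignore_attr = TRUE)
  }
})

test_that("negative branch lengths are clamped and logged", {
  labs <- c("A", "B", "C", "D")
  d <- matrix(c(0, 0.1, 0.4, 0.45,
                0.1, 0, 0.42, 0.47,
                0.4, 0.42, 0, 0.05,
                0.45, 0.47, 0.05, 0), 4, 4,
              dimnames = list(labs, labs))
  # perturb towards a violation of additivity
  d["A", "D"] <- d["D", "A"] <- 0.08
  nj <- neighbor_joining(d)
  expect_true(all(nj$tree$edge.length >= 0))
  if (nrow(nj$clamped)) expect_true(all(nj$clamped$deficit > 0))
})

test_that("NJ refuses fewer than three taxa", {
  d <- matrix(c(0, 1, 1, 0), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(neighbor_joining(d), "3 taxa")
})
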