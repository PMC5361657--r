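# Bray-Curtis, PERMANOVA, ANOSIM, MRPP, UPGMA, global scan. Independent
# oracles: brute-force enumeration in helper-fixtures.R and vegan.

test_that("Bray-Curtis matches its worked examples", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)
  expect_equal(bray_curtis(c(2, 1), c(1, 1)), 0.2)
  expect_warning(res <- bray_curtis(c(-0.1, 1), c(0.5, 0.5)), "clamped")
  expect_equal(res, bray_curtis(c(0, 1), c(0.5, 0.5)))
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(bray_curtis(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("Bray-Curtis matrix agrees with vegan::vegdist", {
  skip_if_not_installed("vegan")
  m <- random_profile_matrix(8, 12, seed = 21)
  mine <- as.matrix(bray_curtis_matrix(m))
  ref <- as.matrix(vegan::vegdist(m, method = "bray"))
  expect_equal(unname(mine), unname(ref), tolerance = 1e-12)
})

test_that("PERMANOVA reproduces the 1-D 4-point instance exactly", {
  d <- dist(c(0, 1, 3, 4))
  g <- c("A", "A", "B", "B")
  res <- permanova(d, g, permutation_settings(exact_enumeration = TRUE))
  expect_equal(unname(res$ss["total"]), 10)
  expect_equal(unname(res$ss["between"]), 9)
  expect_equal(unname(res$statistic), 18)
  expect_equal(res$R2, 0.9)
  # swapping the two group labels reproduces the same partition and the
  # same F, so the maximum appears twice among the 6 labelings: p = 2/6
  expect_equal(res$n_perm, 6)
  expect_equal(res$p_value, 1 / 3)
})

test_that("PERMANOVA decomposition is additive and label-invariant", {
  m <- random_profile_matrix(10, 8, seed = 22)
  d <- bray_curtis_matrix(m)
  g <- rep(c("A", "B"), each = 5)
  res <- permanova(d, g, permutation_settings(n_perm = 49, seed = 1))
  expect_equal(unname(res$ss["within"] + res$ss["between"]),
               unname(res$ss["total"]), tolerance = 1e-10)
  # reorder samples together with labels: identical F and R2
  o <- sample(10)
  d2 <- as.dist(as.matrix(d)[o, o])
  res2 <- permanova(d2, g[o], permutation_settings(n_perm = 49, seed = 1))
  expect_equal(res2$statistic, res$statistic, tolerance = 1e-12)
  expect_equal(res2$R2, res$R2, tolerance = 1e-12)
})

test_that("exact enumeration equals brute force for all three tests", {
  for (case in list(list(n = 6, n1 = 3, seed = 23),
                    list(n = 8, n1 = 4, seed = 24))) {
    m <- as.matrix(bray_curtis_matrix(
      random_profile_matrix(case$n, 10, seed = case$seed)))
    g <- rep(c("A", "B"), c(case$n1, case$n - case$n1))
    st <- permutation_settings(exact_enumeration = TRUE)

    pm <- permanova(as.dist(m), g, st)
    f_all <- brute_force_two_group(case$n, case$n1,
                                   stat_fun = function(gg)
                                     oracle_permanova_F(m, gg))
    expect_equal(unname(pm$statistic), oracle_permanova_F(m, g),
                 tolerance = 1e-12)
    expect_equal(pm$p_value, mean(f_all >= oracle_permanova_F(m, g) - 1e-12))

    an <- anosim(as.dist(m), g, st)
    r_all <- brute_force_two_group(case$n, case$n1,
                                   stat_fun = function(gg)
                                     oracle_anosim_R(m, gg))
    expect_equal(unname(an$statistic), oracle_anosim_R(m, g),
                 tolerance = 1e-12)
    expect_equal(an$p_value, mean(r_all >= oracle_anosim_R(m, g) - 1e-12))

    mr <- mrpp(as.dist(m), g, st)
    d_all <- brute_force_two_group(case$n, case$n1,
                                   stat_fun = function(gg)
                                     oracle_mrpp_delta(m, gg))
    expect_equal(mr$delta, oracle_mrpp_delta(m, g), tolerance = 1e-12)
    expect_equal(mr$delta_exp, mean(d_all), tolerance = 1e-12)
    expect_equal(mr$p_value, mean(d_all <= oracle_mrpp_delta(m, g) + 1e-12))
  }
})

test_that("statistics agree with vegan on random data", {
  skip_if_not_installed("vegan")
  m <- random_profile_matrix(10, 15, seed = 25)
  g <- rep(c("A", "B"), each = 5)
  d <- vegan::vegdist(m, method = "bray")
  st <- permutation_settings(n_perm = 99, seed = 2)

  ref <- vegan::adonis2(d ~ g, permutations = 19)
  mine <- permanova(d, g, st)
  expect_equal(unname(mine$statistic), ref$F[1], tolerance = 1e-10)
  expect_equal(mine$R2, ref$R2[1], tolerance = 1e-10)

  ref_an <- vegan::anosim(d, g, permutations = 19)
  expect_equal(unname(anosim(d, g, st)$statistic),
               unname(ref_an$statistic), tolerance = 1e-10)

  ref_mr <- vegan::mrpp(d, g, permutations = 19, weight.type = 1)
  expect_equal(mrpp(d, g, st)$delta, ref_mr$delta, tolerance = 1e-10)
})

test_that("ANOSIM saturates at R = 1 under complete separation", {
  m <- matrix(c(0, 1, 5, 6,
                1, 0, 7, 5,
                5, 7, 0, 2,
                6, 5, 2, 0), 4, 4,
              dimnames = rep(list(paste0("s", 1:4)), 2))
  g <- c("A", "A", "B", "B")
  res <- anosim(as.dist(m), g, permutation_settings(exact_enumeration = TRUE))
  expect_equal(unname(res$statistic), 1)
  expect_true(abs(unname(res$statistic)) <= 1)
})

test_that("ANOSIM R is near zero when groups are random", {
  set.seed(26)
  rs <- replicate(20, {
    m <- matrix(abs(rnorm(80, 1, 0.3)), nrow = 8)
    rownames(m) <- paste0("s", 1:8)
    g <- sample(rep(c("A", "B"), each = 4))
    unname(anosim(bray_curtis_matrix(m), g,
                  permutation_settings(n_perm = 1))$statistic)
  })
  expect_lt(abs(mean(rs)), 0.15)
})

test_that("MRPP direction properties hold", {
  # all pairwise distances equal: no group structure, A = 0
  m <- matrix(1, 6, 6) - diag(6)
  dimnames(m) <- rep(list(paste0("s", 1:6)), 2)
  g <- rep(c("A", "B"), each = 3)
  res <- mrpp(as.dist(m), g, permutation_settings(exact_enumeration = TRUE))
  expect_equal(unname(res$statistic), 0, tolerance = 1e-12)

  # tight, well-separated clusters: positive A, minimal enumeration p
  pts <- c(0, 0.01, 0.02, 10, 10.01, 10.02)
  d <- dist(pts)
  attr(d, "Labels") <- paste0("s", 1:6)
  res2 <- mrpp(d, g, permutation_settings(exact_enumeration = TRUE))
  expect_gt(unname(res2$statistic), 0)
  expect_equal(res2$p_value, 2 / choose(6, 3))  # labeling + its swap
})

test_that("group validation rejects singletons and single groups", {
  d <- dist(c(0, 1, 3, 4))
  expect_error(permanova(d, c("A", "A", "A", "A")), "two groups")
  expect_error(anosim(d, c("A", "A", "A", "B")), "singleton")
  expect_error(mrpp(d, c("A", "B", "B", "B")), "singleton")
})

test_that("UPGMA dendrograms have the documented heights and topology", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("a", "b"),
                                                        c("a", "b")))
  nwk <- upgma_dendrogram(as.dist(d2))
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, c("a", "b"))
  expect_equal(unname(tree$edge.length), c(0.2, 0.2))

  m3 <- matrix(c(0, 1, 4,
                 1, 0, 4,
                 4, 4, 0), 3, 3,
               dimnames = rep(list(c("A", "B", "C")), 2))
  tree3 <- ape::read.tree(text = upgma_dendrogram(as.dist(m3)))
  coph <- ape::cophenetic.phylo(tree3)
  expect_equal(coph["A", "B"], 1)   # closest pair merges first
  expect_equal(coph["A", "C"], 4)   # new cluster at the average distance
  expect_equal(coph["B", "C"], 4)

  # permuting labels permutes leaves, not topology
  o <- c(3, 1, 2)
  tree3b <- ape::read.tree(text = upgma_dendrogram(as.dist(m3[o, o])))
  expect_equal(ape::cophenetic.phylo(tree3b)["A", "B"], 1)
})

test_that("global scan covers the grid and strengthens over time", {
  sim <- generate_dataset(simulation_config(seed = 31))
  scan <- suppressWarnings(
    global_scan(sim$dataset, test_layout(),
                permutation_settings(n_perm = 99, seed = 7)))
  expect_equal(nrow(scan), 14L)
  expect_equal(scan$time, seq(0.5, 7, by = 0.5))
  expect_true(all(scan$permanova_p >= 1 / 100))
  expect_true(all(scan$anosim_R >= -1 & scan$anosim_R <= 1))
  expect_true(all(scan$permanova_R2 >= 0 & scan$permanova_R2 <= 1))
  # planted effects live in log/stationary phase
  expect_gt(scan$permanova_R2[14], scan$permanova_R2[1])
  # deterministic under a fixed seed
  scan2 <- suppressWarnings(
    global_scan(sim$dataset, test_layout(),
                permutation_settings(n_perm = 99, seed = 7)))
  expect_identical(scan, scan2)
})
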