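# Welch tests, BH adjustment, outcome classification, substrate summary,
# census.

test_that("welch_test matches its closed forms and stats::t.test", {
  res <- welch_test(1.0, 0.1, 5, 0.5, 0.1, 5)
  expect_equal(res$t, 0.5 / sqrt(0.004), tolerance = 1e-10)
  expect_equal(res$df, 8)  # equal variances and n collapse to n1 + n2 - 2

  expect_equal(welch_test(1, 0.2, 5, 1, 0.3, 5)$t, 0)
  expect_equal(welch_test(1, 0.2, 5, 1, 0.3, 5)$p, 1)

  # agree with t.test on raw vectors
  set.seed(1)
  x <- rnorm(6, 1, 0.3); y <- rnorm(4, 0.4, 0.1)
  tt <- t.test(x, y)
  mine <- welch_test(mean(x), sd(x), 6, mean(y), sd(y), 4)
  expect_equal(mine$t, abs(unname(tt$statistic)), tolerance = 1e-10)
  expect_equal(mine$df, unname(tt$parameter), tolerance = 1e-10)
  expect_equal(mine$p, tt$p.value, tolerance = 1e-10)

  expect_error(welch_test(1, 0, 5, 2, 0, 5), "degenerate")
  expect_error(welch_test(1, 0.1, 1, 2, 0.1, 5), "n >= 2")
})

test_that("Welch df never exceeds n1 + n2 - 2", {
  set.seed(2)
  for (i in 1:25) {
    n1 <- sample(2:10, 1); n2 <- sample(2:10, 1)
    s1 <- runif(1, 0.01, 1); s2 <- runif(1, 0.01, 1)
    res <- welch_test(rnorm(1), s1, n1, rnorm(1), s2, n2)
    expect_lte(res$df, n1 + n2 - 2 + 1e-9)
    expect_gte(res$df, min(n1, n2) - 1 - 1e-9)
  }
  # equality iff the two standard errors coincide
  expect_equal(welch_test(0, 0.3, 4, 1, 0.3, 4)$df, 6)
})

test_that("BH adjustment matches the worked example and its properties", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(3)
  p <- runif(40)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  # NAs are excluded from the family, not counted in m
  p_na <- c(0.01, NA, 0.02, 0.03, NA)
  expect_equal(bh_adjust(p_na)[c(1, 3, 4)], c(0.03, 0.03, 0.03))
  expect_true(all(is.na(bh_adjust(p_na)[c(2, 5)])))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("outcome classification reproduces the endpoint-table rows", {
  expect_equal(as.integer(classify_outcome(1.49, 1.16, 1e-6)), 5L)
  expect_equal(as.integer(classify_outcome(0.71, 1.04, 1e-6)), 4L)
  expect_equal(as.integer(classify_outcome(0.66, 0.12, 1e-8)), 3L)
  expect_equal(as.integer(classify_outcome(1.69, 1.47, 0.08)), 2L)
  expect_equal(as.integer(classify_outcome(0.25, 0.15, NA)), 1L)
})

test_that("outcome classification edge semantics", {
  # mirror case: measurable EHB- only, flagged
  oc <- classify_outcome(0.2, 0.9, 0.001)
  expect_equal(as.integer(oc), 4L)
  expect_true(attr(oc, "mirror"))
  expect_false(attr(classify_outcome(0.71, 1.04, 1e-6), "mirror"))
  # significant but exactly equal means has no direction
  expect_error(classify_outcome(1.2, 1.2, 0.001), "direction")
  # boundary: exactly at the lower bound is negligible
  expect_equal(as.integer(classify_outcome(0.3, 0.3, NA)), 1L)
  # shift invariance while both stay measurable with unchanged direction
  for (shift in c(0, 0.2, 0.8)) {
    expect_equal(as.integer(classify_outcome(1.0 + shift, 0.6 + shift,
                                             0.001)), 5L)
  }
})

test_that("substrate summary recovers a planted effect end to end", {
  sim <- generate_dataset(simulation_config(seed = 11))
  s <- summarize_substrates(sim$dataset)
  expect_equal(nrow(s), 95L)
  expect_false("water" %in% s$substrate)
  truth <- sim$truth[match(s$substrate, sim$truth$substrate), ]
  planted5 <- truth$code == 5L
  expect_true(mean(s$outcome[planted5] == 5L) > 0.9)
  # negligible-both substrates are untested: absent adjusted p
  expect_true(all(is.na(s$p_adj[truth$code == 1L])))
  expect_true(all(!is.na(s$p_adj[truth$code %in% 4:5])))
  expect_true(all(s$p_adj >= s$p_raw - 1e-12, na.rm = TRUE))
})

test_that("an all-noise dataset yields outcome 1 everywhere", {
  cfg <- simulation_config(seed = 12, proportions = c(`1` = 95))
  sim <- generate_dataset(cfg)
  s <- summarize_substrates(sim$dataset)
  expect_true(all(s$outcome == 1L))
  expect_true(all(is.na(s$p_adj)))
})

test_that("census on a synthetic summary satisfies its invariants", {
  sim <- generate_dataset(simulation_config(seed = 13))
  s <- summarize_substrates(sim$dataset)
  cen <- census(s)
  expect_equal(cen$n_plus_higher + cen$n_minus_higher, cen$n_significant)
  expect_lte(cen$used_plus, cen$n_substrates)
  expect_equal(cen$n_negligible_both + cen$n_no_difference +
                 cen$n_significant, 95L)
  expect_true(all(cen$per_class_fractions >= 0 &
                    cen$per_class_fractions <= 1))
  # the water row must be excluded by the caller
  tab <- load_table1()
  expect_error(census(tab), "water")
})

test_that("rounding intervals behave as documented", {
  # printed t 14.63 is attainable from rounded 1.49/0.02/1.16/0.04 even
  # though point recomputation gives ~16.5
  point <- welch_test(1.49, 0.02, 5, 1.16, 0.04, 5)
  expect_gt(point$t, 16)
  iv <- welch_interval(1.49, 0.02, 1.16, 0.04)
  expect_true(iv$t_lower <= 14.63 && 14.63 <= iv$t_upper)
  expect_true(iv$df_lower <= 6.21 && 6.21 <= iv$df_upper)
  # a printed zero SD makes the t interval unbounded above
  expect_equal(welch_interval(0.11, 0, 0.10, 0)$t_upper, Inf)
  # df interval always inside [n-1, 2(n-1)]
  expect_gte(iv$df_lower, 4)
  expect_lte(iv$df_upper, 8)
})
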