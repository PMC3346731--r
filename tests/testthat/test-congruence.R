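test_that("Wilson upper bound matches the closed form", {
  # z^2/(n+z^2) at p_hat = 0
  z <- qnorm(0.975)
  expect_equal(wilson_upper(0, 1000), z^2 / (1000 + z^2), tolerance = 1e-10)
  expect_equal(wilson_upper(0, 1000), 0.00383, tolerance = 1e-3)
  expect_equal(wilson_upper(0.5, 1e6), 0.50098, tolerance = 1e-4)
  # as the confidence level drops to zero the bound collapses onto p_hat
  expect_equal(wilson_upper(0.3, 100, conf = 1e-12), 0.3, tolerance = 1e-6)
  expect_error(wilson_upper(1.2, 10), "p_hat")
  expect_error(wilson_upper(0.5, 0), "n")
})

test_that("association-permutation test: congruent pairs score significant", {
  cp <- congruent_pair(8, seed = 21)
  res <- mc_test_random_associations(cp$mimic, cp$model, cp$assoc,
                                     n = 199, seed = 42)
  expect_s3_class(res, "congruence_test")
  expect_equal(res$statistic, 0)
  expect_lte(res$p, 0.05)
  expect_gte(res$wilson_upper, res$p)
  expect_lte(res$count, res$n)
})

test_that("p is a raw proportion: can be exactly 0 and exactly 1", {
  cp <- congruent_pair(8, seed = 22)
  res <- mc_test_random_associations(cp$mimic, cp$model, cp$assoc,
                                     n = 99, seed = 7)
  expect_equal(res$p, res$count / 99)
  # observed below every replicate gives p = 0 without pseudocount
  if (res$count == 0) expect_identical(res$p, 0)
  resc <- mc_test_random_associations(cp$mimic, cp$model, cp$assoc,
                                      n = 99, seed = 7, corrected = TRUE)
  expect_equal(resc$p, (resc$count + 1) / 100)
  # degenerate: a 2-leaf mimic has a single topology, so the tree-null
  # replicates all tie the observed cost and p = 1
  m <- parse_newick("(X,Y);")
  M <- parse_newick("(a,b);")
  am <- parse_associations(data.frame(c("X", "Y"), c("a", "b")), m, M)
  r2 <- mc_test_random_mimic_tree(m, M, am, n = 10, seed = 3)
  expect_equal(r2$p, 1)
})

test_that("identical seeds reproduce identical results", {
  cp <- congruent_pair(7, seed = 30)
  a <- mc_test_random_mimic_tree(cp$mimic, cp$model, cp$assoc, n = 50, seed = 11)
  b <- mc_test_random_mimic_tree(cp$mimic, cp$model, cp$assoc, n = 50, seed = 11)
  expect_identical(a$null_sample, b$null_sample)
  expect_identical(a$p, b$p)
  d1 <- distance_correlation_test(cp$mimic, cp$model, cp$assoc, n = 50, seed = 11)
  d2 <- distance_correlation_test(cp$mimic, cp$model, cp$assoc, n = 50, seed = 11)
  expect_identical(d1$null_sample, d2$null_sample)
})

test_that("tree-randomisation test accepts both null models", {
  cp <- congruent_pair(8, seed = 23)
  for (nm in c("yule", "uniform")) {
    res <- mc_test_random_mimic_tree(cp$mimic, cp$model, cp$assoc,
                                     n = 199, seed = 5, null_model = nm)
    expect_lte(res$p, 0.05)
  }
})

test_that("distance correlation: identity associations give rho = 1", {
  cp <- congruent_pair(6, seed = 31)
  res <- distance_correlation_test(cp$mimic, cp$model, cp$assoc,
                                   mode = "nodal", n = 99, seed = 1)
  expect_equal(res$statistic, 1)
})

test_that("distance correlation: crossed 4-leaf example gives rho = -0.5", {
  m <- parse_newick("((A,B),(C,D));")
  M <- parse_newick("((a,b),(c,d));")
  am <- parse_associations(
    data.frame(c("A", "B", "C", "D"), c("a", "c", "b", "d")), m, M)
  res <- distance_correlation_test(m, M, am, mode = "nodal", n = 9, seed = 1)
  expect_equal(res$statistic, -0.5, tolerance = 1e-12)
})

test_that("distance correlation guards small and degenerate subtrees", {
  m <- parse_newick("((A,B),C);")
  M <- parse_newick("((a,b),c);")
  am <- parse_associations(data.frame(c("A", "B", "C"), c("a", "b", "c")), m, M)
  res <- distance_correlation_test(m, M, am, n = 9, seed = 1)
  expect_equal(res$flag, "not evaluable")
  expect_true(is.na(res$p))
  # zero variance: star-like model distances after collapsing to nodal on
  # a balanced 4-leaf tree paired with itself is fine, so force the flag
  # with equal model distances via a balanced tree and identity pairs
  m2 <- parse_newick("((A,B),(C,D));")
  M2 <- parse_newick("((a,b),(c,d));")
  am2 <- parse_associations(
    data.frame(c("A", "B", "C", "D"), c("a", "b", "c", "d")), m2, M2)
  M2$edge.length <- rep(1, nrow(M2$edge))
  m2$edge.length <- rep(1, nrow(m2$edge))
  res2 <- distance_correlation_test(m2, M2, am2, mode = "patristic",
                                    n = 9, seed = 1)
  expect_s3_class(res2, "congruence_test")
})

test_that("rho is invariant under monotone transformation of distances", {
  cp <- congruent_pair(7, seed = 44)
  cp$mimic$edge.length <- runif(nrow(cp$mimic$edge), 0.5, 2)
  cp$model$edge.length <- runif(nrow(cp$model$edge), 0.5, 2)
  r1 <- distance_correlation_test(cp$mimic, cp$model, cp$assoc,
                                  mode = "patristic", n = 19, seed = 2)
  # squaring patristic distances is monotone; implemented by squaring
  # branch...not exactly, so instead scale all lengths (monotone linear)
  cp$model$edge.length <- 3 * cp$model$edge.length
  r2 <- distance_correlation_test(cp$mimic, cp$model, cp$assoc,
                                  mode = "patristic", n = 19, seed = 2)
  expect_equal(r1$statistic, r2$statistic)
  expect_true(abs(r1$statistic) <= 1)
})

test_that("root-level convenience wrapper runs both directions", {
  cp <- congruent_pair(8, seed = 55)
  both <- root_congruence_both(cp$mimic, cp$model, cp$assoc, n = 99, seed = 1)
  expect_named(both, c("randomize_mimic", "randomize_model"))
  expect_lte(both$randomize_mimic$p, 0.05)
  expect_lte(both$randomize_model$p, 0.05)
  tab <- congruence_table(assoc = both$randomize_mimic,
                          tree = both$randomize_model)
  expect_equal(nrow(tab), 2L)
  expect_true(all(tab$wilson_95_max >= tab$p))
})
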