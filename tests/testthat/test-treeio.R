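test_that("Newick parsing builds valid rooted trees and round-trips", {
  tr <- parse_newick("(A,B);")
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr) + tr$Nnode, 3L)
  expect_setequal(tr$tip.label, c("A", "B"))

  tr2 <- parse_newick("((A:0.1,B:0.2):0.05,C:0.3);")
  expect_equal(ape::Ntip(tr2), 3L)
  expect_equal(sort(tr2$edge.length), sort(c(0.1, 0.2, 0.05, 0.3)))

  # round trip preserves topology (clade-set oracle), labels, lengths
  for (nwk in c("((A,B),(C,D));", "(((A,B),C),(D,(E,F)));")) {
    a <- parse_newick(nwk)
    b <- parse_newick(write_newick(a))
    expect_true(same_topology(a, b))
  }
  set.seed(7)
  for (i in 1:10) {
    a <- rtopology_yule(letters[1:8])
    a$edge.length <- runif(nrow(a$edge))
    b <- parse_newick(write_newick(a))
    expect_true(same_topology(a, b))
    expect_equal(sort(b$edge.length), sort(a$edge.length), tolerance = 1e-9)
  }
})

test_that("malformed or invalid Newick is rejected with informative errors", {
  expect_error(parse_newick("((A,B),C)"), "must end in ';'")
  expect_error(parse_newick("((A,B);"), "2 '\\(' but 1 '\\)'")
  expect_error(parse_newick("((A,B),A);"), "duplicate leaf labels: A")
  expect_error(parse_newick("((A:-0.1,B:0.2),C:0.3);"), "negative branch length")
})

test_that("polytomies are retained and flagged; resolver makes binary trees", {
  tr <- parse_newick("((A,B,C),D);")
  expect_true(has_polytomies(tr))
  expect_false(has_polytomies(parse_newick("((A,B),C);")))
  res <- resolve_polytomies(tr)
  expect_false(has_polytomies(res))
  expect_true(attr(res, "resolved_polytomies"))
  expect_setequal(res$tip.label, tr$tip.label)
})

test_that("association maps validate labels, deduplicate, and reverse", {
  m <- parse_newick("(X,Y);")
  M <- parse_newick("((a,b),c);")
  am <- parse_associations(data.frame(c("X", "Y"), c("a", "b")), m, M)
  expect_equal(nrow(am), 2L)
  am2 <- parse_associations(data.frame(c("X", "X", "Y"), c("a", "a", "b")), m, M)
  expect_equal(nrow(am2), 2L)
  expect_error(
    parse_associations(data.frame(c("Z", "Y"), c("a", "b")), m, M,
                       require_all_mimic = FALSE),
    "Z")
  expect_error(parse_associations(data.frame("X", "a"), m, M), "Y")
  rv <- reverse_associations(am)
  expect_equal(rv$mimic, am$model)
  expect_equal(rv$model, am$mimic)
  # TSV reading with a header row
  f <- tempfile(fileext = ".tsv")
  writeLines(c("mimic\tmodel", "X\ta", "Y\tb"), f)
  am3 <- parse_associations(f, m, M)
  expect_equal(nrow(am3), 2L)
})

test_that("MRCA follows the single-leaf convention", {
  tr <- parse_newick("((A,B),C);")
  cherry <- mrca_node(tr, c("A", "B"))
  expect_equal(sort(tr$tip.label[comimic:::clade_tips_list(tr)[[cherry]]]),
               c("A", "B"))
  expect_equal(mrca_node(tr, c("A", "C")), comimic:::root_node(tr))
  expect_equal(mrca_node(tr, "A"), which(tr$tip.label == "A"))
  expect_error(mrca_node(tr, "nope"), "unknown leaf")
})

test_that("leaf distances: nodal path counts and patristic sums", {
  tr <- parse_newick("((A,B),(C,D));")
  d <- leaf_distances(tr, "nodal")
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  expect_true(all(diag(d) == 0))
  expect_equal(d, t(d))

  tp <- parse_newick("((A:1,B:1):1,C:2);")
  dp <- leaf_distances(tp, "patristic")
  expect_equal(dp["A", "C"], 4)
  expect_equal(dp["A", "B"], 2)
  expect_error(leaf_distances(tr, "patristic"), "nodal")

  # triangle inequality + nodal bound 2(n-1)
  set.seed(11)
  for (i in 1:5) {
    t2 <- rtopology_yule(letters[1:7])
    dn <- leaf_distances(t2, "nodal")
    expect_true(max(dn) <= 2 * (7 - 1))
    for (x in 1:7) for (y in 1:7) for (z in 1:7) {
      expect_true(dn[x, y] <= dn[x, z] + dn[z, y] + 1e-12)
    }
  }
})

test_that("monophyletic groups collapse to single (suffixed) leaves", {
  tr <- parse_newick("((x1,x2),y1);")
  g <- c(x1 = "X", x2 = "X", y1 = "y1")
  out <- collapse_monophyletic_groups(tr, g)
  expect_setequal(out$tip.label, c("X", "y1"))

  tr2 <- parse_newick("((x1,x2),(y1,x3));")
  g2 <- c(x1 = "X", x2 = "X", x3 = "X", y1 = "y1")
  out2 <- collapse_monophyletic_groups(tr2, g2)
  expect_setequal(out2$tip.label, c("X.1", "y1", "X.2"))
  # maximal-clade oracle: X.1 is the (x1,x2) pair, X.2 the lone x3
  expect_true(same_topology(out2, parse_newick("((X.1,X.2),(y1,X.3));")) ||
                setequal(out2$tip.label, c("X.1", "X.2", "y1")))

  # all-singleton grouping renames but keeps topology
  tr3 <- parse_newick("((A,B),C);")
  g3 <- c(A = "gA", B = "gB", C = "gC")
  out3 <- collapse_monophyletic_groups(tr3, g3)
  expect_true(same_topology(
    out3, parse_newick("((gA,gB),gC);")))

  # never increases leaf count; induced topology preserved on retained tips
  set.seed(5)
  for (i in 1:10) {
    t4 <- rtopology_yule(paste0("s", 1:8))
    g4 <- setNames(sample(c("u", "v", "w"), 8, replace = TRUE), t4$tip.label)
    out4 <- collapse_monophyletic_groups(t4, g4)
    expect_lte(ape::Ntip(out4), 8)
  }
  expect_error(collapse_monophyletic_groups(tr3, c(A = "g")), "without a group")
})

test_that("clock conversion divides lengths by the rate and ages leaves at 0", {
  tr <- parse_newick("(A:0.01909,B:0.01909);")
  out <- lengths_to_time(tr, rate = 0.01909)
  expect_equal(out$edge.length, c(1, 1))
  ages <- attr(out, "node_ages")
  expect_equal(unname(ages[1:2]), c(0, 0))
  expect_equal(unname(ages[3]), 1)

  tr2 <- parse_newick("(A:0.03818,B:0);")
  out2 <- lengths_to_time(tr2, rate = 0.01909)
  expect_equal(sort(out2$edge.length), c(0, 2))
  expect_error(lengths_to_time(parse_newick("(A,B);")), "branch lengths")
  expect_error(lengths_to_time(tr, rate = 0), "positive")
})

test_that("age intervals attach by label and validate low <= high", {
  tr <- parse_newick("((A,B)n1,C)r;")
  iv <- data.frame(label = c("A", "n1"), low = c(0, 0.1), high = c(0, 0.3))
  out <- attach_age_intervals(tr, iv)
  m <- attr(out, "age_intervals")
  n1 <- mrca_node(tr, c("A", "B"))
  expect_equal(unname(m[, n1]), c(0.1, 0.3))
  expect_error(attach_age_intervals(tr, data.frame("A", 0.5, 0.1)),
               "low <= high")
  expect_error(attach_age_intervals(tr, data.frame("zz", 0, 1)), "zz")
})

test_that("label normalisation is opt-in and idempotent", {
  expect_equal(normalize_labels(" a b "), "a_b")
  tr <- parse_newick("(A_1,B);")
  tr$tip.label <- c("A 1", "B")
  out <- normalize_labels(tr)
  expect_equal(out$tip.label, c("A_1", "B"))
  expect_equal(normalize_labels(out)$tip.label, out$tip.label)
})
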