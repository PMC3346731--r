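mk_aln <- function(seqs, groups) {
  grouped_alignment(seqs, groups)
}

test_that("segregating sites use complete deletion within the group", {
  aln <- mk_aln(c(s1 = "AAAAAAAAAA", s2 = "AAAAAAAAAA", s3 = "AAAAAAAAAA"),
                c(s1 = "g", s2 = "g", s3 = "g"))
  expect_equal(unname(segregating_sites(aln, "g")), c(0, 10))

  # two polymorphic gap-free columns out of ten
  aln2 <- mk_aln(c(s1 = "ACAAAAAAAA", s2 = "AAAAAAAAAT", s3 = "AAAAAAAAAA"),
                 c(s1 = "g", s2 = "g", s3 = "g"))
  s <- segregating_sites(aln2, "g")
  expect_equal(unname(s), c(2, 10))

  # a gap removes its column from L_eff entirely
  aln3 <- mk_aln(c(s1 = "A-AAAAAAAA", s2 = "AAAAAAAAAT", s3 = "AAAAAAAAAA"),
                 c(s1 = "g", s2 = "g", s3 = "g"))
  s3 <- segregating_sites(aln3, "g")
  expect_equal(unname(s3), c(1, 9))
  # ambiguity codes count as missing, like gaps
  aln4 <- mk_aln(c(s1 = "ANAAAAAAAA", s2 = "AAAAAAAAAA"),
                 c(s1 = "g", s2 = "g"))
  expect_equal(unname(segregating_sites(aln4, "g"))[2], 9)
  expect_error(segregating_sites(aln3, "absent"), "no sequences")
})

test_that("Watterson's theta follows S/(a L_eff)", {
  aln <- mk_aln(c(s1 = "AAAAAAAAAA", s2 = "AAAAAAAAAA", s3 = "AAAAAAAAAA"),
                c(s1 = "g", s2 = "g", s3 = "g"))
  expect_equal(watterson_theta(aln, "g"), 0)
  aln2 <- mk_aln(c(s1 = "ACAAAAAAAA", s2 = "AAAAAAAAAT", s3 = "AAAAAAAAAA"),
                 c(s1 = "g", s2 = "g", s3 = "g"))
  expect_equal(watterson_theta(aln2, "g"), 2 / ((1 + 1 / 2) * 10),
               tolerance = 1e-12)
})

test_that("pairwise diversity averages p-distances with pairwise deletion", {
  aln <- mk_aln(c(s1 = "AAAAAAAAAA", s2 = "AAAAAAAAAA"),
                c(s1 = "g", s2 = "g"))
  expect_equal(pairwise_diversity(aln, "g"), 0)
  # pairwise differences 1, 2, 1 over 10 sites -> mean 4/30
  aln2 <- mk_aln(c(s1 = "CAAAAAAAAA", s2 = "AAAAAAAAAT", s3 = "CAAAAAAAAT"),
                 c(s1 = "g", s2 = "g", s3 = "g"))
  expect_equal(pairwise_diversity(aln2, "g"), 4 / 30, tolerance = 1e-12)
  # agreement with an established raw-distance implementation
  m <- aln2$mat
  bin <- ape::as.DNAbin(m)
  d <- ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE)
  expect_equal(pairwise_diversity(aln2, "g"), mean(d), tolerance = 1e-12)
})

test_that("between-group divergence averages cross-group p-distances", {
  aln <- mk_aln(c(a1 = "AAAA", b1 = "AAAA"), c(a1 = "A", b1 = "B"))
  expect_equal(between_group_divergence(aln, "A", "B"), 0)
  aln2 <- mk_aln(c(a1 = "AAAA", b1 = "AATT"), c(a1 = "A", b1 = "B"))
  expect_equal(between_group_divergence(aln2, "A", "B"), 0.5)
  # hand-averaged 0.1 and 0.3 -> 0.2
  aln3 <- mk_aln(c(a1 = "AAAAAAAAAA", a2 = "AAAAAAAATT", b1 = "TAAAAAAAAA"),
                 c(a1 = "A", a2 = "A", b1 = "B"))
  expect_equal(between_group_divergence(aln3, "A", "B"), 0.2,
               tolerance = 1e-12)
  expect_error(between_group_divergence(aln3, "A", "absent"), "no sequences")
})

test_that("statistics are invariant to sequence order", {
  set.seed(99)
  tr <- rtopology_yule(paste0("g.", 1:6))
  tr$edge.length <- runif(nrow(tr$edge), 0.01, 0.05)
  aln <- simulate_alignment(tr, L = 500, seed = 5)
  perm <- sample(nrow(aln$mat))
  aln2 <- grouped_alignment(aln$mat[perm, , drop = FALSE], aln$groups[perm])
  expect_equal(watterson_theta(aln, "g"), watterson_theta(aln2, "g"))
  expect_equal(pairwise_diversity(aln, "g"), pairwise_diversity(aln2, "g"))
  expect_equal(unname(segregating_sites(aln, "g")),
               unname(segregating_sites(aln2, "g")))
})

test_that("popgen_stats bundles the invariant identity theta = S/(a L_eff)", {
  aln <- mk_aln(c(s1 = "ACAAAAAAAA", s2 = "AAAAAAAAAT", s3 = "AAAAAAAAAA"),
                c(s1 = "g", s2 = "g", s3 = "g"))
  st <- popgen_stats(aln, "g")
  expect_equal(st$theta_w_per_bp, st$S / (st$a * st$L_eff))
  expect_true(st$pi_per_bp >= 0 && st$pi_per_bp <= 1)
  # per-locus averaging over a partition
  aln$partition <- list(c(1, 5), c(6, 10))
  st2 <- popgen_stats(aln, "g", per_locus = TRUE)
  expect_equal(nrow(st2$per_locus), 2L)
})

test_that("FASTA and NEXUS readers round-trip a small alignment", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">s1", "ACGTACGT", ">s2", "ACGTACGA"), f)
  aln <- read_alignment_fasta(f, groups = c(s1 = "g", s2 = "g"))
  expect_equal(dim(aln$mat), c(2L, 8L))
  expect_equal(paste(aln$mat["s2", ], collapse = ""), "ACGTACGA")

  nx <- tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN DATA;",
               "DIMENSIONS NTAX=2 NCHAR=8;",
               "FORMAT DATATYPE=DNA MISSING=? GAP=-;",
               "MATRIX", "s1 ACGTACGT", "s2 ACGTACGA", ";", "END;"), nx)
  aln2 <- read_alignment_nexus(nx, groups = c(s1 = "g", s2 = "g"))
  expect_equal(aln2$mat, aln$mat)

  g <- tempfile(fileext = ".tsv")
  writeLines(c("label\tgroup", "s1\tx", "s2\ty"), g)
  gr <- read_groups_tsv(g)
  expect_equal(unname(gr[c("s1", "s2")]), c("x", "y"))
})

test_that("unequal lengths and unknown labels are rejected", {
  expect_error(grouped_alignment(c(a = "ACGT", b = "ACG"), c(a = "g", b = "g")),
               "equal length")
  expect_error(grouped_alignment(c(a = "ACGT", b = "ACGA"), c(a = "g")),
               "without a group")
})
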