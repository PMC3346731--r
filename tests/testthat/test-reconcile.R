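test_that("identical shapes reconcile at zero cost with all codivergences", {
  m <- parse_newick("((A,B),C);")
  M <- parse_newick("((a,b),c);")
  am <- parse_associations(data.frame(c("A", "B", "C"), c("a", "b", "c")), m, M)
  r <- reconcile_min_cost(m, M, am)
  expect_equal(r$cost, 0)
  expect_equal(length(r$solutions), 1L)
  expect_equal(unname(event_tally(r$solutions[[1]])), c(2L, 0L, 0L, 0L))
})

test_that("two mimics on one model leaf is a single duplication", {
  m <- parse_newick("(X,Y);")
  M <- parse_newick("(a,b);")
  am <- parse_associations(data.frame(c("X", "Y"), c("a", "a")), m, M)
  r <- reconcile_min_cost(m, M, am)
  expect_equal(r$cost, 1)
  expect_equal(unname(event_tally(r$solutions[[1]])), c(0L, 1L, 0L, 0L))
})

test_that("split mimic cherry: codivergence+loss ties duplication+switch at cost 2", {
  m <- parse_newick("(X,Y);")
  M <- parse_newick("((a,b),c);")
  am <- parse_associations(data.frame(c("X", "Y"), c("a", "c")), m, M)
  r <- reconcile_min_cost(m, M, am)
  expect_equal(r$cost, 2)
  expect_equal(reconcile_cost_bruteforce(m, M, am), 2)
  tallies <- lapply(r$solutions, function(s) unname(event_tally(s)))
  has_tally <- function(t) any(vapply(tallies, identical, TRUE, y = t))
  # the two qualitatively distinct optima: codivergence at the model root
  # with one loss, and a duplication whose daughter switches
  expect_true(has_tally(c(1L, 0L, 0L, 1L)))
  expect_true(has_tally(c(0L, 1L, 1L, 0L)))
})

test_that("DP equals brute force and C++ equals R on random small instances", {
  set.seed(202)
  n_codiv_seen <- 0
  for (i in 1:60) {
    inst <- random_instance(2:5, one_to_one = (i %% 2 == 0))
    costs <- event_costs(0, sample(0:2, 1), sample(0:2, 1), sample(0:3, 1))
    r <- reconcile_min_cost(inst$mimic, inst$model, inst$assoc, costs)
    bf <- reconcile_cost_bruteforce(inst$mimic, inst$model, inst$assoc, costs)
    cp <- reconcile_cost(inst$mimic, inst$model, inst$assoc, costs)
    expect_equal(r$cost, bf)
    expect_equal(cp, bf)
    # every reported solution attains the minimum and satisfies the
    # cost = tally . costs identity
    for (s in r$solutions) {
      expect_equal(s$total_cost, r$cost)
      expect_equal(sum(event_tally(s) * as.numeric(costs)), r$cost)
    }
    n_codiv_seen <- n_codiv_seen + event_tally(r$solutions[[1]])["n_codiv"]
  }
  expect_gt(n_codiv_seen, 0)
})

test_that("zero cost under defaults iff the association induces congruence", {
  set.seed(303)
  for (i in 1:20) {
    cp <- congruent_pair(sample(4:8, 1))
    expect_equal(reconcile_cost(cp$mimic, cp$model, cp$assoc), 0)
  }
  # perturbed association on a congruent pair is no longer free
  cp <- congruent_pair(6, seed = 9)
  sw <- cp$assoc
  sw$model[1:2] <- sw$model[2:1]
  expect_gt(reconcile_cost(cp$mimic, cp$model, sw), 0)
})

test_that("raising any single event cost never lowers the minimum", {
  set.seed(404)
  for (i in 1:15) {
    inst <- random_instance(3:5)
    base <- event_costs(0, 1, 1, 2)
    c0 <- reconcile_cost(inst$mimic, inst$model, inst$assoc, base)
    for (ev in c("codivergence", "duplication", "switch", "loss")) {
      up <- as.numeric(base)
      names(up) <- names(base)
      up[ev] <- up[ev] + 2
      c1 <- reconcile_cost(inst$mimic, inst$model, inst$assoc,
                           do.call(event_costs, as.list(up)))
      expect_gte(c1, c0)
    }
  }
})

test_that("solution cap is respected and all kept solutions share the cost", {
  m <- rtopology_yule(paste0("p", 1:6))
  M <- rtopology_yule(paste0("h", 1:6))
  set.seed(5)
  am <- parse_associations(
    data.frame(m$tip.label, sample(M$tip.label)), m, M)
  r <- reconcile_min_cost(m, M, am, max_solutions = 3)
  expect_lte(length(r$solutions), 3L)
  expect_true(all(vapply(r$solutions, function(s) s$total_cost, 0) == r$cost))
})

test_that("codivergence ceiling is the internal-node count", {
  expect_equal(max_codivergences(rtopology_yule(paste0("t", 1:12))), 11L)
  expect_equal(max_codivergences(parse_newick("(A,B);")), 1L)
  for (n in c(3, 5, 9)) {
    expect_equal(max_codivergences(rtopology_yule(paste0("t", 1:n))), n - 1L)
  }
  # n_codiv never exceeds the ceiling
  set.seed(77)
  inst <- random_instance(4:5)
  r <- reconcile_min_cost(inst$mimic, inst$model, inst$assoc)
  expect_lte(event_tally(r$solutions[[1]])["n_codiv"],
             max_codivergences(inst$mimic))
})

test_that("polytomies are rejected by the DP with a pointer to the resolver", {
  m <- parse_newick("((A,B,C),D);")
  M <- parse_newick("((a,b),(c,d));")
  am <- data.frame(c("A", "B", "C", "D"), c("a", "b", "c", "d"))
  expect_error(reconcile_min_cost(m, M, am), "resolve_polytomies")
  r <- reconcile_min_cost(resolve_polytomies(m), M,
                          parse_associations(am, resolve_polytomies(m), M))
  expect_s3_class(r, "reconciliation_set")
})

test_that("temporal consistency reports closed-interval overlap per codivergence", {
  cp <- congruent_pair(3, seed = 1)
  r <- reconcile_min_cost(cp$mimic, cp$model, cp$assoc)
  sol <- r$solutions[[1]]
  nn <- ape::Ntip(cp$mimic) + cp$mimic$Nnode
  ivP <- matrix(NA_real_, 2, nn)
  ivM <- matrix(NA_real_, 2, nn)
  cd <- sol$events[sol$events$event == "codivergence", ]
  # overlap, disjoint, shared-endpoint, and missing cases
  ivP[, cd$mimic_node[1]] <- c(0.1, 0.3); ivM[, cd$model_node[1]] <- c(0.2, 0.5)
  ivP[, cd$mimic_node[2]] <- c(0.1, 0.2); ivM[, cd$model_node[2]] <- c(0.3, 0.4)
  out <- temporal_consistency(sol, ivP, ivM)
  expect_equal(out$overlap[1], "yes")
  expect_equal(out$overlap[2], "no")
  ivM[, cd$model_node[2]] <- c(0.2, 0.3)
  out2 <- temporal_consistency(sol, ivP, ivM)
  expect_equal(out2$overlap[2], "yes")
  ivP[, cd$mimic_node[1]] <- NA
  out3 <- temporal_consistency(sol, ivP, ivM)
  expect_equal(out3$overlap[1], "unknown")
})

test_that("the Heliconius example reconciles with the narrated switches and loss", {
  hx <- heliconius_country_example()
  r <- reconcile_min_cost(hx$mimic, hx$model, hx$assoc)
  expect_equal(length(r$solutions), 1L)
  sol <- r$solutions[[1]]
  ev <- sol$events
  sw <- ev[ev$event == "switch", ]
  lab <- function(v) ifelse(v <= 12, hx$model$tip.label[v], NA)
  # ecuadoriensis colonises etylus; the Trinidad melpomene lineage
  # colonises Trinidad hydara
  expect_setequal(na.omit(lab(sw$switch_target)), c("ety_EE", "hyd_T"))
  expect_equal(nrow(sw), 2L)
})
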