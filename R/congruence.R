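# Monte-Carlo significance tests of topological congruence between a
# mimic and a model phylogeny: minimum reconciliation cost against two
# randomisation nulls, Wilson score upper bounds on Monte-Carlo p-values,
# and the node-wise pairwise-distance Spearman test.

#' Wilson score interval upper bound for a binomial proportion
#'
#' Two-sided Wilson interval at confidence `conf`; the upper limit is
#' `(p + z^2/2n + z sqrt(p(1-p)/n + z^2/4n^2)) / (1 + z^2/n)`. Used to
#' bound Monte-Carlo p-values, where the Wilson interval remains sensible
#' at p = 0.
#'
#' @param p_hat Observed proportion in `[0, 1]`.
#' @param n Number of trials (>= 1).
#' @param conf Confidence level (default 0.95, z = 1.959964).
#' @return Upper bound on the proportion.
#' @export
wilson_upper <- function(p_hat, n, conf = 0.95) {
  if (any(p_hat < 0) || any(p_hat > 1)) stop("p_hat must lie in [0, 1]")
  if (any(n < 1)) stop("n must be >= 1")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  (p_hat + z^2 / (2 * n) + z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2))) /
    (1 + z^2 / n)
}

new_test_result <- function(statistic, n, count, seed, null_type,
                            corrected = FALSE, flag = NA_character_,
                            null_sample = NULL) {
  n <- as.integer(n)
  p <- if (is.na(count)) NA_real_ else if (corrected) (count + 1) / (n + 1) else count / n
  structure(list(
    statistic = statistic,
    n = n,
    count = count,
    p = p,
    wilson_upper = if (is.na(p)) NA_real_ else wilson_upper(p, n),
    seed = seed,
    null_type = null_type,
    corrected = corrected,
    flag = flag,
    null_sample = null_sample
  ), class = "congruence_test")
}

#' @export
print.congruence_test <- function(x, ...) {
  cat(sprintf("congruence test [%s]: statistic = %s, p = %s [95%% max %s] (n = %d)\n",
              x$null_type,
              format(x$statistic, digits = 4),
              format(x$p, digits = 4),
              format(x$wilson_upper, digits = 4), x$n))
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

# shared fast-path pieces for the two minimum-cost Monte-Carlo tests
mc_setup <- function(mimic, model, assoc, costs) {
  validate_phylo(mimic); validate_phylo(model)
  if (!inherits(assoc, "assoc_map")) {
    assoc <- parse_associations(assoc, mimic, model)
  }
  list(
    edgeP = mimic$edge, ntipP = ape::Ntip(mimic),
    edgeM = model$edge, ntipM = ape::Ntip(model),
    mi = match(assoc$mimic, mimic$tip.label),
    Mi = match(assoc$model, model$tip.label),
    costs = as.numeric(costs),
    labels = mimic$tip.label
  )
}

#' Minimum-cost congruence test with randomised leaf associations
#'
#' Null hypothesis: the current mimic-model associations are not a
#' consequence of a shared history. The null distribution of the minimum
#' reconciliation cost is generated by uniformly permuting the model-leaf
#' column of the association pairs. `p` is the raw proportion of null
#' replicates with cost less than or equal to the observed minimum (no
#' pseudocount by default, so p may be exactly 0; set `corrected = TRUE`
#' for the (r+1)/(n+1) version).
#'
#' @param mimic,model Rooted fully resolved `phylo` trees.
#' @param assoc An `assoc_map`.
#' @param costs An [event_costs()] regime.
#' @param n Number of Monte-Carlo replicates (>= 1).
#' @param seed Integer seed (results are reproducible given the seed).
#' @param corrected Use the (r+1)/(n+1) p-value.
#' @return A `congruence_test` result.
#' @export
mc_test_random_associations <- function(mimic, model, assoc,
                                        costs = event_costs(),
                                        n = 1000L, seed = 1L,
                                        corrected = FALSE) {
  if (n < 1L) stop("n must be >= 1")
  s <- mc_setup(mimic, model, assoc, costs)
  obs <- dp_min_cost(s$edgeP, s$ntipP, s$edgeM, s$ntipM,
                     cbind(s$mi, s$Mi), s$costs)
  set.seed(seed)
  nulls <- numeric(n)
  for (r in seq_len(n)) {
    Mi_perm <- s$Mi[sample.int(length(s$Mi))]
    nulls[r] <- dp_min_cost(s$edgeP, s$ntipP, s$edgeM, s$ntipM,
                            cbind(s$mi, Mi_perm), s$costs)
  }
  new_test_result(obs, n, sum(nulls <= obs), seed, "random-associations",
                  corrected, null_sample = nulls)
}

#' Minimum-cost congruence test with a randomised mimic tree
#'
#' Null hypothesis: the branching order of the mimic tree does not depend
#' on the model tree. The mimic topology is regenerated on the same leaf
#' set under a Yule (default) or uniform-topology null, keeping the
#' associations fixed.
#'
#' @inheritParams mc_test_random_associations
#' @param null_model `"yule"` (random sequential joins) or `"uniform"`
#'   (uniform labelled rooted topologies, PDA).
#' @return A `congruence_test` result.
#' @export
mc_test_random_mimic_tree <- function(mimic, model, assoc,
                                      costs = event_costs(),
                                      n = 1000L, seed = 1L,
                                      null_model = c("yule", "uniform"),
                                      corrected = FALSE) {
  if (n < 1L) stop("n must be >= 1")
  null_model <- match.arg(null_model)
  s <- mc_setup(mimic, model, assoc, costs)
  obs <- dp_min_cost(s$edgeP, s$ntipP, s$edgeM, s$ntipM,
                     cbind(s$mi, s$Mi), s$costs)
  gen <- if (null_model == "yule") rtopology_yule else rtopology_uniform
  set.seed(seed)
  nulls <- numeric(n)
  for (r in seq_len(n)) {
    # same tip labels in the same index slots, so the association index
    # vectors carry over unchanged
    tr <- gen(s$labels)
    nulls[r] <- dp_min_cost(tr$edge, s$ntipP, s$edgeM, s$ntipM,
                            cbind(s$mi, s$Mi), s$costs)
  }
  new_test_result(obs, n, sum(nulls <= obs), seed,
                  paste0("random-mimic-tree(", null_model, ")"),
                  corrected, null_sample = nulls)
}

# distance mode default: patristic when both trees carry lengths
pick_mode <- function(mimic, model, mode) {
  if (!is.null(mode)) return(match.arg(mode, c("patristic", "nodal")))
  if (!is.null(mimic$edge.length) && !is.null(model$edge.length))
    "patristic" else "nodal"
}

#' Node-wise pairwise-distance correlation test
#'
#' For a focus node of the mimic tree, the associated leaves of the other
#' tree are found and their most recent common ancestor determines the
#' counterpart subtree. The statistic is the Spearman rank correlation
#' (average ranks for ties) between mimic and model leaf-pair distances
#' over the association pairs in the focus subtree; significance comes
#' from permuting the mimic leaf labels within the focus subtree. This
#' tests topological congruence without reconstructing an explicit event
#' history.
#'
#' @inheritParams mc_test_random_associations
#' @param focus Node of the (randomised) mimic tree: an ape node index or
#'   a character vector of leaf labels whose MRCA is used; default the
#'   mimic root.
#' @param mode `"patristic"` or `"nodal"`; `NULL` picks patristic when
#'   both trees have branch lengths, else nodal.
#' @return A `congruence_test`; `p = (# null rho >= observed rho) / n`.
#'   With fewer than 4 association pairs in the focus subtree the result
#'   is flagged `"not evaluable"`; zero variance in either distance vector
#'   flags `"undefined statistic"`.
#' @export
distance_correlation_test <- function(mimic, model, assoc, focus = NULL,
                                      mode = NULL, n = 1000L, seed = 1L,
                                      corrected = FALSE) {
  if (n < 1L) stop("n must be >= 1")
  validate_phylo(mimic); validate_phylo(model)
  if (!inherits(assoc, "assoc_map")) {
    assoc <- parse_associations(assoc, mimic, model)
  }
  mode <- pick_mode(mimic, model, mode)
  if (is.null(focus)) focus <- root_node(mimic)
  if (is.character(focus)) focus <- mrca_node(mimic, focus)
  tipsP <- clade_tips_list(mimic)[[focus]]
  focus_leaves <- mimic$tip.label[tipsP]
  pairs <- assoc[assoc$mimic %in% focus_leaves, , drop = FALSE]
  if (nrow(pairs) < 4L) {
    return(new_test_result(NA_real_, n, NA_integer_, seed,
                           "subtree-permutation",
                           corrected, flag = "not evaluable"))
  }
  dP <- leaf_distances(mimic, mode)
  dM <- leaf_distances(model, mode)
  ij <- utils::combn(nrow(pairs), 2L)
  vec <- function(d, labs) d[cbind(labs[ij[1, ]], labs[ij[2, ]])]
  x0 <- vec(dP, pairs$mimic)
  y <- vec(dM, pairs$model)
  if (stats::sd(x0) == 0 || stats::sd(y) == 0) {
    return(new_test_result(NA_real_, n, NA_integer_, seed,
                           "subtree-permutation",
                           corrected, flag = "undefined statistic"))
  }
  rho <- function(x) suppressWarnings(stats::cor(x, y, method = "spearman"))
  obs <- rho(x0)
  set.seed(seed)
  nulls <- numeric(n)
  labs <- pairs$mimic
  uniq <- unique(labs)
  for (r in seq_len(n)) {
    perm <- stats::setNames(uniq[sample.int(length(uniq))], uniq)
    xl <- unname(perm[labs])
    xr <- dP[cbind(xl[ij[1, ]], xl[ij[2, ]])]
    nr <- rho(xr)
    nulls[r] <- if (is.na(nr)) -Inf else nr
  }
  new_test_result(obs, n, sum(nulls >= obs), seed, "subtree-permutation",
                  corrected, null_sample = nulls)
}

#' Distance-correlation tests at both roots
#'
#' Runs [distance_correlation_test()] at the mimic root (randomising the
#' mimic) and, with roles reversed, at the model root (randomising the
#' model), reproducing the two root-level columns of a congruence table.
#'
#' @inheritParams distance_correlation_test
#' @return List with elements `randomize_mimic` and `randomize_model`.
#' @export
root_congruence_both <- function(mimic, model, assoc, mode = NULL,
                                 n = 1000L, seed = 1L) {
  a <- distance_correlation_test(mimic, model, assoc, focus = NULL,
                                 mode = mode, n = n, seed = seed)
  rev <- reverse_associations(assoc)
  b <- distance_correlation_test(model, mimic, rev, focus = NULL,
                                 mode = mode, n = n,
                                 seed = substream_seed(seed, 2L))
  list(randomize_mimic = a, randomize_model = b)
}

#' Table-style summary of congruence tests
#'
#' @param ... Named `congruence_test` objects.
#' @return Data frame with statistic, p and Wilson 95% upper bound.
#' @export
congruence_table <- function(...) {
  tests <- list(...)
  data.frame(
    test = names(tests),
    statistic = vapply(tests, function(t) t$statistic, 0),
    p = vapply(tests, function(t) t$p, 0),
    wilson_95_max = vapply(tests, function(t) t$wilson_upper, 0),
    n = vapply(tests, function(t) t$n, 0L),
    row.names = NULL
  )
}
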