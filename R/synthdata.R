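# Seed-controlled generators for every statistical structure the pipeline
# assumes: null tree topologies, paired codivergent radiations with event
# truth-logs, multispecies-coalescent gene trees, and JC69 alignments.

#' Deterministic per-replicate substream seed
#'
#' One master seed; replicate i gets a derived seed so that replicates are
#' independent yet the whole experiment is reproducible.
#'
#' @param seed Master seed (integer).
#' @param i Replicate index (>= 1).
#' @return An integer seed below 2^31.
#' @export
substream_seed <- function(seed, i) {
  x <- (as.numeric(seed) %% 2147483647) * 48271 + 1009 * as.numeric(i)
  as.integer(x %% 2147483647)
}

# build a phylo from a sequence of joins over n tips.
# joins: (n-1) x 2 matrix of lineage ids merged at each step, where
# lineages 1..n are tips and join j creates lineage n+j.
joins_to_phylo <- function(joins, labels) {
  n <- length(labels)
  # ape wants tips 1..n, root n+1; join j (1-based, last join = root)
  # creates internal node id 2n - j
  nnode <- n - 1L
  id_of <- c(seq_len(n), integer(nnode))
  edge <- matrix(0L, 2L * n - 2L, 2L)
  k <- 0L
  for (j in seq_len(nnode)) {
    new_id <- 2L * n - j
    id_of[n + j] <- new_id
    for (child in joins[j, ]) {
      k <- k + 1L
      edge[k, ] <- c(new_id, id_of[child])
    }
  }
  tr <- structure(list(edge = edge, Nnode = nnode, tip.label = labels),
                  class = "phylo", order = "postorder")
  ape::reorder.phylo(tr, "cladewise")
}

#' Random tree topology under the Yule (coalescent-join) null
#'
#' Generated by random sequential joins with a uniform pick among the
#' currently active lineages; this is the labelled-topology distribution of
#' the Yule pure-birth process. Topology only (no branch lengths).
#'
#' @param labels Character vector of leaf labels (n >= 2).
#' @return A rooted binary `phylo`.
#' @export
rtopology_yule <- function(labels) {
  n <- length(labels)
  stopifnot(n >= 2L)
  active <- seq_len(n)
  joins <- matrix(0L, n - 1L, 2L)
  for (j in seq_len(n - 1L)) {
    pick <- sample.int(length(active), 2L)
    joins[j, ] <- active[pick]
    active <- c(active[-pick], n + j)
  }
  joins_to_phylo(joins, labels)
}

#' Random tree topology uniform over labelled rooted topologies (PDA)
#'
#' Sequential leaf insertion at a uniformly chosen edge (including the root
#' stem), giving each of the (2n-3)!! labelled rooted binary topologies
#' equal probability.
#'
#' @param labels Character vector of leaf labels (n >= 2).
#' @return A rooted binary `phylo`.
#' @export
rtopology_uniform <- function(labels) {
  n <- length(labels)
  stopifnot(n >= 2L)
  nest <- list(labels[1L], labels[2L])
  for (k in seq.int(3L, length.out = n - 2L)) {
    spots <- insertion_points(nest)
    pick <- spots[[sample.int(length(spots), 1L)]]
    nest <- insert_at(nest, pick, labels[k])
  }
  parse_newick(paste0(nest_to_newick(nest), ";"))
}

# ---- nested-list tree helpers (shared with the MDC search) ---------------

nest_to_newick <- function(nest) {
  if (is.character(nest)) return(nest)
  paste0("(", paste(vapply(nest, nest_to_newick, ""), collapse = ","), ")")
}

# enumerate insertion points as integer paths; c() is the root stem and
# c(i, j, ...) descends through child indices to an edge above that node
insertion_points <- function(nest, path = integer(0)) {
  out <- list(path)
  if (!is.character(nest)) {
    for (i in seq_along(nest)) {
      out <- c(out, insertion_points(nest[[i]], c(path, i)))
    }
  }
  out
}

# insert `leaf` on the edge above the node addressed by `path`
insert_at <- function(nest, path, leaf) {
  if (!length(path)) return(list(nest, leaf))
  nest[[path[1L]]] <- insert_at(nest[[path[1L]]], path[-1L], leaf)
  nest
}

canonical_nest <- function(nest) {
  if (is.character(nest)) return(nest)
  kids <- lapply(nest, canonical_nest)
  keys <- vapply(kids, nest_to_newick, "")
  kids[order(keys)]
}

#' Parameters for the paired-radiation simulator
#'
#' The generative counterpart of the reconciliation event model: a model
#' (host-analogue) tree grows by a Yule process, and mimic lineages track
#' model lineages, codiverging at model speciations and occasionally
#' duplicating, switching, or dying along branches.
#'
#' @param n Target leaf count of the model tree (>= 2).
#' @param p_codiv Probability a mimic lineage codiverges at each model
#'   speciation it reaches (else it follows one daughter at random).
#' @param p_dup,p_switch,p_loss Per-lineage, per-model-branch probabilities
#'   of duplication, duplication-with-switch, and death. A switch target is
#'   drawn uniformly among model branches alive at the event time, keeping
#'   simulated histories time-consistent.
#' @param height Total height the model tree is rescaled to.
#' @return A list of class `cophylo_params`.
#' @export
cophylo_params <- function(n, p_codiv = 1, p_dup = 0, p_switch = 0,
                           p_loss = 0, height = 1) {
  stopifnot(n >= 2L)
  p <- c(p_codiv, p_dup, p_switch, p_loss)
  if (any(p < 0) || any(p > 1) || p_dup + p_switch + p_loss > 1) {
    stop("probabilities must lie in [0,1] with p_dup+p_switch+p_loss <= 1")
  }
  structure(list(n = as.integer(n), p_codiv = p_codiv, p_dup = p_dup,
                 p_switch = p_switch, p_loss = p_loss, height = height),
            class = "cophylo_params")
}

# timed Yule model tree: returns phylo with edge lengths plus per-node
# absolute times (root at 0, leaves at `height`)
sim_yule_timed <- function(n, height = 1) {
  active <- list(1L)
  t <- 0
  births <- list()  # (lineage, time, child ids)
  nxt <- 2L
  node_time <- c(`1` = 0)
  parent_of <- integer(0)
  # grow: each active lineage splits at rate 1
  kids_of <- list()
  tm <- c(0)
  names(tm) <- "1"
  while (length(active) < n) {
    t <- t + stats::rexp(1L, rate = length(active))
    who <- active[[sample.int(length(active), 1L)]]
    c1 <- nxt; c2 <- nxt + 1L; nxt <- nxt + 2L
    kids_of[[as.character(who)]] <- c(c1, c2)
    tm[as.character(c1)] <- t
    tm[as.character(c2)] <- t
    active <- c(active[vapply(active, function(a) a != who, TRUE)],
                list(c1, c2))
    parent_of[c1] <- who; parent_of[c2] <- who
  }
  t_end <- t + stats::rexp(1L, rate = length(active))
  scale <- height / t_end
  leaves <- unlist(active)
  list(kids = kids_of, start = tm * scale, leaves = leaves,
       height = height,
       end = vapply(as.character(seq_len(nxt - 1L)), function(id) {
         if (is.null(kids_of[[id]])) height
         else unname(tm[as.character(kids_of[[id]][1])]) * scale
       }, 0))
}

#' Simulate a codivergent model/mimic tree pair with an event truth-log
#'
#' @param params A [cophylo_params()] object.
#' @param seed Integer seed.
#' @param max_attempts Retries when every mimic lineage dies out.
#' @return A list with `model` and `mimic` (`phylo`), `assoc`
#'   (`assoc_map`), and `log` (data frame of events: codivergence,
#'   duplication, switch, follow_loss, death, with times).
#' @export
simulate_cophylogeny <- function(params, seed = 1L, max_attempts = 50L) {
  stopifnot(inherits(params, "cophylo_params"))
  set.seed(seed)
  for (attempt in seq_len(max_attempts)) {
    Y <- sim_yule_timed(params$n, params$height)
    res <- try_mimic_on(Y, params)
    if (!is.null(res)) {
      model <- yule_to_phylo(Y)
      mimic <- nestlen_to_phylo(res$nest, prefix = "m")
      assoc <- parse_associations(
        data.frame(mimic = mimic$tip.label,
                   model = sub("^m[0-9]+[.]", "", mimic$tip.label)),
        mimic, model)
      return(list(model = model, mimic = mimic, assoc = assoc,
                  log = res$log))
    }
  }
  stop("all mimic lineages died out in every attempt; lower p_loss")
}

# convert the simulated Yule structure to phylo (leaves L<id>)
yule_to_phylo <- function(Y) {
  build <- function(id) {
    k <- Y$kids[[as.character(id)]]
    len <- Y$end[[as.character(id)]] - unname(Y$start[as.character(id)])
    if (is.null(k)) {
      sprintf("L%d:%.10f", id, len)
    } else {
      sprintf("(%s,%s):%.10f", build(k[1]), build(k[2]), len)
    }
  }
  parse_newick(paste0(build(1L), ";"))
}

# mimic simulation over a timed model structure; returns a nested-list
# mimic tree with branch lengths, or NULL on total extinction
try_mimic_on <- function(Y, params) {
  log_env <- new.env()
  log_env$rows <- list()
  note <- function(event, time, model_lineage, detail = NA_character_) {
    log_env$rows[[length(log_env$rows) + 1L]] <-
      data.frame(event = event, time = time, model_lineage = model_lineage,
                 detail = detail, stringsAsFactors = FALSE)
  }
  leaf_counter <- new.env(); leaf_counter$i <- 0L
  alive_at <- function(time) {
    ids <- as.integer(names(Y$start))
    ids[unname(Y$start[as.character(ids)]) <= time & Y$end[ids] > time]
  }
  # follow one mimic lineage living on model lineage `id` from time t0;
  # returns list(nest=, len_start=t0) or NULL if extinct
  follow <- function(id, t0) {
    t_end <- Y$end[[as.character(id)]]
    u <- stats::runif(1)
    p <- params
    if (u < p$p_loss) {
      note("death", stats::runif(1, t0, t_end), id)
      return(NULL)
    } else if (u < p$p_loss + p$p_dup) {
      td <- stats::runif(1, t0, t_end)
      note("duplication", td, id)
      a <- follow_from(id, td); b <- follow_from(id, td)
      return(pair_or_single(a, b, td, t0))
    } else if (u < p$p_loss + p$p_dup + p$p_switch) {
      td <- stats::runif(1, t0, t_end)
      targets <- setdiff(alive_at(td), id)
      if (length(targets)) {
        tgt <- targets[sample.int(length(targets), 1L)]
        note("switch", td, id, detail = as.character(tgt))
        a <- follow_from(id, td)
        b <- follow_from(tgt, td)
        return(pair_or_single(a, b, td, t0))
      }
      # no contemporaneous target: fall through to plain survival
    }
    follow_to_end(id, t0)
  }
  # continue on lineage `id` from time t (no further branch events drawn)
  follow_from <- function(id, t) follow_to_end(id, t)
  follow_to_end <- function(id, t0) {
    t_end <- Y$end[[as.character(id)]]
    k <- Y$kids[[as.character(id)]]
    if (is.null(k)) {
      leaf_counter$i <- leaf_counter$i + 1L
      lab <- sprintf("m%d.L%d", leaf_counter$i, id)
      return(list(nest = lab, t_start = t0, t_tip = t_end))
    }
    if (stats::runif(1) < params$p_codiv) {
      note("codivergence", t_end, id)
      a <- follow(k[1], t_end)
      b <- follow(k[2], t_end)
      pair_or_single(a, b, t_end, t0)
    } else {
      side <- k[sample.int(2L, 1L)]
      note("follow_loss", t_end, id, detail = as.character(setdiff(k, side)))
      res <- follow(side, t_end)
      if (is.null(res)) return(NULL)
      res$t_start <- t0
      res
    }
  }
  pair_or_single <- function(a, b, t_div, t0) {
    if (is.null(a) && is.null(b)) return(NULL)
    if (is.null(a)) { b$t_start <- t0; return(b) }
    if (is.null(b)) { a$t_start <- t0; return(a) }
    list(nest = list(a, b), t_start = t0, t_div = t_div)
  }
  root <- follow(1L, 0)
  if (is.null(root)) return(NULL)
  log <- if (length(log_env$rows)) do.call(rbind, log_env$rows) else
    data.frame(event = character(0), time = numeric(0),
               model_lineage = integer(0), detail = character(0))
  list(nest = root, log = log)
}

# nested structure with t_start/t_div/t_tip -> phylo with branch lengths
nestlen_to_phylo <- function(node, prefix = "m") {
  if (is.character(node$nest)) {
    # a single surviving lineage: 1-leaf tree built by hand (not Newick)
    return(structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                          tip.label = node$nest, Nnode = 1L,
                          edge.length = node$t_tip - node$t_start),
                     class = "phylo"))
  }
  build <- function(nd) {
    if (is.character(nd$nest)) {
      sprintf("%s:%.10f", nd$nest, nd$t_tip - nd$t_start)
    } else {
      kids <- vapply(nd$nest, function(ch) build(ch), "")
      sprintf("(%s):%.10f", paste(kids, collapse = ","),
              nd$t_div - nd$t_start)
    }
  }
  parse_newick(paste0(build(node), ";"))
}

#' Simulate gene trees under the multispecies coalescent
#'
#' Standard neutral coalescent within each branch of a population tree:
#' with k lineages in a branch of scaled population size theta, the waiting
#' time to the next coalescence is exponential with rate k(k-1)/theta
#' (pairwise rate 2/theta). Time units are shared with the population-tree
#' branch durations; with a per-site mutation rate of 1 per time unit the
#' expected pairwise diversity in a single population equals theta.
#'
#' @param pop_tree Rooted `phylo` whose edge lengths are branch durations.
#' @param theta Scaled population size; a single value or a vector over all
#'   nodes (the value applies to the branch above the node; the root entry
#'   governs the ancestral population).
#' @param n_loci Number of independent gene trees.
#' @param alleles_per_pop Alleles sampled per population (single value or
#'   named vector by population label).
#' @param seed Integer seed.
#' @return List with `trees` (`multiPhylo`, allele leaves named
#'   `pop.index`) and `map` (data frame allele -> population).
#' @export
simulate_gene_trees <- function(pop_tree, theta, n_loci = 1L,
                                alleles_per_pop = 1L, seed = 1L) {
  validate_phylo(pop_tree)
  ntip <- ape::Ntip(pop_tree)
  nn <- ntip + pop_tree$Nnode
  if (length(theta) == 1L) theta <- rep(theta, nn)
  if (any(theta <= 0)) stop("theta must be positive")
  if (length(alleles_per_pop) == 1L) {
    alleles_per_pop <- stats::setNames(rep(alleles_per_pop, ntip),
                                       pop_tree$tip.label)
  }
  durations <- numeric(nn)
  if (!is.null(pop_tree$edge.length)) {
    durations[pop_tree$edge[, 2]] <- pop_tree$edge.length
  }
  if (any(durations < 0)) stop("branch durations must be >= 0")
  ch <- children_list(pop_tree)
  post <- postorder_nodes(pop_tree)
  set.seed(seed)
  trees <- vector("list", n_loci)
  map <- NULL
  for (locus in seq_len(n_loci)) {
    # lineage: list(nwk=, height=absolute time before present at lineage top)
    pool <- vector("list", nn)
    for (v in seq_len(ntip)) {
      pop <- pop_tree$tip.label[v]
      k <- alleles_per_pop[[pop]]
      pool[[v]] <- lapply(seq_len(k), function(i)
        list(nwk = sprintf("%s.%d", pop, i), h = 0))
    }
    depth <- node_depths(pop_tree, use_lengths = TRUE)
    age <- max(depth[seq_len(ntip)]) - depth  # time before present at node
    for (v in post) {
      lin <- if (v <= ntip) pool[[v]] else do.call(c, pool[ch[[v]]])
      t0 <- age[v]
      tmax <- if (v == root_node(pop_tree)) Inf else t0 + durations[v]
      t <- t0
      while (length(lin) > 1L) {
        k <- length(lin)
        w <- stats::rexp(1L, rate = k * (k - 1) / theta[v])
        if (t + w > tmax) break
        t <- t + w
        pick <- sample.int(k, 2L)
        a <- lin[[pick[1]]]; b <- lin[[pick[2]]]
        joined <- list(
          nwk = sprintf("(%s:%.10f,%s:%.10f)", a$nwk, t - a$h,
                        b$nwk, t - b$h),
          h = t)
        lin <- c(lin[-pick], list(joined))
      }
      pool[[v]] <- lin
    }
    root_lin <- pool[[root_node(pop_tree)]][[1L]]
    trees[[locus]] <- parse_newick(paste0(root_lin$nwk, ";"))
    if (is.null(map)) {
      labs <- trees[[locus]]$tip.label
      map <- data.frame(allele = labs,
                        pop = sub("[.][0-9]+$", "", labs),
                        stringsAsFactors = FALSE)
    }
  }
  class(trees) <- "multiPhylo"
  list(trees = trees, map = map)
}

#' Simulate a JC69 alignment along a tree
#'
#' Evolves an L-site sequence from a uniform-random root down the tree
#' under the Jukes-Cantor model: on a branch of length d (expected
#' substitutions/site at rate 1) each site changes with probability
#' (3/4)(1 - exp(-4 d rate / 3)), uniformly to one of the other bases.
#'
#' @param tree `phylo` with branch lengths.
#' @param rate Per-site rate multiplier applied to branch lengths.
#' @param L Number of sites.
#' @param seed Integer seed.
#' @param group_from_prefix Assign groups from the leaf-label prefix before
#'   the first "." (the allele naming of [simulate_gene_trees()]).
#' @return A [grouped_alignment()].
#' @export
simulate_alignment <- function(tree, rate = 1, L = 1000L, seed = 1L,
                               group_from_prefix = TRUE) {
  validate_phylo(tree)
  if (is.null(tree$edge.length)) stop("branch lengths are required")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  seqs <- matrix(NA_integer_, nn, L)
  seqs[root_node(tree), ] <- sample.int(4L, L, replace = TRUE)
  elen <- numeric(nn)
  elen[tree$edge[, 2]] <- tree$edge.length
  par <- parent_vec(tree)
  for (v in rev(postorder_nodes(tree))) {
    if (par[v] == 0L) next
    p_change <- 0.75 * (1 - exp(-4 * rate * elen[v] / 3))
    s <- seqs[par[v], ]
    hit <- stats::runif(L) < p_change
    if (any(hit)) {
      # new base uniform among the other three
      s[hit] <- ((s[hit] - 1L + sample.int(3L, sum(hit), replace = TRUE)) %% 4L) + 1L
    }
    seqs[v, ] <- s
  }
  mat <- matrix(bases[seqs[seq_len(ntip), , drop = FALSE]], ntip, L)
  rownames(mat) <- tree$tip.label
  groups <- if (group_from_prefix) {
    stats::setNames(sub("[.].*$", "", tree$tip.label), tree$tip.label)
  } else {
    stats::setNames(rep("all", ntip), tree$tip.label)
  }
  grouped_alignment(mat, groups)
}
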