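# Minimise-Deep-Coalescence scoring of a population tree against gene
# trees, and a heuristic SPR search for optimal population trees.
# Scoring is topology-only; gene-tree polytomies are treated as soft
# (simultaneous divergence), never auto-resolved.

#' Extra (deep-coalescing) gene lineages for one gene tree
#'
#' For each population-tree branch, counts the gene lineages present at
#' the branch top under the most parsimonious embedding of the gene tree,
#' and returns the total excess over one. Two gene lineages can coalesce
#' within a population branch only when the leaf set of their gene-tree
#' MRCA is drawn entirely from populations below that branch, so the
#' lineage count at the top of the branch above population node v equals
#' the number of maximal gene-tree clades whose alleles all come from v's
#' populations. Zero iff the gene tree is displayable without extra
#' lineages. Gene-tree polytomies are never auto-resolved: they count as
#' simultaneous divergences, so lineages separated by a polytomy remain
#' separate below it.
#'
#' @param gene_tree Rooted `phylo` (polytomies allowed).
#' @param pop_tree Rooted `phylo` whose leaves are populations.
#' @param map Data frame (allele, pop) or named character vector
#'   allele -> population.
#' @return Non-negative integer count of extra lineages.
#' @export
extra_lineages <- function(gene_tree, pop_tree, map) {
  validate_phylo(gene_tree); validate_phylo(pop_tree)
  map <- as_allele_map(map, gene_tree, pop_tree)
  ntipG <- ape::Ntip(gene_tree)
  tipsG <- clade_tips_list(gene_tree)
  parG <- parent_vec(gene_tree)
  nnG <- ntipG + gene_tree$Nnode
  pop_of_tip <- unname(map[gene_tree$tip.label])

  ntipS <- ape::Ntip(pop_tree)
  tipsS <- clade_tips_list(pop_tree)
  nnS <- ntipS + pop_tree$Nnode
  total <- 0L
  for (v in seq_len(nnS)) {
    if (v == root_node(pop_tree)) next  # no branch above the root
    pops <- pop_tree$tip.label[tipsS[[v]]]
    inA <- pop_of_tip %in% pops  # gene tips drawn from populations below v
    if (!any(inA)) next
    # clade_ok[u]: every allele below gene node u comes from pops below v
    clade_ok <- logical(nnG)
    for (u in seq_len(nnG)) clade_ok[u] <- all(inA[tipsG[[u]]])
    maximal <- clade_ok & (parG == 0L | !clade_ok[pmax(parG, 1L)])
    total <- total + sum(maximal) - 1L
  }
  total
}

as_allele_map <- function(map, gene_tree, pop_tree) {
  if (is.data.frame(map)) {
    map <- stats::setNames(as.character(map[[2]]), as.character(map[[1]]))
  }
  miss <- setdiff(gene_tree$tip.label, names(map))
  if (length(miss)) {
    stop("gene-tree leaves without a population: ", paste(miss, collapse = ", "))
  }
  bad <- setdiff(unname(map[gene_tree$tip.label]), pop_tree$tip.label)
  if (length(bad)) {
    stop("mapped populations absent from the population tree: ",
         paste(bad, collapse = ", "))
  }
  map
}

#' Total MDC score over a set of gene trees
#'
#' @param gene_trees List (or `multiPhylo`) of rooted gene trees.
#' @param pop_tree Candidate population tree.
#' @param map Allele -> population map covering every gene-tree leaf.
#' @return Sum of [extra_lineages()] over the gene trees.
#' @export
mdc_score <- function(gene_trees, pop_tree, map) {
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  sum(vapply(gene_trees, extra_lineages, 0L, pop_tree = pop_tree, map = map))
}

# ---- topology enumeration and SPR moves over nested-list trees -----------

#' All rooted binary topologies on a label set
#'
#' Recursive leaf insertion; (2n-3)!! topologies, so only sensible for
#' small n (guarded at n <= 8).
#'
#' @param labels Character vector of leaf labels.
#' @return List of `phylo` trees.
#' @export
all_rooted_topologies <- function(labels) {
  n <- length(labels)
  if (n > 8L) stop("refusing to enumerate > 8 leaves ((2n-3)!! trees)")
  if (n == 1L) return(list(parse_newick(paste0(labels, ";"))))
  nests <- list(list(labels[1L], labels[2L]))
  for (k in seq.int(3L, length.out = n - 2L)) {
    nxt <- list()
    for (nest in nests) {
      for (pt in insertion_points(nest)) {
        nxt[[length(nxt) + 1L]] <- insert_at(nest, pt, labels[k])
      }
    }
    nests <- nxt
  }
  lapply(nests, function(x) parse_newick(paste0(nest_to_newick(x), ";")))
}

phylo_to_nest <- function(tree) {
  ch <- children_list(tree)
  ntip <- ape::Ntip(tree)
  build <- function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    lapply(ch[[v]], build)
  }
  build(root_node(tree))
}

nest_leaves <- function(nest) {
  if (is.character(nest)) return(nest)
  unlist(lapply(nest, nest_leaves))
}

# all proper subtrees (as nests), excluding the whole tree
proper_subtrees <- function(nest) {
  out <- list()
  rec <- function(x, at_root) {
    if (!at_root) out[[length(out) + 1L]] <<- x
    if (!is.character(x)) for (k in x) rec(k, FALSE)
  }
  rec(nest, TRUE)
  out
}

# remove the (first) subtree identical to `sub`, suppressing unary nodes
prune_nest <- function(nest, key) {
  if (is.character(nest)) return(nest)
  keys <- vapply(nest, function(k) nest_to_newick(canonical_nest(k)), "")
  hit <- which(keys == key)
  if (length(hit)) {
    rest <- nest[-hit[1L]]
    if (length(rest) == 1L) return(rest[[1L]])
    return(rest)
  }
  for (i in seq_along(nest)) {
    pruned <- prune_nest(nest[[i]], key)
    if (!identical(pruned, nest[[i]])) {
      nest[[i]] <- pruned
      return(nest)
    }
  }
  nest
}

# rooted SPR neighbourhood as canonical newick strings
spr_neighbours <- function(tree) {
  nest <- phylo_to_nest(tree)
  self_key <- nest_to_newick(canonical_nest(nest))
  out <- character(0)
  for (sub in proper_subtrees(nest)) {
    key <- nest_to_newick(canonical_nest(sub))
    rest <- prune_nest(nest, key)
    if (setequal(nest_leaves(rest), nest_leaves(nest))) next  # prune failed
    for (pt in insertion_points(rest)) {
      cand <- insert_at(rest, pt, sub)
      ck <- nest_to_newick(canonical_nest(cand))
      if (ck != self_key) out <- c(out, ck)
    }
  }
  unique(out)
}

# induced population topology of a gene tree: one leaf per population
induced_pop_topology <- function(gene_tree, map, pops) {
  map <- if (is.data.frame(map))
    stats::setNames(as.character(map[[2]]), as.character(map[[1]])) else map
  keep <- gene_tree$tip.label[!duplicated(unname(map[gene_tree$tip.label]))]
  tr <- ape::keep.tip(gene_tree, keep)
  tr$tip.label <- unname(map[tr$tip.label])
  tr$edge.length <- NULL
  tr <- resolve_polytomies(tr)
  missing_pops <- setdiff(pops, tr$tip.label)
  if (length(missing_pops)) return(NULL)
  tr
}

#' Heuristic MDC population-tree search
#'
#' Hill-climbing over rooted topologies with subtree-prune-regraft (SPR)
#' moves, from several starting trees (each gene tree's induced population
#' topology plus random Yule topologies), storing up to `tie_cap` equally
#' good trees. Deterministic given the seed.
#'
#' @param gene_trees List/`multiPhylo` of rooted gene trees.
#' @param map Allele -> population map.
#' @param tie_cap Maximum number of equally good trees stored.
#' @param restarts Number of random-start replicates added to the
#'   gene-tree-derived starts.
#' @param seed Integer seed.
#' @return List of class `mdc_result`: `score` (minimal total deep
#'   coalescences), `trees` (list of optimal `phylo`, <= tie_cap),
#'   `per_gene` (extra-lineage counts of the first optimum).
#' @export
mdc_search <- function(gene_trees, map, tie_cap = 100L, restarts = 10L,
                       seed = 1L) {
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  if (!length(gene_trees)) stop("need at least one gene tree")
  mapv <- if (is.data.frame(map))
    stats::setNames(as.character(map[[2]]), as.character(map[[1]])) else map
  pops <- sort(unique(unname(mapv)))
  if (length(pops) < 3L) stop("need at least 3 populations")

  score_of <- local({
    cache <- new.env(hash = TRUE)
    function(nwk) {
      if (!is.null(cache[[nwk]])) return(cache[[nwk]])
      tr <- parse_newick(paste0(nwk, ";"))
      s <- mdc_score(gene_trees, tr, mapv)
      cache[[nwk]] <- s
      s
    }
  })

  set.seed(seed)
  starts <- list()
  for (g in gene_trees) {
    it <- induced_pop_topology(g, mapv, pops)
    if (!is.null(it)) starts[[length(starts) + 1L]] <- it
  }
  for (r in seq_len(restarts)) {
    starts[[length(starts) + 1L]] <- rtopology_yule(pops)
  }

  best_score <- Inf
  best_set <- character(0)
  for (st in starts) {
    cur <- nest_to_newick(canonical_nest(phylo_to_nest(st)))
    cur_s <- score_of(cur)
    repeat {
      nb <- spr_neighbours(parse_newick(paste0(cur, ";")))
      if (!length(nb)) break
      sc <- vapply(nb, score_of, 0L)
      if (min(sc) < cur_s) {
        pick <- nb[sc == min(sc)]
        cur <- sort(pick)[1L]  # deterministic tie-break
        cur_s <- min(sc)
      } else {
        # collect the plateau around the local optimum
        plateau <- unique(c(cur, nb[sc == cur_s]))
        if (cur_s < best_score) {
          best_score <- cur_s
          best_set <- plateau
        } else if (cur_s == best_score) {
          best_set <- unique(c(best_set, plateau))
        }
        break
      }
    }
  }
  best_set <- sort(best_set)
  if (length(best_set) > tie_cap) best_set <- best_set[seq_len(tie_cap)]
  trees <- lapply(best_set, function(nwk) parse_newick(paste0(nwk, ";")))
  per_gene <- vapply(gene_trees, extra_lineages, 0L,
                     pop_tree = trees[[1L]], map = mapv)
  structure(list(score = best_score, trees = trees, per_gene = per_gene,
                 tie_cap = tie_cap, seed = seed),
            class = "mdc_result")
}

#' @export
print.mdc_result <- function(x, ...) {
  cat("MDC search: minimal total deep coalescences =", x$score, "\n")
  cat(length(x$trees), "optimal population tree(s) stored\n")
  invisible(x)
}

#' Exhaustive minimum MDC score (reference)
#'
#' Scores every rooted topology on the population set; for independent
#' verification of the heuristic on small problems.
#'
#' @inheritParams mdc_search
#' @return List `score`, `trees` (all optima).
#' @export
mdc_exhaustive <- function(gene_trees, map) {
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  mapv <- if (is.data.frame(map))
    stats::setNames(as.character(map[[2]]), as.character(map[[1]])) else map
  pops <- sort(unique(unname(mapv)))
  trees <- all_rooted_topologies(pops)
  sc <- vapply(trees, function(tr) mdc_score(gene_trees, tr, mapv), 0L)
  list(score = min(sc), trees = trees[sc == min(sc)])
}
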