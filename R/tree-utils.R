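# Internal traversal helpers shared by the reconciliation, congruence and
# MDC code. ape convention: tips are 1..n, the root is n+1, internal nodes
# follow. All trees here are rooted.

# list of children for every node (integer vectors, empty for tips)
children_list <- function(tree) {
  nnode <- ape::Ntip(tree) + tree$Nnode
  out <- vector("list", nnode)
  for (i in seq_len(nnode)) out[[i]] <- integer(0)
  e <- tree$edge
  for (k in seq_len(nrow(e))) out[[e[k, 1]]] <- c(out[[e[k, 1]]], e[k, 2])
  out
}

# parent of every node (0 for the root)
parent_vec <- function(tree) {
  nnode <- ape::Ntip(tree) + tree$Nnode
  p <- integer(nnode)
  p[tree$edge[, 2]] <- tree$edge[, 1]
  p
}

root_node <- function(tree) ape::Ntip(tree) + 1L

# nodes in postorder (children before parents)
postorder_nodes <- function(tree) {
  ch <- children_list(tree)
  out <- integer(0)
  stack <- root_node(tree)
  seen <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    seen <- c(seen, v)
    stack <- c(stack, ch[[v]])
  }
  rev(seen)
}

# tip indices under each node, as a list over all nodes
clade_tips_list <- function(tree) {
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  ch <- children_list(tree)
  out <- vector("list", nnode)
  for (v in postorder_nodes(tree)) {
    out[[v]] <- if (v <= ntip) v else sort(unlist(out[ch[[v]]]))
  }
  out
}

# distance (sum of branch lengths, or edge count) from root to every node
node_depths <- function(tree, use_lengths = TRUE) {
  nnode <- ape::Ntip(tree) + tree$Nnode
  d <- numeric(nnode)
  e <- tree$edge
  len <- if (use_lengths) tree$edge.length else rep(1, nrow(e))
  ord <- rev(postorder_nodes(tree))  # preorder
  par <- parent_vec(tree)
  elen <- numeric(nnode)
  elen[e[, 2]] <- len
  for (v in ord) if (par[v] > 0L) d[v] <- d[par[v]] + elen[v]
  d
}

#' Most recent common ancestor of a set of leaves
#'
#' @param tree A rooted `phylo`.
#' @param leaves Character vector of leaf labels (non-empty). The MRCA of a
#'   single leaf is that leaf itself.
#' @return The ape node index of the MRCA.
#' @export
mrca_node <- function(tree, leaves) {
  validate_phylo(tree)
  if (!length(leaves)) stop("'leaves' must be non-empty")
  idx <- match(leaves, tree$tip.label)
  if (anyNA(idx)) {
    stop("unknown leaf label(s): ", paste(leaves[is.na(idx)], collapse = ", "))
  }
  idx <- unique(idx)
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(tree, idx)
}

#' Pairwise leaf distances
#'
#' Patristic distances sum branch lengths along the leaf-to-leaf path;
#' nodal distances count edges. Nodal mode is the natural default when
#' branch lengths are missing (topology-only trees).
#'
#' @param tree A rooted `phylo`.
#' @param mode `"patristic"` or `"nodal"`.
#' @return A symmetric matrix with zero diagonal, leaf labels as dimnames.
#' @export
leaf_distances <- function(tree, mode = c("patristic", "nodal")) {
  validate_phylo(tree)
  mode <- match.arg(mode)
  if (mode == "patristic") {
    if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
      stop("patristic distances need branch lengths on every edge; ",
           "use mode = \"nodal\" for topology-only trees")
    }
  } else {
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  d <- stats::cophenetic(tree)
  # fix ordering to tip.label order for reproducibility
  d[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Collapse monophyletic groups to single leaves
#'
#' Each maximal clade whose leaves all belong to one group is replaced by a
#' single leaf named after the group; when a group yields several collapsed
#' clades (i.e. it is not monophyletic) the leaves are suffixed `.1`, `.2`,
#' ... in the order the clades appear in the tree. This mirrors the
#' practice of collapsing clades of a single wing-pattern morph to one leaf
#' to avoid pseudo-replicating mimicry associations.
#'
#' @param tree A rooted `phylo`.
#' @param grouping Named character vector or 2-column data frame mapping
#'   every leaf label to a group label.
#' @return A `phylo` whose leaves are (possibly suffixed) group labels.
#' @export
collapse_monophyletic_groups <- function(tree, grouping) {
  validate_phylo(tree)
  if (is.data.frame(grouping)) {
    grouping <- stats::setNames(as.character(grouping[[2]]),
                                as.character(grouping[[1]]))
  }
  miss <- setdiff(tree$tip.label, names(grouping))
  if (length(miss)) stop("leaves without a group: ", paste(miss, collapse = ", "))
  ntip <- ape::Ntip(tree)
  grp_of_tip <- unname(grouping[tree$tip.label])

  ch <- children_list(tree)
  nnode <- ntip + tree$Nnode
  node_grp <- rep(NA_character_, nnode)  # group if clade is pure, else NA
  for (v in postorder_nodes(tree)) {
    if (v <= ntip) {
      node_grp[v] <- grp_of_tip[v]
    } else {
      gs <- unique(node_grp[ch[[v]]])
      if (length(gs) == 1L && !is.na(gs)) node_grp[v] <- gs
    }
  }
  par <- parent_vec(tree)
  # maximal pure nodes: pure, and parent impure (or node is root)
  maximal <- which(!is.na(node_grp) &
                     (par == 0L | is.na(node_grp[ifelse(par == 0L, 1L, par)])))
  # order by appearance in the tree drawing (preorder position)
  pre <- rev(postorder_nodes(tree))
  maximal <- maximal[order(match(maximal, pre))]

  tips_of <- clade_tips_list(tree)
  keep_tip <- integer(length(maximal))
  new_lab <- character(length(maximal))
  grp_count <- table(node_grp[maximal])
  seen <- stats::setNames(integer(length(grp_count)), names(grp_count))
  for (i in seq_along(maximal)) {
    v <- maximal[i]
    g <- node_grp[v]
    keep_tip[i] <- tips_of[[v]][1L]
    if (grp_count[[g]] > 1L) {
      seen[g] <- seen[g] + 1L
      new_lab[i] <- paste0(g, ".", seen[g])
    } else {
      new_lab[i] <- g
    }
  }
  drop <- setdiff(seq_len(ntip), keep_tip)
  out <- if (length(drop)) ape::drop.tip(tree, drop, collapse.singles = TRUE) else tree
  out$tip.label[match(tree$tip.label[keep_tip], out$tip.label)] <- new_lab
  validate_phylo(out)
  out
}

#' Convert substitution branch lengths to time
#'
#' Divides every branch length (substitutions/site) by a clock rate
#' (substitutions/site/My), giving branch durations in My, and attaches
#' node ages in Mya under the convention that the deepest leaf sits at age
#' 0 and ages increase rootward.
#'
#' @param tree A `phylo` with branch lengths in substitutions/site.
#' @param rate Substitution rate in substitutions/site/My; must be > 0.
#'   The default is a fossil-calibrated butterfly molecular-clock rate.
#' @return `tree` with branch lengths in My and a `node_ages` attribute
#'   (numeric vector over all nodes, in Mya).
#' @export
lengths_to_time <- function(tree, rate = 0.01909) {
  validate_phylo(tree)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    stop("clock rate must be a single positive number")
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("branch lengths are required to convert to time")
  }
  tree$edge.length <- tree$edge.length / rate
  depth <- node_depths(tree, use_lengths = TRUE)
  ages <- max(depth[seq_len(ape::Ntip(tree))]) - depth
  attr(tree, "node_ages") <- ages
  tree
}

#' Resolve polytomies arbitrarily
#'
#' The reconciliation dynamic programme requires fully resolved trees; this
#' pre-resolver expands polytomies into an arbitrary (deterministic) binary
#' resolution with zero-length inserted branches and flags the result.
#'
#' @param tree A rooted `phylo`.
#' @return A binary `phylo`; attribute `resolved_polytomies` is `TRUE` when
#'   anything was expanded.
#' @export
resolve_polytomies <- function(tree) {
  validate_phylo(tree)
  had <- has_polytomies(tree)
  out <- ape::multi2di(tree, random = FALSE)
  attr(out, "resolved_polytomies") <- had
  out
}
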