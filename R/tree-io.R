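#' Parse a rooted phylogeny from a Newick string
#'
#' Reads a Newick-formatted tree and validates it as a rooted phylogeny:
#' exactly one root, pairwise-distinct non-empty leaf labels, non-negative
#' branch lengths. Polytomies are permitted and flagged (see
#' [has_polytomies()]); unrooted input is rejected rather than auto-rooted,
#' since every downstream analysis here assumes a rooted tree.
#'
#' @param text A Newick string ending in `";"`, or a path to a file whose
#'   first tree is read.
#' @return An object of class `phylo` (see \pkg{ape}).
#' @examples
#' tr <- parse_newick("((A:0.1,B:0.2):0.05,C:0.3);")
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl(";", text, fixed = TRUE) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  }
  txt <- trimws(text)
  if (!endsWith(txt, ";")) {
    stop("Newick string must end in ';' (got: ", substr(txt, max(1L, nchar(txt) - 20L), nchar(txt)), ")")
  }
  opens <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  closes <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (opens != closes) {
    stop("Malformed Newick: ", opens, " '(' but ", closes, " ')'")
  }
  tr <- tryCatch(
    ape::read.tree(text = txt),
    error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(tr)) stop("Newick parse error: unreadable tree string")
  validate_phylo(tr)
  tr
}

#' Serialise a phylogeny to Newick
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @param digits Number of digits for branch lengths.
#' @return The Newick string (invisibly when writing to file).
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  validate_phylo(tree)
  s <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Validate the rooted-phylogeny invariants
#'
#' Errors unless `tree` is a rooted `phylo` with unique non-empty leaf
#' labels and non-negative branch lengths (when present).
#'
#' @param tree A `phylo` object.
#' @return `tree`, invisibly.
#' @export
validate_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (is.null(tree$tip.label) || any(!nzchar(tree$tip.label))) {
    stop("leaf labels must be non-empty strings")
  }
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) stop("duplicate leaf labels: ", paste(dup, collapse = ", "))
  if (ape::Ntip(tree) >= 2L && !ape::is.rooted(tree)) {
    stop("tree is unrooted; analyses here require rooted trees (root it explicitly)")
  }
  if (!is.null(tree$edge.length)) {
    neg <- tree$edge.length < 0
    if (any(neg)) {
      stop("negative branch length(s) on edge(s): ",
           paste(which(neg), collapse = ", "))
    }
  }
  invisible(tree)
}

#' Does the tree contain polytomies?
#'
#' @param tree A `phylo` object.
#' @return `TRUE` if any internal node has more than two children.
#' @export
has_polytomies <- function(tree) {
  tab <- tabulate(tree$edge[, 1])
  any(tab > 2L)
}

#' Read trees from a NEXUS TREES block
#'
#' Convenience wrapper over [ape::read.nexus()]; every tree is validated.
#'
#' @param file Path to a NEXUS file containing a TREES block.
#' @return A `phylo` or `multiPhylo` object.
#' @export
read_nexus_trees <- function(file) {
  trs <- ape::read.nexus(file)
  if (inherits(trs, "phylo")) {
    validate_phylo(trs)
  } else {
    lapply(trs, validate_phylo)
  }
  trs
}

#' Build a mimic-to-model leaf association map
#'
#' Associations define the tanglegram: each row links one mimic leaf to the
#' model leaf it resembles. Many-to-many associations are allowed; duplicate
#' rows are dropped. Every mimic leaf must appear in at least one pair.
#'
#' @param x A two-column data frame (or matrix) of `(mimic_label,
#'   model_label)` pairs, or the path to a two-column TSV (header optional;
#'   a header is detected when the first row's labels are absent from both
#'   trees but later rows validate).
#' @param mimic,model Rooted `phylo` trees carrying the referenced leaves.
#' @param direction Free-text tag recording which tree plays "model"
#'   (the analyses can be re-run with roles reversed).
#' @param require_all_mimic If `TRUE` (default) every mimic leaf must be
#'   associated; model leaves may be unmatched.
#' @return A data frame of class `assoc_map` with columns `mimic`, `model`.
#' @export
parse_associations <- function(x, mimic, model,
                               direction = "mimic->model",
                               require_all_mimic = TRUE) {
  validate_phylo(mimic)
  validate_phylo(model)
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    x <- utils::read.table(x, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
    # drop a header row if its entries match no leaves
    if (nrow(x) > 1L &&
        !(x[1, 1] %in% mimic$tip.label) && !(x[1, 2] %in% model$tip.label)) {
      x <- x[-1L, , drop = FALSE]
    }
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (ncol(x) < 2L) stop("association table needs two columns (mimic, model)")
  df <- data.frame(mimic = as.character(x[[1]]),
                   model = as.character(x[[2]]),
                   stringsAsFactors = FALSE)
  df <- unique(df)
  bad_m <- setdiff(df$mimic, mimic$tip.label)
  bad_M <- setdiff(df$model, model$tip.label)
  if (length(bad_m) || length(bad_M)) {
    stop("association labels missing from trees: ",
         if (length(bad_m)) paste0("mimic [", paste(bad_m, collapse = ", "), "] "),
         if (length(bad_M)) paste0("model [", paste(bad_M, collapse = ", "), "]"))
  }
  if (require_all_mimic) {
    orphan <- setdiff(mimic$tip.label, df$mimic)
    if (length(orphan)) {
      stop("mimic leaves without any association: ",
           paste(orphan, collapse = ", "))
    }
  }
  rownames(df) <- NULL
  class(df) <- c("assoc_map", "data.frame")
  attr(df, "direction") <- direction
  df
}

#' Reverse the roles in an association map
#'
#' Swaps the mimic and model columns, reproducing the reversed-roles
#' analysis in which the former model tree is treated as the mimic.
#'
#' @param assoc An `assoc_map`.
#' @return An `assoc_map` with columns swapped and the direction tag flipped.
#' @export
reverse_associations <- function(assoc) {
  stopifnot(inherits(assoc, "assoc_map"))
  out <- data.frame(mimic = assoc$model, model = assoc$mimic,
                    stringsAsFactors = FALSE)
  out <- unique(out)
  class(out) <- c("assoc_map", "data.frame")
  attr(out, "direction") <- paste0("reversed(", attr(assoc, "direction"), ")")
  out
}

#' Opt-in leaf-label normalisation
#'
#' Leaf matching is exact and case-sensitive by default. This helper trims
#' whitespace and maps spaces to underscores so that labels from different
#' sources can be matched deliberately.
#'
#' @param x Character vector of labels, or a `phylo` whose tip labels are
#'   normalised.
#' @return Object of the same type with normalised labels.
#' @export
normalize_labels <- function(x) {
  norm <- function(s) gsub("[ ]+", "_", trimws(s))
  if (inherits(x, "phylo")) {
    x$tip.label <- norm(x$tip.label)
    return(x)
  }
  norm(x)
}

#' Attach 95% node-age credibility intervals
#'
#' Ages are in Mya, with leaves at age 0 and ages increasing rootward.
#' Intervals are supplied as a three-column table (node label, low, high);
#' labels refer to leaf labels or internal-node labels of the tree.
#'
#' @param tree A `phylo` object.
#' @param intervals Data frame or TSV path with columns label, low, high.
#' @return `tree` with an `age_intervals` attribute: a matrix with rows
#'   `low`, `high` and one column per node (NA where unknown).
#' @export
attach_age_intervals <- function(tree, intervals) {
  validate_phylo(tree)
  if (is.character(intervals) && length(intervals) == 1L && file.exists(intervals)) {
    intervals <- utils::read.table(intervals, sep = "\t", header = FALSE,
                                   stringsAsFactors = FALSE)
  }
  intervals <- as.data.frame(intervals)
  if (ncol(intervals) < 3L) stop("need columns: node label, low, high")
  lab <- as.character(intervals[[1]])
  lo <- as.numeric(intervals[[2]])
  hi <- as.numeric(intervals[[3]])
  if (any(!is.finite(lo) | !is.finite(hi)) || any(lo < 0) || any(lo > hi)) {
    stop("age intervals must satisfy 0 <= low <= high")
  }
  nnode <- ape::Ntip(tree) + tree$Nnode
  m <- matrix(NA_real_, nrow = 2L, ncol = nnode,
              dimnames = list(c("low", "high"), NULL))
  all_labs <- c(tree$tip.label,
                if (!is.null(tree$node.label)) tree$node.label else
                  rep(NA_character_, tree$Nnode))
  idx <- match(lab, all_labs)
  if (anyNA(idx)) {
    stop("interval labels not found in tree: ",
         paste(lab[is.na(idx)], collapse = ", "))
  }
  m["low", idx] <- lo
  m["high", idx] <- hi
  attr(tree, "age_intervals") <- m
  tree
}
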