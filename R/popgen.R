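# Alignment-based statistics: segregating sites, Watterson's theta,
# pairwise nucleotide diversity, and between-group uncorrected divergence.
# Conventions: ambiguity codes and gaps are treated as missing; the
# within-group segregating-site count uses complete deletion (a stable
# effective length for Watterson's formula) while pairwise statistics use
# pairwise deletion.

VALID_BASES <- c("A", "C", "G", "T")

#' Grouped multiple-sequence alignment
#'
#' Equal-length sequences with a group label per sequence (species,
#' country, morph, region, ...) and an optional locus partition.
#'
#' @param x Either a character matrix (rows = sequences, one residue per
#'   cell, rownames = labels) or a named character vector of equal-length
#'   sequence strings.
#' @param groups Named character vector (or 2-column data frame) mapping
#'   every sequence label to a group.
#' @param partition Optional list of `c(start, end)` 1-based inclusive
#'   column spans, disjoint, naming loci.
#' @return An object of class `grouped_alignment` with elements `mat`,
#'   `groups`, `partition`.
#' @export
grouped_alignment <- function(x, groups, partition = NULL) {
  if (!is.matrix(x)) {
    labs <- names(x)
    if (is.null(labs)) stop("sequences must be named")
    lens <- nchar(x)
    if (length(unique(lens)) != 1L) {
      stop("sequences must have equal length (got lengths ",
           paste(unique(lens), collapse = ", "), ")")
    }
    x <- do.call(rbind, strsplit(unname(x), ""))
    rownames(x) <- labs
  }
  if (is.null(rownames(x))) stop("alignment rows must be labelled")
  if (anyDuplicated(rownames(x))) stop("duplicate sequence labels")
  x[] <- toupper(x)
  if (is.data.frame(groups)) {
    groups <- stats::setNames(as.character(groups[[2]]),
                              as.character(groups[[1]]))
  }
  miss <- setdiff(rownames(x), names(groups))
  if (length(miss)) {
    stop("sequences without a group label: ", paste(miss, collapse = ", "))
  }
  groups <- groups[rownames(x)]
  if (!is.null(partition)) {
    sp <- do.call(rbind, partition)
    if (any(sp[, 1] > sp[, 2]) || any(sp < 1) || any(sp > ncol(x))) {
      stop("partition spans must lie within the alignment")
    }
    cols <- unlist(apply(sp, 1, function(r) r[1]:r[2], simplify = FALSE))
    if (anyDuplicated(cols)) stop("partition spans must be disjoint")
  }
  structure(list(mat = x, groups = groups, partition = partition),
            class = "grouped_alignment")
}

#' @export
print.grouped_alignment <- function(x, ...) {
  cat("grouped_alignment:", nrow(x$mat), "sequences x", ncol(x$mat),
      "columns;", length(unique(x$groups)), "groups\n")
  invisible(x)
}

#' Read a FASTA alignment into a grouped_alignment
#'
#' @param file FASTA path.
#' @param groups Group mapping as in [grouped_alignment()]; defaults to a
#'   single group `"all"`.
#' @return A `grouped_alignment`.
#' @export
read_alignment_fasta <- function(file, groups = NULL) {
  dna <- ape::read.FASTA(file)
  mat <- toupper(as.character(as.matrix(dna)))
  if (is.null(groups)) {
    groups <- stats::setNames(rep("all", nrow(mat)), rownames(mat))
  }
  grouped_alignment(mat, groups)
}

#' Read a NEXUS DATA/CHARACTERS block into a grouped_alignment
#'
#' @inheritParams read_alignment_fasta
#' @return A `grouped_alignment`.
#' @export
read_alignment_nexus <- function(file, groups = NULL) {
  lst <- ape::read.nexus.data(file)
  seqs <- vapply(lst, function(s) paste(toupper(s), collapse = ""), "")
  if (is.null(groups)) {
    groups <- stats::setNames(rep("all", length(seqs)), names(seqs))
  }
  grouped_alignment(seqs, groups)
}

#' Read a 2-column (label, group) TSV
#'
#' @param file TSV path, header optional (detected when the first row
#'   repeats the column words "label"/"group").
#' @return Named character vector label -> group.
#' @export
read_groups_tsv <- function(file) {
  x <- utils::read.table(file, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, comment.char = "#")
  if (tolower(x[1, 1]) %in% c("label", "sequence", "id") ||
      tolower(x[1, 2]) == "group") {
    x <- x[-1L, , drop = FALSE]
  }
  stats::setNames(as.character(x[[2]]), as.character(x[[1]]))
}

group_rows <- function(aln, group) {
  idx <- which(aln$groups %in% group)
  if (!length(idx)) stop("no sequences in group: ", paste(group, collapse = ","))
  idx
}

#' Segregating sites under complete deletion within a group
#'
#' Columns containing any gap or ambiguity code within the group are
#' excluded entirely, giving the effective length `L_eff`; `S` counts the
#' retained columns with two or more distinct bases.
#'
#' @param aln A `grouped_alignment`.
#' @param group Group label (or vector of labels pooled together).
#' @return Named vector `c(S = , L_eff = )`.
#' @export
segregating_sites <- function(aln, group) {
  idx <- group_rows(aln, group)
  if (length(idx) < 2L) stop("group needs >= 2 sequences")
  m <- aln$mat[idx, , drop = FALSE]
  ok <- colSums(matrix(m %in% VALID_BASES, nrow(m), ncol(m))) == nrow(m)
  L_eff <- sum(ok)
  S <- 0L
  if (L_eff) {
    mm <- m[, ok, drop = FALSE]
    S <- sum(apply(mm, 2, function(col) length(unique(col)) > 1L))
  }
  c(S = S, L_eff = L_eff)
}

#' Watterson's theta per base pair
#'
#' `theta_W = S / (a_{n-1} L_eff)` with `a_{n-1} = sum_{i=1}^{n-1} 1/i`,
#' the segregating-sites estimator of `theta = 4 Ne mu` scaled per site.
#'
#' @inheritParams segregating_sites
#' @return theta_W per base pair.
#' @export
watterson_theta <- function(aln, group) {
  idx <- group_rows(aln, group)
  n <- length(idx)
  if (n < 2L) stop("group needs >= 2 sequences")
  s <- segregating_sites(aln, group)
  a <- sum(1 / seq_len(n - 1L))
  if (s[["L_eff"]] == 0L) return(0)
  unname(s[["S"]] / (a * s[["L_eff"]]))
}

# per-site uncorrected p-distance between two residue vectors, pairwise
# deletion (only columns where both are unambiguous bases)
p_distance <- function(a, b) {
  ok <- a %in% VALID_BASES & b %in% VALID_BASES
  if (!any(ok)) return(NA_real_)
  mean(a[ok] != b[ok])
}

#' Pairwise nucleotide diversity (pi) per base pair
#'
#' Mean over all within-group sequence pairs of the per-site mismatch
#' proportion, with pairwise deletion of gaps/ambiguities.
#'
#' @inheritParams segregating_sites
#' @return pi per base pair.
#' @export
pairwise_diversity <- function(aln, group) {
  idx <- group_rows(aln, group)
  if (length(idx) < 2L) stop("group needs >= 2 sequences")
  m <- aln$mat[idx, , drop = FALSE]
  pr <- utils::combn(nrow(m), 2L)
  mean(vapply(seq_len(ncol(pr)), function(k)
    p_distance(m[pr[1, k], ], m[pr[2, k], ]), 0), na.rm = TRUE)
}

#' Average uncorrected between-group divergence per base pair
#'
#' Mean over all cross-group pairs of the per-site uncorrected p-distance
#' (pairwise deletion).
#'
#' @param aln A `grouped_alignment`.
#' @param groupA,groupB Group labels; both must be non-empty.
#' @return d per base pair.
#' @export
between_group_divergence <- function(aln, groupA, groupB) {
  ia <- group_rows(aln, groupA)
  ib <- group_rows(aln, groupB)
  vals <- numeric(0)
  for (i in ia) for (j in ib) {
    vals <- c(vals, p_distance(aln$mat[i, ], aln$mat[j, ]))
  }
  mean(vals, na.rm = TRUE)
}

#' Full population-genetic summary for one group
#'
#' @inheritParams segregating_sites
#' @param per_locus When the alignment carries a locus partition, also
#'   compute each statistic per locus and report the across-locus mean.
#' @return A list of class `popgen_stats`: n, L_eff, S, a (harmonic sum),
#'   theta_w_per_bp, pi_per_bp, plus the deletion conventions used.
#' @export
popgen_stats <- function(aln, group, per_locus = FALSE) {
  idx <- group_rows(aln, group)
  n <- length(idx)
  s <- segregating_sites(aln, group)
  a <- sum(1 / seq_len(n - 1L))
  out <- list(
    group = paste(group, collapse = "+"),
    n = n,
    S = unname(s[["S"]]),
    L_eff = unname(s[["L_eff"]]),
    a = a,
    theta_w_per_bp = watterson_theta(aln, group),
    pi_per_bp = pairwise_diversity(aln, group),
    S_deletion = "complete (within group)",
    pairwise_deletion = TRUE
  )
  if (per_locus && !is.null(aln$partition)) {
    per <- lapply(aln$partition, function(span) {
      sub <- aln
      sub$mat <- aln$mat[, span[1]:span[2], drop = FALSE]
      c(theta = watterson_theta(sub, group),
        pi = pairwise_diversity(sub, group))
    })
    out$per_locus <- do.call(rbind, per)
    out$theta_w_locus_mean <- mean(out$per_locus[, "theta"])
    out$pi_locus_mean <- mean(out$per_locus[, "pi"])
  }
  class(out) <- "popgen_stats"
  out
}

#' @export
print.popgen_stats <- function(x, ...) {
  cat(sprintf(
    "popgen [%s]: n=%d, S=%d, L_eff=%d, theta_W=%.4f/bp, pi=%.4f/bp\n",
    x$group, x$n, x$S, x$L_eff, x$theta_w_per_bp, x$pi_per_bp))
  invisible(x)
}
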