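#' Event cost regime for cophylogeny mapping
#'
#' Costs for the four recoverable historical events. The defaults follow
#' the standard regime for event-based cophylogeny mapping: codivergence is
#' free, duplication and model switch cost one each, and a loss costs two.
#' A switch node is a duplication one of whose daughter lineages colonises
#' a non-ancestral model lineage; it is charged
#' `duplication + switch` and counted in both tallies.
#'
#' @param codivergence,duplication,switch,loss Non-negative event costs.
#' @return A named numeric vector of class `event_costs`.
#' @export
event_costs <- function(codivergence = 0, duplication = 1, switch = 1, loss = 2) {
  x <- c(codivergence = codivergence, duplication = duplication,
         switch = switch, loss = loss)
  if (any(!is.finite(x)) || any(x < 0)) stop("event costs must be non-negative")
  class(x) <- "event_costs"
  x
}

# ---- internal geometry tables for one model tree --------------------------

# Precompute, for a rooted model tree:
#   ch: children list; par: parent vector; post: postorder; ntip;
#   insub[x, y]: y lies in the subtree rooted at x (including x);
#   lossn[x, y]: number of internal model nodes passed, without a mimic
#     divergence, by a lineage entering at x and holding its next event at
#     y (counts internal nodes on the x..y path excluding y);
#   allowed[h, ]: legal switch targets from h (everything except h and its
#     strict ancestors).
model_tables <- function(tree) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  ch <- children_list(tree)
  par <- parent_vec(tree)
  post <- postorder_nodes(tree)
  isint <- lengths(ch) > 0L
  # cntInt[v]: internal nodes on the root..v path inclusive
  cntInt <- integer(nn)
  for (v in rev(post)) {
    cntInt[v] <- (if (par[v] > 0L) cntInt[par[v]] else 0L) + as.integer(isint[v])
  }
  insub <- matrix(FALSE, nn, nn)
  tips_of <- vector("list", nn)
  for (v in post) {
    below <- v
    if (isint[v]) below <- c(v, unlist(lapply(ch[[v]], function(c2) which(insub[c2, ]))))
    insub[v, below] <- TRUE
  }
  lossn <- matrix(NA_integer_, nn, nn)
  for (x in seq_len(nn)) {
    ys <- which(insub[x, ])
    lossn[x, ys] <- cntInt[ys] - cntInt[x] + as.integer(isint[x]) -
      as.integer(isint[ys])
  }
  allowed <- matrix(TRUE, nn, nn)
  for (h in seq_len(nn)) {
    a <- h
    anc <- integer(0)
    while (par[a] > 0L) { anc <- c(anc, par[a]); a <- par[a] }
    allowed[h, c(h, anc)] <- FALSE
  }
  list(ntip = ntip, nn = nn, ch = ch, par = par, post = post,
       isint = isint, insub = insub, lossn = lossn, allowed = allowed)
}

# association as a list: for each mimic tip index, integer vector of
# permissible model tip indices
assoc_index <- function(assoc, mimic, model) {
  mi <- match(assoc$mimic, mimic$tip.label)
  Mi <- match(assoc$model, model$tip.label)
  out <- vector("list", ape::Ntip(mimic))
  for (k in seq_along(mi)) out[[mi[k]]] <- c(out[[mi[k]]], Mi[k])
  lapply(out, unique)
}

BIGC <- 1e15

# Full dynamic programme in R. Returns the cost matrix C[p, h] plus the
# tables needed for backtracking. C[p, h] is the minimum cost of embedding
# the mimic subtree rooted at p with p's event placed exactly at model
# position h.
reconcile_dp <- function(mimic, model, assoc_idx, costs, tabM = NULL) {
  ntipP <- ape::Ntip(mimic)
  nnP <- ntipP + mimic$Nnode
  chP <- children_list(mimic)
  if (any(lengths(chP) > 2L)) {
    stop("the reconciliation DP requires fully resolved (binary) trees; ",
         "see resolve_polytomies()")
  }
  if (is.null(tabM)) tabM <- model_tables(model)
  cc <- costs[["codivergence"]]; cd <- costs[["duplication"]]
  cs <- costs[["switch"]]; cl <- costs[["loss"]]
  nnM <- tabM$nn
  C <- matrix(BIGC, nnP, nnM)
  # entry table B[p, x]: best cost of a lineage entering the model at x
  # (event at x, or descend with one loss per internal node passed)
  B <- matrix(BIGC, nnP, nnM)
  entry_of <- function(crow) {
    b <- rep(BIGC, nnM)
    for (x in tabM$post) {
      b[x] <- if (tabM$isint[x]) {
        min(crow[x], cl + min(b[tabM$ch[[x]]]))
      } else crow[x]
    }
    b
  }
  for (p in postorder_nodes(mimic)) {
    if (p <= ntipP) {
      C[p, assoc_idx[[p]]] <- 0
    } else {
      k1 <- chP[[p]][1L]; k2 <- chP[[p]][2L]
      b1 <- B[k1, ]; b2 <- B[k2, ]
      c1 <- C[k1, ]; c2 <- C[k2, ]
      for (h in seq_len(nnM)) {
        best <- BIGC
        if (tabM$isint[h]) {
          hl <- tabM$ch[[h]][1L]; hr <- tabM$ch[[h]][2L]
          best <- min(best, cc + b1[hl] + b2[hr], cc + b1[hr] + b2[hl])
        }
        best <- min(best, cd + b1[h] + b2[h])
        ok <- tabM$allowed[h, ]
        if (any(ok)) {
          best <- min(best,
                      cd + cs + b1[h] + min(c2[ok]),
                      cd + cs + b2[h] + min(c1[ok]))
        }
        C[p, h] <- best
      }
    }
    B[p, ] <- entry_of(C[p, ])
  }
  list(C = C, B = B, tabM = tabM, chP = chP, ntipP = ntipP, nnP = nnP,
       costs = costs, assoc_idx = assoc_idx)
}

# ---- solution backtracking ------------------------------------------------

# Enumerate co-optimal solutions from a finished DP, deterministically
# ordered, truncated to `cap`. A solution is a list of per-mimic-node
# records plus loss bookkeeping.
enum_solutions <- function(dp, cap = 100L) {
  eps <- 1e-9
  cl <- dp$costs[["loss"]]
  tabM <- dp$tabM

  # entry options: lineage of mimic node p entering model at x
  entry_opts <- function(p, x) {
    hs <- which(tabM$insub[x, ])
    val <- dp$C[p, hs] + cl * tabM$lossn[x, hs]
    best <- min(val)
    hs <- hs[val <= best + eps]
    lapply(sort(hs), function(h) list(h = h, nloss = tabM$lossn[x, h]))
  }

  combine <- function(lists) {
    # cross product of children solution lists, truncated
    out <- list(list())
    for (l in lists) {
      nxt <- list()
      for (a in out) {
        for (b in l) {
          nxt[[length(nxt) + 1L]] <- c(a, list(b))
          if (length(nxt) >= cap * 4L) break
        }
        if (length(nxt) >= cap * 4L) break
      }
      out <- nxt
    }
    out
  }

  sols_at <- function(p, h) {
    if (p <= dp$ntipP) {
      return(list(list(rows = list(list(node = p, pos = h, event = "leaf",
                                        target = NA_integer_)),
                       nloss = 0L)))
    }
    k1 <- dp$chP[[p]][1L]; k2 <- dp$chP[[p]][2L]
    target <- dp$C[p, h]
    opts <- list()
    cc <- dp$costs[["codivergence"]]; cd <- dp$costs[["duplication"]]
    cs <- dp$costs[["switch"]]
    if (tabM$isint[h]) {
      hl <- tabM$ch[[h]][1L]; hr <- tabM$ch[[h]][2L]
      for (ord in list(c(k1, hl, k2, hr), c(k1, hr, k2, hl))) {
        if (cc + dp$B[ord[1], ord[2]] + dp$B[ord[3], ord[4]] <= target + eps) {
          opts[[length(opts) + 1L]] <- list(event = "codivergence",
                                            kind = "entry2", spec = ord)
        }
      }
    }
    if (cd + dp$B[k1, h] + dp$B[k2, h] <= target + eps) {
      opts[[length(opts) + 1L]] <- list(event = "duplication", kind = "entry2",
                                        spec = c(k1, h, k2, h))
    }
    ok <- which(tabM$allowed[h, ])
    for (sw in list(c(k1, k2), c(k2, k1))) {
      stay <- sw[1]; mv <- sw[2]
      base <- cd + cs + dp$B[stay, h]
      tgt <- ok[dp$C[mv, ok] + base <= target + eps]
      for (t in sort(tgt)) {
        opts[[length(opts) + 1L]] <- list(event = "switch", kind = "switch",
                                          spec = c(stay, h, mv, t))
      }
    }
    res <- list()
    for (op in opts) {
      s <- op$spec
      if (op$kind == "entry2") {
        e1 <- entry_opts(s[1], s[2]); e2 <- entry_opts(s[3], s[4])
        for (a in e1) for (b in e2) {
          sub1 <- sols_at(s[1], a$h); sub2 <- sols_at(s[3], b$h)
          for (x1 in sub1) for (x2 in sub2) {
            rows <- c(list(list(node = p, pos = h, event = op$event,
                                target = NA_integer_)),
                      x1$rows, x2$rows)
            res[[length(res) + 1L]] <-
              list(rows = rows, nloss = a$nloss + b$nloss + x1$nloss + x2$nloss)
            if (length(res) >= cap * 4L) return(res)
          }
        }
      } else {  # switch: stay child enters at h, mover's event exactly at t
        e1 <- entry_opts(s[1], s[2])
        for (a in e1) {
          sub1 <- sols_at(s[1], a$h); sub2 <- sols_at(s[3], s[4])
          for (x1 in sub1) for (x2 in sub2) {
            rows <- c(list(list(node = p, pos = h, event = "switch",
                                target = s[4])),
                      x1$rows, x2$rows)
            res[[length(res) + 1L]] <-
              list(rows = rows, nloss = a$nloss + x1$nloss + x2$nloss)
            if (length(res) >= cap * 4L) return(res)
          }
        }
      }
    }
    res
  }

  rootP <- dp$ntipP + 1L
  best <- min(dp$C[rootP, ])
  roots <- which(dp$C[rootP, ] <= best + eps)
  out <- list()
  for (h in sort(roots)) {
    for (s in sols_at(rootP, h)) {
      out[[length(out) + 1L]] <- s
      if (length(out) >= cap * 4L) break
    }
    if (length(out) >= cap * 4L) break
  }
  # deterministic order + dedup by event-string key
  keys <- vapply(out, function(s) {
    r <- s$rows
    ord <- order(vapply(r, `[[`, 0L, "node"))
    paste(vapply(r[ord], function(z)
      paste(z$node, z$pos, z$event, z$target, sep = ":"), ""), s$nloss,
      collapse = "|")
  }, "")
  out <- out[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  out <- out[order(keys)]
  if (length(out) > cap) out <- out[seq_len(cap)]
  list(cost = best, solutions = out)
}

# ---- user-facing operations ----------------------------------------------

#' Minimum-cost cophylogenetic reconciliations
#'
#' Maps the mimic tree onto the model tree by dynamic programming over
#' mimic-postorder x model positions. Events at internal mimic nodes are
#' codivergence (tracking a model divergence), duplication (divergence on
#' the same model lineage), or switch (a duplication one of whose daughters
#' colonises any non-ancestral model lineage; charged duplication+switch).
#' One loss is charged per model internal node passed through by a mimic
#' lineage without a mimic divergence. All co-optimal reconciliations are
#' returned, deterministically ordered and capped.
#'
#' @param mimic,model Rooted, fully resolved `phylo` trees.
#' @param assoc An `assoc_map` from [parse_associations()] (every mimic
#'   leaf associated; many-to-many allowed).
#' @param costs An [event_costs()] regime.
#' @param max_solutions Cap on the number of co-optimal solutions kept.
#' @return An object of class `reconciliation_set`: a list with elements
#'   `cost` (the global minimum), `solutions` (list of `reconciliation`
#'   objects), `costs`, and the input labels.
#' @export
reconcile_min_cost <- function(mimic, model, assoc, costs = event_costs(),
                               max_solutions = 100L) {
  validate_phylo(mimic); validate_phylo(model)
  if (!inherits(assoc, "assoc_map")) {
    assoc <- parse_associations(assoc, mimic, model)
  }
  if (has_polytomies(mimic) || has_polytomies(model)) {
    stop("reconcile_min_cost requires fully resolved trees; ",
         "see resolve_polytomies()")
  }
  ai <- assoc_index(assoc, mimic, model)
  if (any(lengths(ai) == 0L)) {
    stop("every mimic leaf must be associated with at least one model leaf")
  }
  dp <- reconcile_dp(mimic, model, ai, costs)
  en <- enum_solutions(dp, cap = as.integer(max_solutions))
  ntipP <- ape::Ntip(mimic)
  sols <- lapply(en$solutions, function(s) {
    rows <- s$rows
    df <- data.frame(
      mimic_node = vapply(rows, `[[`, 0L, "node"),
      model_node = vapply(rows, `[[`, 0L, "pos"),
      event = vapply(rows, `[[`, "", "event"),
      switch_target = vapply(rows, `[[`, 0L, "target"),
      stringsAsFactors = FALSE
    )
    df <- df[order(df$mimic_node), , drop = FALSE]
    rownames(df) <- NULL
    tally <- c(
      n_codiv = sum(df$event == "codivergence"),
      n_dup = sum(df$event %in% c("duplication", "switch")),
      n_switch = sum(df$event == "switch"),
      n_loss = s$nloss
    )
    total <- sum(tally * costs[c("codivergence", "duplication", "switch", "loss")])
    structure(list(events = df, tally = tally, total_cost = total,
                   n_loss = s$nloss),
              class = "reconciliation")
  })
  structure(list(cost = en$cost, solutions = sols, costs = costs,
                 mimic = mimic, model = model, assoc = assoc),
            class = "reconciliation_set")
}

#' @export
print.reconciliation_set <- function(x, ...) {
  cat("Cophylogenetic reconciliation: minimum cost", x$cost, "\n")
  cat(length(x$solutions), "co-optimal solution(s) kept\n")
  if (length(x$solutions)) {
    t1 <- x$solutions[[1]]$tally
    cat("first solution:", t1["n_codiv"], "codivergences,",
        t1["n_dup"], "duplications,", t1["n_switch"], "switches,",
        t1["n_loss"], "losses\n")
  }
  invisible(x)
}

#' Fast minimum reconciliation cost
#'
#' Cost-only path used inside Monte-Carlo loops; identical model to
#' [reconcile_min_cost()] but implemented in C++.
#'
#' @inheritParams reconcile_min_cost
#' @return The minimum total cost (a single number).
#' @export
reconcile_cost <- function(mimic, model, assoc, costs = event_costs()) {
  if (!inherits(assoc, "assoc_map")) {
    assoc <- parse_associations(assoc, mimic, model)
  }
  mi <- match(assoc$mimic, mimic$tip.label)
  Mi <- match(assoc$model, model$tip.label)
  dp_min_cost(mimic$edge, ape::Ntip(mimic), model$edge, ape::Ntip(model),
              cbind(mi, Mi), as.numeric(costs))
}

#' Ceiling on the number of codivergence events
#'
#' Each codivergence is a divergence of the mimic tree, so the number of
#' internal mimic nodes bounds the count (n - 1 for a fully resolved
#' n-leaf tree).
#'
#' @param mimic A rooted `phylo`.
#' @return Integer count of internal (non-leaf) nodes.
#' @export
max_codivergences <- function(mimic) {
  validate_phylo(mimic)
  mimic$Nnode
}

#' Event tally of a reconciliation
#'
#' @param rec A `reconciliation` (one element of
#'   `reconcile_min_cost(...)$solutions`).
#' @return Named integer vector `(n_codiv, n_dup, n_switch, n_loss)`. A
#'   switch node counts as both a duplication and a switch.
#' @export
event_tally <- function(rec) {
  stopifnot(inherits(rec, "reconciliation"))
  rec$tally
}

#' Temporal consistency of reconstructed codivergences
#'
#' For every codivergence event, reports whether the mimic node's 95% age
#' interval and its model node's interval intersect (closed intervals, so
#' touching endpoints overlap). Events lacking an interval on either side
#' are reported as `"unknown"`.
#'
#' @param rec A `reconciliation`.
#' @param mimic_ages,model_ages Either trees carrying an `age_intervals`
#'   attribute (see [attach_age_intervals()]) or 2-row matrices
#'   (`low`/`high`) with one column per node.
#' @return Data frame with columns `mimic_node`, `model_node`, `overlap`
#'   (`"yes"`, `"no"`, `"unknown"`).
#' @export
temporal_consistency <- function(rec, mimic_ages, model_ages) {
  stopifnot(inherits(rec, "reconciliation"))
  get_iv <- function(x) {
    if (inherits(x, "phylo")) attr(x, "age_intervals") else x
  }
  ivP <- get_iv(mimic_ages); ivM <- get_iv(model_ages)
  ev <- rec$events
  cd <- ev[ev$event == "codivergence", , drop = FALSE]
  ans <- character(nrow(cd))
  for (i in seq_len(nrow(cd))) {
    a <- ivP[, cd$mimic_node[i]]
    b <- ivM[, cd$model_node[i]]
    ans[i] <- if (anyNA(a) || anyNA(b)) "unknown"
      else if (a[1] <= b[2] && b[1] <= a[2]) "yes" else "no"
  }
  data.frame(mimic_node = cd$mimic_node, model_node = cd$model_node,
             overlap = ans, stringsAsFactors = FALSE)
}

#' Brute-force minimum reconciliation cost (reference implementation)
#'
#' Enumerates every assignment of internal mimic nodes to model positions
#' and scores each under the same event model as the dynamic programme.
#' Exponential; intended for small trees as an independent check.
#'
#' @inheritParams reconcile_min_cost
#' @return Minimum total cost.
#' @export
reconcile_cost_bruteforce <- function(mimic, model, assoc, costs = event_costs()) {
  if (!inherits(assoc, "assoc_map")) {
    assoc <- parse_associations(assoc, mimic, model)
  }
  ai <- assoc_index(assoc, mimic, model)
  tabM <- model_tables(model)
  ntipP <- ape::Ntip(mimic)
  nnP <- ntipP + mimic$Nnode
  chP <- children_list(mimic)
  internalP <- (ntipP + 1L):nnP
  cc <- costs[["codivergence"]]; cd <- costs[["duplication"]]
  cs <- costs[["switch"]]; cl <- costs[["loss"]]
  nnM <- tabM$nn

  # leaves may have several permissible positions (many-to-many maps)
  pos_options <- vector("list", nnP)
  for (p in seq_len(ntipP)) pos_options[[p]] <- ai[[p]]
  for (p in internalP) pos_options[[p]] <- seq_len(nnM)

  node_cost <- function(h, h1, h2) {
    best <- BIGC
    if (tabM$isint[h]) {
      hl <- tabM$ch[[h]][1L]; hr <- tabM$ch[[h]][2L]
      for (o in list(c(hl, hr), c(hr, hl))) {
        if (tabM$insub[o[1], h1] && tabM$insub[o[2], h2]) {
          best <- min(best, cc + cl * (tabM$lossn[o[1], h1] + tabM$lossn[o[2], h2]))
        }
      }
    }
    if (tabM$insub[h, h1] && tabM$insub[h, h2]) {
      best <- min(best, cd + cl * (tabM$lossn[h, h1] + tabM$lossn[h, h2]))
    }
    if (tabM$insub[h, h1] && tabM$allowed[h, h2]) {
      best <- min(best, cd + cs + cl * tabM$lossn[h, h1])
    }
    if (tabM$insub[h, h2] && tabM$allowed[h, h1]) {
      best <- min(best, cd + cs + cl * tabM$lossn[h, h2])
    }
    best
  }

  grid <- expand.grid(pos_options, KEEP.OUT.ATTRS = FALSE)
  best <- BIGC
  for (r in seq_len(nrow(grid))) {
    pos <- as.integer(grid[r, ])
    tot <- 0
    for (p in internalP) {
      k <- chP[[p]]
      tot <- tot + node_cost(pos[p], pos[k[1]], pos[k[2]])
      if (tot >= best) break
    }
    if (tot < best) best <- tot
  }
  best
}
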