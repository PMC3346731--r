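# shared test utilities: small random problem instances and an
# independent clade-set representation for topology comparison

# set of leaf-label clades (one per internal node), as sorted strings
clade_sets <- function(tree) {
  ntip <- ape::Ntip(tree)
  tips <- comimic:::clade_tips_list(tree)
  keys <- vapply(seq.int(ntip + 1L, ntip + tree$Nnode), function(v)
    paste(sort(tree$tip.label[tips[[v]]]), collapse = "|"), "")
  sort(keys)
}

same_topology <- function(a, b) {
  setequal(a$tip.label, b$tip.label) && identical(clade_sets(a), clade_sets(b))
}

# random reconciliation instance with one-to-one (or many-to-one)
# associations; leaf counts drawn from `sizes`
random_instance <- function(sizes = 2:5, one_to_one = TRUE) {
  np <- sample(sizes, 1L)
  nm <- sample(sizes, 1L)
  mimic <- rtopology_yule(paste0("p", seq_len(np)))
  model <- rtopology_yule(paste0("h", seq_len(nm)))
  model_leaves <- if (one_to_one && nm >= np) {
    sample(model$tip.label, np)
  } else {
    sample(model$tip.label, np, replace = TRUE)
  }
  assoc <- parse_associations(
    data.frame(mimic = mimic$tip.label, model = model_leaves), mimic, model)
  list(mimic = mimic, model = model, assoc = assoc)
}

# a congruent pair: mimic is a relabelled copy of the model
congruent_pair <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  model <- rtopology_yule(paste0("h", seq_len(n)))
  mimic <- model
  mimic$tip.label <- sub("^h", "p", model$tip.label)
  assoc <- parse_associations(
    data.frame(mimic = mimic$tip.label, model = model$tip.label),
    mimic, model)
  list(mimic = mimic, model = model, assoc = assoc)
}
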