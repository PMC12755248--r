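# Shared fixtures, built in code. Expensive exhaustive artifacts (the
# 6-leaf catalog and its precomputed neighborhoods) are cached per test run.

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cache)) {
    assign(name, force(expr), envir = .cache)
  }
  get(name, envir = .cache)
}

catalog6 <- function() cached("catalog6", enumerate_trees(letters[1:6]))

# split-key sets of all 105 six-leaf trees
keys6 <- function() {
  cached("keys6", lapply(catalog6()$trees, function(t) t$keys))
}

# canonical identity strings of the NNI / SPR neighborhoods of each tree
nni_nbkeys6 <- function() {
  cached("nni_nbkeys6", lapply(catalog6()$trees, function(t) {
    vapply(nni_neighbors(t), function(x) paste(x$keys, collapse = ";"),
           character(1L))
  }))
}

spr_nbkeys6 <- function() {
  cached("spr_nbkeys6", lapply(catalog6()$trees, function(t) {
    vapply(spr_neighbors(t), function(x) paste(x$keys, collapse = ";"),
           character(1L))
  }))
}

tree_id <- function(t) paste(t$keys, collapse = ";")

# a caterpillar tree with the given leaf order
caterpillar <- function(labels) {
  n <- length(labels)
  stopifnot(n >= 4)
  inner <- paste0("(", labels[1], ",", labels[2], ")")
  for (i in 3:(n - 1)) inner <- paste0("(", inner, ",", labels[i], ")")
  read_newick(paste0("(", inner, ",", labels[n], ");"))
}

# the classic maximally RF-distant pair connected by one SPR move: take a
# caterpillar and relocate its first leaf to the far end
max_rf_pair <- function(n) {
  labels <- letters[seq_len(n)]
  list(t = caterpillar(labels),
       r = caterpillar(c(labels[-1], labels[1])))
}

quartets <- function() {
  lapply(c("((a,b),(c,d));", "((a,c),(b,d));", "((a,d),(b,c));"),
         read_newick)
}

as_phylo <- function(t) ape::read.tree(text = write_newick(t))
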