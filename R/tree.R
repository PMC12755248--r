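#' Unrooted binary phylogenetic tree topologies
#'
#' A `treetop` object stores an unrooted binary leaf-labeled tree as the set
#' of bipartitions (splits) induced by its edges. Every edge of a binary
#' tree on `n >= 3` leaves cuts the leaf set into two non-empty parts; the
#' collection of all `2n - 3` such splits identifies the topology uniquely,
#' so the split set is used as the primary representation throughout the
#' package. Branch lengths are never stored: all distances here are purely
#' topological.
#'
#' @param x object to test or print.
#' @param ... unused.
#'
#' @return `is_treetop()` returns a logical scalar.
#' @seealso [read_newick()], [tree_splits()], [tree_from_splits()]
#' @name treetop
NULL

# Fast internal constructor. `sides` is a list of character vectors, each
# one side of a split; they are canonicalized and sorted by key. Cheap
# structural checks only; full pairwise compatibility is checked by
# validate_treetop() on untrusted input.
new_treetop <- function(tips, sides) {
  tips <- sort.int(tips, method = "radix")
  n <- length(tips)
  sides <- lapply(sides, canonical_side, tips = tips)
  keys <- vapply(sides, side_key, character(1L))
  if (anyDuplicated(keys)) {
    stop("duplicate splits in tree construction", call. = FALSE)
  }
  if (n >= 3L && length(sides) != 2L * n - 3L) {
    stop("expected ", 2L * n - 3L, " splits for ", n, " leaves, got ",
         length(sides), call. = FALSE)
  }
  ord <- order(keys, method = "radix")
  structure(
    list(tips = tips, splits = sides[ord], keys = keys[ord]),
    class = "treetop"
  )
}

# Incremental constructor: drop the splits with keys in `drop` and add the
# (possibly unsorted) sides in `add`, reusing the canonical form of all
# untouched splits. Used by single-move applications, where all but one or
# two splits carry over unchanged.
tree_replace_splits <- function(t, drop, add) {
  keep <- !(t$keys %in% drop)
  asides <- lapply(add, canonical_side, tips = t$tips)
  akeys <- vapply(asides, side_key, character(1L))
  keys <- c(t$keys[keep], akeys)
  if (anyDuplicated(keys)) {
    stop("duplicate splits in tree construction", call. = FALSE)
  }
  sides <- c(t$splits[keep], asides)
  ord <- order(keys, method = "radix")
  structure(list(tips = t$tips, splits = sides[ord], keys = keys[ord]),
            class = "treetop")
}

#' @rdname treetop
#' @export
is_treetop <- function(x) inherits(x, "treetop")

#' Validate a treetop object
#'
#' Checks the full set of invariants of an unrooted binary topology: leaf
#' labels are well-formed and unique, there are exactly `2n - 3` splits of
#' which `n` are trivial (single-leaf sides) and `n - 3` are non-trivial,
#' every side is a non-empty proper subset of the leaf set, and all pairs
#' of splits are compatible.
#'
#' @param t a [treetop] object.
#' @return `t`, invisibly; errors if an invariant fails.
#' @export
validate_treetop <- function(t) {
  stopifnot(is_treetop(t))
  check_labels(t$tips)
  n <- length(t$tips)
  if (n < 3L) stop("trees must have at least 3 leaves", call. = FALSE)
  if (length(t$splits) != 2L * n - 3L) {
    stop("expected ", 2L * n - 3L, " splits, found ", length(t$splits),
         call. = FALSE)
  }
  sizes <- lengths(t$splits)
  if (sum(sizes == 1L) != n) {
    stop("expected ", n, " trivial splits, found ", sum(sizes == 1L),
         call. = FALSE)
  }
  for (s in t$splits) {
    if (length(s) == 0L || length(s) >= n || !all(s %in% t$tips)) {
      stop("split side is not a proper non-empty subset of the leaf set",
           call. = FALSE)
    }
  }
  m <- length(t$splits)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      if (!splits_compatible(t$splits[[i]], t$splits[[j]], t$tips)) {
        stop("incompatible splits: {", side_key(t$splits[[i]]), "} and {",
             side_key(t$splits[[j]]), "}", call. = FALSE)
      }
    }
  }
  invisible(t)
}

# Canonical identity string for hashing / deduplication (keys are sorted in
# the constructor, so this is stable across construction orders).
tree_key <- function(t) paste(t$keys, collapse = ";")

#' @rdname treetop
#' @export
print.treetop <- function(x, ...) {
  cat("Unrooted binary tree topology, ", length(x$tips), " leaves\n",
      sep = "")
  cat(write_newick(x), "\n", sep = "")
  invisible(x)
}

#' Number of leaves of a tree
#'
#' @param t a [treetop] object.
#' @return integer leaf count.
#' @export
n_leaves <- function(t) {
  stopifnot(is_treetop(t))
  length(t$tips)
}

check_same_tips <- function(t, r) {
  if (length(t$tips) != length(r$tips) || !all(t$tips == r$tips)) {
    stop("trees are on different leaf sets", call. = FALSE)
  }
  invisible(TRUE)
}
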