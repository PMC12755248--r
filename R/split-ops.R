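#' Splits (bipartitions) of a tree
#'
#' Every edge of an unrooted binary tree on leaf set X induces a split A|B:
#' the bipartition of X into the two components obtained by cutting the
#' edge. The split set of a tree uniquely identifies it. Splits are
#' returned in canonical orientation: each is represented by its smaller
#' side (ties broken by the side containing the smallest label), sorted.
#'
#' @param t a [treetop] object.
#' @param trivial if `FALSE`, only non-trivial splits (both sides with at
#'   least two leaves) are returned.
#' @return a list of character vectors, one canonical side per edge;
#'   `2n - 3` splits in total, `n - 3` of them non-trivial.
#' @examples
#' tree_splits(read_newick("((a,b),(c,d));"), trivial = FALSE)
#' @export
tree_splits <- function(t, trivial = TRUE) {
  stopifnot(is_treetop(t))
  if (trivial) t$splits else t$splits[lengths(t$splits) > 1L]
}

#' Split size
#'
#' The size of a split A|B is `min(|A|, |B|)`, i.e. the size of its smaller
#' side. Trivial splits have size 1.
#'
#' @param side one side of a split (character vector of labels); in
#'   canonical orientation this is already the smaller side.
#' @return integer.
#' @export
split_size_of <- function(side) length(side)

#' Reconstruct a tree from its split set
#'
#' Inverse of [tree_splits()]: given the complete split set of an unrooted
#' binary tree (exactly `2n - 3` distinct, pairwise compatible splits over
#' a common leaf set), returns the unique tree with that split set.
#' Incompatible or incomplete split sets are rejected.
#'
#' @param sides a list of character vectors, each one side of a split
#'   (either orientation).
#' @param tips optional character vector of leaf labels; defaults to the
#'   union of all sides. Must be supplied if some leaf appears in no side,
#'   which cannot happen for a complete split set.
#' @return a [treetop] object.
#' @examples
#' t <- read_newick("((a,b),(c,d));")
#' is_isomorphic(tree_from_splits(tree_splits(t)), t)
#' @export
tree_from_splits <- function(sides, tips = NULL) {
  if (!is.list(sides) || length(sides) == 0L) {
    stop("expected a non-empty list of split sides", call. = FALSE)
  }
  if (is.null(tips)) tips <- sort.int(unique(unlist(sides)), method = "radix")
  check_labels(tips)
  n <- length(tips)
  if (n < 3L) stop("split sets describe trees with at least 3 leaves",
                   call. = FALSE)
  if (length(sides) != 2L * n - 3L) {
    stop("incomplete split set: expected ", 2L * n - 3L,
         " splits for ", n, " leaves, got ", length(sides), call. = FALSE)
  }
  t <- new_treetop(tips, sides)   # errors on duplicates
  validate_treetop(t)             # errors on incompatibility
  t
}

#' Robinson-Foulds distance
#'
#' The RF distance between two trees on the same leaf set is the size of
#' the symmetric difference of their split sets, `|Γ(T) Δ Γ(R)|`. Trivial
#' splits are shared by all trees on the same leaf set and cancel, so the
#' value equals the usual count over non-trivial splits. It is always even,
#' zero exactly for isomorphic trees, and at most `2(n - 3)`.
#'
#' @param t,r [treetop] objects on the same leaf set.
#' @return an even non-negative integer.
#' @examples
#' rf_distance(read_newick("((a,b),(c,d));"), read_newick("((a,c),(b,d));"))
#' @export
rf_distance <- function(t, r) {
  stopifnot(is_treetop(t), is_treetop(r))
  check_same_tips(t, r)
  rf_keys(t$keys, r$keys)
}

rf_keys <- function(k1, k2) {
  length(k1) + length(k2) - 2L * sum(k1 %in% k2)
}

#' Leaf-label-preserving isomorphism
#'
#' Two phylogenetic trees are isomorphic when a graph isomorphism between
#' them preserves leaf labels; equivalently, when their leaf sets and split
#' sets coincide. Trees on different leaf sets are simply non-isomorphic.
#'
#' @param t,r [treetop] objects.
#' @return logical scalar.
#' @export
is_isomorphic <- function(t, r) {
  stopifnot(is_treetop(t), is_treetop(r))
  length(t$tips) == length(r$tips) && all(t$tips == r$tips) &&
    length(t$keys) == length(r$keys) && all(t$keys == r$keys)
}
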