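#' Nearest Neighbor Interchange moves
#'
#' An NNI move acts on an internal edge e of an unrooted binary tree. The
#' four subtrees hanging off the two endpoints of e can be exchanged across
#' the edge in two non-trivial ways, each producing one of the two
#' alternative resolutions of the degree-4 node obtained by contracting e.
#' An NNI move changes exactly one split (the one induced by e), so the RF
#' distance between a tree and any of its NNI neighbors is always 2.
#'
#' `nni_move()` describes a move declaratively by the split of the edge it
#' acts on plus a swap choice, so moves survive re-parsing and
#' canonicalization of the tree.
#'
#' @param edge character vector: one side of a non-trivial split of the
#'   source tree (either orientation).
#' @param choice 1 or 2. With the subtrees on the edge's canonical side
#'   ordered as `A1, A2` and on the far side as `B1, B2` (each pair in
#'   lexicographic order), choice 1 exchanges `A2` and `B1`, choice 2
#'   exchanges `A2` and `B2`.
#' @return an object of class `nni_move`.
#' @seealso [apply_nni()], [nni_neighbors()], [is_nni_adjacent()]
#' @export
nni_move <- function(edge, choice) {
  choice <- as.integer(choice)
  stopifnot(is.character(edge), length(edge) >= 1L, choice %in% 1:2)
  structure(list(edge = sort.int(edge, method = "radix"), choice = choice),
            class = "nni_move")
}

#' @export
print.nni_move <- function(x, ...) {
  cat("NNI move on edge {", paste(x$edge, collapse = ","), "}, swap ",
      x$choice, "\n", sep = "")
  invisible(x)
}

#' Apply an NNI move
#'
#' @param t a [treetop] object.
#' @param m an [nni_move()] whose edge is an internal edge of `t`.
#' @return the rearranged [treetop]; it differs from `t` in exactly one
#'   split and has RF distance 2 from `t`.
#' @export
apply_nni <- function(t, m) {
  stopifnot(is_treetop(t), inherits(m, "nni_move"))
  a <- canonical_side(m$edge, t$tips)
  key <- side_key(a)
  if (!key %in% t$keys) {
    stop("move edge is not an edge of the tree", call. = FALSE)
  }
  if (length(a) < 2L || length(a) > length(t$tips) - 2L) {
    stop("NNI moves act on internal edges only (non-trivial splits)",
         call. = FALSE)
  }
  sb <- sides_both_of(t)
  ach <- clade_children(sb, a)
  b <- setdiff(t$tips, a)
  bch <- clade_children(sb, b)
  newside <- if (m$choice == 1L) {
    c(ach[[1L]], bch[[1L]])       # swap A2 <-> B1: edge now splits A1+B1
  } else {
    c(ach[[1L]], bch[[2L]])       # swap A2 <-> B2: edge now splits A1+B2
  }
  tree_replace_splits(t, key, list(newside))
}

#' NNI neighborhood of a tree
#'
#' All trees exactly one NNI move away from `t`: two per internal edge,
#' `2(n - 3)` in total, pairwise non-isomorphic and none isomorphic to `t`.
#'
#' @param t a [treetop] object with at least 4 leaves.
#' @return a list of [treetop] objects.
#' @export
nni_neighbors <- function(t) {
  stopifnot(is_treetop(t))
  if (length(t$tips) < 4L) stop("NNI requires at least 4 leaves", call. = FALSE)
  internal <- t$splits[lengths(t$splits) > 1L]
  out <- vector("list", 2L * length(internal))
  k <- 0L
  for (e in internal) {
    for (ch in 1:2) {
      k <- k + 1L
      out[[k]] <- apply_nni(t, nni_move(e, ch))
    }
  }
  out
}

#' NNI adjacency oracle
#'
#' Two trees on the same leaf set are NNI-adjacent when there is an edge e
#' in one and f in the other whose contraction yields isomorphic
#' (non-binary) trees. The check is performed directly on that definition:
#' contracting an internal edge removes its split, and two trees (binary or
#' not) are isomorphic exactly when their split sets coincide, so the
#' oracle searches for a pair of non-trivial splits whose removal equalizes
#' the two split sets. Isomorphic trees are not adjacent (the graph has no
#' self-loops).
#'
#' @param t,r [treetop] objects on the same leaf set.
#' @return logical scalar.
#' @export
is_nni_adjacent <- function(t, r) {
  stopifnot(is_treetop(t), is_treetop(r))
  check_same_tips(t, r)
  if (is_isomorphic(t, r)) return(FALSE)
  kt <- t$keys
  kr <- r$keys
  nt <- kt[lengths(t$splits) > 1L]
  nr <- kr[lengths(r$splits) > 1L]
  for (st in nt) {
    ct <- kt[kt != st]
    for (sr in nr) {
      cr <- kr[kr != sr]
      if (length(ct) == length(cr) && all(ct == cr)) return(TRUE)
    }
  }
  FALSE
}

# Recover the NNI move turning t1 into its neighbor t2 (used to attach move
# descriptors to constructed paths).
nni_step_between <- function(t1, t2) {
  old <- setdiff(t1$keys, t2$keys)
  if (length(old) != 1L) {
    stop("trees do not differ in exactly one split", call. = FALSE)
  }
  edge <- t1$splits[[match(old, t1$keys)]]
  for (ch in 1:2) {
    m <- nni_move(edge, ch)
    if (is_isomorphic(apply_nni(t1, m), t2)) return(m)
  }
  stop("trees are not NNI-adjacent", call. = FALSE)
}
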