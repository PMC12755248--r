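#' Subtree Prune and Regraft moves
#'
#' An SPR move removes an edge of the tree, splitting it into two
#' components; the component named by `prune` keeps its attachment point
#' (its old degree-2 node), and is reconnected to a new node placed on an
#' edge `regraft` of the other component, after which the leftover degree-2
#' node is suppressed. Regrafting onto the edge that absorbed the original
#' attachment point recreates the source tree; such degenerate moves are
#' valid applications but are excluded from [spr_neighbors()].
#'
#' The move is declarative: `prune` names the pruned component by its leaf
#' set (which side of the cut edge is moved is therefore explicit), and
#' `regraft` names an edge of the remaining component by the split it
#' induces *in that component* (i.e. on the leaf set `X \ prune`).
#'
#' @param prune character vector: the leaf set of the pruned component;
#'   must be one side of a split of the source tree.
#' @param regraft character vector: one side (either orientation) of a
#'   split of the remaining component.
#' @return an object of class `spr_move`.
#' @seealso [apply_spr()], [spr_neighbors()]
#' @export
spr_move <- function(prune, regraft) {
  stopifnot(is.character(prune), length(prune) >= 1L,
            is.character(regraft), length(regraft) >= 1L)
  structure(list(prune = sort.int(prune, method = "radix"),
                 regraft = sort.int(regraft, method = "radix")),
            class = "spr_move")
}

#' @export
print.spr_move <- function(x, ...) {
  cat("SPR move: prune {", paste(x$prune, collapse = ","),
      "}, regraft at {", paste(x$regraft, collapse = ","), "}\n", sep = "")
  invisible(x)
}

#' Apply an SPR move
#'
#' @param t a [treetop] object.
#' @param m an [spr_move()] valid for `t`.
#' @return the rearranged [treetop] on the same leaf set; the split
#'   separating the pruned component from the rest is present in the
#'   result.
#' @export
apply_spr <- function(t, m) {
  stopifnot(is_treetop(t), inherits(m, "spr_move"))
  p <- m$prune
  if (!all(p %in% t$tips)) {
    stop("pruned leaf set contains unknown labels", call. = FALSE)
  }
  s <- setdiff(t$tips, p)
  if (length(p) == 0L || length(s) < 2L) {
    stop("remaining component must contain at least 2 leaves", call. = FALSE)
  }
  if (!side_key(canonical_side(p, t$tips)) %in% t$keys) {
    stop("pruned leaf set is not a pendant subtree (one side of a split)",
         call. = FALSE)
  }
  rest <- restrict_pairs(t, s)
  fkey <- side_key(canonical_side_in(m$regraft, s))
  fi <- match(fkey, vapply(rest, `[[`, character(1L), "key"))
  if (is.na(fi)) {
    stop("regraft edge is not an edge of the remaining component",
         call. = FALSE)
  }
  f1 <- rest[[fi]]$u
  f2 <- rest[[fi]]$v
  # rooted clades of the pruned pendant subtree (kept intact by the move)
  la <- length(p)
  inner <- Filter(function(x) length(x) < la && all(x %in% p),
                  sides_both_of(t))
  sides <- c(list(p), inner, list(c(f1, p), f1))
  for (i in seq_along(rest)) {
    if (i == fi) next
    pr <- rest[[i]]
    sides <- c(sides, if (side_contains_edge(pr$u, f1, f2)) {
      list(c(pr$u, p))
    } else {
      list(pr$u)
    })
  }
  new_treetop(t$tips, sides)
}

# canonical_side against an arbitrary universe given as a sorted vector
canonical_side_in <- function(side, universe) {
  side <- sort.int(side, method = "radix")
  if (!all(side %in% universe)) {
    stop("split side is not a subset of its component", call. = FALSE)
  }
  k <- length(side)
  nu <- length(universe)
  if (2L * k < nu) return(side)
  other <- setdiff(universe, side)
  if (2L * k > nu) return(other)
  if (universe[1L] %in% side) side else other
}

#' SPR neighborhood of a tree
#'
#' All trees exactly one SPR move from `t` (excluding `t` itself): for
#' every split, either side may be pruned, and the pruned component may be
#' regrafted on any edge of the remaining component other than the edge
#' that absorbed its original attachment point. The NNI neighborhood is
#' always a subset of the SPR neighborhood.
#'
#' @param t a [treetop] object with at least 4 leaves.
#' @return a list of pairwise non-isomorphic [treetop] objects.
#' @export
spr_neighbors <- function(t) {
  stopifnot(is_treetop(t))
  if (length(t$tips) < 4L) stop("SPR requires at least 4 leaves", call. = FALSE)
  self <- tree_key(t)
  seen <- character(0L)
  out <- list()
  for (sp in t$splits) {
    comp <- setdiff(t$tips, sp)
    for (p in list(sp, comp)) {
      s <- if (identical(p, sp)) comp else sp
      if (length(s) < 3L) next  # the only edge of the rest is the degenerate one
      # edge of the remaining component holding the old attachment point:
      # the two subtrees flanking the pruned one merge into a single edge
      d <- clade_children(sides_both_of(t), s)
      f0 <- side_key(canonical_side_in(d[[1L]], s))
      for (pr in restrict_pairs(t, s)) {
        if (pr$key == f0) next
        nb <- apply_spr(t, spr_move(p, pr$u))
        k <- tree_key(nb)
        if (k == self || k %in% seen) next
        seen <- c(seen, k)
        out <- c(out, list(nb))
      }
    }
  }
  out
}
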