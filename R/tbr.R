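#' Tree Bisection and Reconnection moves
#'
#' A TBR move removes an edge of the tree and suppresses the resulting
#' degree-2 nodes, leaving two unrooted components; a new node is placed on
#' one chosen edge in each component and the two new nodes are joined by a
#' new edge. Unlike SPR, neither component remembers its old attachment
#' point. Every SPR move (and hence every NNI move) can be written as a
#' TBR move.
#'
#' @param bisect character vector: one side of a split of the source tree;
#'   the edge inducing that split is removed.
#' @param reattach_a reattachment edge in the component spanning `bisect`,
#'   given as one side of a split of that component; `NULL` when the
#'   component has at most 2 leaves (at most one candidate edge).
#' @param reattach_b reattachment edge in the other component, same
#'   convention.
#' @return an object of class `tbr_move`.
#' @seealso [apply_tbr()], [tbr_neighbors()]
#' @export
tbr_move <- function(bisect, reattach_a = NULL, reattach_b = NULL) {
  stopifnot(is.character(bisect), length(bisect) >= 1L)
  srt <- function(x) if (is.null(x)) NULL else sort.int(x, method = "radix")
  structure(list(bisect = srt(bisect), reattach_a = srt(reattach_a),
                 reattach_b = srt(reattach_b)),
            class = "tbr_move")
}

#' @export
print.tbr_move <- function(x, ...) {
  fmt <- function(v) if (is.null(v)) "<unique>" else paste(v, collapse = ",")
  cat("TBR move: bisect {", paste(x$bisect, collapse = ","),
      "}, reattach at {", fmt(x$reattach_a), "} / {", fmt(x$reattach_b),
      "}\n", sep = "")
  invisible(x)
}

# Lift the splits of one unrooted component (universe u, split pairs
# `pairs`) into splits of the full tree when the other component (leaf set
# `other`) is attached by a new node on edge `fi`. Returns a list of sides.
attach_component <- function(pairs, fi, other) {
  if (length(pairs) == 0L) return(list())
  f1 <- pairs[[fi]]$u
  f2 <- pairs[[fi]]$v
  sides <- list(c(f1, other), f1)
  for (i in seq_along(pairs)) {
    if (i == fi) next
    pr <- pairs[[i]]
    sides <- c(sides, if (side_contains_edge(pr$u, f1, f2)) {
      list(c(pr$u, other))
    } else {
      list(pr$u)
    })
  }
  sides
}

#' Apply a TBR move
#'
#' @param t a [treetop] object.
#' @param m a [tbr_move()] valid for `t`.
#' @return the rearranged [treetop] on the same leaf set.
#' @export
apply_tbr <- function(t, m) {
  stopifnot(is_treetop(t), inherits(m, "tbr_move"))
  p <- m$bisect
  if (!all(p %in% t$tips)) {
    stop("bisection side contains unknown labels", call. = FALSE)
  }
  s <- setdiff(t$tips, p)
  if (length(p) == 0L || length(s) == 0L) {
    stop("bisection side must be a proper non-empty subset", call. = FALSE)
  }
  if (!side_key(canonical_side(p, t$tips)) %in% t$keys) {
    stop("bisection side is not one side of a split of the tree",
         call. = FALSE)
  }
  lift_one <- function(universe, reattach, other, which) {
    pairs <- restrict_pairs(t, universe)
    if (length(pairs) == 0L) {
      if (!is.null(reattach)) {
        stop("component {", paste(universe, collapse = ","),
             "} has no edges; reattach_", which, " must be NULL",
             call. = FALSE)
      }
      return(list())   # single leaf: its pendant edge is the new edge itself
    }
    if (is.null(reattach)) {
      if (length(pairs) > 1L) {
        stop("reattach_", which, " is required: component has ",
             length(pairs), " candidate edges", call. = FALSE)
      }
      fi <- 1L
    } else {
      fkey <- side_key(canonical_side_in(reattach, universe))
      fi <- match(fkey, vapply(pairs, `[[`, character(1L), "key"))
      if (is.na(fi)) {
        stop("reattach_", which, " is not an edge of its component",
             call. = FALSE)
      }
    }
    attach_component(pairs, fi, other)
  }
  sides <- c(list(p),
             lift_one(p, m$reattach_a, s, "a"),
             lift_one(s, m$reattach_b, p, "b"))
  new_treetop(t$tips, sides)
}

#' TBR neighborhood of a tree
#'
#' All trees one TBR move away from `t` (excluding `t`). Contains the SPR
#' neighborhood, which in turn contains the NNI neighborhood. Intended for
#' small trees; the neighborhood grows cubically.
#'
#' @param t a [treetop] object with at least 4 leaves.
#' @return a list of pairwise non-isomorphic [treetop] objects.
#' @export
tbr_neighbors <- function(t) {
  stopifnot(is_treetop(t))
  if (length(t$tips) < 4L) stop("TBR requires at least 4 leaves", call. = FALSE)
  self <- tree_key(t)
  seen <- character(0L)
  out <- list()
  for (sp in t$splits) {
    comp <- setdiff(t$tips, sp)
    pa <- restrict_pairs(t, sp)
    pb <- restrict_pairs(t, comp)
    ea <- if (length(pa) == 0L) list(NULL) else lapply(pa, `[[`, "u")
    eb <- if (length(pb) == 0L) list(NULL) else lapply(pb, `[[`, "u")
    for (a in ea) {
      for (b in eb) {
        nb <- apply_tbr(t, tbr_move(sp, a, b))
        k <- tree_key(nb)
        if (k == self || k %in% seen) next
        seen <- c(seen, k)
        out <- c(out, list(nb))
      }
    }
  }
  out
}

# Express an SPR move as the equivalent TBR move: bisect the pruned edge,
# reattach the pruned component at the edge created by suppressing its old
# root, and the other component at the SPR regraft edge.
spr_as_tbr <- function(t, m) {
  stopifnot(is_treetop(t), inherits(m, "spr_move"))
  p <- m$prune
  a <- if (length(p) < 2L) {
    NULL
  } else {
    clade_children(sides_both_of(t), sort.int(p, method = "radix"))[[1L]]
  }
  tbr_move(p, a, m$regraft)
}
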