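#' Monotone-RF path in the NNI graph
#'
#' Constructs, for any two trees on the same leaf set, a path in the NNI
#' graph from `t` to `r` along which the RF distance to `r` never
#' increases. Such a path always exists, although a strictly decreasing
#' one may not (see [find_nni_counterexamples()]).
#'
#' The construction recurses on the number of leaves. Isomorphic trees
#' yield the single-tree path, and any two distinct 4-leaf trees are
#' NNI-adjacent, giving a one-move path. Otherwise, if the trees share a
#' non-trivial split, [shared_split_recursion()] reduces the problem to
#' the two sides of that split independently; if they share none (maximum
#' RF distance), [cherry_walk()] first walks a cherry of `r` together in
#' `t` until the RF distance drops below the maximum, after which a shared
#' split exists and the recursion applies. All choices (shared split,
#' cherry, swap orientation) are made deterministically, so the same input
#' always yields the same path.
#'
#' @param t,r [treetop] objects on the same leaf set.
#' @return a [treepath] in mode `"nni_monotone"` from `t` to `r`.
#' @examples
#' p <- nni_monotone_path(read_newick("((a,b),(c,d));"),
#'                        read_newick("((a,c),(b,d));"))
#' p$rf_profile
#' @export
nni_monotone_path <- function(t, r) {
  stopifnot(is_treetop(t), is_treetop(r))
  check_same_tips(t, r)
  if (is_isomorphic(t, r)) {
    return(new_treepath(list(t), list(), "nni_monotone"))
  }
  n <- length(t$tips)
  if (n == 4L) {
    return(new_treepath(list(t, r), list(nni_step_between(t, r)),
                        "nni_monotone"))
  }
  shared <- shared_nontrivial_sides(t, r)
  if (length(shared) > 0L) {
    s <- pick_canonical_split(shared)
    return(shared_split_recursion(t, r, s))
  }
  cw <- cherry_walk(t, r)
  rest <- nni_monotone_path(cw$tree, r)
  concat_paths(cw$prefix, rest, "nni_monotone")
}

shared_nontrivial_sides <- function(t, r) {
  keep <- lengths(t$splits) > 1L & t$keys %in% r$keys
  t$splits[keep]
}

# deterministic split choice: minimum size, then lexicographic by key
pick_canonical_split <- function(sides) {
  keys <- vapply(sides, side_key, character(1L))
  ord <- order(lengths(sides), keys, method = "radix")
  sides[[ord[1L]]]
}

#' Shared-split reduction for monotone NNI paths
#'
#' Given a non-trivial split A|B present in both trees, collapses side A
#' in both to a fresh leaf and recursively connects the reduced trees,
#' then does the same for side B. The first reduced path is lifted by
#' expanding the fresh leaf with the A-subtree of `t`, the second with the
#' B-subtree of `r`; the last tree of the first lifted path and the first
#' tree of the second are then isomorphic (both consist of `t`'s A-side
#' and `r`'s B-side glued across A|B) and the two are concatenated there.
#' The junction isomorphism is asserted at run time. Substituting a leaf
#' by a fixed subtree preserves symmetric differences of split sets, so
#' the lifted paths inherit their monotone RF profiles, and the shared
#' split A|B — like every shared split — is present in every tree on the
#' path.
#'
#' @param t,r [treetop] objects on the same leaf set.
#' @param s one side (either orientation) of a non-trivial split shared by
#'   `t` and `r`.
#' @return a [treepath] in mode `"nni_monotone"` from `t` to `r`.
#' @export
shared_split_recursion <- function(t, r, s) {
  stopifnot(is_treetop(t), is_treetop(r))
  check_same_tips(t, r)
  a_side <- canonical_side(sort.int(s, method = "radix"), t$tips)
  key <- side_key(a_side)
  if (!key %in% t$keys || !key %in% r$keys || length(a_side) < 2L) {
    stop("`s` must be a non-trivial split shared by both trees",
         call. = FALSE)
  }
  b_side <- setdiff(t$tips, a_side)
  a_leaf <- fresh_label(t$tips, ".a")
  b_leaf <- fresh_label(t$tips, ".b")

  p_a <- nni_monotone_path(collapse_side(t, a_side, a_leaf),
                           collapse_side(r, a_side, a_leaf))
  p_b <- nni_monotone_path(collapse_side(t, b_side, b_leaf),
                           collapse_side(r, b_side, b_leaf))

  sub_a <- induced_subtree(t, a_side)   # t's subtree spanning A
  sub_b <- induced_subtree(r, b_side)   # r's subtree spanning B
  lift_a <- lapply(p_a$trees, expand_leaf, leaf = a_leaf, sub = sub_a)
  lift_b <- lapply(p_b$trees, expand_leaf, leaf = b_leaf, sub = sub_b)

  junction_left <- lift_a[[length(lift_a)]]
  if (!is_isomorphic(junction_left, lift_b[[1L]])) {
    stop("internal error: junction trees of the shared-split recursion ",
         "are not isomorphic", call. = FALSE)
  }
  trees <- c(lift_a, lift_b[-1L])
  moves <- lapply(seq_len(length(trees) - 1L), function(i) {
    nni_step_between(trees[[i]], trees[[i + 1L]])
  })
  new_treepath(trees, moves, "nni_monotone")
}

fresh_label <- function(tips, base) {
  lab <- base
  while (lab %in% tips) lab <- paste0(lab, "z")
  lab
}

#' Cherry walk for trees sharing no split
#'
#' When `t` and `r` share no non-trivial split (they are at the maximum RF
#' distance `2(n-3)`), no shared-split reduction applies. This routine
#' picks a cherry `(c1, c2)` of `r` — deterministically the
#' lexicographically smallest pair, with `c1` the smaller label — and
#' moves `c1` towards `c2` in the current tree: each NNI move acts on the
#' second edge of the current path from `c1` to `c2` and exchanges the
#' far-side component containing `c2` with the near-side sibling of `c1`,
#' shortening the path by one edge. The walk stops at the first tree whose
#' RF distance to `r` is strictly below the maximum, which happens at the
#' latest when the cherry is formed. Along the returned prefix the RF
#' distance to `r` stays at the maximum and drops only at the last tree.
#'
#' @param t,r [treetop] objects on the same leaf set sharing no
#'   non-trivial split, at least 5 leaves.
#' @return a list with elements `tree` (the first tree strictly closer to
#'   `r`), `prefix` (a [treepath] from `t` to `tree`; its own profile is
#'   measured to `tree`), and `rf_to_target` (the RF distances from each
#'   prefix tree to `r`).
#' @export
cherry_walk <- function(t, r) {
  stopifnot(is_treetop(t), is_treetop(r))
  check_same_tips(t, r)
  n <- length(t$tips)
  if (n < 5L) stop("cherry walk requires at least 5 leaves", call. = FALSE)
  if (length(shared_nontrivial_sides(t, r)) > 0L) {
    stop("trees share a non-trivial split; the cherry walk applies only ",
         "to maximally distant trees", call. = FALSE)
  }
  cherries <- Filter(function(s) length(s) == 2L, r$splits)
  keys <- vapply(cherries, side_key, character(1L))
  ch <- cherries[[order(keys, method = "radix")[1L]]]
  c1 <- ch[1L]
  c2 <- ch[2L]

  maxrf <- rf_keys(t$keys, r$keys)
  cur <- t
  trees <- list(t)
  rf_trace <- maxrf
  for (iter in seq_len(n)) {
    # edges separating c1 from c2, i.e. the c1-c2 path; their c1-sides
    # form an inclusion chain ordered by size
    sb <- sides_both_of(cur)
    c1_sides <- Filter(function(s) c1 %in% s && !c2 %in% s, sb)
    c1_sides <- c1_sides[order(lengths(c1_sides))]
    if (length(c1_sides) < 3L) {
      stop("internal error: cherry formed without the RF distance dropping",
           call. = FALSE)
    }
    d <- c1_sides[[2L]]                       # second edge on the c1->c2 path
    dch <- clade_children(sb, d)
    d1 <- if (c1 %in% dch[[1L]]) dch[[1L]] else dch[[2L]]   # holds c1
    f <- setdiff(cur$tips, d)
    fch <- clade_children(sb, f)
    e_c2 <- if (c2 %in% fch[[1L]]) fch[[1L]] else fch[[2L]] # holds c2
    dkey <- side_key(canonical_side(d, cur$tips))
    nxt <- tree_replace_splits(cur, dkey, list(c(d1, e_c2)))
    trees <- c(trees, list(nxt))
    cur <- nxt
    rf_cur <- rf_keys(cur$keys, r$keys)
    rf_trace <- c(rf_trace, rf_cur)
    if (rf_cur < maxrf) break
  }
  if (rf_trace[length(rf_trace)] >= maxrf) {
    stop("internal error: cherry walk failed to reduce the RF distance",
         call. = FALSE)
  }
  moves <- lapply(seq_len(length(trees) - 1L), function(i) {
    nni_step_between(trees[[i]], trees[[i + 1L]])
  })
  list(tree = cur,
       prefix = new_treepath(trees, moves, "nni_monotone"),
       rf_to_target = rf_trace)
}
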