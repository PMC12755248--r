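#' One strictly RF-decreasing SPR step
#'
#' Selects the move used by [spr_strict_path()]: among the non-trivial
#' splits of `target` absent from `current`, take one of minimum size
#' (ties broken lexicographically by canonical side); call it A|B with A
#' the canonical (smaller) side. In `target`, A decomposes into the two
#' child clades A1 and A2; by the minimality of A|B, both A1 and A2 are
#' also pendant subtrees of `current` (any smaller split of `target` is
#' present in `current`, and singletons always are). The move prunes the
#' smaller of the two (ties lexicographic) from `current` and regrafts it
#' on the edge connecting the other one to the rest of the tree, creating
#' an edge that induces A|B.
#'
#' Every split changed by this move separates A1 from A2 in `current` and
#' is therefore absent from `target`, while the created split A|B is
#' present in it, so the RF distance to `target` strictly decreases (by at
#' least 2, possibly more). Both facts are asserted at run time.
#'
#' @param current,target non-isomorphic [treetop] objects on the same leaf
#'   set.
#' @return a list with elements `move` (the [spr_move()]), `tree` (the
#'   result of applying it to `current`), and `split` (the canonical side
#'   of the newly created split).
#' @export
spr_strict_step <- function(current, target) {
  stopifnot(is_treetop(current), is_treetop(target))
  check_same_tips(current, target)
  if (is_isomorphic(current, target)) {
    stop("trees are isomorphic; no step needed", call. = FALSE)
  }
  absent <- target$splits[lengths(target$splits) > 1L &
                            !target$keys %in% current$keys]
  if (length(absent) == 0L) {
    stop("internal error: non-isomorphic trees with no absent split",
         call. = FALSE)
  }
  a <- pick_canonical_split(absent)
  ch <- clade_children(sides_both_of(target), a)
  ord <- order(lengths(ch),
               vapply(ch, side_key, character(1L)), method = "radix")
  a1 <- ch[[ord[1L]]]   # pruned: the smaller child clade
  a2 <- ch[[ord[2L]]]
  for (x in list(a1, a2)) {
    if (!side_key(canonical_side(x, current$tips)) %in% current$keys) {
      stop("internal error: minimality violated — clade {",
           paste(x, collapse = ","),
           "} of the target is not pendant in the current tree",
           call. = FALSE)
    }
  }
  rest <- setdiff(current$tips, a1)
  m <- spr_move(prune = a1, regraft = canonical_side_in(a2, rest))
  res <- apply_spr(current, m)
  akey <- side_key(canonical_side(a, current$tips))
  if (!akey %in% res$keys) {
    stop("internal error: SPR step failed to create the selected split",
         call. = FALSE)
  }
  if (rf_keys(res$keys, target$keys) >= rf_keys(current$keys, target$keys)) {
    stop("internal error: SPR step did not decrease the RF distance",
         call. = FALSE)
  }
  list(move = m, tree = res, split = a)
}

#' Strictly RF-decreasing path in the SPR graph
#'
#' Connects `t` to `r` by a sequence of SPR moves along which the RF
#' distance to `r` strictly decreases — by at least 2 — at every step, so
#' the path has at most `dRF(t, r) / 2` moves. Each step is produced by
#' [spr_strict_step()], which realizes a minimum-size missing split of the
#' target; shared splits are never broken along the way.
#'
#' @param t,r [treetop] objects on the same leaf set with at least 4
#'   leaves.
#' @return a [treepath] in mode `"spr_strict"` from `t` to `r`.
#' @examples
#' t <- read_newick("(a,(b,(c,(d,(e,f)))));")
#' r <- read_newick("(a,(c,(d,(e,(f,b)))));")
#' spr_strict_path(t, r)$rf_profile
#' @export
spr_strict_path <- function(t, r) {
  stopifnot(is_treetop(t), is_treetop(r))
  check_same_tips(t, r)
  if (length(t$tips) < 4L) {
    stop("paths require at least 4 leaves", call. = FALSE)
  }
  trees <- list(t)
  moves <- list()
  cur <- t
  bound <- rf_keys(t$keys, r$keys) %/% 2L + 1L
  for (i in seq_len(bound)) {
    if (is_isomorphic(cur, r)) break
    st <- spr_strict_step(cur, r)
    trees <- c(trees, list(st$tree))
    moves <- c(moves, list(st$move))
    cur <- st$tree
  }
  if (!is_isomorphic(cur, r)) {
    stop("internal error: SPR path did not reach the target within ",
         bound, " steps", call. = FALSE)
  }
  new_treepath(trees, moves, "spr_strict")
}
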