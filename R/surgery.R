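#' Collapse one side of a split to a single leaf
#'
#' Replaces the pendant subtree spanning one side of a non-trivial split
#' with a single fresh leaf. This is the reduction used by the recursive
#' NNI path construction: collapsing the same shared side in two trees
#' yields a smaller pair whose symmetric split-set differences are
#' unchanged. Every split of the result is a split of the input with the
#' collapsed side's members replaced by the fresh label.
#'
#' @param t a [treetop] object.
#' @param side character vector of labels: one side of a non-trivial split
#'   of `t` (either orientation).
#' @param fresh a single new leaf label, not present in `t`.
#' @return a [treetop] on `(X \ side) ∪ {fresh}` with
#'   `|X| - length(side) + 1` leaves.
#' @seealso [expand_leaf()], its inverse.
#' @export
collapse_side <- function(t, side, fresh) {
  stopifnot(is_treetop(t))
  check_labels(fresh)
  if (length(fresh) != 1L) stop("`fresh` must be a single label", call. = FALSE)
  if (fresh %in% t$tips) {
    stop("fresh label '", fresh, "' collides with an existing leaf",
         call. = FALSE)
  }
  side <- sort.int(side, method = "radix")
  if (length(side) < 2L || length(side) > length(t$tips) - 2L) {
    stop("`side` must be one side of a non-trivial split", call. = FALSE)
  }
  key <- side_key(canonical_side(side, t$tips))
  if (!key %in% t$keys) {
    stop("`side` is not a side of any split of the tree", call. = FALSE)
  }
  la <- length(side)
  sides <- vector("list", length(t$splits))
  m <- 0L
  for (u in t$splits) {
    v <- setdiff(t$tips, u)
    u_in <- all(u %in% side)
    v_in <- all(v %in% side)
    if (u_in && length(u) == la) {
      m <- m + 1L; sides[[m]] <- fresh      # the collapsed split itself
    } else if (v_in && length(v) == la) {
      m <- m + 1L; sides[[m]] <- u          # same split, other orientation
    } else if (u_in || v_in) {
      next                                  # edge inside the collapsed subtree
    } else if (all(side %in% u)) {
      m <- m + 1L; sides[[m]] <- c(setdiff(u, side), fresh)
    } else {
      m <- m + 1L; sides[[m]] <- u          # side lies in the complement of u
    }
  }
  new_treetop(c(setdiff(t$tips, side), fresh), sides[seq_len(m)])
}

#' Pendant subtrees with an attachment handle
#'
#' [induced_subtree()] extracts the subtree of `t` spanning a leaf subset
#' `a` that hangs off a single edge (a *pendant* subtree: `a` must be one
#' side of a split of `t`). The result is a `pendant` object: the leaf set
#' together with the rooted clade structure below the attachment point,
#' which is exactly what is needed to re-attach the subtree elsewhere.
#'
#' @param t a [treetop] object.
#' @param a non-empty proper subset of the leaf set of `t`, forming one
#'   side of a split (a single leaf always qualifies).
#' @return a `pendant` object with fields `tips` and `clades` (the proper
#'   sub-sides of `a` in `t`, i.e. the clades of the rooted subtree).
#' @seealso [expand_leaf()]
#' @export
induced_subtree <- function(t, a) {
  stopifnot(is_treetop(t))
  a <- sort.int(unique(a), method = "radix")
  if (length(a) == 0L || length(a) >= length(t$tips)) {
    stop("`a` must be a non-empty proper subset of the leaf set",
         call. = FALSE)
  }
  if (!all(a %in% t$tips)) stop("`a` contains unknown labels", call. = FALSE)
  if (length(a) > 1L) {
    key <- side_key(canonical_side(a, t$tips))
    if (!key %in% t$keys) {
      stop("`a` does not hang off a single edge of the tree ",
           "(not one side of a split)", call. = FALSE)
    }
  }
  la <- length(a)
  clades <- Filter(function(s) length(s) < la && all(s %in% a),
                   sides_both_of(t))
  new_pendant(a, clades)
}

new_pendant <- function(tips, clades) {
  structure(list(tips = sort.int(tips, method = "radix"), clades = clades),
            class = "pendant")
}

#' @export
print.pendant <- function(x, ...) {
  cat("Pendant subtree on {", paste(x$tips, collapse = ", "),
      "} (attached at its root)\n", sep = "")
  invisible(x)
}

#' Expand a leaf into a pendant subtree
#'
#' Replaces a single leaf of `t` by a pendant subtree: the inverse of
#' [collapse_side()]. The split set of the result is the split set of `t`
#' with the leaf replaced by the subtree's leaf set in every split, plus
#' the internal splits of the subtree. Symmetric differences of split sets
#' are preserved under this substitution, which is the property the
#' recursive path constructions rely on: expanding the same leaf with the
#' same subtree in two trees leaves their RF distance unchanged.
#'
#' @param t a [treetop] object.
#' @param leaf a leaf label of `t`.
#' @param sub a `pendant` object (see [induced_subtree()]) whose labels are
#'   disjoint from the other leaves of `t`.
#' @return a [treetop] on `(X \ {leaf}) ∪ tips(sub)`.
#' @export
expand_leaf <- function(t, leaf, sub) {
  stopifnot(is_treetop(t), inherits(sub, "pendant"))
  if (length(leaf) != 1L || !leaf %in% t$tips) {
    stop("`leaf` must be a single leaf of the tree", call. = FALSE)
  }
  keep <- setdiff(t$tips, leaf)
  clash <- intersect(sub$tips, keep)
  if (length(clash) > 0L) {
    stop("subtree labels collide with existing leaves: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  subst <- lapply(t$splits, function(u) {
    if (leaf %in% u) c(setdiff(u, leaf), sub$tips) else u
  })
  new_treetop(c(keep, sub$tips), c(subst, sub$clades))
}
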