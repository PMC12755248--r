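#' Insert a new leaf on an edge
#'
#' Subdivides the edge inducing the given split with a new node and
#' attaches a new leaf there. This is the elementary step behind both
#' exhaustive enumeration and uniform random generation: a tree on `k`
#' leaves has `2k - 3` edges, and attaching leaf `k + 1` to each edge of
#' each tree on `k` leaves produces every tree on `k + 1` leaves exactly
#' once.
#'
#' @param t a [treetop] object.
#' @param edge one side (either orientation) of a split of `t`.
#' @param label the new leaf label.
#' @return a [treetop] with one more leaf.
#' @export
insert_leaf <- function(t, edge, label) {
  stopifnot(is_treetop(t))
  check_labels(label)
  if (length(label) != 1L) stop("`label` must be a single label", call. = FALSE)
  if (label %in% t$tips) {
    stop("label '", label, "' already present", call. = FALSE)
  }
  e <- canonical_side(sort.int(edge, method = "radix"), t$tips)
  ekey <- side_key(e)
  if (!ekey %in% t$keys) stop("`edge` is not an edge of the tree",
                              call. = FALSE)
  e2 <- setdiff(t$tips, e)
  sides <- list(label, e, e2)   # new pendant plus the two halves of `edge`
  for (i in seq_along(t$splits)) {
    if (t$keys[i] == ekey) next
    u <- t$splits[[i]]
    v <- setdiff(t$tips, u)
    sides <- c(sides, if (side_contains_edge(u, e, e2)) {
      list(c(u, label))
    } else {
      list(u)
    })
  }
  new_treetop(c(t$tips, label), sides)
}

#' Three-leaf star tree
#'
#' The unique (trivially binary) unrooted topology on three leaves: a
#' single internal node adjacent to all three.
#'
#' @param labels exactly three distinct labels.
#' @return a [treetop] object.
#' @export
star3 <- function(labels) {
  check_labels(labels)
  if (length(labels) != 3L) stop("need exactly 3 labels", call. = FALSE)
  new_treetop(labels, as.list(labels))
}

#' Enumerate all unrooted binary topologies
#'
#' Builds the complete catalog of unrooted binary trees on the given
#' labels by stepwise leaf insertion: every tree on `k` leaves receives
#' the next leaf on each of its `2k - 3` edges, which produces every
#' `(k+1)`-leaf topology exactly once. The catalog size is the double
#' factorial `(2n - 5)!!`: 3 trees for n = 4, 15 for n = 5, 105 for n = 6,
#' 945 for n = 7.
#'
#' @param labels ordered character vector of 3 to 9 distinct leaf labels
#'   (the upper bound keeps the catalog of practical size).
#' @return an object of class `treespace_catalog`: a list with
#'   `labels` and `trees` (a list of [treetop] objects, pairwise
#'   non-isomorphic).
#' @examples
#' length(enumerate_trees(letters[1:6])$trees)  # 105
#' @export
enumerate_trees <- function(labels) {
  check_labels(labels)
  n <- length(labels)
  if (n < 3L || n > 9L) {
    stop("enumeration supports 3 to 9 leaves, got ", n, call. = FALSE)
  }
  trees <- list(star3(labels[1:3]))
  if (n > 3L) {
    for (k in 4:n) {
      nxt <- vector("list", length(trees) * (2L * (k - 1L) - 3L))
      j <- 0L
      for (tr in trees) {
        for (e in tr$splits) {
          j <- j + 1L
          nxt[[j]] <- insert_leaf(tr, e, labels[k])
        }
      }
      trees <- nxt
    }
  }
  structure(list(labels = labels, trees = trees),
            class = "treespace_catalog")
}

#' @export
print.treespace_catalog <- function(x, ...) {
  cat("Treespace catalog: ", length(x$trees),
      " unrooted binary trees on {",
      paste(x$labels, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Graph distance in a rearrangement graph
#'
#' Length of a shortest path between two trees in the NNI or SPR graph,
#' computed by breadth-first search with canonical deduplication of
#' visited topologies. Computing these distances is NP-hard in general;
#' this oracle is deliberately restricted to small trees (`n <= 7`) where
#' exhaustive search is feasible.
#'
#' @param t,r [treetop] objects on the same leaf set of at most 7 leaves.
#' @param move_kind `"nni"` or `"spr"`.
#' @return a non-negative integer.
#' @export
graph_distance <- function(t, r, move_kind = c("nni", "spr")) {
  move_kind <- match.arg(move_kind)
  stopifnot(is_treetop(t), is_treetop(r))
  check_same_tips(t, r)
  if (length(t$tips) > 7L) {
    stop("graph distances are only computed exhaustively for n <= 7",
         call. = FALSE)
  }
  target <- tree_key(r)
  if (tree_key(t) == target) return(0L)
  nbfun <- if (move_kind == "nni") nni_neighbors else spr_neighbors
  frontier <- list(t)
  visited <- tree_key(t)
  depth <- 0L
  repeat {
    depth <- depth + 1L
    nxt <- list()
    for (x in frontier) {
      for (nb in nbfun(x)) {
        k <- tree_key(nb)
        if (k == target) return(depth)
        if (!k %in% visited) {
          visited <- c(visited, k)
          nxt <- c(nxt, list(nb))
        }
      }
    }
    if (length(nxt) == 0L) {
      stop("internal error: rearrangement graph is connected; BFS exhausted",
           call. = FALSE)
    }
    frontier <- nxt
  }
}

#' Search for pairs with no strictly RF-decreasing NNI step
#'
#' Exhaustively scans all ordered pairs (T, R) of trees on `n` leaves and
#' returns those for which T is not isomorphic to R and *no* NNI neighbor
#' of T is strictly closer to R (in RF distance) than T itself. From any
#' such T, a strictly RF-decreasing NNI path to R cannot even begin, which
#' certifies that strictly decreasing NNI paths do not exist in general.
#' Such pairs exist for n = 6 (all of them at the maximum RF distance
#' 2(n-3) = 6, with every neighbor of T also at distance 6), while for
#' n = 4 the search is empty: any two distinct quartets are NNI-adjacent,
#' so a strict step always exists.
#'
#' @param n leaf count, between 4 and 7.
#' @param labels optional labels (defaults to the first `n` letters).
#' @return a list of records, each with elements `t`, `r` ([treetop]
#'   objects), `rf` (their RF distance) and `neighbor_rf` (integer vector
#'   of RF distances from each NNI neighbor of `t` to `r`).
#' @export
find_nni_counterexamples <- function(n, labels = NULL) {
  n <- as.integer(n)
  if (n < 4L || n > 7L) {
    stop("counterexample search supports 4 <= n <= 7", call. = FALSE)
  }
  if (is.null(labels)) labels <- letters[seq_len(n)]
  cat_ <- enumerate_trees(labels)
  trees <- cat_$trees
  keysets <- lapply(trees, `[[`, "keys")
  nb_keysets <- lapply(trees, function(tr) {
    lapply(nni_neighbors(tr), `[[`, "keys")
  })
  out <- list()
  for (i in seq_along(trees)) {
    for (j in seq_along(trees)) {
      if (i == j) next
      d <- rf_keys(keysets[[i]], keysets[[j]])
      nd <- vapply(nb_keysets[[i]], rf_keys, integer(1L), k2 = keysets[[j]])
      if (all(nd >= d)) {
        out <- c(out, list(list(t = trees[[i]], r = trees[[j]], rf = d,
                                neighbor_rf = nd)))
      }
    }
  }
  out
}
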