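# Internal split-set primitives.
#
# A tree is represented by its split set: every edge of an unrooted binary
# tree on leaf set X induces a bipartition A|B of X, and the set of all
# 2n - 3 such bipartitions determines the tree uniquely. Each split is
# stored as its canonical side: the smaller side, ties broken by taking the
# side that contains the lexicographically smallest leaf label. Sides are
# sorted character vectors; keys are the sides pasted with "|" (labels are
# validated never to contain that character).

.label_regex <- "^[A-Za-z0-9_.-]+$"

check_labels <- function(labels) {
  if (length(labels) == 0L) {
    stop("tree has no leaf labels", call. = FALSE)
  }
  bad <- labels[!grepl(.label_regex, labels)]
  if (length(bad) > 0L) {
    stop("invalid leaf label(s): ", paste(unique(bad), collapse = ", "),
         " (allowed characters: A-Za-z0-9_.-)", call. = FALSE)
  }
  dup <- unique(labels[duplicated(labels)])
  if (length(dup) > 0L) {
    stop("duplicate leaf label(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  invisible(labels)
}

side_key <- function(side) paste(side, collapse = "|")

# Canonical orientation of the split {side, tips \ side}.
canonical_side <- function(side, tips) {
  side <- sort.int(side, method = "radix")
  canonical_side_sorted(side, tips)
}

# same, for a side already sorted in C (radix) order; complements of the
# sorted tip vector are computed without re-sorting
canonical_side_sorted <- function(side, tips) {
  n <- length(tips)
  k <- length(side)
  if (2L * k < n) return(side)
  other <- setdiff(tips, side)
  if (2L * k > n) return(other)
  # tie: the side holding the smallest label overall
  if (tips[1L] %in% side) side else other
}

split_size <- function(side) length(side)  # canonical side is the smaller one

is_trivial_side <- function(side) length(side) == 1L

# Two splits (given as one side each, same universe) are compatible iff one
# of the four intersections of sides/complements is empty, i.e. the sides
# are nested or disjoint (as sides or complements).
splits_compatible <- function(u, v, tips) {
  if (!any(u %in% v)) return(TRUE)                     # u ∩ v = 0
  if (all(u %in% v) || all(v %in% u)) return(TRUE)     # nested
  length(u) + length(v) - sum(u %in% v) == length(tips) # u ∪ v = X
}

# TRUE iff the edge inducing split {f1, f2} (a partition of the current
# universe) lies inside the component of leaves `u` obtained by cutting
# another edge of the same tree.
side_contains_edge <- function(u, f1, f2) {
  (length(f1) < length(u) && all(f1 %in% u)) ||
    (length(f2) < length(u) && all(f2 %in% u))
}

# The two subtrees hanging below a clade: among all sides (either
# orientation) strictly inside `a`, the two maximal ones, which partition a.
# Returns them ordered by their key.
clade_children <- function(sides_both, a) {
  la <- length(a)
  best <- NULL
  for (s in sides_both) {
    if (length(s) < la && all(s %in% a)) {
      if (is.null(best) || length(s) > length(best)) best <- s
    }
  }
  if (is.null(best)) stop("clade has no proper sub-sides", call. = FALSE)
  other <- setdiff(a, best)
  ch <- list(best, other)
  if (side_key(other) < side_key(best)) ch <- list(other, best)
  ch
}

# All sides in both orientations: canonical sides plus their complements.
sides_both_of <- function(t) {
  c(t$splits, lapply(t$splits, function(s) setdiff(t$tips, s)))
}

# Restrict the split set of `t` to the leaf subset `s` (the split set of the
# induced subtree with degree-2 vertices suppressed). Returns a list of
# pairs (u, v) partitioning sort(s), deduplicated.
restrict_pairs <- function(t, s) {
  s <- sort.int(s, method = "radix")
  out <- vector("list", length(t$splits))
  keys <- character(length(t$splits))
  m <- 0L
  for (sp in t$splits) {
    u <- sp[sp %in% s]
    if (length(u) == 0L || length(u) == length(s)) next
    v <- setdiff(s, u)
    cs <- if (2L * length(u) < length(s)) u
          else if (2L * length(u) > length(s)) v
          else if (s[1L] %in% u) u else v
    k <- side_key(cs)
    if (k %in% keys[seq_len(m)]) next
    m <- m + 1L
    out[[m]] <- list(u = u, v = v, key = k)
    keys[m] <- k
  }
  out[seq_len(m)]
}
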