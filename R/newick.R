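#' Read a tree from a Newick string
#'
#' Parses a single semicolon-terminated Newick statement into a [treetop].
#' Branch lengths and internal node labels are accepted and discarded: the
#' package deals with topologies only. A rooted bifurcation at the top level
#' is accepted and unrooted by suppressing the root; the usual unrooted
#' encoding with a top-level trifurcation is accepted as-is. Any remaining
#' node of degree 2, or any node of degree greater than 3, is rejected:
#' only fully resolved (binary) unrooted trees are supported.
#'
#' @param text a Newick string, e.g. `"((a,b),(c,d));"`.
#' @return a [treetop] object.
#' @examples
#' t <- read_newick("((a,b),(c,d));")
#' write_newick(t)
#' @seealso [write_newick()], [read_newick_lines()]
#' @export
read_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    stop("expected a single non-empty Newick string", call. = FALSE)
  }
  ph <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) NULL
  )
  if (is.null(ph) || !inherits(ph, "phylo")) {
    stop("could not parse Newick input: ", trimws(text), call. = FALSE)
  }
  as_treetop_phylo(ph)
}

# Convert an ape "phylo" object to a treetop, enforcing binary unrootedness.
as_treetop_phylo <- function(ph) {
  labs <- ph$tip.label
  check_labels(labs)
  n <- length(labs)
  if (n < 3L) {
    stop("trees must have at least 3 leaves, got ", n, call. = FALSE)
  }
  if (ape::is.rooted(ph)) ph <- ape::unroot(ph)
  deg <- tabulate(ph$edge, nbins = n + ph$Nnode)
  internal <- (n + 1L):(n + ph$Nnode)
  if (any(deg[internal] == 2L)) {
    stop("tree has an unresolved degree-2 node; only binary trees are supported",
         call. = FALSE)
  }
  if (any(deg[internal] != 3L)) {
    stop("tree is not binary: internal node of degree ",
         max(deg[internal]), call. = FALSE)
  }
  if (any(deg[seq_len(n)] != 1L)) {
    stop("malformed tree: labeled node of degree > 1", call. = FALSE)
  }
  if (nrow(ph$edge) != 2L * n - 3L) {
    stop("malformed tree: expected ", 2L * n - 3L, " edges, found ",
         nrow(ph$edge), call. = FALSE)
  }
  ph <- ape::reorder.phylo(ph, "postorder")
  desc <- vector("list", n + ph$Nnode)
  desc[seq_len(n)] <- as.list(labs)
  for (i in seq_len(nrow(ph$edge))) {
    p <- ph$edge[i, 1L]
    ch <- ph$edge[i, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  sides <- lapply(seq_len(nrow(ph$edge)), function(i) desc[[ph$edge[i, 2L]]])
  new_treetop(labs, sides)
}

#' Write a tree as a canonical Newick string
#'
#' Serializes a [treetop] to a deterministic Newick string: the tree is
#' written as a trifurcation rooted at the internal node adjacent to the
#' lexicographically smallest leaf, with siblings everywhere ordered by
#' their smallest descendant label. Isomorphic trees therefore always
#' produce byte-identical strings, and `read_newick(write_newick(t))` is
#' isomorphic to `t`.
#'
#' @param t a [treetop] object.
#' @return a Newick string (semicolon-terminated, no branch lengths).
#' @export
write_newick <- function(t) {
  stopifnot(is_treetop(t))
  tips <- t$tips
  x0 <- tips[1L]
  # clades: for each split, the side away from x0
  clades <- lapply(t$splits, function(s) {
    if (x0 %in% s) setdiff(tips, s) else s
  })
  render <- function(a) {
    if (length(a) == 1L) return(a)
    ch <- clade_children(clades, a)
    if (ch[[1L]][1L] > ch[[2L]][1L]) ch <- ch[c(2L, 1L)]
    paste0("(", render(ch[[1L]]), ",", render(ch[[2L]]), ")")
  }
  rest <- setdiff(tips, x0)
  ch <- clade_children(clades, rest)
  if (ch[[1L]][1L] > ch[[2L]][1L]) ch <- ch[c(2L, 1L)]
  paste0("(", x0, ",", render(ch[[1L]]), ",", render(ch[[2L]]), ");")
}

#' Read and write Newick-per-line tree lists
#'
#' Plain-text multi-tree files hold one semicolon-terminated Newick string
#' per line; this is the interchange format used for path output.
#'
#' @param path file path.
#' @param trees a list of [treetop] objects.
#' @return `read_newick_lines()` returns a list of [treetop] objects;
#'   `write_newick_lines()` returns `path` invisibly.
#' @export
read_newick_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, read_newick)
}

#' @rdname read_newick_lines
#' @export
write_newick_lines <- function(trees, path) {
  writeLines(vapply(trees, write_newick, character(1L)), con = path)
  invisible(path)
}
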