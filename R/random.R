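#' Seeded uniform random topology
#'
#' Draws an unrooted binary topology uniformly from all `(2n - 5)!!`
#' topologies on the given labels, by sequential leaf attachment: starting
#' from the 3-leaf star on the first three labels, each subsequent leaf is
#' attached to an edge chosen uniformly at random. Since a tree on `k`
#' leaves has `2k - 3` edges and every topology arises from exactly one
#' insertion sequence, the draw is exactly uniform.
#'
#' @param labels ordered character vector of at least 3 distinct labels,
#'   or a single integer `n >= 3` (labels then default to `t1 ... tn`).
#' @param seed optional integer; when supplied, the draw is a
#'   deterministic function of the seed (the caller's RNG state is left
#'   untouched). When `NULL`, the current RNG stream is used.
#' @return a [treetop] object.
#' @examples
#' is_isomorphic(random_tree(6, seed = 1), random_tree(6, seed = 1))
#' @export
random_tree <- function(labels, seed = NULL) {
  if (is.numeric(labels) && length(labels) == 1L) {
    labels <- paste0("t", seq_len(as.integer(labels)))
  }
  check_labels(labels)
  n <- length(labels)
  if (n < 3L) stop("random trees need at least 3 leaves", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  t <- star3(labels[1:3])
  for (k in seq_len(n)[-(1:3)]) {
    e <- t$splits[[sample.int(length(t$splits), 1L)]]
    t <- insert_leaf(t, e, labels[k])
  }
  t
}
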