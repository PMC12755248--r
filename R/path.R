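#' Tree rearrangement paths
#'
#' A `treepath` is a sequence of trees `[T0, ..., Tk]` together with the
#' moves connecting consecutive entries and the profile of RF distances
#' from each tree to the final one. Paths come in two modes:
#' `"nni_monotone"` (consecutive trees NNI-adjacent, RF profile
#' non-increasing) and `"spr_strict"` (consecutive trees one SPR move
#' apart, RF profile strictly decreasing by at least 2 per step).
#'
#' @param x a `treepath`.
#' @param ... unused.
#' @name treepath
NULL

new_treepath <- function(trees, moves, mode) {
  stopifnot(is.list(trees), length(trees) >= 1L,
            length(moves) == length(trees) - 1L,
            mode %in% c("nni_monotone", "spr_strict"))
  target <- trees[[length(trees)]]
  profile <- vapply(trees, function(x) rf_keys(x$keys, target$keys),
                    integer(1L))
  structure(list(trees = trees, moves = moves, mode = mode,
                 rf_profile = profile),
            class = "treepath")
}

#' @rdname treepath
#' @export
print.treepath <- function(x, ...) {
  cat("Tree rearrangement path (", x$mode, "), ",
      length(x$trees) - 1L, " move(s), ", length(x$trees[[1L]]$tips),
      " leaves\n", sep = "")
  cat("RF profile to target:", paste(x$rf_profile, collapse = " "), "\n")
  invisible(x)
}

#' @rdname treepath
#' @export
path_length <- function(x) {
  stopifnot(inherits(x, "treepath"))
  length(x$trees) - 1L
}

concat_paths <- function(p1, p2, mode) {
  stopifnot(is_isomorphic(p1$trees[[length(p1$trees)]], p2$trees[[1L]]))
  new_treepath(c(p1$trees, p2$trees[-1L]), c(p1$moves, p2$moves), mode)
}

#' Path provenance table
#'
#' Summarizes a path as a data frame: one row per tree with the step
#' index, the Newick string, the type and description of the move leading
#' into the tree, and the RF distance to the final tree.
#'
#' @param p a [treepath].
#' @return a `data.frame` with columns `step`, `newick`, `move`, `rf_to_target`.
#' @export
path_table <- function(p) {
  stopifnot(inherits(p, "treepath"))
  fmt_move <- function(m) {
    if (inherits(m, "nni_move")) {
      paste0("NNI edge={", paste(m$edge, collapse = ","), "} swap=", m$choice)
    } else if (inherits(m, "spr_move")) {
      paste0("SPR prune={", paste(m$prune, collapse = ","),
             "} regraft={", paste(m$regraft, collapse = ","), "}")
    } else if (inherits(m, "tbr_move")) {
      paste0("TBR bisect={", paste(m$bisect, collapse = ","), "}")
    } else {
      "?"
    }
  }
  data.frame(
    step = seq_along(p$trees) - 1L,
    newick = vapply(p$trees, write_newick, character(1L)),
    move = c("", vapply(p$moves, fmt_move, character(1L))),
    rf_to_target = p$rf_profile,
    stringsAsFactors = FALSE
  )
}

#' Validate a tree rearrangement path
#'
#' Checks every invariant a constructed path must satisfy: consecutive
#' trees are distinct and adjacent under the rearrangement of the given
#' mode, recorded moves (when present) reproduce the next tree exactly,
#' and the RF profile to the final tree is non-increasing
#' (`"nni_monotone"`) or strictly decreasing by at least 2 per step
#' (`"spr_strict"`) and ends at 0.
#'
#' NNI adjacency is checked with the contraction-based oracle
#' [is_nni_adjacent()], independently of any recorded moves. SPR adjacency
#' is checked by re-applying the recorded move (or, with
#' `neighborhoods = TRUE` or when moves are absent, by full membership in
#' [spr_neighbors()], which is feasible for small trees only).
#'
#' @param p a [treepath] (or any list with a `trees` element containing
#'   [treetop] objects, in which case `moves` may be missing).
#' @param mode `"nni_monotone"` or `"spr_strict"`; defaults to the path's
#'   own mode.
#' @param neighborhoods check SPR adjacency by exhaustive neighborhood
#'   membership instead of move re-application.
#' @return an object of class `treepath_validation`: a list with `ok`
#'   (overall), per-step logical vectors `adjacent` and `moves_ok`, the
#'   profile checks `profile_monotone`, `profile_strict` (mode-dependent),
#'   `ends_at_zero`, and `first_violation` (the first failing step index,
#'   or `NA`).
#' @export
validate_path <- function(p, mode = NULL,
                          neighborhoods = FALSE) {
  trees <- p$trees
  moves <- p$moves
  if (is.null(mode)) mode <- p$mode
  stopifnot(mode %in% c("nni_monotone", "spr_strict"),
            is.list(trees), length(trees) >= 1L)
  k <- length(trees) - 1L
  target <- trees[[length(trees)]]
  profile <- vapply(trees, function(x) rf_keys(x$keys, target$keys),
                    integer(1L))
  distinct <- adjacent <- moves_ok <- rep(TRUE, max(k, 0L))
  have_moves <- !is.null(moves) && length(moves) == k
  for (i in seq_len(k)) {
    a <- trees[[i]]
    b <- trees[[i + 1L]]
    distinct[i] <- !is_isomorphic(a, b)
    if (have_moves) {
      res <- tryCatch({
        m <- moves[[i]]
        applied <- if (inherits(m, "nni_move")) apply_nni(a, m)
                   else if (inherits(m, "spr_move")) apply_spr(a, m)
                   else if (inherits(m, "tbr_move")) apply_tbr(a, m)
                   else stop("unknown move type")
        is_isomorphic(applied, b)
      }, error = function(e) FALSE)
      moves_ok[i] <- isTRUE(res)
    }
    adjacent[i] <- if (mode == "nni_monotone") {
      is_nni_adjacent(a, b)
    } else if (neighborhoods || !have_moves) {
      kb <- tree_key(b)
      any(vapply(spr_neighbors(a), function(x) tree_key(x) == kb,
                 logical(1L)))
    } else {
      # one SPR apart, witnessed by the recorded move (NNI moves count:
      # every NNI move is an SPR move)
      moves_ok[i] && distinct[i]
    }
  }
  steps_rf_ok <- if (k == 0L) logical(0L) else {
    if (mode == "spr_strict") diff(profile) <= -2L else diff(profile) <= 0L
  }
  ends_at_zero <- profile[length(profile)] == 0L
  step_ok <- distinct & adjacent & moves_ok & steps_rf_ok
  first_violation <- if (all(step_ok)) NA_integer_ else which(!step_ok)[1L]
  structure(list(
    ok = all(step_ok) && ends_at_zero,
    mode = mode,
    n_steps = k,
    rf_profile = profile,
    distinct = distinct,
    adjacent = adjacent,
    moves_ok = moves_ok,
    rf_step_ok = steps_rf_ok,
    ends_at_zero = ends_at_zero,
    first_violation = first_violation
  ), class = "treepath_validation")
}

#' @export
print.treepath_validation <- function(x, ...) {
  cat("Path validation (", x$mode, "): ",
      if (x$ok) "PASS" else "FAIL", "\n", sep = "")
  cat("  steps: ", x$n_steps, "; RF profile: ",
      paste(x$rf_profile, collapse = " "), "\n", sep = "")
  if (!x$ok) {
    if (!is.na(x$first_violation)) {
      cat("  first violated step:", x$first_violation, "\n")
    }
    if (!x$ends_at_zero) cat("  profile does not end at 0\n")
  }
  invisible(x)
}
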