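test_that("isomorphic inputs give the single-tree path", {
  t <- read_newick("(((a,b),c),(d,e));")
  r <- read_newick("((c,(b,a)),(e,d));")
  for (p in list(nni_monotone_path(t, r), spr_strict_path(t, r))) {
    expect_identical(path_length(p), 0L)
    expect_identical(p$rf_profile, 0L)
    expect_true(validate_path(p)$ok)
  }
})

test_that("distinct quartets are joined by a single NNI move", {
  q <- quartets()
  for (i in 1:3) {
    for (j in 1:3) {
      if (i == j) next
      p <- nni_monotone_path(q[[i]], q[[j]])
      expect_identical(path_length(p), 1L)
      expect_identical(p$rf_profile, c(2L, 0L))
      expect_true(validate_path(p)$ok)
    }
  }
})

test_that("monotone NNI paths hold on seeded random pairs of larger trees", {
  # 500 seeded pairs at n = 7 and 8, a few larger ones at n = 10
  sizes <- c(rep(7L, 250L), rep(8L, 250L), rep(10L, 15L))
  bad <- 0L
  for (idx in seq_along(sizes)) {
    n <- sizes[idx]
    t <- random_tree(n, seed = idx)
    r <- random_tree(n, seed = 5000L + idx)
    p <- nni_monotone_path(t, r)
    v <- validate_path(p, mode = "nni_monotone")
    if (!v$ok ||
        !is_isomorphic(p$trees[[1L]], t) ||
        !is_isomorphic(p$trees[[length(p$trees)]], r) ||
        # no construction-helper labels may survive in emitted trees
        !all(vapply(p$trees, function(x) identical(x$tips, t$tips),
                    logical(1L)))) {
      bad <- bad + 1L
    }
  }
  expect_identical(bad, 0L)
})

test_that("a pair differing on one side keeps the other side untouched", {
  # both trees contain the split {a,b,c,d} | {e,f,g}; they agree on the
  # {e,f,g} side and differ inside {a,b,c,d}
  t <- read_newick("(((a,b),(c,d)),(e,(f,g)));")
  r <- read_newick("(((a,c),(b,d)),(e,(f,g)));")
  p <- shared_split_recursion(t, r, c("a", "b", "c", "d"))
  expect_true(validate_path(p, mode = "nni_monotone")$ok)
  # every split shared by the endpoints (the whole B side among them)
  # appears in every tree along the path
  shared <- intersect(vapply(tree_splits(t), paste, character(1L), collapse = "|"),
                      vapply(tree_splits(r), paste, character(1L), collapse = "|"))
  for (x in p$trees) {
    xk <- vapply(tree_splits(x), paste, character(1L), collapse = "|")
    expect_true(all(shared %in% xk))
  }
})

test_that("shared splits of the endpoints survive along both path kinds", {
  for (seed in 1:10) {
    t <- random_tree(9, seed = seed)
    r <- random_tree(9, seed = 900 + seed)
    shared <- intersect(t$keys, r$keys)
    for (p in list(nni_monotone_path(t, r), spr_strict_path(t, r))) {
      for (x in p$trees) {
        expect_true(all(shared %in% x$keys))
      }
    }
  }
})

test_that("cherry walk stays at maximum RF and then drops", {
  found <- 0L
  trees <- catalog6()$trees
  for (i in seq_len(30)) {
    for (j in seq_len(105)) {
      if (rf_distance(trees[[i]], trees[[j]]) != 6L) next
      found <- found + 1L
      cw <- cherry_walk(trees[[i]], trees[[j]])
      trace <- cw$rf_to_target
      k <- length(trace)
      expect_true(all(trace[-k] == 6L))
      expect_lt(trace[k], 6L)
      expect_true(validate_path(cw$prefix, mode = "nni_monotone")$ok ||
                    path_length(cw$prefix) == 0L)
      # the walk is bounded by the initial c1-c2 path length minus 2
      expect_lte(path_length(cw$prefix), 6L - 2L)
      if (found >= 120L) break
    }
    if (found >= 120L) break
  }
  expect_gt(found, 0L)
})

test_that("cherry walk refuses trees sharing a split", {
  t <- read_newick("(((a,b),c),(d,(e,f)));")
  expect_error(cherry_walk(t, t), "share")
})

test_that("SPR step converges in one move when one leaf is misplaced", {
  # b sits inside the cherry {a,b} of `cur` but belongs beside c in `tgt`
  cur <- read_newick("((((a,b),c),d),(e,f));")
  tgt <- read_newick("((((a,c),b),d),(e,f));")
  st <- spr_strict_step(cur, tgt)
  expect_true(is_isomorphic(st$tree, tgt))
})

test_that("SPR step decrease is exactly 2 when one split lies between", {
  # current: ((a,b),c) vs target cherry (a,c): the a-to-c path crosses one
  # changed split
  cur <- read_newick("(((a,b),c),(d,e));")
  tgt <- read_newick("(((a,c),b),(d,e));")
  st <- spr_strict_step(cur, tgt)
  expect_identical(rf_distance(cur, tgt) - rf_distance(st$tree, tgt), 2L)
})

test_that("an SPR step can resolve several splits at once", {
  # search seeded 8-leaf pairs for a step whose RF decrease exceeds 2,
  # i.e. a move through a multi-edge path between the two target clades
  # that repairs several splits simultaneously
  found <- FALSE
  for (seed in 1:60) {
    t <- random_tree(8, seed = seed)
    r <- random_tree(8, seed = 800 + seed)
    p <- spr_strict_path(t, r)
    if (any(diff(p$rf_profile) <= -4L)) {
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("strict SPR paths hold on seeded random pairs up to n = 30", {
  for (n in c(6, 10, 20, 30)) {
    for (seed in 1:10) {
      t <- random_tree(n, seed = seed)
      r <- random_tree(n, seed = 700 + seed)
      p <- spr_strict_path(t, r)
      v <- validate_path(p)
      expect_true(v$ok)
      expect_lte(path_length(p), rf_distance(t, r) / 2)
      expect_true(is_isomorphic(p$trees[[length(p$trees)]], r))
      if (path_length(p) > 0L) {
        expect_true(all(diff(p$rf_profile) <= -2L))
      }
    }
  }
})

test_that("the validator reports the first violated step", {
  t <- random_tree(7, seed = 1)
  r <- random_tree(7, seed = 2)
  p <- nni_monotone_path(t, r)
  skip_if(path_length(p) < 3L)
  mutated <- p
  mutated$trees[[2L]] <- random_tree(7, seed = 99)
  v <- validate_path(mutated, mode = "nni_monotone")
  expect_false(v$ok)
  expect_identical(v$first_violation, 1L)
})

test_that("an SPR path fails NNI-mode validation where moves jump farther", {
  pair <- max_rf_pair(7)
  p <- spr_strict_path(pair$t, pair$r)
  skip_if(path_length(p) != 1L)
  v <- validate_path(p, mode = "nni_monotone")
  # profile is fine (strict implies weak) but the single move is not an NNI
  expect_true(all(v$rf_step_ok))
  expect_false(all(v$adjacent))
  expect_false(v$ok)
})

test_that("strict SPR paths double as TBR paths", {
  for (seed in 1:6) {
    t <- random_tree(6, seed = seed)
    r <- random_tree(6, seed = 60 + seed)
    p <- spr_strict_path(t, r)
    for (i in seq_len(path_length(p))) {
      tb <- rfpaths:::spr_as_tbr(p$trees[[i]], p$moves[[i]])
      expect_true(is_isomorphic(apply_tbr(p$trees[[i]], tb),
                                p$trees[[i + 1L]]))
    }
  }
})
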