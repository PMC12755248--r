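test_that("the two NNI swaps on a quartet give the other two topologies", {
  q <- quartets()
  got <- sort(c(write_newick(apply_nni(q[[1]], nni_move(c("a", "b"), 1))),
                write_newick(apply_nni(q[[1]], nni_move(c("a", "b"), 2)))))
  expect_identical(got, sort(c(write_newick(q[[2]]), write_newick(q[[3]]))))
})

test_that("NNI moves are involutions and change exactly one split", {
  for (seed in 1:5) {
    t <- random_tree(7, seed = seed)
    for (e in tree_splits(t, trivial = FALSE)) {
      for (ch in 1:2) {
        m <- nni_move(e, ch)
        r <- apply_nni(t, m)
        expect_identical(rf_distance(t, r), 2L)
        expect_true(is_isomorphic(apply_nni(r, nni_step_between(r, t)), t))
      }
    }
  }
})

test_that("every internal edge of every 6-leaf tree yields RF 2 under NNI", {
  for (t in catalog6()$trees) {
    for (nb in nni_neighbors(t)) {
      expect_identical(rf_distance(t, nb), 2L)
    }
  }
})

test_that("NNI moves on trivial or absent edges are rejected", {
  t <- read_newick("(((a,b),c),(d,e));")
  expect_error(apply_nni(t, nni_move("a", 1)), "internal")
  expect_error(apply_nni(t, nni_move(c("a", "c"), 1)), "not an edge")
})

test_that("neighborhood sizes are 2(n - 3), distinct, excluding self", {
  for (n in 4:7) {
    t <- random_tree(n, seed = n)
    nb <- nni_neighbors(t)
    expect_length(nb, 2L * (n - 3L))
    ids <- vapply(nb, tree_id, character(1L))
    expect_identical(anyDuplicated(ids), 0L)
    expect_false(tree_id(t) %in% ids)
  }
})

test_that("contraction oracle agrees with neighborhood membership at n=6", {
  trees <- catalog6()$trees
  nbk <- nni_nbkeys6()
  withr::with_seed(3, pick <- sample.int(105, 25))
  for (i in pick) {
    for (j in seq_len(105)) {
      expect_identical(is_nni_adjacent(trees[[i]], trees[[j]]),
                       tree_id(trees[[j]]) %in% nbk[[i]])
    }
  }
})

test_that("NNI adjacency is symmetric and irreflexive", {
  trees <- catalog6()$trees
  nbk <- nni_nbkeys6()
  for (i in seq_len(105)) {
    expect_false(tree_id(trees[[i]]) %in% nbk[[i]])
    for (k in nbk[[i]]) {
      j <- match(k, vapply(trees, tree_id, character(1L)))
      expect_true(tree_id(trees[[i]]) %in% nbk[[j]])
    }
  }
})

test_that("SPR can relocate a leaf across the tree, reaching max RF", {
  pair <- max_rf_pair(6)
  m <- spr_move(prune = "a", regraft = "f")
  moved <- apply_spr(pair$t, m)
  expect_true(is_isomorphic(moved, pair$r))
  expect_identical(rf_distance(pair$t, moved), 2L * (6L - 3L))
})

test_that("degenerate regrafts recreate the source tree", {
  t <- read_newick("(((a,b),c),(d,e));")
  # prune the cherry {a,b}; its flanking edges in the rest merge into the
  # edge separating c from {d,e}
  back <- apply_spr(t, spr_move(prune = c("a", "b"), regraft = "c"))
  expect_true(is_isomorphic(back, t))
  # and such moves are excluded from the neighborhood
  ids <- vapply(spr_neighbors(t), tree_id, character(1L))
  expect_false(tree_id(t) %in% ids)
})

test_that("SPR moves are validated", {
  t <- read_newick("(((a,b),c),(d,e));")
  expect_error(apply_spr(t, spr_move(c("a", "c"), "d")), "pendant")
  expect_error(apply_spr(t, spr_move(c("a", "b"), "a")), "component")
  expect_error(apply_spr(t, spr_move(t$tips[-1], "z")), "unknown|remaining")
})

test_that("rearrangement neighborhoods nest: NNI within SPR within TBR", {
  trees <- catalog6()$trees
  nbn <- nni_nbkeys6()
  nbs <- spr_nbkeys6()
  withr::with_seed(9, pick <- sample.int(105, 12))
  for (i in pick) {
    expect_true(all(nbn[[i]] %in% nbs[[i]]))
    tbrk <- vapply(tbr_neighbors(trees[[i]]), tree_id, character(1L))
    expect_true(all(nbs[[i]] %in% tbrk))
    expect_false(tree_id(trees[[i]]) %in% c(nbs[[i]], tbrk))
  }
})

test_that("quartets have identical NNI and SPR neighborhoods", {
  q <- quartets()
  for (t in q) {
    expect_setequal(vapply(spr_neighbors(t), tree_id, character(1L)),
                    vapply(nni_neighbors(t), tree_id, character(1L)))
    expect_length(spr_neighbors(t), 2L)
  }
})

test_that("every SPR move is expressible as a TBR move", {
  for (seed in c(2, 4)) {
    t <- random_tree(7, seed = seed)
    for (sp in tree_splits(t)) {
      for (p in list(sp, setdiff(t$tips, sp))) {
        s <- setdiff(t$tips, p)
        if (length(s) < 3L) next
        for (pr in rfpaths:::restrict_pairs(t, s)) {
          m <- spr_move(p, pr$u)
          expect_true(is_isomorphic(apply_spr(t, m),
                                    apply_tbr(t, rfpaths:::spr_as_tbr(t, m))))
        }
      }
    }
  }
})

test_that("TBR handles single-leaf components via NULL reattachment", {
  t <- read_newick("(((a,b),c),(d,e));")
  r <- apply_tbr(t, tbr_move("a", NULL, c("d", "e")))
  expect_no_error(validate_treetop(r))
  expect_error(apply_tbr(t, tbr_move("a", "a", c("d", "e"))), "no edges")
  expect_error(apply_tbr(t, tbr_move(c("a", "b"), NULL, NULL)), "required")
})
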