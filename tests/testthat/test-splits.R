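test_that("split counts follow 2n - 3 with n - 3 non-trivial", {
  # exhaustive at n = 4..6, seeded random at n = 7..12
  for (n in 4:6) {
    for (t in enumerate_trees(letters[seq_len(n)])$trees) {
      expect_length(tree_splits(t), 2L * n - 3L)
      expect_length(tree_splits(t, trivial = FALSE), n - 3L)
    }
  }
  for (n in 7:12) {
    t <- random_tree(n, seed = n)
    expect_length(tree_splits(t), 2L * n - 3L)
    expect_length(tree_splits(t, trivial = FALSE), n - 3L)
    expect_no_error(validate_treetop(t))
  }
})

test_that("all split pairs of a tree are pairwise compatible", {
  compat <- function(u, v, tips) {
    # brute force: some side of one nests in a side of the other or they
    # are disjoint
    uc <- setdiff(tips, u)
    vc <- setdiff(tips, v)
    any(length(intersect(u, v)) == 0L, length(intersect(u, vc)) == 0L,
        length(intersect(uc, v)) == 0L, length(intersect(uc, vc)) == 0L)
  }
  for (seed in 1:20) {
    t <- random_tree(8, seed = seed)
    sp <- tree_splits(t)
    for (i in seq_along(sp)) {
      for (j in seq_len(i - 1L)) {
        expect_true(compat(sp[[i]], sp[[j]], t$tips))
      }
    }
  }
})

test_that("tree_from_splits inverts tree_splits on all 5- and 6-leaf trees", {
  for (n in 5:6) {
    for (t in enumerate_trees(letters[seq_len(n)])$trees) {
      expect_true(is_isomorphic(tree_from_splits(tree_splits(t)), t))
    }
  }
})

test_that("incompatible or incomplete split sets are rejected", {
  t <- read_newick("((a,b),(c,d));")
  sp <- tree_splits(t)
  expect_error(tree_from_splits(sp[-1L]), "incomplete")
  # {a,b}|{c,d,e} and {a,c}|{b,d,e} cannot coexist in one tree
  bad <- c(as.list(letters[1:5]), list(c("a", "b"), c("a", "c")))
  expect_error(tree_from_splits(bad), "ncompatible")
})

test_that("RF distance is an even metric bounded by 2(n - 3)", {
  trees <- catalog6()$trees
  withr::with_seed(7, ids <- sample.int(105, 30))
  for (i in ids) {
    for (j in ids) {
      d <- rf_distance(trees[[i]], trees[[j]])
      expect_identical(d %% 2L, 0L)
      expect_lte(d, 6L)
      expect_identical(d, rf_distance(trees[[j]], trees[[i]]))
      expect_identical(d == 0L, is_isomorphic(trees[[i]], trees[[j]]))
    }
  }
  # triangle inequality on seeded random triples
  withr::with_seed(11, {
    for (rep in 1:2000) {
      ijk <- sample.int(105, 3L)
      a <- trees[[ijk[1]]]; b <- trees[[ijk[2]]]; c <- trees[[ijk[3]]]
      expect_lte(rf_distance(a, c),
                 rf_distance(a, b) + rf_distance(b, c))
    }
  })
})

test_that("RF on different leaf sets is an error, not a restriction", {
  expect_error(rf_distance(read_newick("((a,b),(c,d));"),
                           read_newick("((a,b),(c,e));")),
               "different leaf sets")
})

test_that("RF distance agrees with an independent implementation", {
  skip_if_not_installed("phangorn")
  for (seed in 1:30) {
    n <- c(8L, 16L, 32L)[(seed %% 3L) + 1L]
    a <- random_tree(n, seed = seed)
    b <- random_tree(n, seed = 1000L + seed)
    expect_identical(rf_distance(a, b),
                     as.integer(phangorn::RF.dist(as_phylo(a), as_phylo(b))))
  }
})

test_that("maximum RF distance is attained exactly without shared splits", {
  trees <- catalog6()$trees
  ks <- keys6()
  shared_nontrivial <- function(i, j) {
    st <- ks[[i]][lengths(trees[[i]]$splits) > 1L]
    sr <- ks[[j]][lengths(trees[[j]]$splits) > 1L]
    length(intersect(st, sr))
  }
  withr::with_seed(5, pick <- sample.int(105, 40))
  for (i in pick) {
    for (j in seq_len(105)) {
      d <- rf_distance(trees[[i]], trees[[j]])
      expect_identical(d == 6L,
                       i != j && shared_nontrivial(i, j) == 0L)
    }
  }
})
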