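test_that("JC distance matches the closed form and errors at saturation", {
  same <- new_alignment(c(a = "ACGTACGT", b = "ACGTACGT"))
  expect_equal(jc_distance(same, 1, 2), 0)
  ten <- new_alignment(c(a = strrep("A", 10), b = paste0("C", strrep("A", 9))))
  expect_equal(jc_distance(ten, 1, 2), -0.75 * log(1 - 0.4 / 3),
               tolerance = 1e-9)
  expect_equal(jc_distance(ten, 1, 2), 0.10732, tolerance = 1e-4)
  sat <- new_alignment(c(a = "AAAA", b = "CCCC"))
  expect_error(jc_distance(sat, 1, 2), "saturated")
})

test_that("NJ recovers the worked additive 4-taxon tree exactly", {
  # tree ((a:1,b:2):1,(c:3,d:4)): additive distances
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(D)
  truth <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:4):0);")
  expect_identical(tree_splits(tr), tree_splits(truth))
  expect_equal(sort(tr$edge.length), c(1, 1, 2, 3, 4), tolerance = 1e-9)
  # 3 taxa: forced topology, three-point branch lengths
  D3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- nj_tree(D3)
  expect_equal(sort(t3$edge.length), c(0.5, 1.5, 2.5), tolerance = 1e-9)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("RF distance matches the split-set oracle", {
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  t2 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(rf_distance(t1, t1), 0L)
  expect_equal(rf_distance(t1, t2), 2L)
  expect_error(rf_distance(t1, ape::read.tree(text = "((a,b),(c,e));")),
               "leaf set")
  set.seed(3)
  for (rep in 1:10) {
    x <- ape::rtree(8); y <- ape::rtree(8)
    y$tip.label <- sample(x$tip.label)
    expect_equal(rf_distance(x, y), oracle_rf(x, y))
  }
})

test_that("RF distance behaves as a metric on random trees", {
  set.seed(9)
  trees <- lapply(1:4, function(i) {
    tr <- ape::rtree(7)
    tr$tip.label <- paste0("s", 1:7)
    tr
  })
  for (i in 1:4) {
    expect_equal(rf_distance(trees[[i]], trees[[i]]), 0L)
    for (j in 1:4) {
      dij <- rf_distance(trees[[i]], trees[[j]])
      expect_equal(dij, rf_distance(trees[[j]], trees[[i]]))
      for (k in 1:4) {
        expect_lte(dij, rf_distance(trees[[i]], trees[[k]]) +
                     rf_distance(trees[[k]], trees[[j]]))
      }
    }
  }
})

test_that("SH-like support is 1 for a window's own tree and bounded", {
  aln <- simulate_tree_alignment(rand_tree(6, 61), 1200, seed = 61)
  own <- recscan:::window_nj(aln, c(1L, 600L))
  s_self <- sh_like_support(aln, c(1L, 600L), own, n_rell = 100, seed = 2)
  expect_equal(s_self, 1.0)
  other <- recscan:::window_nj(aln, c(601L, 1200L))
  s_other <- sh_like_support(aln, c(1L, 600L), other, n_rell = 100, seed = 2)
  expect_true(s_other >= 0 && s_other <= 1)
  expect_error(sh_like_support(aln, c(5L, 4L), own), "zero-length")
})

test_that("compatibility matrix contrasts recombinant and clean alignments", {
  clean <- simulate_tree_alignment(rand_tree(6, 62), 2000, seed = 62)
  sim <- simulate_recombination(
    CLADE_TREE6, 2000,
    data.frame(donor = "t4", acceptor = "t1", begin = 1L, end = 999L),
    seed = 63
  )
  cm_clean <- compatibility_matrix(clean, 500, 250, n_rell = 100, seed = 3)
  cm_rec <- compatibility_matrix(sim$aln, 500, 250, n_rell = 100, seed = 3)
  expect_equal(diag(cm_clean$matrix), rep(0, nrow(cm_clean$windows)))
  expect_identical(cm_clean$support, t(cm_clean$support))
  rf_lower <- function(cm) cm$rf[lower.tri(cm$rf)]
  expect_lte(stats::median(rf_lower(cm_clean), na.rm = TRUE),
             stats::median(rf_lower(cm_rec), na.rm = TRUE))
})

test_that("stripping removes or splits recombinant regions", {
  sim <- sim_triplet(81)
  ev <- tibble::tibble(event_id = 1L, recombinants = "R",
                       n_recombinants = 1L, begin = 300L, end = 699L)
  none <- strip_recombination(sim$aln, recscan:::empty_events(), "remove")
  expect_identical(none$mat, sim$aln$mat)
  rem <- strip_recombination(sim$aln, ev, "remove")
  expect_equal(aln_length(rem), aln_length(sim$aln))
  ri <- match("R", rem$names)
  expect_true(all(rem$mat[ri, 300:699] == "-"))
  expect_identical(rem$mat[ri, c(1:299, 700:1000)],
                   sim$aln$mat[match("R", sim$aln$names), c(1:299, 700:1000)])
  sp <- strip_recombination(sim$aln, ev, "split")
  expect_equal(n_seq(sp), n_seq(sim$aln) + 1L)
  expect_true(all(c("R_minor", "R_major") %in% sp$names))
  minor <- sp$mat[match("R_minor", sp$names), ]
  expect_true(all(minor[c(1:299, 700:1000)] == "-"))
  expect_error(strip_recombination(sim$aln,
                                   tibble::tibble(recombinants = "ghost",
                                                  begin = 1L, end = 10L),
                                   "remove"), "unknown sequence")
})
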