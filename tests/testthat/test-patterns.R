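test_that("breakpoint density counts windows containing each breakpoint", {
  bps <- new_breakpoint_set(500, 10000)
  d <- breakpoint_density(bps, 200, 1)
  hit <- d$count == 1L
  expect_true(all(d$start[hit] <= 500 & d$end[hit] >= 500))
  expect_true(all(d$count[!hit] == 0L))
  # empty set: all-zero series
  none <- new_breakpoint_set(numeric(0), 10000)
  expect_true(all(breakpoint_density(none, 200)$count == 0L))
  # non-overlapping windows conserve the breakpoint total
  set.seed(2)
  pos <- sample.int(9973, 57, replace = TRUE)
  d2 <- breakpoint_density(new_breakpoint_set(pos, 9973), 100)
  expect_equal(sum(d2$count), 57L)
  expect_error(new_breakpoint_set(c(1, 20000), 10000), "must lie")
})

test_that("hotspot test flags a strong implanted hotspot and nothing when empty", {
  set.seed(5)
  pos <- c(sample(4901:5000, 50, replace = TRUE),
           sample.int(10000, 50, replace = TRUE))
  hs <- hotspot_test(new_breakpoint_set(pos, 10000), 100, 1000, seed = 6)
  expect_true(hs$hot[hs$start == 4901])
  expect_true(all(hs$local_lo <= hs$perm_mean + 1e-9))
  expect_true(all(hs$local_hi >= hs$perm_mean - 1e-9))
  # no breakpoints: no calls
  hs0 <- hotspot_test(new_breakpoint_set(numeric(0), 10000), 100, 1000, 1)
  expect_false(any(hs0$hot) || any(hs0$cold))
  expect_error(hotspot_test(new_breakpoint_set(1, 100), 10, 99, 1), ">= 1000")
})

test_that("pair matrix conserves event counts and flags a repeated pair", {
  # all events share (begin, end) near one cell
  set.seed(7)
  ev <- tibble::tibble(begin = 1900L + sample(-20:20, 30, TRUE),
                       end = 4100L + sample(-20:20, 30, TRUE))
  pm <- breakpoint_pair_matrix(ev, 8000, n_bins = 20, n_permutations = 500,
                               seed = 8)
  expect_equal(sum(pm$counts), 30L)
  hot_cell <- which(pm$counts == max(pm$counts), arr.ind = TRUE)[1, ]
  expect_true(pm$flagged[hot_cell[1], hot_cell[2]])
  # no events: all-zero, no flags
  pm0 <- breakpoint_pair_matrix(tibble::tibble(begin = integer(),
                                               end = integer()),
                                8000, n_permutations = 100, seed = 1)
  expect_true(all(pm0$counts == 0L))
  expect_false(any(pm0$flagged))
})

test_that("region count matrix reflects fragment separation", {
  aln <- simulate_tree_alignment(rand_tree(5, 41), 1000, seed = 41)
  no_ev <- recscan:::empty_events()
  rc0 <- region_count_matrix(aln, no_ev, n_grid = 20, n_permutations = 0)
  expect_true(all(rc0$counts == n_seq(aln)))
  # one event in one sequence separates pairs straddling its breakpoints
  ev <- tibble::tibble(
    event_id = 1L, recombinants = aln$names[1], n_recombinants = 1L,
    begin = 300L, end = 699L
  )
  rc1 <- region_count_matrix(aln, ev, n_grid = 20, n_permutations = 50,
                             seed = 2)
  g <- rc1$grid
  inside <- g >= 300 & g <= 699
  outside_l <- g < 300
  expect_true(all(rc1$counts[outside_l, inside] == n_seq(aln) - 1L))
  expect_true(all(rc1$counts[inside, inside] == n_seq(aln)))
  # symmetry
  expect_identical(rc1$counts, t(rc1$counts))
  # adding an event can only reduce co-inheritance counts
  ev2 <- rbind(ev, tibble::tibble(event_id = 2L, recombinants = aln$names[2],
                                  n_recombinants = 1L, begin = 100L, end = 499L))
  rc2 <- region_count_matrix(aln, ev2, n_grid = 20, n_permutations = 0)
  expect_true(all(rc2$counts <= rc1$counts))
})

test_that("feature association distinguishes on-boundary from uniform breakpoints", {
  feats <- data.frame(begin = c(1000L, 5000L), end = c(2000L, 6000L))
  on_bounds <- new_breakpoint_set(c(1000, 2000, 5000, 6000), 10000)
  fa <- feature_association_test(on_bounds, feats, 999, seed = 3)
  expect_equal(fa$observed, 0)
  expect_lte(fa$p_association, 2 / 1000 + 1e-9)
  # single whole-genome feature: distances measured to its two ends
  whole <- data.frame(begin = 1L, end = 10000L)
  mid <- new_breakpoint_set(5000, 10000)
  fa2 <- feature_association_test(mid, whole, 199, seed = 4)
  expect_equal(fa2$observed, 4999)
  expect_equal(fa2$n_boundaries, 2L)
  expect_error(feature_association_test(mid, data.frame()[0, ], 100, 1),
               "non-empty")
})

test_that("permutation machinery is reproducible given the seed", {
  set.seed(11)
  pos <- sample.int(5000, 40, replace = TRUE)
  bps <- new_breakpoint_set(pos, 5000)
  h1 <- hotspot_test(bps, 100, 1000, seed = 21)
  h2 <- hotspot_test(bps, 100, 1000, seed = 21)
  expect_identical(tibble::as_tibble(h1), tibble::as_tibble(h2))
})
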