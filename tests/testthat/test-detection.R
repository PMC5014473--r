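test_that("binomial identity tail matches closed forms", {
  expect_equal(binomial_identity_p(10, 0, 0.5), 1.0)
  expect_equal(binomial_identity_p(1, 1, 0.25), 0.25)
  expect_equal(binomial_identity_p(10, 10, 0.5), 0.5^10)
  expect_error(binomial_identity_p(10, 5, 1), "strictly")
  expect_error(binomial_identity_p(10, 11, 0.5), "0 <= m <= l")
})

test_that("maxchi frame peak matches the worked 2x2 value and the oracle", {
  # 20 matches then 20 mismatches, window 20: single frame, chi-square 40,
  # peak at the first right-half site (1-based index 21)
  v <- c(rep(1L, 20), rep(0L, 20))
  pk <- recscan:::maxchi_peak_cpp(v, 20L)
  expect_equal(pk$stat, 40)
  expect_equal(pk$pos, 21L)
  # random vectors: exact equality with the exhaustive enumeration
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(30:120, 1)
    w <- sample(5:(n %/% 2), 1)
    v <- sample(0:1, n, replace = TRUE)
    pk <- recscan:::maxchi_peak_cpp(v, w)
    or <- oracle_maxchi(v, w)
    expect_equal(pk$stat, or$stat)
    expect_equal(pk$pos, or$pos)
  }
})

test_that("chimaera machinery treats A/B symbols like match/mismatch", {
  # "AAAABBBB" with window 4: single frame, chi-square 8, peak at centre
  v <- c(rep(1L, 4), rep(0L, 4))
  pk <- recscan:::maxchi_peak_cpp(v, 4L)
  expect_equal(pk$stat, 8)
  expect_equal(pk$pos, 5L)
})

test_that("maximum descent matches walk arithmetic and the quadratic oracle", {
  d <- max_descent(strsplit("AAABBBAAA", "")[[1]])
  expect_equal(d$stat, 3)
  expect_equal(c(d$from, d$to), c(4L, 6L))
  expect_equal(max_descent(rep("A", 10))$stat, 0)
  set.seed(11)
  for (rep in 1:20) {
    steps <- sample(c(-1L, 1L), sample(5:60, 1), replace = TRUE)
    got <- recscan:::maxdescent_cpp(steps)
    or <- oracle_descent_one(steps)
    expect_equal(got$stat, or$stat)
    expect_equal(c(got$from, got$to), c(or$from, or$to))
    # the scan-level orientation-symmetric statistic matches its oracle too
    gs <- recscan:::symdescent_cpp(steps)
    os <- oracle_maxdescent(steps)
    expect_equal(gs$stat, os$stat)
    expect_equal(c(gs$from, gs$to), c(os$from, os$to))
  }
})

test_that("scans decline degenerate triplets", {
  aln <- new_alignment(c(a = strrep("ACGT", 30), b = strrep("ACGT", 30),
                         c = strrep("ACGT", 30)))
  trip <- make_triplet(aln, 1:3)
  expect_null(rdp_scan(trip))
  expect_null(maxchi_scan(trip))
  expect_null(chimaera_scan(trip))
  expect_null(threeseq_scan(trip))
  expect_null(siscan_scan(trip, seed = 1))
})

test_that("every method detects a strongly implanted event on the triplet", {
  sim <- sim_triplet(21)
  trip <- make_triplet(sim$aln, match(c("R", "P1", "D"), sim$aln$names))
  set.seed(1)
  rdp <- rdp_scan(trip)
  expect_lt(rdp$p_raw, 1e-3)
  for (m in list(rdp, maxchi_scan(trip), chimaera_scan(trip),
                 siscan_scan(trip, seed = 2))) {
    expect_false(is.null(m))
    expect_equal(m$recombinant_name, "R")
    expect_equal(m$minor_parent, "D")
    expect_lt(m$p_raw, 0.01)
    # detected region overlaps the implanted one
    expect_gt(min(m$end, 699) - max(m$begin, 300), 0)
  }
  # the walk statistic flags the region; at three sequences its recombinant
  # attribution can legitimately land on either side of the mirror, so only
  # the region and the implicated pair are asserted
  ts <- threeseq_scan(trip)
  expect_false(is.null(ts))
  expect_lt(ts$p_raw, 0.01)
  expect_gt(min(ts$end, 699) - max(ts$begin, 300), 0)
  expect_true("R" %in% c(ts$recombinant_name, ts$minor_parent))
})

test_that("statistics are invariant under relabelling of the two parents", {
  sim <- sim_triplet(33)
  rows <- match(c("R", "P1", "D"), sim$aln$names)
  t1 <- make_triplet(sim$aln, rows)
  t2 <- make_triplet(sim$aln, rows[c(1L, 3L, 2L)]) # swap the parents
  # informative vector flips every symbol
  i1 <- informative_sites(t1, 1L); i2 <- informative_sites(t2, 1L)
  expect_identical(i1$pos, i2$pos)
  expect_identical(ifelse(i1$sym == "A", "B", "A"), i2$sym)
  set.seed(5); m1 <- maxchi_scan(t1)
  set.seed(5); m2 <- maxchi_scan(t2)
  expect_equal(m1$stat, m2$stat)
  expect_equal(c(m1$begin, m1$end), c(m2$begin, m2$end))
  expect_equal(recscan:::symdescent_cpp(ifelse(i1$sym == "A", 1L, -1L))$stat,
               recscan:::symdescent_cpp(ifelse(i2$sym == "A", 1L, -1L))$stat)
  r1 <- rdp_scan(t1); r2 <- rdp_scan(t2)
  expect_equal(r1$stat, r2$stat)
  expect_equal(r1$recombinant_name, r2$recombinant_name)
})

test_that("recombinant identification flags the implanted row and symmetry", {
  sim <- sim_triplet(44)
  trip <- make_triplet(sim$aln, match(c("R", "P1", "D"), sim$aln$names))
  region <- range(which(trip$kept_columns >= 300 & trip$kept_columns <= 699))
  id <- identify_recombinant(trip, region)
  expect_equal(id$name, "R")
  expect_equal(id$status, "ok")
  # parent relabelling leaves the answer unchanged
  trip2 <- make_triplet(sim$aln, match(c("P1", "D", "R"), sim$aln$names))
  id2 <- identify_recombinant(trip2, region)
  expect_equal(id2$name, "R")
  # three near-equidistant rows without an event: ambiguous
  null_aln <- simulate_tree_alignment("(a:0.1,b:0.1,c:0.1);", 1000, seed = 9)
  tripn <- make_triplet(null_aln, 1:3)
  idn <- identify_recombinant(tripn, c(200L, 500L))
  expect_equal(idn$status, "ambiguous")
  # region covering the whole view is ambiguous by construction
  ida <- identify_recombinant(trip, c(1L, ncol(trip$v)))
  expect_equal(ida$status, "ambiguous")
})

test_that("bootscan supports switch to the donor inside the region", {
  tree <- "(((R:0.02,P1:0.02):0.08,D:0.10):0.05,OUT:0.15);"
  sim <- simulate_recombination(
    tree, 2000,
    data.frame(donor = "D", acceptor = "R", begin = 600, end = 1399),
    seed = 11
  )
  rows <- match(c("R", "P1", "D"), sim$aln$names)
  b <- bootscan_scan(sim$aln, rows, match("OUT", sim$aln$names), seed = 3)
  expect_false(is.null(b))
  expect_equal(b$recombinant_name, "R")
  expect_equal(b$minor_parent, "D")
  expect_gte(b$stat, 0.9)
  expect_gt(min(b$end, 1399) - max(b$begin, 600), 0)
  # supports are frequencies of disjoint outcomes
  sup <- b$profile[, c("support_topo_12", "support_topo_13", "support_topo_23")]
  expect_true(all(sup >= 0 & sup <= 1))
  expect_true(all(rowSums(sup) <= 1 + 1e-9))
  # four identical rows carry no resolution
  same <- new_alignment(setNames(rep(strrep("ACGT", 100), 4), letters[1:4]))
  expect_null(bootscan_scan(same, 1:3, 4L, window_len = 50, seed = 1))
})

test_that("permutation p-values are valid and null-calibrated", {
  # (k+1)/(N+1) estimator never returns 0, and raw p-values are super-uniform
  # on recombination-free alignments (ECDF at 0.05 stays below 0.08)
  ps <- list(rdp = c(), maxchi = c(), chimaera = c(), threeseq = c())
  for (a in 1:5) {
    aln <- simulate_tree_alignment(rand_tree(10, 300 + a), 2000, seed = 300 + a)
    imat <- recscan:::encode_alignment(aln)
    trips <- enumerate_triplets(10)
    set.seed(a)
    for (t in seq_len(nrow(trips))) {
      trip <- make_triplet(aln, trips[t, ], imat)
      for (m in names(ps)) {
        cand <- switch(m,
          rdp = rdp_scan(trip), maxchi = maxchi_scan(trip),
          chimaera = chimaera_scan(trip), threeseq = threeseq_scan(trip))
        ps[[m]] <- c(ps[[m]], if (is.null(cand)) 1 else cand$p_raw)
      }
    }
  }
  for (m in names(ps)) {
    expect_length(ps[[m]], 600L)
    expect_true(all(ps[[m]] > 0 & ps[[m]] <= 1))
    expect_lte(mean(ps[[m]] <= 0.05), 0.08)
  }
})
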