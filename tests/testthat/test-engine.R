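test_that("triplet enumeration is complete and ordered", {
  expect_equal(nrow(enumerate_triplets(3)), 1L)
  expect_equal(nrow(enumerate_triplets(5)), 10L)
  tt <- enumerate_triplets(5)
  expect_false(any(duplicated(tt)))
  expect_true(all(tt[, 1] < tt[, 2] & tt[, 2] < tt[, 3]))
  expect_error(enumerate_triplets(2), ">=3 sequences")
})

test_that("configuration validates, serializes and reloads losslessly", {
  cfg <- rec_config(alpha = 0.01, methods = c("rdp", "maxchi"))
  expect_equal(cfg$alpha, 0.01)
  expect_error(rec_config(nonsense = 1), "unknown config keys")
  expect_error(rec_config(methods = "geneconv"), "unknown methods")
  tf <- withr::local_tempfile()
  write_config(cfg, tf)
  back <- read_config(tf)
  expect_equal(unclass(back), unclass(cfg), tolerance = 1e-12)
})

test_that("scan retains implanted-event candidates and honours alpha", {
  sim <- sim_triplet(17)
  sc <- scan_alignment(sim$aln, rec_config(seed = 2))
  expect_gt(length(sc$candidates), 0L)
  td <- tidy(sc)
  expect_true(all(td$p_corrected <= 0.05))
  expect_true(any(td$recombinant == "R"))
  # alpha = 0 retains nothing
  sc0 <- scan_alignment(sim$aln, rec_config(seed = 2, alpha = 0))
  expect_length(sc0$candidates, 0L)
})

test_that("consolidation groups overlapping same-donor candidates", {
  sim <- sim_triplet(23)
  sc <- scan_alignment(sim$aln, rec_config(seed = 4))
  ev <- consolidate_events(sc)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$recombinants, "R")
  expect_equal(ev$minor_parent, "D")
  # breakpoint CIs bracket the point estimates
  expect_true(ev$begin_lo <= ev$begin && ev$begin <= ev$begin_hi)
  expect_true(ev$end_lo <= ev$end && ev$end <= ev$end_hi)
  # at least one method's corrected p clears alpha
  pcols <- unlist(ev[1, c("p_rdp", "p_maxchi", "p_chimaera", "p_threeseq")])
  expect_true(any(pcols <= 0.05, na.rm = TRUE))
})

test_that("candidates on disjoint regions of different sequences stay separate", {
  sim <- simulate_recombination(
    CLADE_TREE6, 3000,
    data.frame(donor = c("t4", "t5"), acceptor = c("t1", "t2"),
               begin = c(300L, 1800L), end = c(899L, 2399L)),
    seed = 31
  )
  ev <- consolidate_events(scan_alignment(sim$aln, rec_config(seed = 3)))
  expect_gte(nrow(ev), 2L)
  recs <- unlist(strsplit(ev$recombinants, ","))
  expect_true(all(c("t1", "t2") %in% recs))
})

test_that("descendants of one ancestral recombinant share one event", {
  # implant into an ancestor-like donor clade member, then let three
  # descendants inherit the same mosaic by copying it before divergence:
  # simulate the recombinant once and evolve three copies shallowly
  base <- simulate_recombination(
    "((anc:0.02,P1:0.03):0.08,D:0.10);", 1500,
    data.frame(donor = "D", acceptor = "anc", begin = 500L, end = 1099L),
    seed = 12
  )
  anc <- base$aln$mat[match("anc", base$aln$names), ]
  # three shallow descendants of the recombinant ancestor (~1% divergence)
  set.seed(14)
  mut <- function(row, p = 0.0075) {
    idx <- which(runif(length(row)) < p)
    row[idx] <- sample(c("A", "C", "G", "T"), length(idx), replace = TRUE)
    row
  }
  mat <- rbind(mut(anc), mut(anc), mut(anc),
               base$aln$mat[match("P1", base$aln$names), ],
               base$aln$mat[match("D", base$aln$names), ])
  aln <- new_alignment(mat, names = c("d1", "d2", "d3", "P1", "D"))
  ev <- consolidate_events(scan_alignment(aln, rec_config(seed = 6)))
  expect_equal(nrow(ev), 1L)
  expect_setequal(strsplit(ev$recombinants, ",")[[1]], c("d1", "d2", "d3"))
})

test_that("disassembly terminates cleanly and reports stable coordinates", {
  # no recombination: empty list after one iteration
  aln <- simulate_tree_alignment(rand_tree(6, 71), 1500, seed = 71)
  res <- iterate_disassembly(aln, rec_config(seed = 7))
  expect_equal(nrow(res), 0L)
  expect_equal(attr(res, "iterations"), 1L)
  # two disjoint implanted events in different sequences
  sim <- simulate_recombination(
    CLADE_TREE6, 3000,
    data.frame(donor = c("t4", "t5"), acceptor = c("t1", "t2"),
               begin = c(300L, 1800L), end = c(899L, 2399L)),
    seed = 72
  )
  res2 <- iterate_disassembly(sim$aln, rec_config(seed = 8))
  expect_equal(nrow(res2), 2L)
  for (k in 1:2) {
    truth <- sim$truth$events[match(res2$recombinants[k],
                                    sim$truth$events$recombinant), ]
    expect_gt(min(res2$end[k], truth$end) - max(res2$begin[k], truth$begin), 0)
  }
  expect_false(attr(res2, "incomplete"))
})

test_that("scans are reproducible bit-exactly given the config seed", {
  sim <- sim_triplet(55)
  cfg <- rec_config(seed = 9)
  t1 <- tidy(consolidate_events(scan_alignment(sim$aln, cfg)))
  t2 <- tidy(consolidate_events(scan_alignment(sim$aln, cfg)))
  expect_identical(t1, t2)
})
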