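# Independent brute-force oracles and shared simulation scenarios.

chi2_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  if (den <= 0) return(0)
  n * (a * d - b * c)^2 / den
}

# Exhaustive sliding-frame chi-square maximum (plain loops, no prefix sums).
oracle_maxchi <- function(v01, w) {
  n <- length(v01)
  best <- -1; pos <- NA_integer_
  for (s in seq_len(n - 2 * w + 1L)) {
    left <- v01[s:(s + w - 1L)]
    right <- v01[(s + w):(s + 2 * w - 1L)]
    st <- chi2_2x2(sum(left), w - sum(left), sum(right), w - sum(right))
    if (st > best + 1e-12) { best <- st; pos <- s + w }
  }
  list(stat = best, pos = pos)
}

# O(n^2) maximum descent over all (i, j), leftmost maximizer; symmetrized
# over the two orientations with the implementation's tie rule.
oracle_descent_one <- function(steps) {
  walk <- c(0, cumsum(steps))
  n <- length(steps)
  best <- 0; bi <- 0L; bj <- 0L
  for (i in 0:(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- walk[i + 1L] - walk[j + 1L]
      if (d > best + 1e-12) { best <- d; bi <- i; bj <- j }
    }
  }
  list(stat = best, from = bi + 1L, to = bj)
}

oracle_maxdescent <- function(steps) {
  d1 <- oracle_descent_one(steps)
  d2 <- oracle_descent_one(-steps)
  take2 <- (d2$stat > d1$stat + 1e-12) ||
    (abs(d2$stat - d1$stat) <= 1e-12 &&
       (d2$from < d1$from || (d2$from == d1$from && d2$to < d1$to)))
  if (take2) c(d2, orientation = -1) else c(d1, orientation = 1)
}

# Canonical internal-split set of an unrooted tree (manual enumeration).
tree_splits <- function(tr) {
  tr <- ape::unroot(tr)
  ntip <- length(tr$tip.label)
  out <- character(0)
  for (e in seq_len(nrow(tr$edge))) {
    child <- tr$edge[e, 2L]
    if (child <= ntip) next
    tips <- ape::extract.clade(tr, child)$tip.label
    other <- setdiff(tr$tip.label, tips)
    if (length(tips) < 2L || length(other) < 2L) next
    a <- paste(sort(tips), collapse = ",")
    b <- paste(sort(other), collapse = ",")
    out <- c(out, if (a < b) a else b)
  }
  unique(out)
}

oracle_rf <- function(t1, t2) {
  s1 <- tree_splits(t1); s2 <- tree_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# Brute-force best HMM path log-likelihood over ALL state paths for every
# binary observation vector of length `len` (vectorized over 2^len x 2^len).
all_binary <- function(len) {
  m <- as.matrix(expand.grid(rep(list(0:1), len)))[, len:1, drop = FALSE]
  dimnames(m) <- NULL
  m
}

oracle_viterbi_all <- function(len, switch_prob, emission_error) {
  P <- all_binary(len)               # state paths: 1 = tracking parent A
  O <- all_binary(len)               # observations: 1 = symbol A
  e <- emission_error
  mism <- O %*% t(1 - P) + (1 - O) %*% t(P)
  sw <- rowSums(abs(P[, -1, drop = FALSE] - P[, -len, drop = FALSE]))
  ll <- log(0.5) + mism * log(e) + (len - mism) * log1p(-e)
  ll <- sweep(ll, 2L, sw * log(switch_prob) +
                (len - 1 - sw) * log1p(-switch_prob), `+`)
  list(obs = O, best = apply(ll, 1L, max))
}

# --- shared simulation scenarios (the study conditions) -------------------

# Triplet scenario: recombinant R with close major-parent representative P1
# and donor D at JC ~0.2 from P1.
TRIPLET_TREE <- "((R:0.02,P1:0.02):0.08,D:0.10);"

sim_triplet <- function(seed, length = 1000L, region = c(300L, 699L)) {
  simulate_recombination(
    TRIPLET_TREE, length,
    data.frame(donor = "D", acceptor = "R",
               begin = region[1L], end = region[2L]),
    seed = seed
  )
}

# Two-clade tree for multi-event scenarios: acceptors t1-t3 in one clade,
# donors t4-t6 across (between-clade JC ~0.2).
CLADE_TREE6 <- "((t1:0.04,t2:0.04,t3:0.04):0.06,(t4:0.04,t5:0.04,t6:0.04):0.06);"

EVENTS3 <- data.frame(
  donor = c("t4", "t5", "t6"), acceptor = c("t1", "t2", "t3"),
  begin = c(400L, 1300L, 2200L), end = c(899L, 1799L, 2699L)
)

# Random nonclock tree rescaled to a mean pairwise distance (for null scans).
rand_tree <- function(n, seed, depth = 0.2) {
  set.seed(seed)
  tr <- ape::rtree(n)
  d <- ape::cophenetic.phylo(tr)
  tr$edge.length <- tr$edge.length * depth / mean(d[upper.tri(d)])
  tr
}
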