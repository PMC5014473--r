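# Per-triplet recombination signal statistics. Each *_scan() returns a
# rec_signal candidate or NULL ("absent"), with a diagnostic attached to NULL
# via attr(, "reason") where useful.

#' Binomial tail probability of a local identity excess
#'
#' Probability of observing at least `m` identical columns in an `l`-column
#' window when the background identity of the pair is `p`:
#' `sum_{i=m..l} C(l,i) p^i (1-p)^(l-i)`.
#'
#' @param l comparable columns in the window.
#' @param m matching columns observed.
#' @param p background identity fraction, strictly inside (0, 1).
#' @return The upper binomial tail (a probability).
#' @export
binomial_identity_p <- function(l, m, p) {
  if (p <= 0 || p >= 1) stop("background identity p must lie strictly in (0,1)")
  if (m < 0 || m > l) stop("require 0 <= m <= l")
  if (m == 0) return(1.0)
  pbinom(m - 1L, size = l, prob = p, lower.tail = FALSE)
}

# Sequential Monte-Carlo p for permutation nulls: (k+1)/(n_done+1), with the
# sampler stopping once `early_k` exceedances have been seen.
PERM_EARLY_K <- 12L

absent <- function(reason) NULL

# Two-pass Viterbi segmentation of a binary vector, returning the minority
# state segment containing (or nearest to) `peak`; NULL when the vector has a
# single segment. `positions` translate vector indices to view coordinates.
minority_region <- function(bin, peak) {
  sym <- ifelse(bin, "A", "B")
  seg <- viterbi_segments(sym)
  err <- estimate_emission_error(sym, seg)
  seg <- viterbi_segments(sym, emission_error = err)
  if (nrow(seg) < 2L) {
    # single segment: fall back to the peak split, taking the side whose
    # state differs from the overall majority
    n <- length(bin)
    if (peak <= 1L || peak > n) return(NULL)
    left_rate <- mean(bin[seq_len(peak - 1L)])
    right_rate <- mean(bin[peak:n])
    if (left_rate <= right_rate) c(1L, peak - 1L) else c(peak, n)
  } else {
    totals <- tapply(seg$end - seg$start + 1L, seg$state, sum)
    minority <- names(totals)[which.min(totals)]
    cand <- seg[seg$state == minority, , drop = FALSE]
    inside <- cand$start <= peak & cand$end >= peak
    pick <- if (any(inside)) which(inside)[1L] else {
      which.min(pmin(abs(cand$start - peak), abs(cand$end - peak)))
    }
    c(cand$start[pick], cand$end[pick])
  }
}

# Assemble a rec_signal candidate from a detected region on a triplet.
new_signal <- function(method, trip, region_view, stat, p_raw,
                       peak_view = NA_integer_, recombinant = NULL,
                       profile = NULL, tie_margin = 0.05) {
  region_view <- as.integer(region_view)
  if (region_view[2L] < region_view[1L]) return(absent("empty region"))
  warnings <- character(0)
  if (is.null(recombinant)) {
    idr <- identify_recombinant(trip, region_view, tie_margin = tie_margin)
    recombinant <- idr$index
    if (idr$status != "ok") {
      warnings <- c(warnings, "ambiguous - possible recombinant misidentification")
    }
  }
  parents <- setdiff(1:3, recombinant)
  info <- informative_sites(trip, recombinant)
  inside <- info$pos >= region_view[1L] & info$pos <= region_view[2L]
  if (any(inside)) {
    frac_a <- mean(info$sym[inside] == "A")
    donor <- if (frac_a >= 0.5) info$parents[1L] else info$parents[2L]
  } else {
    donor <- NA_integer_
  }
  major <- if (is.na(donor)) NA_integer_ else setdiff(parents, donor)
  orig <- view_to_original(trip, region_view[1L], region_view[2L])
  structure(list(
    method = method,
    rows = trip$rows,
    names = trip$names,
    recombinant = recombinant,
    recombinant_name = trip$names[recombinant],
    minor_parent = if (is.na(donor)) "unknown" else trip$names[donor],
    major_parent = if (is.na(major)) "unknown" else trip$names[major],
    region_view = region_view,
    begin = orig[1L], end = orig[2L],
    peak = if (is.na(peak_view)) NA_integer_ else trip$kept_columns[peak_view],
    stat = stat, p_raw = min(1, p_raw),
    profile = profile, warnings = warnings
  ), class = "rec_signal")
}

#' @export
print.rec_signal <- function(x, ...) {
  cat(sprintf(
    "<rec_signal> %s: recombinant %s (minor %s / major %s) region %d-%d, stat %.3g, p %.3g\n",
    x$method, x$recombinant_name, x$minor_parent, x$major_parent,
    x$begin, x$end, x$stat, x$p_raw
  ))
  invisible(x)
}

#' Pairwise-identity rank-inversion scan (RDP-style)
#'
#' Slides a window over the gap-stripped triplet view and flags windows in
#' which the locally most similar pair differs from the overall most similar
#' pair. The maximal run of consecutively flagged windows (with a consistent
#' local winner) defines the candidate region; its p-value is the binomial
#' tail of the winning pair's identity excess over its background identity,
#' Bonferroni-multiplied by the number of windows examined.
#'
#' @param trip a [make_triplet()].
#' @param window_len window width in gap-free columns (>= 10).
#' @param step window step.
#' @return A `rec_signal` or `NULL` (absent).
#' @export
rdp_scan <- function(trip, window_len = 30L, step = 1L) {
  if (window_len < 10L) stop("window_len must be >= 10")
  m <- triplet_n_col(trip)
  if (m < window_len) return(absent("view shorter than window"))
  if (length(trip$variable_sites) == 0L) return(absent("no variable sites"))
  starts <- seq.int(1L, m - window_len + 1L, by = step)
  nw <- length(starts)
  idm <- matrix(0, nrow = 3L, ncol = nw)
  for (pr in 1:3) {
    cs <- c(0, cumsum(trip$match[[pr]]))
    idm[pr, ] <- (cs[starts + window_len] - cs[starts]) / window_len
  }
  top <- which.max(trip$overall_identity)
  localmax <- pmax(idm[1L, ], idm[2L, ], idm[3L, ])
  flagged <- idm[top, ] < localmax - 1e-12
  if (!any(flagged)) return(absent("no rank inversion"))
  lab <- integer(nw)
  for (pr in setdiff(1:3, top)) {
    lab[flagged & idm[pr, ] >= localmax - 1e-12 & lab == 0L] <- pr
  }
  r <- rle(lab)
  ends <- cumsum(r$lengths); st <- ends - r$lengths + 1L
  keep <- which(r$values > 0L)
  if (length(keep) == 0L) return(absent("no rank inversion"))
  best_run <- keep[which.max(r$lengths[keep])]
  w1 <- st[best_run]; w2 <- ends[best_run]
  pr <- r$values[best_run]
  region <- c(starts[w1], starts[w2] + window_len - 1L)
  if (region[1L] <= 1L && region[2L] >= m) {
    return(absent("region spans whole view"))
  }
  l <- region[2L] - region[1L] + 1L
  mm <- sum(trip$match[[pr]][region[1L]:region[2L]])
  p0 <- min(max(trip$overall_identity[pr], 1 / (2 * m)), 1 - 1 / (2 * m))
  p_raw <- min(1, binomial_identity_p(l, mm, p0) * nw)
  gain <- idm[pr, w1:w2] - idm[top, w1:w2]
  wbest <- w1 + which.max(gain) - 1L
  peak_view <- min(m, starts[wbest] + window_len %/% 2L)
  recomb <- intersect(trip$pair_idx[[pr]], trip$pair_idx[[top]])
  profile <- tibble::tibble(
    center = trip$kept_columns[pmin(m, starts + window_len %/% 2L)],
    id_12 = idm[1L, ], id_13 = idm[2L, ], id_23 = idm[3L, ]
  )
  new_signal("rdp", trip, region, stat = max(gain), p_raw = p_raw,
             peak_view = peak_view, recombinant = recomb, profile = profile)
}

# Shared engine for the sliding-frame chi-square methods. `vec01` is the
# binary vector, `positions` its view coordinates.
chi_frame_scan <- function(method, trip, vec01, positions, window_len,
                           n_permutations, recombinant = NULL) {
  n <- length(vec01)
  if (n < 2L * window_len) return(absent("too few sites for frame"))
  pk <- maxchi_peak_cpp(as.integer(vec01), window_len)
  if (pk$stat <= 0) return(absent("homogeneous match vector"))
  pm <- maxchi_perm_cpp(as.integer(vec01), window_len, pk$stat,
                        n_permutations, PERM_EARLY_K)
  p_raw <- (pm$k + 1) / (pm$n + 1)
  reg <- minority_region(as.logical(vec01), pk$pos)
  if (is.null(reg)) return(absent("no segmentation"))
  region_view <- c(positions[reg[1L]], positions[reg[2L]])
  new_signal(method, trip, region_view, stat = pk$stat, p_raw = p_raw,
             peak_view = positions[pk$pos], recombinant = recombinant)
}

#' Sliding-frame chi-square scan on pairwise matches (MaxChi)
#'
#' Over the triplet's variable sites, slides a `2*window_len`-site frame along
#' the match/mismatch vector of one sequence pair; at each frame position the
#' 2x2 chi-square of (match, mismatch) x (left half, right half) is computed
#' (no continuity correction). The peak (leftmost on ties) is tested by
#' permutation of the site labels.
#'
#' @param trip a [make_triplet()].
#' @param pair `NULL` (scan all three pairs, return the best candidate) or a
#'   pair index 1..3 in the order (1,2), (1,3), (2,3).
#' @param window_len variable sites per frame half.
#' @param n_permutations permutation-null size.
#' @return A `rec_signal` or `NULL`.
#' @export
maxchi_scan <- function(trip, pair = NULL, window_len = 35L,
                        n_permutations = 2000L) {
  vs <- trip$variable_sites
  run_one <- function(pr) {
    chi_frame_scan("maxchi", trip, trip$match[[pr]][vs], vs,
                   window_len, n_permutations)
  }
  if (!is.null(pair)) return(run_one(pair))
  # permutations are spent only on the pair with the largest peak statistic
  # (the pair that would be reported); the triplet-level Bonferroni absorbs
  # the selection
  if (length(vs) < 2L * window_len) return(absent("too few sites for frame"))
  stats <- vapply(1:3, function(pr) {
    maxchi_peak_cpp(as.integer(trip$match[[pr]][vs]), window_len)$stat
  }, 0)
  if (max(stats) <= 0) return(absent("homogeneous match vectors"))
  cand <- run_one(which.max(stats))
  # Bonferroni over the three candidate vectors the selection considered
  if (!is.null(cand)) cand$p_raw <- min(1, cand$p_raw * 3)
  cand
}

#' Sliding-frame chi-square scan on informative sites (Chimaera)
#'
#' Identical machinery to [maxchi_scan()], applied to the A/B informative-site
#' vector of a candidate recombinant (A vs B plays match vs mismatch).
#'
#' @inheritParams maxchi_scan
#' @param candidate triplet member index of the putative recombinant, or
#'   `NULL` to try all three and return the best.
#' @export
chimaera_scan <- function(trip, candidate = NULL, window_len = 35L,
                          n_permutations = 2000L) {
  run_one <- function(r) {
    info <- informative_sites(trip, r)
    if (length(info$pos) < 2L * window_len) {
      return(absent("too few informative sites"))
    }
    chi_frame_scan("chimaera", trip, info$sym == "A", info$pos,
                   window_len, n_permutations, recombinant = r)
  }
  if (!is.null(candidate)) return(run_one(candidate))
  stats <- vapply(1:3, function(r) {
    info <- informative_sites(trip, r)
    if (length(info$pos) < 2L * window_len) return(-1)
    maxchi_peak_cpp(as.integer(info$sym == "A"), window_len)$stat
  }, 0)
  if (max(stats) <= 0) return(absent("no candidate yields a frame signal"))
  cand <- run_one(which.max(stats))
  if (!is.null(cand)) cand$p_raw <- min(1, cand$p_raw * sum(stats >= 0))
  cand
}

#' Maximum descent of the informative-site random walk
#'
#' Walk +1 at `"A"` sites and -1 at `"B"` sites; the statistic is the maximum
#' descent `max_{i<j} walk[i] - walk[j]` (0 for a non-decreasing walk),
#' leftmost maximizer on ties. The scan tries both parent orderings, so its
#' reported statistic is the larger of the two orientations' descents.
#'
#' @param sym character vector of `"A"`/`"B"` symbols.
#' @return list with `stat` and `from`, `to` (the 1-based site interval
#'   achieving the descent).
#' @export
max_descent <- function(sym) {
  steps <- ifelse(sym == "A", 1L, -1L)
  maxdescent_cpp(steps)
}

#' Random-walk maximum-descent scan (3SEQ-style)
#'
#' @inheritParams chimaera_scan
#' @param n_permutations permutation-null size.
#' @return A `rec_signal` or `NULL`.
#' @export
threeseq_scan <- function(trip, candidate = NULL, n_permutations = 1000L) {
  run_one <- function(r) {
    info <- informative_sites(trip, r)
    if (length(info$pos) == 0L) return(absent("no informative sites"))
    steps <- ifelse(info$sym == "A", 1L, -1L)
    d <- symdescent_cpp(steps) # both parent orderings
    if (d$stat <= 0) return(absent("flat walk"))
    pm <- maxdescent_perm_cpp(steps, d$stat, n_permutations, PERM_EARLY_K)
    p_raw <- (pm$k + 1) / (pm$n + 1)
    region_view <- c(info$pos[d$from], info$pos[d$to])
    new_signal("threeseq", trip, region_view, stat = d$stat, p_raw = p_raw,
               peak_view = info$pos[d$to], recombinant = r)
  }
  if (!is.null(candidate)) return(run_one(candidate))
  # descents are not comparable across candidates (a near-constant vector has
  # a huge mirrored descent), so each candidate is tested and the best
  # permutation p kept, Bonferroni-multiplied by the number tried
  best <- NULL; tried <- 0L
  for (r in 1:3) {
    cand <- run_one(r)
    if (is.null(cand)) next
    tried <- tried + 1L
    if (is.null(best) || cand$p_raw < best$p_raw ||
        (cand$p_raw == best$p_raw && cand$stat > best$stat)) {
      best <- cand
    }
  }
  if (is.null(best)) return(absent("no candidate yields a walk signal"))
  best$p_raw <- min(1, best$p_raw * tried)
  best
}

#' Sister-scanning z-score scan (SiScan-style)
#'
#' Per window, the three pairwise-match counts are compared with their null
#' distribution under independent within-column permutation of the three
#' residues; the signal is the maximal run of windows in which some pair's
#' z-score exceeds `z_threshold` with a consistent winning pair.
#'
#' @param trip a [make_triplet()].
#' @param window_len window width in gap-free columns.
#' @param step window step.
#' @param n_randomizations within-column permutation replicates (>= 100).
#' @param z_threshold z-score call threshold.
#' @param seed optional seed applied locally (otherwise the ambient RNG
#'   stream is used).
#' @return A `rec_signal` or `NULL`.
#' @export
siscan_scan <- function(trip, window_len = 100L, step = 20L,
                        n_randomizations = 500L, z_threshold = 3,
                        seed = NULL) {
  if (n_randomizations < 100L) stop("n_randomizations must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  m <- triplet_n_col(trip)
  if (m < window_len) return(absent("view shorter than window"))
  s_class <- trip$match[[1L]] + trip$match[[2L]] + trip$match[[3L]] # 3 xxx, 1 xxy, 0 xyz
  cs_xxx <- c(0, cumsum(s_class == 3L))
  cs_xxy <- c(0, cumsum(s_class == 1L))
  csm <- lapply(trip$match, function(v) c(0, cumsum(v)))
  starts <- seq.int(1L, m - window_len + 1L, by = step)
  nw <- length(starts)
  z <- matrix(NA_real_, nrow = 3L, ncol = nw)
  for (k in seq_len(nw)) {
    a <- starts[k]; b <- a + window_len
    n3 <- cs_xxx[b] - cs_xxx[a]
    mw <- cs_xxy[b] - cs_xxy[a]
    obs <- vapply(csm, function(cs) cs[b] - cs[a], 0)
    if (mw == 0L) next
    sims <- rmultinom(n_randomizations, mw, rep(1 / 3, 3)) + n3
    mu <- rowMeans(sims)
    sg <- apply(sims, 1L, sd)
    ok <- sg > 0
    z[ok, k] <- (obs[ok] - mu[ok]) / sg[ok]
  }
  if (all(is.na(z))) return(absent("degenerate randomization variance"))
  zmax <- suppressWarnings(apply(z, 2L, max, na.rm = TRUE))
  zmax[!is.finite(zmax)] <- NA_real_
  flagged <- !is.na(zmax) & zmax > z_threshold
  if (!any(flagged)) return(absent("no window exceeds z threshold"))
  lab <- integer(nw)
  for (k in which(flagged)) lab[k] <- which.max(replace(z[, k], is.na(z[, k]), -Inf))
  r <- rle(lab)
  ends <- cumsum(r$lengths); st <- ends - r$lengths + 1L
  keep <- which(r$values > 0L)
  best_run <- keep[which.max(r$lengths[keep])]
  w1 <- st[best_run]; w2 <- ends[best_run]
  pr <- r$values[best_run]
  region <- c(starts[w1], min(m, starts[w2] + window_len - 1L))
  zpeak <- max(z[pr, w1:w2], na.rm = TRUE)
  p_raw <- min(1, pnorm(zpeak, lower.tail = FALSE) * nw)
  top <- which.max(trip$overall_identity)
  recomb <- if (pr == top) NULL else intersect(trip$pair_idx[[pr]], trip$pair_idx[[top]])
  if (length(recomb) != 1L) recomb <- NULL
  wpk <- w1 + which.max(z[pr, w1:w2]) - 1L
  peak_view <- min(m, starts[wpk] + window_len %/% 2L)
  new_signal("siscan", trip, region, stat = zpeak, p_raw = p_raw,
             peak_view = peak_view, recombinant = recomb)
}

#' Bootscan window-phylogeny scan
#'
#' Per window, column-resampled bootstrap replicates of the Jukes-Cantor
#' distance matrix of the three triplet rows plus an outgroup; each replicate
#' votes for the 4-taxon topology minimizing the four-point sums. A signal is
#' a run of windows in which a candidate recombinant's supported sister parent
#' switches, with supporting windows on both flanks at or above
#' `support_threshold`. The follow-up p-value is the binomial identity tail
#' over the informative sites of the switch region.
#'
#' @param aln alignment.
#' @param rows triplet row indices.
#' @param outgroup row index of the outgroup (distinct from `rows`).
#' @param window_len,step window geometry in gap-free columns.
#' @param n_bootstraps bootstrap replicates per window (>= 100).
#' @param support_threshold minimum support for a parent call.
#' @param seed optional local seed.
#' @param imat optional precomputed integer encoding of `aln`.
#' @return A `rec_signal` (on the triplet view, coordinates original) or
#'   `NULL`.
#' @export
bootscan_scan <- function(aln, rows, outgroup, window_len = 200L, step = 20L,
                          n_bootstraps = 100L, support_threshold = 0.7,
                          seed = NULL, imat = NULL) {
  if (n_bootstraps < 100L) stop("n_bootstraps must be >= 100")
  if (outgroup %in% rows) stop("outgroup must be distinct from the triplet rows")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(imat)) imat <- encode_alignment(aln)
  trip <- make_triplet(aln, rows, imat)
  quad <- imat[c(rows, outgroup), , drop = FALSE]
  keep4 <- which(colSums(quad >= 5L) == 0L)
  if (length(keep4) < window_len) return(absent("view shorter than window"))
  q <- quad[, keep4, drop = FALSE]
  pairs4 <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L), c(1L, 4L), c(2L, 4L), c(3L, 4L))
  mism <- vapply(pairs4, function(p) q[p[1L], ] != q[p[2L], ],
                 logical(ncol(q))) # len x 6
  m4 <- ncol(q)
  starts <- seq.int(1L, m4 - window_len + 1L, by = step)
  nw <- length(starts)
  u <- matrix(0, nrow = 3L, ncol = nw) # topology support: (12|3o),(13|2o),(23|1o)
  for (k in seq_len(nw)) {
    idx <- starts[k]:(starts[k] + window_len - 1L)
    Mw <- mism[idx, , drop = FALSE] * 1
    W <- rmultinom(n_bootstraps, window_len, rep(1 / window_len, window_len))
    pd <- crossprod(Mw, W) / window_len            # 6 x nboot
    pd <- pmin(pd, 0.70)
    d <- -0.75 * log(1 - 4 * pd / 3)
    s12 <- d[1L, ] + d[6L, ] # d(1,2) + d(3,o)
    s13 <- d[2L, ] + d[5L, ] # d(1,3) + d(2,o)
    s23 <- d[3L, ] + d[4L, ] # d(2,3) + d(1,o)
    S <- rbind(s12, s13, s23)
    win <- apply(S, 2L, function(col) {
      w <- which(col == min(col))
      if (length(w) == 1L) w else NA_integer_
    })
    tab <- tabulate(win[!is.na(win)], nbins = 3L)
    u[, k] <- tab / n_bootstraps
  }
  # candidate r's two parent supports are the topology frequencies of the
  # cherries containing r: r=1 -> rows (1,2); r=2 -> (1,3); r=3 -> (2,3)
  cand_top <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  parent_of <- list(c(2L, 3L), c(1L, 3L), c(1L, 2L))
  best <- NULL
  for (r in 1:3) {
    sup <- u[cand_top[[r]], , drop = FALSE] # 2 x nw: support for parent1, parent2
    winner <- ifelse(sup[1L, ] >= support_threshold, 1L,
                     ifelse(sup[2L, ] >= support_threshold, 2L, 0L))
    for (minor in 1:2) {
      other <- 3L - minor
      runs <- logical_runs(winner == minor)
      if (nrow(runs) == 0L) next
      for (ri in order(-runs$len)) {
        w1 <- runs$start[ri]; w2 <- runs$end[ri]
        has_left <- any(winner[seq_len(w1 - 1L)] == other)
        has_right <- w2 < nw && any(winner[(w2 + 1L):nw] == other)
        if (!(has_left && has_right)) next
        region4 <- c(starts[w1], min(m4, starts[w2] + window_len - 1L))
        region_orig <- c(keep4[region4[1L]], keep4[region4[2L]])
        region_view <- c(
          findInterval(region_orig[1L], trip$kept_columns) + 1L,
          findInterval(region_orig[2L], trip$kept_columns)
        )
        region_view[1L] <- min(region_view[1L], triplet_n_col(trip))
        if (region_view[2L] < region_view[1L]) next
        info <- informative_sites(trip, r)
        inside <- info$pos >= region_view[1L] & info$pos <= region_view[2L]
        if (!any(inside)) next
        donor_parent <- parent_of[[r]][minor]
        donor_sym <- if (donor_parent == info$parents[1L]) "A" else "B"
        l <- sum(inside)
        mmatch <- sum(info$sym[inside] == donor_sym)
        p0 <- mean(info$sym == donor_sym)
        p0 <- min(max(p0, 1 / (2 * length(info$sym))),
                  1 - 1 / (2 * length(info$sym)))
        p_raw <- min(1, binomial_identity_p(l, mmatch, p0) * nw)
        sup_peak <- max(sup[minor, w1:w2])
        cand <- new_signal("bootscan", trip, region_view, stat = sup_peak,
                           p_raw = p_raw, recombinant = r)
        if (!is.null(cand)) {
          cand$profile <- tibble::tibble(
            center = keep4[pmin(m4, starts + window_len %/% 2L)],
            support_topo_12 = u[1L, ], support_topo_13 = u[2L, ],
            support_topo_23 = u[3L, ]
          )
          if (is.null(best) || cand$p_raw < best$p_raw) best <- cand
        }
        break # longest valid run per (candidate, direction) is enough
      }
    }
  }
  if (is.null(best)) absent("no supported parent switch") else best
}

#' Identify the recombinant member of a triplet for a given region
#'
#' For each candidate, the signed affinity (+1 matches first parent, -1
#' matches second) is averaged over informative sites inside and outside the
#' region; the affinity-flip score is the product of the two means. The
#' candidate with the most negative score (the one whose parental affinity
#' flips most strongly across the region boundary) is called recombinant;
#' near-ties within `tie_margin` are labelled ambiguous.
#'
#' @param trip a [make_triplet()].
#' @param region_view 1-based inclusive interval in view coordinates.
#' @param tie_margin minimum score separation for an unambiguous call.
#' @return list with `index` (1..3), `name`, `status` (`"ok"`/`"ambiguous"`)
#'   and the three `scores`.
#' @export
identify_recombinant <- function(trip, region_view, tie_margin = 0.05) {
  scores <- rep(NA_real_, 3L)
  for (r in 1:3) {
    info <- informative_sites(trip, r)
    if (length(info$pos) == 0L) next
    x <- ifelse(info$sym == "A", 1, -1)
    inside <- info$pos >= region_view[1L] & info$pos <= region_view[2L]
    if (!any(inside) || all(inside)) next
    scores[r] <- mean(x[inside]) * mean(x[!inside])
  }
  if (all(is.na(scores))) {
    return(list(index = 1L, name = trip$names[1L], status = "ambiguous",
                scores = scores))
  }
  ord <- order(scores, na.last = TRUE)
  idx <- ord[1L]
  status <- "ok"
  if (sum(!is.na(scores)) > 1L &&
      scores[ord[2L]] - scores[idx] < tie_margin) {
    status <- "ambiguous"
  }
  if (scores[idx] > -tie_margin) status <- "ambiguous"
  list(index = idx, name = trip$names[idx], status = status, scores = scores)
}
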