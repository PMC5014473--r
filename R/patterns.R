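# Alignment-wide breakpoint-pattern statistics: hot/cold spots, breakpoint
# pair matrices, site-pair co-inheritance matrices, feature association.

#' Construct a breakpoint set
#'
#' @param df data frame with columns `event_id`, `sequence`, `pos` (1-based),
#'   `kind` (`"begin"`/`"end"`); or a bare numeric vector of positions.
#' @param length alignment length.
#' @param mask optional integer vector of permissible positions for the
#'   permutation nulls (defaults to the whole alignment).
#' @return a `rec_bpset` tibble with attributes `alignment_length`, `mask`.
#' @export
new_breakpoint_set <- function(df, length, mask = NULL) {
  if (is.numeric(df) && is.null(dim(df))) {
    df <- tibble::tibble(
      event_id = seq_along(df), sequence = "seq", pos = as.integer(df),
      kind = "begin"
    )
  }
  df <- tibble::as_tibble(df)
  stopifnot(all(c("event_id", "sequence", "pos", "kind") %in% names(df)))
  if (nrow(df) && (min(df$pos) < 1L || max(df$pos) > length)) {
    stop("breakpoint positions must lie in [1, alignment length]")
  }
  attr(df, "alignment_length") <- as.integer(length)
  attr(df, "mask") <- mask
  class(df) <- c("rec_bpset", class(df))
  df
}

#' Breakpoint set of an events table
#'
#' One `begin` and one `end` breakpoint per (event, recombinant sequence).
#'
#' @param events a `rec_events` tibble.
#' @param length alignment length.
#' @export
breakpoints_from_events <- function(events, length) {
  if (nrow(events) == 0L) {
    return(new_breakpoint_set(
      tibble::tibble(event_id = integer(), sequence = character(),
                     pos = integer(), kind = character()), length))
  }
  recs <- strsplit(events$recombinants, ",\\s*")
  rows <- lapply(seq_len(nrow(events)), function(k) {
    tibble::tibble(
      event_id = events$event_id[k],
      sequence = rep(recs[[k]], 2L),
      pos = rep(c(events$begin[k], events$end[k]), each = length(recs[[k]])),
      kind = rep(c("begin", "end"), each = length(recs[[k]]))
    )
  })
  new_breakpoint_set(do.call(rbind, rows), length)
}

pattern_windows <- function(L, window_len, step) {
  starts <- seq.int(1L, max(1L, L - window_len + 1L), by = step)
  ends <- pmin(L, starts + window_len - 1L)
  if (step == window_len && ends[length(ends)] < L) {
    # complete the partition so non-overlapping window counts conserve totals
    starts <- c(starts, ends[length(ends)] + 1L)
    ends <- c(ends, L)
  }
  cbind(start = starts, end = ends)
}

#' Sliding-window breakpoint density
#'
#' @param bps a [new_breakpoint_set()].
#' @param window_len window width (>= 1).
#' @param step window step.
#' @return tibble with `start`, `end`, `center`, `count`.
#' @export
breakpoint_density <- function(bps, window_len, step = window_len) {
  L <- attr(bps, "alignment_length")
  win <- pattern_windows(L, window_len, step)
  pos <- sort(bps$pos)
  count <- findInterval(win[, "end"], pos) - findInterval(win[, "start"] - 1L, pos)
  tibble::tibble(
    start = win[, "start"], end = win[, "end"],
    center = (win[, "start"] + win[, "end"]) %/% 2L,
    count = as.integer(count)
  )
}

#' Permutation test for recombination hot- and cold spots
#'
#' The null re-places every breakpoint independently and uniformly over its
#' permissible region (the whole alignment, or the detectability mask when the
#' breakpoint set carries one). Windows whose observed count exceeds the
#' global 95% envelope (the 95th percentile of the across-window maximum of
#' permuted counts) are called hot; windows below the global lower envelope
#' (5th percentile of the across-window minimum) are called cold. Per-window
#' local 2.5%/97.5% envelopes are reported for plotting.
#'
#' @param bps a [new_breakpoint_set()].
#' @param window_len window width.
#' @param n_permutations permutation replicates (>= 1000).
#' @param seed integer seed.
#' @param step window step (default: non-overlapping windows).
#' @return A `rec_hotspots` object: tibble of windows with `count`,
#'   `perm_mean`, `local_lo`, `local_hi`, `hot`, `cold`; attributes
#'   `global_upper`, `global_lower`.
#' @export
hotspot_test <- function(bps, window_len, n_permutations = 1000L, seed = 1L,
                         step = window_len) {
  if (n_permutations < 1000L) stop("n_permutations must be >= 1000")
  set.seed(seed)
  L <- attr(bps, "alignment_length")
  mask <- attr(bps, "mask")
  win <- pattern_windows(L, window_len, step)
  nw <- nrow(win)
  obs <- breakpoint_density(bps, window_len, step)$count
  nb <- nrow(bps)
  if (nb == 0L) {
    out <- tibble::tibble(
      start = win[, "start"], end = win[, "end"],
      center = (win[, "start"] + win[, "end"]) %/% 2L,
      count = 0L, perm_mean = 0, local_lo = 0, local_hi = 0,
      hot = FALSE, cold = FALSE
    )
    attr(out, "global_upper") <- 0; attr(out, "global_lower") <- 0
    class(out) <- c("rec_hotspots", class(out))
    return(out)
  }
  draw <- function(n) {
    if (is.null(mask)) sample.int(L, n, replace = TRUE) else {
      mask[sample.int(length(mask), n, replace = TRUE)]
    }
  }
  perm_counts <- matrix(0L, nrow = nw, ncol = n_permutations)
  contiguous <- step == window_len
  for (b in seq_len(n_permutations)) {
    pos <- draw(nb)
    if (contiguous) {
      idx <- pmin(nw, (pos - 1L) %/% window_len + 1L)
      perm_counts[, b] <- tabulate(idx, nbins = nw)
    } else {
      pos <- sort(pos)
      perm_counts[, b] <- findInterval(win[, "end"], pos) -
        findInterval(win[, "start"] - 1L, pos)
    }
  }
  local_lo <- apply(perm_counts, 1L, quantile, probs = 0.025, type = 1L)
  local_hi <- apply(perm_counts, 1L, quantile, probs = 0.975, type = 1L)
  gmax <- apply(perm_counts, 2L, max)
  gmin <- apply(perm_counts, 2L, min)
  global_upper <- quantile(gmax, 0.95, type = 1L)
  global_lower <- quantile(gmin, 0.05, type = 1L)
  out <- tibble::tibble(
    start = win[, "start"], end = win[, "end"],
    center = (win[, "start"] + win[, "end"]) %/% 2L,
    count = obs,
    perm_mean = rowMeans(perm_counts),
    local_lo = as.numeric(local_lo), local_hi = as.numeric(local_hi),
    hot = obs > global_upper, cold = obs < global_lower
  )
  attr(out, "global_upper") <- as.numeric(global_upper)
  attr(out, "global_lower") <- as.numeric(global_lower)
  class(out) <- c("rec_hotspots", class(out))
  out
}

#' Binned breakpoint-pair matrix with permutation flags
#'
#' 2-D histogram of each event's (begin, end) pair; the null permutes begins
#' and ends independently (uniform re-placement, begin < end enforced by
#' rejection). Cells whose observed count exceeds the cell-wise 97.5%
#' permutation percentile are flagged as hotspot pairs.
#'
#' @param events a `rec_events` tibble (or data frame with `begin`, `end`).
#' @param length alignment length.
#' @param n_bins bins per axis.
#' @param n_permutations permutation replicates.
#' @param seed integer seed.
#' @return A `rec_pairmatrix`: list with `counts` (begin bins x end bins),
#'   `threshold` (per-cell 97.5% percentile), `flagged`, `breaks`.
#' @export
breakpoint_pair_matrix <- function(events, length, n_bins = 20L,
                                   n_permutations = 1000L, seed = 1L) {
  set.seed(seed)
  breaks <- seq(0.5, length + 0.5, length.out = n_bins + 1L)
  bin_of <- function(x) pmin(n_bins, pmax(1L, findInterval(x, breaks)))
  ne <- nrow(events)
  counts <- matrix(0L, n_bins, n_bins)
  if (ne > 0L) {
    bb <- bin_of(events$begin); eb <- bin_of(events$end)
    for (k in seq_len(ne)) counts[bb[k], eb[k]] <- counts[bb[k], eb[k]] + 1L
  }
  perm <- array(0L, dim = c(n_bins, n_bins, n_permutations))
  if (ne > 0L) {
    for (b in seq_len(n_permutations)) {
      bg <- sample.int(length, ne, replace = TRUE)
      en <- sample.int(length, ne, replace = TRUE)
      bad <- bg >= en
      while (any(bad)) {
        bg[bad] <- sample.int(length, sum(bad), replace = TRUE)
        en[bad] <- sample.int(length, sum(bad), replace = TRUE)
        bad <- bg >= en
      }
      bb <- bin_of(bg); eb <- bin_of(en)
      for (k in seq_len(ne)) perm[bb[k], eb[k], b] <- perm[bb[k], eb[k], b] + 1L
    }
  }
  threshold <- apply(perm, c(1L, 2L), quantile, probs = 0.975, type = 1L)
  structure(list(
    counts = counts, threshold = threshold,
    flagged = counts > threshold & counts > 0L,
    breaks = breaks, n_events = ne
  ), class = "rec_pairmatrix")
}

#' @export
print.rec_pairmatrix <- function(x, ...) {
  cat(sprintf("<rec_pairmatrix> %d events, %d flagged cell(s)\n",
              x$n_events, sum(x$flagged)))
  invisible(x)
}

# Fragment index of each grid point for one sequence given its sorted
# fragment-start boundaries.
fragment_index <- function(grid, boundaries) {
  findInterval(grid, sort(boundaries))
}

#' Site-pair co-inheritance count matrix
#'
#' Over a coarse site grid, counts for every site pair the number of
#' sequences in which the two sites derive from the same parental fragment
#' (no breakpoint of that sequence between them). The upper triangle holds
#' counts; the lower triangle the two-sided permutation CDF position of each
#' count under uniform re-placement of each event's ordered (begin, end)
#' pair (values near 1: co-inherited more than expected; near 0: less).
#'
#' @param aln alignment (supplies the sequence set).
#' @param events a `rec_events` tibble.
#' @param n_grid grid points.
#' @param n_permutations permutation replicates.
#' @param seed integer seed.
#' @return A `rec_regioncount`: list with `grid`, `counts` (symmetric),
#'   `quantile` (co-inheritance CDF position), `matrix` (counts upper /
#'   quantile lower).
#' @export
region_count_matrix <- function(aln, events, n_grid = 100L,
                                n_permutations = 200L, seed = 1L) {
  set.seed(seed)
  L <- aln_length(aln)
  grid <- unique(round(seq(1L, L, length.out = n_grid)))
  ng <- length(grid)
  recs <- if (nrow(events)) strsplit(events$recombinants, ",\\s*") else list()
  seq_events <- lapply(aln$names, function(nm) {
    which(vapply(recs, function(r) nm %in% r, TRUE))
  })
  count_mat <- function(boundary_list) {
    cm <- matrix(0L, ng, ng)
    for (s in seq_along(boundary_list)) {
      f <- fragment_index(grid, boundary_list[[s]])
      cm <- cm + outer(f, f, "==")
    }
    cm
  }
  obs_bounds <- lapply(seq_along(aln$names), function(s) {
    ev <- seq_events[[s]]
    if (length(ev) == 0L) return(numeric(0))
    c(events$begin[ev], events$end[ev] + 1L) - 0.5
  })
  counts <- count_mat(obs_bounds)
  qs <- matrix(NA_real_, ng, ng)
  if (nrow(events) > 0L && n_permutations > 0L) {
    less <- matrix(0L, ng, ng); equal <- matrix(0L, ng, ng)
    for (b in seq_len(n_permutations)) {
      pb <- lapply(seq_along(aln$names), function(s) {
        ev <- seq_events[[s]]
        if (length(ev) == 0L) return(numeric(0))
        out <- numeric(0)
        for (k in ev) {
          x <- sample.int(L, 2L)
          out <- c(out, min(x) - 0.5, max(x) + 0.5)
        }
        out
      })
      pm <- count_mat(pb)
      less <- less + (pm < counts)
      equal <- equal + (pm == counts)
    }
    qs <- (less + 0.5 * equal) / n_permutations
  }
  comb <- counts
  comb[lower.tri(comb)] <- qs[lower.tri(qs)]
  structure(list(grid = grid, counts = counts, quantile = qs, matrix = comb,
                 n_permutations = n_permutations),
            class = "rec_regioncount")
}

#' @export
print.rec_regioncount <- function(x, ...) {
  cat(sprintf("<rec_regioncount> %d grid points; count range %d-%d\n",
              length(x$grid), min(x$counts), max(x$counts)))
  invisible(x)
}

#' Association between breakpoints and genome features
#'
#' The statistic is the mean distance from each breakpoint to the nearest
#' feature boundary. Both tails are reported: `p_association` (permuted mean
#' distance <= observed) and `p_avoidance` (>= observed), with `(k+1)/(N+1)`
#' smoothing under uniform re-placement of breakpoints.
#'
#' @param bps a [new_breakpoint_set()].
#' @param features data frame with columns `begin`, `end` (1-based inclusive,
#'   within the alignment).
#' @param n_permutations permutation replicates.
#' @param seed integer seed.
#' @return tibble with `observed`, `p_association`, `p_avoidance`,
#'   `n_breakpoints`, `n_boundaries`.
#' @export
feature_association_test <- function(bps, features, n_permutations = 1000L,
                                     seed = 1L) {
  if (is.null(features) || nrow(features) == 0L) {
    stop("feature list must be non-empty")
  }
  L <- attr(bps, "alignment_length")
  if (min(features$begin) < 1L || max(features$end) > L) {
    stop("features must lie within the alignment")
  }
  set.seed(seed)
  bounds <- sort(unique(c(features$begin, features$end)))
  mean_dist <- function(pos) {
    i <- findInterval(pos, bounds)
    d_left <- ifelse(i == 0L, Inf, pos - bounds[pmax(i, 1L)])
    d_right <- ifelse(i == length(bounds), Inf, bounds[pmin(i + 1L, length(bounds))] - pos)
    mean(pmin(d_left, d_right))
  }
  obs <- mean_dist(bps$pos)
  nb <- nrow(bps)
  k_le <- 0L; k_ge <- 0L
  for (b in seq_len(n_permutations)) {
    d <- mean_dist(sample.int(L, nb, replace = TRUE))
    if (d <= obs + 1e-12) k_le <- k_le + 1L
    if (d >= obs - 1e-12) k_ge <- k_ge + 1L
  }
  tibble::tibble(
    observed = obs,
    p_association = (k_le + 1) / (n_permutations + 1),
    p_avoidance = (k_ge + 1) / (n_permutations + 1),
    n_breakpoints = nb,
    n_boundaries = length(bounds)
  )
}
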