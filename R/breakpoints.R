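# HMM-based breakpoint placement on informative-site vectors, and
# single-switch breakpoint posteriors with HPD intervals.

#' Viterbi segmentation of an informative-site vector
#'
#' Two-state hidden Markov model: the hidden state is which parent the
#' recombinant currently tracks, the emission is the observed `"A"`/`"B"`
#' symbol (mismatch probability `emission_error`), and state switches occur
#' with probability `switch_prob` between adjacent sites. Returns the Viterbi
#' path compressed to segments; breakpoints are the segment boundaries.
#'
#' @param sym character vector of `"A"`/`"B"` symbols (non-empty).
#' @param switch_prob per-step switch probability, in (0, 0.5).
#' @param emission_error emission mismatch probability, in \[0, 0.5).
#' @return data.frame with columns `state`, `start`, `end` (1-based inclusive
#'   site indices).
#' @export
viterbi_segments <- function(sym, switch_prob = 0.01, emission_error = 0.05) {
  n <- length(sym)
  if (n == 0L) stop("empty informative-site vector")
  if (switch_prob <= 0 || switch_prob >= 0.5) stop("switch_prob must be in (0, 0.5)")
  if (emission_error < 0 || emission_error >= 0.5) {
    stop("emission_error must be in [0, 0.5)")
  }
  e <- max(emission_error, 1e-12)
  le_match <- log1p(-e); le_mis <- log(e)
  lt_stay <- log1p(-switch_prob); lt_switch <- log(switch_prob)
  obs_a <- sym == "A"
  # emission log-likelihoods per state (state 1 = tracking parent A)
  em1 <- ifelse(obs_a, le_match, le_mis)
  em2 <- ifelse(obs_a, le_mis, le_match)
  d1 <- log(0.5) + em1[1L]
  d2 <- log(0.5) + em2[1L]
  bt <- matrix(1L, nrow = 2L, ncol = n)
  if (n > 1L) {
    for (i in 2:n) {
      s1 <- c(d1 + lt_stay, d2 + lt_switch)
      s2 <- c(d1 + lt_switch, d2 + lt_stay)
      bt[1L, i] <- which.max(s1)
      bt[2L, i] <- which.max(s2)
      d1n <- s1[bt[1L, i]] + em1[i]
      d2n <- s2[bt[2L, i]] + em2[i]
      d1 <- d1n; d2 <- d2n
    }
  }
  path <- integer(n)
  path[n] <- which.max(c(d1, d2))
  if (n > 1L) for (i in n:2) path[i - 1L] <- bt[path[i], i]
  r <- rle(path)
  ends <- cumsum(r$lengths)
  data.frame(
    state = c("A", "B")[r$values],
    start = ends - r$lengths + 1L,
    end = ends
  )
}

# Log-likelihood of the Viterbi path (used by the brute-force oracle tests).
path_loglik <- function(sym, path, switch_prob, emission_error) {
  e <- max(emission_error, 1e-12)
  obs_a <- sym == "A"
  match <- (path == 1L) == obs_a
  sum(ifelse(match, log1p(-e), log(e))) +
    log(0.5) +
    if (length(path) > 1L) {
      sw <- sum(diff(path) != 0L)
      sw * log(switch_prob) + (length(path) - 1L - sw) * log1p(-switch_prob)
    } else 0
}

#' Estimate the HMM emission error from a segmentation
#'
#' Add-one smoothed fraction of sites disagreeing with their segment's state:
#' `(d + 1) / (n + 2)`, capped just below 0.5.
#'
#' @param sym `"A"`/`"B"` vector.
#' @param segments a segmentation from [viterbi_segments()].
#' @return estimated emission error in (0, 0.5).
#' @export
estimate_emission_error <- function(sym, segments) {
  n <- length(sym)
  d <- 0L
  for (k in seq_len(nrow(segments))) {
    idx <- segments$start[k]:segments$end[k]
    d <- d + sum(sym[idx] != segments$state[k])
  }
  min((d + 1) / (n + 2), 0.49)
}

#' Single-switch breakpoint posterior with HPD interval
#'
#' Enumerates every between-site boundary `k` (switch after site `k`) under a
#' one-switch model: the likelihood is the product of emissions with state A
#' left of the boundary and state B right of it; the better of the two parent
#' orientations is kept at each boundary. The posterior is the normalized
#' likelihood under a uniform prior over boundaries; the 95% HPD is the
#' smallest contiguous boundary set containing the mode with mass >= `level`.
#'
#' @param sym `"A"`/`"B"` vector of length >= 2.
#' @param emission_error emission mismatch probability.
#' @param positions optional original coordinates of the informative sites;
#'   when given, each boundary `k` is also reported as the midpoint (rounded
#'   down) of the flanking informative columns.
#' @param level HPD mass.
#' @return An object of class `rec_bp_posterior`: list with `boundary`
#'   (1..n-1), `mass`, `mode`, `hpd` (`c(lo, hi)` boundary indices), and, when
#'   `positions` is given, `coord`, `mode_coord`, `hpd_coord`.
#' @export
breakpoint_posterior <- function(sym, emission_error = 0.05, positions = NULL,
                                 level = 0.95) {
  n <- length(sym)
  if (n < 2L) stop("need at least two informative sites")
  e <- min(max(emission_error, 1e-12), 0.49)
  a <- sym == "A"
  # prefix counts of A's
  ca <- cumsum(a)
  total_a <- ca[n]
  k <- seq_len(n - 1L)
  # orientation A|B: left mismatches = #B in 1..k, right = #A in k+1..n
  mis_ab <- (k - ca[k]) + (total_a - ca[k])
  mis_ba <- ca[k] + ((n - k) - (total_a - ca[k]))
  ll <- pmax(mis_ab, -1) # placeholder shape
  ll_ab <- mis_ab * log(e) + (n - mis_ab) * log1p(-e)
  ll_ba <- mis_ba * log(e) + (n - mis_ba) * log1p(-e)
  ll <- pmax(ll_ab, ll_ba)
  ll <- ll - max(ll)
  mass <- exp(ll) / sum(exp(ll))
  mode <- which.max(mass)
  hpd <- hpd_contiguous(mass, mode, level)
  out <- list(boundary = k, mass = mass, mode = mode, hpd = hpd, level = level)
  if (!is.null(positions)) {
    stopifnot(length(positions) == n)
    coord <- (positions[k] + positions[k + 1L]) %/% 2L
    out$coord <- coord
    out$mode_coord <- coord[mode]
    out$hpd_coord <- c(coord[hpd[1L]], coord[hpd[2L]])
  }
  structure(out, class = "rec_bp_posterior")
}

# Smallest contiguous window containing `mode` with mass >= level (leftmost,
# then narrowest, on ties).
hpd_contiguous <- function(mass, mode, level = 0.95) {
  n <- length(mass)
  cs <- c(0, cumsum(mass))
  best <- c(1L, n); best_w <- n
  for (i in seq_len(mode)) {
    for (j in mode:n) {
      if (cs[j + 1L] - cs[i] >= level - 1e-12) {
        w <- j - i
        if (w < best_w) { best <- c(i, j); best_w <- w }
        break
      }
    }
  }
  best
}

#' @export
print.rec_bp_posterior <- function(x, ...) {
  cat(sprintf("<rec_bp_posterior> %d boundaries; mode %d; %d%% HPD [%d, %d]\n",
              length(x$boundary), x$mode, round(100 * x$level),
              x$hpd[1L], x$hpd[2L]))
  if (!is.null(x$mode_coord)) {
    cat(sprintf("  original coordinates: mode %d, HPD [%d, %d]\n",
                x$mode_coord, x$hpd_coord[1L], x$hpd_coord[2L]))
  }
  invisible(x)
}

#' @export
tidy.rec_bp_posterior <- function(x, ...) {
  tibble::tibble(
    boundary = x$boundary,
    coord = if (is.null(x$coord)) NA_integer_ else x$coord,
    mass = x$mass,
    in_hpd = x$boundary >= x$hpd[1L] & x$boundary <= x$hpd[2L]
  )
}

# Breakpoint placement (point estimates + HPD CIs in original coordinates)
# for a signal region on a triplet. Begin is fitted on the left flank plus
# region, end on the region plus right flank; a region edge touching the view
# boundary pins that breakpoint with a degenerate CI.
event_breakpoints <- function(trip, recombinant, region_view,
                              emission_error = 0.05) {
  info <- informative_sites(trip, recombinant)
  m <- triplet_n_col(trip)
  orig <- view_to_original(trip, region_view[1L], region_view[2L])
  fallback <- list(
    begin = orig[1L], begin_ci = c(orig[1L], orig[1L]),
    end = orig[2L], end_ci = c(orig[2L], orig[2L]),
    begin_posterior = NULL, end_posterior = NULL
  )
  if (length(info$pos) < 2L) return(fallback)
  pos_orig <- trip$kept_columns[info$pos]
  inside <- which(info$pos >= region_view[1L] & info$pos <= region_view[2L])
  if (length(inside) == 0L) return(fallback)
  refine_error <- function(sym) {
    seg <- viterbi_segments(sym, emission_error = emission_error)
    estimate_emission_error(sym, seg)
  }
  out <- fallback
  lo <- min(inside); hi <- max(inside)
  # begin: left flank + region, switch expected at the region's left junction
  if (region_view[1L] > 1L && lo > 1L) {
    idx <- seq_len(hi)
    sym <- info$sym[idx]
    bp <- breakpoint_posterior(sym, refine_error(sym),
                               positions = pos_orig[idx])
    out$begin <- bp$mode_coord
    out$begin_ci <- bp$hpd_coord
    out$begin_posterior <- bp
  }
  # end: region + right flank
  if (region_view[2L] < m && hi < length(info$pos)) {
    idx <- lo:length(info$pos)
    sym <- info$sym[idx]
    bp <- breakpoint_posterior(sym, refine_error(sym),
                               positions = pos_orig[idx])
    out$end <- bp$mode_coord
    out$end_ci <- bp$hpd_coord
    out$end_posterior <- bp
  }
  if (out$end < out$begin) { # guard against degenerate orderings
    tmp <- out$begin; out$begin <- out$end; out$end <- tmp
    tmp <- out$begin_ci; out$begin_ci <- out$end_ci; out$end_ci <- tmp
  }
  out
}
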