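# Distance-based phylogenetics: JC distances, NJ window trees, RF and
# SH-like (RELL) compatibility matrices, and recombination-aware exports.

#' Jukes-Cantor distance between two alignment rows
#'
#' `d = -(3/4) log(1 - 4p/3)` with `p` the observed difference proportion over
#' comparable columns (neither row gap/`N`).
#'
#' @param aln alignment.
#' @param i,j row indices.
#' @return substitutions/site.
#' @export
jc_distance <- function(aln, i, j) {
  p <- 1 - pairwise_identity(aln, i, j)
  if (is.na(p)) stop("no comparable columns between rows ", i, " and ", j)
  if (p >= 0.75) {
    stop(sprintf("JC distance saturated (p = %.3f) for pair %s / %s",
                 p, aln$names[i], aln$names[j]))
  }
  -0.75 * log(1 - 4 * p / 3)
}

# Pairwise JC matrix with saturation capped (p clamped to 0.70) — engine
# plumbing where an error on a saturated pair would abort a whole scan.
jc_matrix <- function(aln, cap = TRUE) {
  n <- n_seq(aln)
  D <- matrix(0, n, n, dimnames = list(aln$names, aln$names))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      id <- pairwise_identity(aln, i, j)
      p <- if (is.na(id)) 0.70 else min(1 - id, if (cap) 0.70 else 1 - id)
      if (!cap && p >= 0.75) {
        stop(sprintf("JC distance saturated for pair %s / %s",
                     aln$names[i], aln$names[j]))
      }
      D[i, j] <- D[j, i] <- -0.75 * log(1 - 4 * min(p, 0.7499) / 3)
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ via [ape::nj()]; negative branch lengths are clamped to zero.
#'
#' @param D symmetric non-negative distance matrix with zero diagonal.
#' @param names leaf names (default from `D`'s dimnames).
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(D, names = rownames(D)) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(diag(D) != 0)) stop("distance matrix must have a zero diagonal")
  if (any(D < 0)) stop("distance matrix must be non-negative")
  if (!is.null(names)) dimnames(D) <- list(names, names)
  tr <- ape::nj(as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Robinson-Foulds distance between two trees
#'
#' Size of the symmetric difference of the internal split (bipartition) sets.
#'
#' @param t1,t2 `phylo` trees over the same leaf set.
#' @return non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees must share the same leaf set")
  }
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2),
                               check.labels = TRUE))
}

# phyDat for a column window of the alignment.
window_phydat <- function(aln, window) {
  cols <- window[1L]:window[2L]
  m <- aln$mat[, cols, drop = FALSE]
  rownames(m) <- aln$names
  phangorn::as.phyDat(m)
}

# NJ tree for a column window; NULL when the window lacks resolution
# (fewer than 4 pairwise-distinct sequences after gap handling).
window_nj <- function(aln, window) {
  sub <- new_alignment(aln$mat[, window[1L]:window[2L], drop = FALSE],
                       names = aln$names)
  D <- jc_matrix(sub, cap = TRUE)
  distinct <- sum(!duplicated(round(D, 10), MARGIN = 1L))
  if (distinct < 4L) return(NULL)
  nj_tree(D)
}

# Per-site JC log-likelihoods of `tree` on a window, with one coarse global
# branch-length rescaling pass (optimize over a scale factor).
site_loglik <- function(aln, window, tree, refit = TRUE) {
  dat <- window_phydat(aln, window)
  tree$edge.length <- pmax(tree$edge.length, 1e-6)
  fit_at <- function(s) {
    tr <- tree
    tr$edge.length <- tr$edge.length * s
    phangorn::pml(tr, dat)
  }
  s <- 1
  if (refit) {
    opt <- optimize(function(x) fit_at(exp(x))$logLik,
                    interval = c(log(0.2), log(5)), maximum = TRUE, tol = 0.05)
    s <- exp(opt$maximum)
  }
  fit <- fit_at(s)
  fit$siteLik[attr(dat, "index")]
}

#' SH-like RELL support of one window's data for another window's tree
#'
#' Per-site JC log-likelihoods are computed on window `window_i`'s data for
#' both that window's own NJ tree and `tree_j` (fixed topologies, NJ branch
#' lengths with one coarse rescaling pass). Support is the fraction of RELL
#' bootstrap resamples in which the centered log-likelihood difference of
#' `tree_j` is no worse than its observed difference (1 for the window's own
#' topology).
#'
#' @param aln alignment.
#' @param window_i 1-based inclusive column interval `c(from, to)`.
#' @param tree_j a `phylo` over the same leaves.
#' @param n_rell RELL bootstrap replicates.
#' @param seed optional local seed.
#' @return support in \[0, 1\], or `NA` when the window lacks resolution.
#' @export
sh_like_support <- function(aln, window_i, tree_j, n_rell = 200L, seed = NULL) {
  if (window_i[2L] < window_i[1L]) stop("zero-length window")
  if (!is.null(seed)) set.seed(seed)
  ti <- window_nj(aln, window_i)
  if (is.null(ti)) return(NA_real_)
  li <- site_loglik(aln, window_i, ti)
  lj <- site_loglik(aln, window_i, tree_j)
  nsite <- length(li)
  d_obs <- sum(li) - sum(lj)
  W <- rmultinom(n_rell, nsite, rep(1 / nsite, nsite))
  dL <- as.numeric(crossprod(li - lj, W))
  dc <- dL - mean(dL)
  mean(dc >= d_obs - 1e-9)
}

#' Sliding-window phylogenetic compatibility matrices
#'
#' NJ tree per window; lower triangle holds Robinson-Foulds distances between
#' window trees, upper triangle the symmetrized SH-like RELL support of each
#' window's data for the other window's tree. Diagonal is RF 0 / support 1.
#' Windows without 4 pairwise-distinct sequences yield `NA` rows/columns.
#'
#' @param aln alignment.
#' @param window_len,step window geometry in columns.
#' @param n_rell RELL replicates per ordered window pair.
#' @param seed seed for the RELL resampling.
#' @return An object of class `rec_compat`: list with `windows` (tibble of
#'   1-based inclusive window coordinates), `rf` and `support` matrices, and
#'   `matrix` (combined: RF below the diagonal, support above).
#' @export
compatibility_matrix <- function(aln, window_len = 500L, step = 100L,
                                 n_rell = 200L, seed = 1L) {
  L <- aln_length(aln)
  starts <- seq.int(1L, max(1L, L - window_len + 1L), by = step)
  windows <- cbind(starts, pmin(L, starts + window_len - 1L))
  nw <- nrow(windows)
  if (nw < 2L) stop("need at least two windows")
  set.seed(seed)
  trees <- lapply(seq_len(nw), function(k) window_nj(aln, windows[k, ]))
  rf <- matrix(NA_real_, nw, nw)
  sup <- matrix(NA_real_, nw, nw)
  liks <- vector("list", nw) # liks[[i]][[j]]: site logL of tree j on data i
  for (i in seq_len(nw)) {
    if (is.null(trees[[i]])) next
    rf[i, i] <- 0; sup[i, i] <- 1
    liks[[i]] <- lapply(seq_len(nw), function(j) {
      if (is.null(trees[[j]])) return(NULL)
      site_loglik(aln, windows[i, ], trees[[j]])
    })
  }
  for (i in seq_len(nw)) {
    for (j in seq_len(nw)) {
      if (i == j || is.null(trees[[i]]) || is.null(trees[[j]])) next
      if (i > j) rf[i, j] <- rf_distance(trees[[i]], trees[[j]])
      li <- liks[[i]][[i]]; lj <- liks[[i]][[j]]
      nsite <- length(li)
      d_obs <- sum(li) - sum(lj)
      W <- rmultinom(n_rell, nsite, rep(1 / nsite, nsite))
      dL <- as.numeric(crossprod(li - lj, W))
      dc <- dL - mean(dL)
      sup[i, j] <- mean(dc >= d_obs - 1e-9)
    }
  }
  sup_sym <- (sup + t(sup)) / 2
  comb <- matrix(NA_real_, nw, nw)
  comb[lower.tri(comb)] <- rf[lower.tri(rf)]
  comb[upper.tri(comb)] <- sup_sym[upper.tri(sup_sym)]
  diag(comb) <- 0
  structure(list(
    windows = tibble::tibble(window = seq_len(nw),
                             begin = windows[, 1L], end = windows[, 2L]),
    rf = rf, support = sup_sym, matrix = comb
  ), class = "rec_compat")
}

#' @export
print.rec_compat <- function(x, ...) {
  cat(sprintf("<rec_compat> %d windows (%d-%d ... %d-%d)\n",
              nrow(x$windows), x$windows$begin[1L], x$windows$end[1L],
              x$windows$begin[nrow(x$windows)], x$windows$end[nrow(x$windows)]))
  invisible(x)
}

#' Strip detected recombination from an alignment
#'
#' `remove` replaces each recombinant region by gaps in the recombinant rows
#' (column count unchanged); `split` replaces each recombinant row by two
#' rows — the region-only residues (`_minor` suffix) and the complement
#' (`_major` suffix).
#'
#' @param aln alignment.
#' @param events a [consolidate_events()] / [iterate_disassembly()] events
#'   tibble, or any data frame with columns `recombinants` (comma-separated
#'   names) or `recombinant`, plus `begin` and `end` (1-based inclusive).
#' @param mode `"remove"` or `"split"`.
#' @return the edited alignment.
#' @export
strip_recombination <- function(aln, events, mode = c("remove", "split")) {
  mode <- match.arg(mode)
  if (is.null(events) || nrow(events) == 0L) return(aln)
  recs <- if ("recombinants" %in% names(events)) {
    strsplit(events$recombinants, ",\\s*")
  } else {
    as.list(events$recombinant)
  }
  mat <- aln$mat
  nms <- aln$names
  for (k in seq_len(nrow(events))) {
    region <- events$begin[k]:events$end[k]
    for (rn in recs[[k]]) {
      # a sequence split by an earlier event is carried forward as fragments;
      # later events apply to whichever fragment holds residues in the region
      targets <- which(nms == rn | original_name(nms) == rn)
      if (length(targets) == 0L) stop("unknown sequence in events: ", rn)
      for (i in sort(targets, decreasing = TRUE)) {
        if (!any(mat[i, region] != "-")) next
        if (mode == "remove") {
          mat[i, region] <- "-"
        } else {
          base <- nms[i]
          minor <- rep("-", ncol(mat)); minor[region] <- mat[i, region]
          major <- mat[i, ]; major[region] <- "-"
          nm_minor <- make.unique(c(nms[-i], paste0(base, "_minor")))[length(nms)]
          nm_major <- make.unique(c(nms[-i], nm_minor,
                                    paste0(base, "_major")))[length(nms) + 1L]
          keep_major <- any(major != "-")
          if (keep_major) {
            mat <- rbind(mat[-i, , drop = FALSE], minor, major)
            nms <- c(nms[-i], nm_minor, nm_major)
          } else {
            mat <- rbind(mat[-i, , drop = FALSE], minor)
            nms <- c(nms[-i], nm_minor)
          }
        }
      }
    }
  }
  rownames(mat) <- NULL
  new_alignment(mat, names = nms)
}
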