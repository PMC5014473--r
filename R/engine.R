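# Full-alignment scanning: triplet enumeration, multiple-testing control,
# consolidation of method signals into events, iterative disassembly.

#' Scan configuration
#'
#' Every threshold, window and seed used by the scan pipeline, with defaults
#' chosen for ~10 kb viral genome alignments. Unknown keys are rejected.
#'
#' @param ... named overrides of the defaults listed below.
#' @return a `rec_config` list.
#' @export
rec_config <- function(...) {
  defaults <- list(
    methods = c("rdp", "maxchi", "chimaera", "threeseq"),
    alpha = 0.05,
    seed = 1L,
    rdp_window = 30L, rdp_step = 1L,
    maxchi_window = 35L, maxchi_permutations = 2000L,
    chimaera_window = 35L, chimaera_permutations = 2000L,
    threeseq_permutations = 1000L,
    siscan_window = 100L, siscan_step = 20L,
    siscan_randomizations = 500L, siscan_z = 3,
    bootscan_window = 200L, bootscan_step = 20L,
    bootscan_replicates = 100L, bootscan_support = 0.7,
    tie_margin = 0.05,
    overlap_frac = 0.5,
    parent_cluster_jc = 0.05,
    max_iterations = 100L,
    min_variable_sites = 4L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  bad <- setdiff(over$methods, c("rdp", "maxchi", "chimaera", "threeseq",
                                 "siscan", "bootscan"))
  if (length(bad)) stop("unknown methods: ", paste(bad, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "rec_config")
}

#' Write / read a scan configuration as JSON
#'
#' @param config a [rec_config()].
#' @param path file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(rec_config, x)
}

#' Enumerate all sequence triplets
#'
#' @param n number of sequences (>= 3).
#' @return integer matrix with `choose(n, 3)` rows, lexicographic order.
#' @export
enumerate_triplets <- function(n) {
  if (n < 3L) stop("recombination analysis requires >=3 sequences")
  t(combn(n, 3L))
}

run_methods_on_triplet <- function(aln, trip, config, imat, outgroup = NA_integer_) {
  out <- list()
  for (method in config$methods) {
    cand <- switch(method,
      rdp = rdp_scan(trip, config$rdp_window, config$rdp_step),
      maxchi = maxchi_scan(trip, NULL, config$maxchi_window,
                           config$maxchi_permutations),
      chimaera = chimaera_scan(trip, NULL, config$chimaera_window,
                               config$chimaera_permutations),
      threeseq = threeseq_scan(trip, NULL, config$threeseq_permutations),
      siscan = siscan_scan(trip, config$siscan_window, config$siscan_step,
                           config$siscan_randomizations, config$siscan_z),
      bootscan = if (!is.na(outgroup)) {
        bootscan_scan(aln, trip$rows, outgroup, config$bootscan_window,
                      config$bootscan_step, config$bootscan_replicates,
                      config$bootscan_support, imat = imat)
      }
    )
    if (!is.null(cand)) out[[length(out) + 1L]] <- cand
  }
  out
}

#' Scan every triplet of an alignment for recombination signals
#'
#' Runs every enabled method on every triplet; raw p-values are Bonferroni
#' multiplied by the number of triplets examined (window-level correction is
#' already inside each method); candidates with corrected p <= `alpha` for at
#' least one method are retained.
#'
#' @param aln alignment (>= 3 sequences).
#' @param config a [rec_config()].
#' @return An object of class `rec_scan`: list with `candidates` (list of
#'   `rec_signal`), `n_triplets`, `aln`, `config`. Use [generics::tidy()] for
#'   a tibble view.
#' @export
scan_alignment <- function(aln, config = rec_config()) {
  n <- n_seq(aln)
  trips <- enumerate_triplets(n)
  set.seed(config$seed)
  imat <- encode_alignment(aln)
  need_outgroup <- "bootscan" %in% config$methods && n >= 4L
  D <- if (need_outgroup || TRUE) jc_matrix(aln) else NULL
  n_triplets <- nrow(trips)
  candidates <- list()
  for (t in seq_len(n_triplets)) {
    rows <- trips[t, ]
    trip <- make_triplet(aln, rows, imat)
    if (length(trip$variable_sites) < config$min_variable_sites) next
    outgroup <- NA_integer_
    if (need_outgroup) {
      others <- setdiff(seq_len(n), rows)
      if (length(others)) {
        outgroup <- others[which.max(colMeans(D[rows, others, drop = FALSE]))]
      }
    }
    found <- run_methods_on_triplet(aln, trip, config, imat, outgroup)
    for (cand in found) {
      cand$p_corrected <- min(1, cand$p_raw * n_triplets)
      if (cand$p_corrected <= config$alpha) {
        candidates[[length(candidates) + 1L]] <- cand
      }
    }
  }
  structure(list(candidates = candidates, n_triplets = n_triplets,
                 aln = aln, config = config, jc = D),
            class = "rec_scan")
}

#' @export
print.rec_scan <- function(x, ...) {
  cat(sprintf("<rec_scan> %d triplets examined, %d retained candidate(s)\n",
              x$n_triplets, length(x$candidates)))
  invisible(x)
}

#' @export
tidy.rec_scan <- function(x, ...) {
  if (length(x$candidates) == 0L) {
    return(tibble::tibble(
      method = character(), recombinant = character(),
      minor_parent = character(), major_parent = character(),
      begin = integer(), end = integer(), peak = integer(),
      stat = double(), p_raw = double(), p_corrected = double(),
      warnings = character()
    ))
  }
  rows <- lapply(x$candidates, function(cd) {
    tibble::tibble(
      method = cd$method, recombinant = cd$recombinant_name,
      minor_parent = cd$minor_parent, major_parent = cd$major_parent,
      begin = cd$begin, end = cd$end,
      peak = if (is.null(cd$peak) || is.na(cd$peak)) NA_integer_ else cd$peak,
      stat = cd$stat, p_raw = cd$p_raw, p_corrected = cd$p_corrected,
      warnings = paste(cd$warnings, collapse = "; ")
    )
  })
  do.call(rbind, rows)
}

# Reciprocal overlap as a fraction of the smaller region: robust to one
# method's inflated region estimate for the same event.
region_overlap_frac <- function(a, b) {
  inter <- max(0L, min(a[2L], b[2L]) - max(a[1L], b[1L]) + 1L)
  inter / min(a[2L] - a[1L] + 1L, b[2L] - b[1L] + 1L)
}

# Single-linkage parent-compatibility clusters at a JC threshold.
parent_clusters <- function(D, h) {
  if (nrow(D) < 2L) return(setNames(1L, rownames(D)))
  hc <- hclust(as.dist(D), method = "single")
  cutree(hc, h = h)
}

#' Consolidate retained signal candidates into recombination events
#'
#' Greedy clustering: candidates join an event when their regions reciprocally
#' overlap (Jaccard >= `overlap_frac`) and their inferred donors fall in the
#' same single-linkage JC cluster (or are unknown). Each event's breakpoints
#' and credible intervals come from the HMM breakpoint machinery applied to
#' the best-supported candidate's triplet; events are ordered by best
#' corrected p.
#'
#' @param scan a [scan_alignment()] result.
#' @return A `rec_events` tibble: one row per event with recombinant set,
#'   parent representatives, breakpoints with 95% HPD intervals, per-method
#'   corrected p-values and warnings. Per-event internals (posteriors, member
#'   candidates) are in `attr(, "details")`.
#' @export
consolidate_events <- function(scan) {
  config <- scan$config
  cands <- scan$candidates
  if (length(cands) == 0L) return(empty_events())
  ord <- order(vapply(cands, `[[`, 0, "p_corrected"),
               vapply(cands, `[[`, 0, "p_raw"),
               -vapply(cands, `[[`, 0, "stat"))
  cands <- cands[ord]
  clus <- parent_clusters(scan$jc, config$parent_cluster_jc)
  donor_cluster <- function(cd) {
    if (cd$minor_parent == "unknown") NA_integer_ else unname(clus[cd$minor_parent])
  }
  events <- list()
  for (cd in cands) {
    pair <- c(cd$recombinant_name, cd$minor_parent)
    placed <- FALSE
    for (k in seq_along(events)) {
      ev <- events[[k]]
      if (region_overlap_frac(c(cd$begin, cd$end), ev$region) < config$overlap_frac) next
      # a triplet signal implicates the unordered (recombinant, donor) pair;
      # mirror attributions of the same event share that pair
      dc <- donor_cluster(cd)
      pair_hit <- length(intersect(setdiff(pair, "unknown"), ev$pair)) > 0L
      donor_ok <- is.na(dc) || is.na(ev$donor_cluster) || dc == ev$donor_cluster
      if (!pair_hit && !donor_ok) next
      ev$members <- c(ev$members, list(cd))
      ev$pair <- union(ev$pair, setdiff(pair, "unknown"))
      events[[k]] <- ev
      placed <- TRUE
      break
    }
    if (!placed) {
      events[[length(events) + 1L]] <- list(
        best = cd, region = c(cd$begin, cd$end),
        donor_cluster = donor_cluster(cd),
        pair = setdiff(pair, "unknown"), members = list(cd)
      )
    }
  }
  rows <- list(); details <- list()
  for (k in seq_along(events)) {
    ev <- events[[k]]
    # recombinant set: sequences implicated as recombinant by the most member
    # candidates (descendant sets sharing one ancestral event keep several).
    # Mirror attributions are excluded: once a better-voted recombinant is
    # accepted, any sequence its candidates name as the donor cannot itself
    # be a recombinant of the same event.
    votes <- sort(table(vapply(ev$members, `[[`, "", "recombinant_name")),
                  decreasing = TRUE)
    keep <- character(0)
    for (s in names(votes)) {
      if (votes[[s]] < 0.5 * votes[[1L]]) break
      minors <- unlist(lapply(ev$members, function(m) {
        if (m$recombinant_name %in% keep) m$minor_parent else NULL
      }))
      if (s %in% minors) next
      keep <- c(keep, s)
    }
    in_keep <- vapply(ev$members, function(m) m$recombinant_name %in% keep, TRUE)
    ev$recombinants <- keep
    cd <- ev$members[in_keep][[1L]] # members are p-ordered; best kept candidate
    events[[k]] <- ev
    trip <- make_triplet(scan$aln, cd$rows)
    bp <- event_breakpoints(trip, cd$recombinant, cd$region_view)
    pm <- setNames(rep(NA_real_, 6L),
                   c("rdp", "maxchi", "chimaera", "threeseq", "siscan", "bootscan"))
    warns <- character(0)
    for (mcd in ev$members) {
      pm[mcd$method] <- min(pm[mcd$method], mcd$p_corrected, na.rm = TRUE)
      warns <- union(warns, mcd$warnings)
    }
    rows[[k]] <- tibble::tibble(
      event_id = NA_integer_,
      recombinants = paste(ev$recombinants, collapse = ","),
      n_recombinants = length(ev$recombinants),
      minor_parent = cd$minor_parent, major_parent = cd$major_parent,
      begin = bp$begin, begin_lo = bp$begin_ci[1L], begin_hi = bp$begin_ci[2L],
      end = bp$end, end_lo = bp$end_ci[1L], end_hi = bp$end_ci[2L],
      best_method = cd$method, best_p = cd$p_corrected,
      p_rdp = pm[["rdp"]], p_maxchi = pm[["maxchi"]],
      p_chimaera = pm[["chimaera"]], p_threeseq = pm[["threeseq"]],
      p_siscan = pm[["siscan"]], p_bootscan = pm[["bootscan"]],
      warnings = paste(warns, collapse = "; ")
    )
    details[[k]] <- list(best = cd, members = ev$members, breakpoints = bp)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$best_p), , drop = FALSE]
  details <- details[order(vapply(rows, function(r) r$best_p, 0))]
  out$event_id <- seq_len(nrow(out))
  attr(out, "details") <- details
  class(out) <- c("rec_events", class(out))
  out
}

empty_events <- function() {
  out <- tibble::tibble(
    event_id = integer(), recombinants = character(),
    n_recombinants = integer(),
    minor_parent = character(), major_parent = character(),
    begin = integer(), begin_lo = integer(), begin_hi = integer(),
    end = integer(), end_lo = integer(), end_hi = integer(),
    best_method = character(), best_p = double(),
    p_rdp = double(), p_maxchi = double(), p_chimaera = double(),
    p_threeseq = double(), p_siscan = double(), p_bootscan = double(),
    warnings = character()
  )
  attr(out, "details") <- list()
  class(out) <- c("rec_events", class(out))
  out
}

# Strip the fragment suffixes added by disassembly so events always report
# original sequence names.
original_name <- function(nm) {
  sub("(_(minor|major))+(\\.\\d+)?$", "", nm)
}

#' Detect the minimal set of recombination events by iterative disassembly
#'
#' Loop: scan, consolidate, accept the best-supported event, split each of its
#' recombinant rows into a region-only row and a complement row (gaps placed,
#' columns never deleted, so coordinates stay stable), and rescan the expanded
#' alignment; stops when a scan yields no candidate or after
#' `max_iterations`. All coordinates are reported against the original
#' alignment; fragment recombinants are reported under their original names.
#'
#' @param aln alignment.
#' @param config a [rec_config()].
#' @return A `rec_events` tibble of accumulated events (attributes:
#'   `iterations`, `incomplete`).
#' @export
iterate_disassembly <- function(aln, config = rec_config()) {
  work <- aln
  acc <- list()
  iterations <- 0L
  incomplete <- FALSE
  repeat {
    if (iterations >= config$max_iterations) { incomplete <- TRUE; break }
    iterations <- iterations + 1L
    scan <- scan_alignment(work, config)
    events <- consolidate_events(scan)
    if (nrow(events) == 0L) break
    best <- events[1L, , drop = FALSE]
    det <- attr(events, "details")[[1L]]
    raw_recs <- strsplit(best$recombinants, ",")[[1L]]
    best$recombinants <- paste(unique(original_name(raw_recs)), collapse = ",")
    best$n_recombinants <- length(unique(original_name(raw_recs)))
    best$minor_parent <- original_name(best$minor_parent)
    best$major_parent <- original_name(best$major_parent)
    acc[[length(acc) + 1L]] <- list(row = best, detail = det)
    region <- best$begin:best$end
    for (rn in raw_recs) {
      i <- match(rn, work$names)
      if (is.na(i)) next
      minor <- rep("-", aln_length(work)); minor[region] <- work$mat[i, region]
      major <- work$mat[i, ]; major[region] <- "-"
      nm <- work$names
      nm_minor <- make.unique(c(nm[-i], paste0(rn, "_minor")))[length(nm)]
      nm_major <- make.unique(c(nm[-i], nm_minor, paste0(rn, "_major")))[length(nm) + 1L]
      work$mat <- rbind(work$mat[-i, , drop = FALSE], minor, major)
      rownames(work$mat) <- NULL
      work$names <- c(nm[-i], nm_minor, nm_major)
    }
  }
  if (length(acc) == 0L) {
    out <- empty_events()
  } else {
    out <- do.call(rbind, lapply(acc, `[[`, "row"))
    out$event_id <- seq_len(nrow(out))
    attr(out, "details") <- lapply(acc, `[[`, "detail")
    class(out) <- c("rec_events", class(out))
  }
  attr(out, "iterations") <- iterations
  attr(out, "incomplete") <- incomplete
  out
}

#' Write an events table as TSV
#'
#' Fixed column order mirroring the scan report: event id, recombinant(s),
#' minor parent, major parent, begin (with 95% HPD bounds), end (with bounds),
#' per-method corrected p-values, warnings.
#'
#' @param events a `rec_events` tibble.
#' @param path output path.
#' @export
write_events_tsv <- function(events, path) {
  cols <- c("event_id", "recombinants", "n_recombinants", "minor_parent",
            "major_parent", "begin", "begin_lo", "begin_hi",
            "end", "end_lo", "end_hi", "best_method", "best_p",
            "p_rdp", "p_maxchi", "p_chimaera", "p_threeseq",
            "p_siscan", "p_bootscan", "warnings")
  df <- as.data.frame(events)[, cols, drop = FALSE]
  write.table(format(df, digits = 6, scientific = TRUE, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
glance.rec_scan <- function(x, ...) {
  tibble::tibble(
    n_sequences = n_seq(x$aln),
    n_triplets = x$n_triplets,
    n_candidates = length(x$candidates),
    alpha = x$config$alpha
  )
}
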