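#' Simulate a tree-evolved nucleotide alignment
#'
#' Evolves `length` sites along `tree` under the Jukes-Cantor model (branch
#' lengths in expected substitutions/site), one row per leaf. Deterministic
#' given `seed`.
#'
#' @param tree a newick string or an [ape::read.tree()] `phylo` object.
#' @param length number of sites.
#' @param seed integer seed.
#' @return A [new_alignment()] with one row per leaf, rows ordered as the
#'   tree's tip labels.
#' @export
simulate_tree_alignment <- function(tree, length, seed) {
  phy <- if (inherits(tree, "phylo")) tree else suppressWarnings(ape::read.tree(text = tree))
  if (is.null(phy)) stop("malformed newick tree")
  if (is.null(phy$edge.length)) stop("tree must carry branch lengths")
  if (any(phy$edge.length < 0)) stop("negative branch length in tree")
  if (length < 1L) stop("alignment length must be >= 1")
  set.seed(seed)
  dat <- phangorn::simSeq(phy, l = length, type = "DNA")
  mat <- toupper(as.character(dat))
  mat <- mat[phy$tip.label, , drop = FALSE]
  new_alignment(mat, names = rownames(mat))
}

#' Create an empty simulation truth record
#'
#' @param tree the newick (or `phylo`) used for simulation.
#' @param seed the integer seed used.
#' @return An object of class `sim_truth` holding an empty event table.
#' @export
new_sim_truth <- function(tree = NULL, seed = NA_integer_) {
  if (inherits(tree, "phylo")) tree <- ape::write.tree(tree)
  structure(
    list(
      events = tibble::tibble(
        recombinant = character(), donor = character(),
        begin = integer(), end = integer(), order = integer()
      ),
      tree = tree, seed = seed
    ),
    class = "sim_truth"
  )
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d implanted event(s), seed %s\n",
              nrow(x$events), x$seed))
  if (nrow(x$events)) print(x$events)
  invisible(x)
}

#' Implant a recombination event into an alignment
#'
#' Replaces the acceptor row's `region` (1-based inclusive) by the donor row's
#' current residues over the same columns, so nested events (donor itself
#' already recombinant) are supported; the generation order is recorded in the
#' truth record.
#'
#' @param aln alignment.
#' @param donor,acceptor sequence names.
#' @param region integer `c(begin, end)`, 1-based inclusive. An empty region
#'   (`end < begin`) leaves both alignment and truth unchanged.
#' @param truth a [new_sim_truth()] record to extend.
#' @return list with elements `aln` and `truth`.
#' @export
implant_recombination <- function(aln, donor, acceptor, region,
                                  truth = new_sim_truth()) {
  di <- match(donor, aln$names)
  ai <- match(acceptor, aln$names)
  if (is.na(di)) stop("unknown donor sequence: ", donor)
  if (is.na(ai)) stop("unknown acceptor sequence: ", acceptor)
  begin <- as.integer(region[1L]); end <- as.integer(region[2L])
  if (end < begin) return(list(aln = aln, truth = truth))
  if (begin < 1L || end > aln_length(aln)) stop("region out of bounds")
  aln$mat[ai, begin:end] <- aln$mat[di, begin:end]
  truth$events <- rbind(
    truth$events,
    tibble::tibble(
      recombinant = acceptor, donor = donor, begin = begin, end = end,
      order = nrow(truth$events) + 1L
    )
  )
  list(aln = aln, truth = truth)
}

#' Simulate an alignment with implanted, truth-labelled recombination events
#'
#' Convenience wrapper: evolve along the tree, then implant each requested
#' event in order.
#'
#' @param tree newick string or `phylo`.
#' @param length sites.
#' @param events `NULL`, or a data frame with columns `donor`, `acceptor`,
#'   `begin`, `end` (1-based inclusive).
#' @param seed integer seed.
#' @return list with `aln` (alignment) and `truth` ([new_sim_truth()] record).
#' @export
simulate_recombination <- function(tree, length, events = NULL, seed = 1L) {
  aln <- simulate_tree_alignment(tree, length, seed)
  truth <- new_sim_truth(tree, seed)
  if (!is.null(events) && nrow(events)) {
    for (k in seq_len(nrow(events))) {
      res <- implant_recombination(
        aln, events$donor[k], events$acceptor[k],
        c(events$begin[k], events$end[k]), truth
      )
      aln <- res$aln; truth <- res$truth
    }
  }
  list(aln = aln, truth = truth)
}

#' Write a simulation truth table as TSV
#'
#' Columns: recombinant, donor, begin, end, order (1-based inclusive
#' coordinates).
#'
#' @param truth a `sim_truth`.
#' @param path output path.
#' @export
write_truth_tsv <- function(truth, path) {
  write.table(truth$events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
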