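# Triplet machinery: the gap-stripped three-row view every per-triplet
# statistic works on. Residues are encoded as integers (match ALN_ALPHABET)
# once per alignment so triplet construction stays cheap inside full scans.

encode_alignment <- function(aln) {
  m <- matrix(match(aln$mat, ALN_ALPHABET), nrow = nrow(aln$mat))
  m
}

#' Build a triplet view of three alignment rows
#'
#' Strips every column in which any of the three rows carries a gap or `N`,
#' classifies variable sites (>= 2 distinct residues among the three), and
#' precomputes per-pair match vectors.
#'
#' @param aln alignment.
#' @param rows integer vector of three distinct row indices.
#' @param imat optional precomputed integer encoding from a full-alignment
#'   scan; computed on the fly when missing.
#' @return An object of class `rec_triplet`.
#' @export
make_triplet <- function(aln, rows, imat = NULL) {
  stopifnot(length(rows) == 3L, !anyDuplicated(rows))
  if (is.null(imat)) imat <- encode_alignment(aln)
  sub <- imat[rows, , drop = FALSE]
  kept <- which(colSums(sub >= 5L) == 0L) # drop '-' (5) and 'N' (6)
  v <- sub[, kept, drop = FALSE]
  m12 <- v[1L, ] == v[2L, ]
  m13 <- v[1L, ] == v[3L, ]
  m23 <- v[2L, ] == v[3L, ]
  structure(list(
    rows = rows,
    names = aln$names[rows],
    v = v,
    kept_columns = kept,
    match = list(m12, m13, m23),       # pair order: (1,2), (1,3), (2,3)
    pair_idx = list(c(1L, 2L), c(1L, 3L), c(2L, 3L)),
    overall_identity = c(mean(m12), mean(m13), mean(m23)),
    variable_sites = which(!(m12 & m13))
  ), class = "rec_triplet")
}

#' @export
print.rec_triplet <- function(x, ...) {
  cat(sprintf("<rec_triplet> rows %s (%s): %d gap-free columns, %d variable\n",
              paste(x$rows, collapse = ","), paste(x$names, collapse = ","),
              ncol(x$v), length(x$variable_sites)))
  invisible(x)
}

triplet_n_col <- function(trip) ncol(trip$v)

#' Informative sites of a candidate recombinant within a triplet
#'
#' Informative sites are view columns where the two putative parents differ
#' and the candidate matches exactly one of them. The symbol is `"A"` when the
#' candidate matches the lower-indexed parent, `"B"` otherwise, so relabelling
#' the parents flips every symbol.
#'
#' @param trip a [make_triplet()] object.
#' @param candidate which triplet member (1, 2 or 3) is the putative
#'   recombinant.
#' @return list with `pos` (view coordinates), `sym` (character `"A"`/`"B"`),
#'   and `parents` (triplet member indices of the two parents, increasing).
#' @export
informative_sites <- function(trip, candidate) {
  p <- setdiff(1:3, candidate)
  v <- trip$v
  differ <- v[p[1L], ] != v[p[2L], ]
  mA <- v[candidate, ] == v[p[1L], ]
  mB <- v[candidate, ] == v[p[2L], ]
  keep <- differ & (mA | mB)
  pos <- which(keep)
  sym <- ifelse(mA[pos], "A", "B")
  list(pos = pos, sym = sym, parents = p)
}

# Map a view-coordinate interval to original 1-based inclusive coordinates.
view_to_original <- function(trip, from, to) {
  c(trip$kept_columns[from], trip$kept_columns[to])
}

# Maximal runs of TRUE in a logical vector, as a data.frame(start, end, len).
logical_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep], len = r$lengths[keep])
}
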