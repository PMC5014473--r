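#' @useDynLib recscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pbinom pnorm sd cor quantile rmultinom runif optimize setNames
#' @importFrom utils combn write.table read.table head tail
NULL

ALN_ALPHABET <- c("A", "C", "G", "T", "-", "N")

#' Construct an alignment object
#'
#' An alignment is an ordered set of named, equal-length, gapped nucleotide
#' sequences. Residues are canonicalized to the alphabet `A,C,G,T,-,N`:
#' lowercase is upcased, `U` becomes `T`, and IUPAC ambiguity codes (and `?`,
#' `.`) collapse to `N`.
#'
#' @param seqs character vector of sequences (one string per sequence), or a
#'   character matrix with one row per sequence and one column per site.
#' @param names unique sequence identifiers; defaults to `names(seqs)`.
#' @return An object of class `rec_alignment` with fields `names` (identifiers)
#'   and `mat` (character matrix, sequences x columns).
#' @export
new_alignment <- function(seqs, names = base::names(seqs)) {
  force(names) # default reads names(seqs); evaluate before seqs is rewritten
  if (is.matrix(seqs)) {
    mat <- seqs
    if (is.null(names)) names <- rownames(mat)
  } else {
    seqs <- as.character(seqs)
    if (length(seqs) < 1L) stop("alignment must contain at least one sequence")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      bad <- which(lens != lens[1L])[1L]
      lab <- if (!is.null(names)) names[bad] else paste0("#", bad)
      stop(sprintf(
        "ragged alignment: sequence '%s' has length %d, expected %d",
        lab, lens[bad], lens[1L]
      ))
    }
    mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  }
  if (nrow(mat) < 1L || ncol(mat) < 1L) {
    stop("alignment must have at least one sequence and one column")
  }
  if (is.null(names)) names <- paste0("seq", seq_len(nrow(mat)))
  names <- trimws(gsub("\\s+", "_", as.character(names)))
  if (anyDuplicated(names)) {
    dups <- unique(names[duplicated(names)])
    stop("duplicate sequence names: ", paste(dups, collapse = ", "))
  }
  mat <- canonicalize_residues(mat)
  dimnames(mat) <- NULL
  structure(list(names = names, mat = mat), class = "rec_alignment")
}

canonicalize_residues <- function(mat) {
  mat[] <- toupper(mat)
  mat[mat == "U"] <- "T"
  mat[mat == "."] <- "-"
  mat[!(mat %in% ALN_ALPHABET)] <- "N"
  mat
}

#' @export
print.rec_alignment <- function(x, ...) {
  cat(sprintf(
    "<rec_alignment> %d sequences x %d columns\n", n_seq(x), aln_length(x)
  ))
  shown <- head(x$names, 6L)
  for (nm in shown) {
    i <- match(nm, x$names)
    row <- paste(head(x$mat[i, ], 50L), collapse = "")
    cat(sprintf("  %-20s %s%s\n", nm, row, if (aln_length(x) > 50L) "..." else ""))
  }
  if (n_seq(x) > 6L) cat(sprintf("  ... and %d more\n", n_seq(x) - 6L))
  invisible(x)
}

#' @rdname new_alignment
#' @param aln an alignment.
#' @export
aln_length <- function(aln) ncol(aln$mat)

#' @rdname new_alignment
#' @export
n_seq <- function(aln) nrow(aln$mat)

#' @rdname new_alignment
#' @export
aln_strings <- function(aln) {
  setNames(apply(aln$mat, 1L, paste, collapse = ""), aln$names)
}

detect_format <- function(path) {
  lines <- readLines(path, n = 50L, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty alignment file: ", path)
  first <- lines[1L]
  if (startsWith(first, ">")) return("fasta")
  if (toupper(substr(first, 1L, 6L)) == "#NEXUS") return("nexus")
  if (grepl("^\\d+\\s+\\d+", first)) return("phylip")
  stop("cannot auto-detect alignment format of ", path)
}

#' Read a nucleotide alignment
#'
#' Reads FASTA, relaxed sequential PHYLIP (whitespace-delimited names), or the
#' data block of a NEXUS file. The format is auto-detected from the leading
#' characters unless given.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"fasta"`, `"phylip"`, `"nexus"`.
#' @return A [new_alignment()] object.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "phylip", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (format == "auto") format <- detect_format(path)
  recs <- switch(format,
    fasta = read_fasta_records(path),
    phylip = read_phylip_records(path),
    nexus = {
      x <- ape::read.nexus.data(path)
      setNames(vapply(x, paste, "", collapse = ""), names(x))
    }
  )
  if (length(recs) < 1L) stop("no sequences found in ", path)
  new_alignment(recs)
}

read_fasta_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no FASTA records in ", path)
  nm <- sub("^>\\s*", "", lines[hdr])
  nm <- vapply(strsplit(nm, "\\s+"), `[`, "", 1L) # first token is the identifier
  ends <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(k) {
    body <- lines[seq(hdr[k] + 1L, ends[k])]
    body <- body[!grepl("^>", body)]
    gsub("\\s", "", paste(body, collapse = ""))
  }, "")
  setNames(seqs, nm)
}

# Relaxed sequential PHYLIP: "n L" header, then name tokens of up to 250 chars
# followed by sequence characters, possibly wrapped over lines.
read_phylip_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  n <- as.integer(hdr[1L]); L <- as.integer(hdr[2L])
  if (is.na(n) || is.na(L)) stop("malformed PHYLIP header in ", path)
  toks <- unlist(strsplit(trimws(lines[-1L]), "\\s+"))
  toks <- toks[nzchar(toks)]
  nm <- character(n); seqs <- character(n)
  k <- 1L
  for (i in seq_len(n)) {
    if (k > length(toks)) stop("truncated PHYLIP file: ", path)
    nm[i] <- toks[k]; k <- k + 1L
    buf <- character(0)
    got <- 0L
    while (got < L) {
      if (k > length(toks)) {
        stop(sprintf("sequence '%s' in %s is shorter than header length %d",
                     nm[i], path, L))
      }
      buf <- c(buf, toks[k]); got <- got + nchar(toks[k]); k <- k + 1L
    }
    seqs[i] <- paste(buf, collapse = "")
    if (nchar(seqs[i]) != L) {
      stop(sprintf("ragged alignment: sequence '%s' has length %d, expected %d",
                   nm[i], nchar(seqs[i]), L))
    }
  }
  setNames(seqs, nm)
}

#' Write an alignment to file
#'
#' @param aln a [new_alignment()] object.
#' @param path output file path.
#' @param format one of `"fasta"`, `"phylip"`, `"nexus"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip", "nexus")) {
  format <- match.arg(format)
  stopifnot(inherits(aln, "rec_alignment"))
  if (n_seq(aln) < 1L) stop("refusing to write an empty alignment")
  rows <- aln_strings(aln)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "fasta") {
    for (i in seq_along(rows)) {
      writeLines(paste0(">", aln$names[i]), con)
      seq <- rows[[i]]
      starts <- seq(1L, nchar(seq), by = 70L)
      writeLines(substring(seq, starts, pmin(starts + 69L, nchar(seq))), con)
    }
  } else if (format == "phylip") {
    writeLines(sprintf("%d %d", n_seq(aln), aln_length(aln)), con)
    writeLines(sprintf("%s  %s", aln$names, rows), con)
  } else {
    close(con); on.exit()
    dat <- strsplit(rows, "", fixed = TRUE)
    names(dat) <- aln$names
    ape::write.nexus.data(dat, file = path, format = "dna", interleaved = FALSE)
  }
  invisible(path)
}

#' Remove columns gapped or ambiguous in any selected row
#'
#' Returns a view alignment holding only `row_subset` and only those columns
#' in which none of the selected rows carries `-` or `N`, together with a
#' column map from view coordinates back to the original alignment.
#'
#' @param aln alignment.
#' @param row_subset integer row indices (non-empty).
#' @return list with `aln` (the view) and `kept_columns` (integer vector:
#'   `kept_columns[v]` is the original 1-based column of view column `v`).
#' @export
strip_shared_gaps <- function(aln, row_subset) {
  if (length(row_subset) == 0L) stop("row_subset must be non-empty")
  sub <- aln$mat[row_subset, , drop = FALSE]
  ok <- colSums(sub == "-" | sub == "N") == 0L
  kept <- which(ok)
  view <- structure(
    list(names = aln$names[row_subset], mat = sub[, kept, drop = FALSE]),
    class = "rec_alignment"
  )
  list(aln = view, kept_columns = kept)
}

#' Pairwise identity of two rows over a column window
#'
#' Identity is computed over comparable columns only (neither row `-`/`N`).
#'
#' @param aln alignment.
#' @param i,j row indices.
#' @param window 1-based inclusive column interval `c(from, to)`; default the
#'   whole alignment.
#' @return Fraction in `[0, 1]`, or `NA` if no comparable column exists.
#' @export
pairwise_identity <- function(aln, i, j, window = c(1L, aln_length(aln))) {
  from <- window[1L]; to <- window[2L]
  if (to < from) stop("empty window")
  if (from < 1L || to > aln_length(aln)) stop("window out of bounds")
  x <- aln$mat[i, from:to]
  y <- aln$mat[j, from:to]
  comp <- !(x == "-" | x == "N" | y == "-" | y == "N")
  if (!any(comp)) return(NA_real_)
  sum(x[comp] == y[comp]) / sum(comp)
}
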