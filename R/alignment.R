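# 20-residue alphabet used throughout; gaps carry no residue mass.
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Characters outside the 20-aa alphabet that are mapped to gap on input.
NONSTANDARD_AA <- c("B", "Z", "X", "U", "O", "J", ".")

#' Construct an alignment object
#'
#' An `alignment` holds equal-length, aligned protein sequences over the
#' 20-residue alphabet plus the gap character `-`, per-sequence weights, and
#' the original column indices retained after any filtering
#' (`column_labels`).
#'
#' @param ids character vector of sequence identifiers.
#' @param seqs character vector of aligned sequences (equal length).
#' @param weights non-negative per-sequence weights; default all 1.
#' @param column_labels original (1-based) column indices of the retained
#'   columns; default `1:L`.
#' @return an object of class `alignment`.
#' @export
alignment <- function(ids, seqs, weights = rep(1, length(seqs)),
                      column_labels = NULL) {
  if (length(seqs) == 0L) stop("alignment must contain at least one sequence")
  if (length(ids) != length(seqs) || length(weights) != length(seqs)) {
    stop("ids, seqs and weights must have equal length")
  }
  L <- unique(nchar(seqs))
  if (length(L) != 1L) {
    stop("ragged alignment: sequences have unequal lengths (",
         paste(sort(unique(nchar(seqs))), collapse = ", "), ")")
  }
  if (L < 1L) stop("alignment columns: L must be >= 1")
  if (any(weights < 0)) stop("weights must be non-negative")
  seqs <- toupper(seqs)
  bad <- setdiff(unique(strsplit(paste(seqs, collapse = ""), "")[[1]]),
                 c(AA_ALPHABET, "-"))
  if (length(bad)) {
    warning("non-standard characters mapped to gap: ",
            paste(bad, collapse = " "))
    for (ch in bad) seqs <- gsub(ch, "-", seqs, fixed = TRUE)
  }
  if (is.null(column_labels)) column_labels <- seq_len(L)
  if (length(column_labels) != L || is.unsorted(column_labels, strictly = TRUE)) {
    stop("column_labels must be strictly increasing with one entry per column")
  }
  structure(list(ids = as.character(ids), seqs = seqs,
                 weights = as.numeric(weights),
                 column_labels = as.integer(column_labels)),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat("alignment:", length(x$seqs), "sequences x", nchar(x$seqs[1]),
      "columns (Meff-style weight sum ", format(sum(x$weights), digits = 5),
      ")\n", sep = " ")
  invisible(x)
}

#' Number of columns of an alignment
#' @param aln an `alignment`.
#' @return integer column count.
#' @export
n_columns <- function(aln) nchar(aln$seqs[1])

# Integer encoding: 0 = gap, 1..20 = AA_ALPHABET index. Rows = sequences.
aln_matrix <- function(aln) {
  chars <- strsplit(aln$seqs, "")
  m <- matrix(0L, nrow = length(chars), ncol = nchar(aln$seqs[1]))
  for (s in seq_along(chars)) {
    idx <- match(chars[[s]], AA_ALPHABET)
    idx[is.na(idx)] <- 0L
    m[s, ] <- idx
  }
  m
}

#' Read a protein multiple sequence alignment
#'
#' Reads FASTA or Stockholm alignments. Sequence order is preserved, all
#' weights are set to 1 and non-standard residue codes (B, Z, X, U, O, J,
#' '.') are mapped to gaps with a warning.
#'
#' @param path file path.
#' @param format `"fasta"` or `"stockholm"`; default guesses from the
#'   extension (`.sto`/`.stk` means Stockholm).
#' @return an [alignment].
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(sto|stk|stockholm)$", path, ignore.case = TRUE))
      "stockholm" else "fasta"
  }
  if (format == "fasta") {
    set <- tryCatch(Biostrings::readBStringSet(path),
                    error = function(e) stop("failed to parse FASTA '", path,
                                             "': ", conditionMessage(e)))
    if (length(set) == 0L) stop("no sequences in FASTA file: ", path)
    ids <- sub("\\s.*$", "", names(set))
    seqs <- unname(as.character(set))
  } else {
    msa <- tryCatch(
      Biostrings::readAAMultipleAlignment(path, format = "stockholm"),
      error = function(e) stop("failed to parse Stockholm '", path, "': ",
                               conditionMessage(e)))
    um <- Biostrings::unmasked(msa)
    ids <- names(um)
    seqs <- unname(as.character(um))
  }
  alignment(ids = ids, seqs = seqs)
}

#' Write an alignment to FASTA
#' @param aln an [alignment].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  set <- Biostrings::BStringSet(aln$seqs)
  names(set) <- aln$ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Pairwise sequence identity
#'
#' Identity between two aligned sequences: matching non-gap columns divided
#' by columns where at least one sequence is non-gap. A pair that is gap in
#' every column has identity 0 by convention.
#'
#' @param a,b equal-length aligned sequences (strings).
#' @return fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences must have equal aligned length")
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  nongap <- ca != "-" | cb != "-"
  if (!any(nongap)) return(0)
  sum(ca == cb & ca != "-" & cb != "-") / sum(nongap)
}

# All-pairs identity matrix, computed with BLAS via one-hot cross-products.
identity_matrix <- function(aln) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  matches <- matrix(0, n, n)
  for (a in seq_along(AA_ALPHABET)) {
    ia <- m == a
    if (any(ia)) matches <- matches + tcrossprod(ia * 1)
  }
  bothgap <- tcrossprod((m == 0L) * 1)
  denom <- ncol(m) - bothgap
  id <- ifelse(denom > 0, matches / denom, 0)
  diag(id)[denom[cbind(1:n, 1:n)] == 0] <- 0
  id
}

#' Remove redundant sequences
#'
#' Greedy scan in input order: a sequence is dropped when its identity to
#' any already-retained sequence exceeds `threshold` (strict `>`). This
#' mirrors the usual alignment-editor redundancy filter and is
#' deterministic given the input order.
#'
#' @param aln an [alignment].
#' @param threshold identity fraction in (0, 1\]; default 0.95.
#' @return the filtered [alignment] (order preserved).
#' @export
filter_redundant <- function(aln, threshold = 0.95) {
  stopifnot(inherits(aln, "alignment"))
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  id <- identity_matrix(aln)
  n <- length(aln$seqs)
  keep <- logical(n)
  kept <- integer(0)
  for (s in seq_len(n)) {
    if (!length(kept) || all(id[s, kept] <= threshold)) {
      keep[s] <- TRUE
      kept <- c(kept, s)
    }
  }
  alignment(aln$ids[keep], aln$seqs[keep], aln$weights[keep],
            aln$column_labels)
}

#' Remove gappy columns
#'
#' Drops columns whose unweighted gap fraction exceeds `max_gap_frac`
#' (strict `>`); `column_labels` keeps track of the surviving original
#' columns.
#'
#' @param aln an [alignment].
#' @param max_gap_frac maximum tolerated gap fraction; default 0.20.
#' @return list with elements `alignment` (filtered) and `dropped`
#'   (original column labels removed).
#' @export
filter_gap_columns <- function(aln, max_gap_frac = 0.20) {
  stopifnot(inherits(aln, "alignment"))
  if (max_gap_frac < 0 || max_gap_frac > 1) {
    stop("max_gap_frac must be in [0, 1]")
  }
  m <- aln_matrix(aln)
  gap_frac <- colMeans(m == 0L)
  keep <- gap_frac <= max_gap_frac
  if (!any(keep)) stop("empty alignment after filtering: every column has ",
                       "gap fraction > ", max_gap_frac)
  seqs <- vapply(strsplit(aln$seqs, ""),
                 function(ch) paste(ch[keep], collapse = ""), character(1))
  list(alignment = alignment(aln$ids, seqs, aln$weights,
                             aln$column_labels[keep]),
       dropped = aln$column_labels[!keep])
}

#' Map alignment columns to reference residue numbers
#'
#' Columns where the chosen reference sequence is non-gap are assigned
#' consecutive residue numbers starting at `numbering_start`, giving the
#' column-to-residue translation used to report coupled positions in a
#' reference numbering (e.g. human PDE5A1).
#'
#' @param aln an [alignment].
#' @param ref_id identifier of the reference sequence.
#' @param numbering_start residue number of the reference's first residue.
#' @return a `position_map`: data frame with columns `column` (current
#'   column index), `column_label` (original column), `residue` (reference
#'   residue number); attributes `ref_id` and `numbering_start`.
#' @export
map_to_reference <- function(aln, ref_id, numbering_start = 1L) {
  stopifnot(inherits(aln, "alignment"))
  i <- match(ref_id, aln$ids)
  if (is.na(i)) stop("reference id not found in alignment: ", ref_id)
  ch <- strsplit(aln$seqs[i], "")[[1]]
  nongap <- which(ch != "-")
  if (!length(nongap)) {
    warning("reference sequence is all gaps; empty position map")
  }
  pm <- data.frame(column = nongap,
                   column_label = aln$column_labels[nongap],
                   residue = numbering_start + seq_along(nongap) - 1L)
  attr(pm, "ref_id") <- ref_id
  attr(pm, "numbering_start") <- numbering_start
  class(pm) <- c("position_map", "data.frame")
  pm
}

#' Restrict a position map to the columns surviving a filter
#'
#' Reference residue numbers are assigned on the alignment the map was
#' built from; restricting (rather than re-mapping after column
#' filtering) keeps a retained column's residue number stable even when
#' filtered-out columns contained reference residues.
#'
#' @param pm a `position_map`.
#' @param aln the column-filtered [alignment()] (its `column_labels`
#'   select the surviving original columns).
#' @return the restricted `position_map`, with `column` re-indexed into
#'   the filtered alignment.
#' @export
subset_position_map <- function(pm, aln) {
  keep <- pm$column_label %in% aln$column_labels
  out <- pm[keep, , drop = FALSE]
  out$column <- match(out$column_label, aln$column_labels)
  attr(out, "ref_id") <- attr(pm, "ref_id")
  attr(out, "numbering_start") <- attr(pm, "numbering_start")
  class(out) <- c("position_map", "data.frame")
  rownames(out) <- NULL
  out
}

#' Write a column/residue map as TSV
#' @param pm a `position_map` from [map_to_reference()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_position_map <- function(pm, path) {
  out <- data.frame(original_column = pm$column_label,
                    kept_column = pm$column,
                    reference_residue_number = pm$residue)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
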