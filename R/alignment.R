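#' Construct a multiple sequence alignment object
#'
#' A rectangular gapped MSA: parallel vectors of ids and equal-length
#' gapped residue strings.  The gap character is `-`; `.` is accepted on
#' input and normalized.  Columns are indexed 1-based.
#'
#' @param ids Character vector of unique sequence identifiers.
#' @param seqs Character vector of gapped residue strings, all the same
#'   length.
#' @return An object of class `alignment` with elements `ids`, `seqs`,
#'   `n_columns`.
#' @export
new_alignment <- function(ids, seqs) {
  stopifnot(is.character(ids), is.character(seqs), length(ids) == length(seqs))
  if (anyDuplicated(ids))
    stop("duplicate ids in alignment: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ids <- unname(ids)
  seqs <- unname(toupper(gsub(".", "-", seqs, fixed = TRUE)))
  w <- unique(nchar(seqs))
  if (length(w) > 1L)
    stop("alignment rows have unequal lengths: ", paste(w, collapse = ", "))
  structure(list(ids = ids, seqs = seqs,
                 n_columns = if (length(w)) w else 0L),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment: %d sequences x %d columns>\n",
              length(x$ids), x$n_columns))
  invisible(x)
}

#' Alignment as a character matrix (rows = sequences, columns = positions)
#' @param aln An [alignment].
#' @return A character matrix with rownames = sequence ids.
#' @export
alignment_matrix <- function(aln) {
  stopifnot(inherits(aln, "alignment"))
  m <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  if (is.null(m)) m <- matrix(character(0), 0, 0)
  rownames(m) <- aln$ids
  m
}

#' Rebuild an alignment from a character matrix
#' @noRd
alignment_from_matrix <- function(m) {
  new_alignment(rownames(m), apply(m, 1L, paste, collapse = ""))
}

#' Remove gaps from one alignment row, recovering the ungapped sequence
#' @param aln An [alignment].
#' @param id Row identifier.
#' @return Ungapped residue string.
#' @export
degap <- function(aln, id) {
  i <- match(id, aln$ids)
  if (is.na(i)) stop("no such id in alignment: ", id)
  gsub("-", "", aln$seqs[i], fixed = TRUE)
}

#' Subset alignment columns
#' @param aln An [alignment].
#' @param columns Integer vector of 1-based column indices to keep.
#' @return An [alignment].
#' @export
subset_columns <- function(aln, columns) {
  m <- alignment_matrix(aln)[, columns, drop = FALSE]
  alignment_from_matrix(m)
}

#' Subset alignment rows by id
#' @param aln An [alignment].
#' @param ids Identifiers to keep, in the order given.
#' @return An [alignment].
#' @export
subset_rows <- function(aln, ids) {
  idx <- match(ids, aln$ids)
  if (anyNA(idx)) stop("ids not in alignment: ",
                       paste(ids[is.na(idx)], collapse = ", "))
  new_alignment(aln$ids[idx], aln$seqs[idx])
}

#' Per-column gap fractions of an alignment
#' @noRd
column_gap_fraction <- function(aln) {
  m <- alignment_matrix(aln)
  colMeans(m == GAP_CHAR)
}
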