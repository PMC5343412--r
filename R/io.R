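#' Read protein sequences from a FASTA file
#'
#' Parses unaligned (or gapped) protein FASTA.  Sequence bodies may be
#' line-wrapped; residues are upper-cased and terminal `*` stop characters
#' are stripped.  Records are returned as a list of `sequence_record`
#' objects (id, description, residues, taxon, source).
#'
#' @param path Path to a FASTA file.
#' @param source Provenance tag stored on each record (defaults to the file
#'   path).
#' @param gapped If `TRUE`, gap characters (`-` or `.`, normalized to `-`)
#'   are permitted, and the result is returned as an [alignment] instead of
#'   a record list.
#' @return A list of `sequence_record`, or an `alignment` when
#'   `gapped = TRUE`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 demo", "ACDE", "FGHI"), fa)
#' read_fasta(fa)[[1]]$residues
#' @export
read_fasta <- function(path, source = path, gapped = FALSE) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty FASTA file: ", path)
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1]) stop("FASTA must start with a '>' header: ", path)
  grp <- cumsum(is_hdr)
  headers <- sub("^>", "", lines[is_hdr])
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers),
                  sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate sequence ids in ", path, ": ", paste(dup, collapse = ", "))
  }
  bodies <- vapply(split(lines[!is_hdr], grp[!is_hdr]),
                   function(x) paste(gsub("\\s", "", x), collapse = ""), "")
  # groups with no body lines
  out_bodies <- setNames(character(length(ids)), as.character(seq_along(ids)))
  out_bodies[names(bodies)] <- bodies
  out_bodies <- toupper(out_bodies)
  out_bodies <- sub("\\*+$", "", out_bodies)
  out_bodies <- gsub(".", "-", out_bodies, fixed = TRUE)

  ok_chars <- paste0("^[", paste(AMINO_ACIDS, collapse = ""), "X",
                     if (gapped) "-", "]*$")
  bad <- !grepl(ok_chars, out_bodies) | grepl("\\*", out_bodies)
  if (any(bad))
    stop("invalid residue characters in sequence(s): ",
         paste(ids[bad], collapse = ", "))
  if (any(!nzchar(out_bodies)))
    stop("empty sequence body for id(s): ",
         paste(ids[!nzchar(out_bodies)], collapse = ", "))

  if (gapped) {
    return(new_alignment(ids, unname(out_bodies)))
  }
  recs <- lapply(seq_along(ids), function(i)
    sequence_record(ids[i], out_bodies[[i]], description = descs[i],
                    source = source))
  log_stage("read_fasta", file = path, n = length(recs))
  recs
}

#' Write sequence records (or an alignment) to FASTA
#'
#' @param x A list of `sequence_record` or an [alignment].
#' @param path Output file path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  if (inherits(x, "alignment")) {
    ids <- x$ids; seqs <- x$seqs; descs <- rep("", length(ids))
  } else {
    ids <- vapply(x, `[[`, "", "id")
    seqs <- vapply(x, `[[`, "", "residues")
    descs <- vapply(x, function(r) r$description %||% "", "")
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(ids)) {
    hdr <- if (nzchar(descs[i])) paste(ids[i], descs[i]) else ids[i]
    writeLines(paste0(">", hdr), con)
    s <- seqs[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a sequence record
#'
#' @param id Unique identifier (no whitespace).
#' @param residues Amino-acid string (20 standard letters plus X); no gaps.
#' @param description Free-text description.
#' @param taxon Optional group label, e.g. `"green_algae"`.
#' @param source Provenance tag (file of origin or simulator).
#' @return An object of class `sequence_record`.
#' @export
sequence_record <- function(id, residues, description = "", taxon = NA_character_,
                            source = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(residues), length(residues) == 1L, nzchar(residues))
  if (grepl("-", residues, fixed = TRUE))
    stop("sequence_record residues must be ungapped: ", id)
  structure(list(id = id, description = description, residues = residues,
                 taxon = taxon, source = source),
            class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("<sequence_record %s: %d aa%s>\n", x$id, nchar(x$residues),
              if (!is.na(x$taxon)) paste0(", taxon=", x$taxon) else ""))
  invisible(x)
}

#' Read a Stockholm-format alignment (sequence lines only)
#'
#' Markup lines (`#=GC`, `#=GS`, `#=GR`, `#=GF`) are ignored; `.` gaps are
#' normalized to `-`.  Interleaved blocks are concatenated.
#'
#' @param path Path to a Stockholm file.
#' @return An [alignment].
#' @export
read_stockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^# STOCKHOLM", lines[1]))
    stop("not a Stockholm file (missing '# STOCKHOLM' header): ", path)
  seq_lines <- lines[!grepl("^#", lines) & !grepl("^//", lines) &
                       nzchar(trimws(lines))]
  if (!length(seq_lines)) stop("Stockholm file has no sequence lines: ", path)
  parts <- strsplit(trimws(seq_lines), "\\s+")
  ids <- vapply(parts, `[[`, "", 1)
  seqs <- vapply(parts, `[[`, "", 2)
  agg <- vapply(split(seqs, factor(ids, levels = unique(ids))),
                paste, "", collapse = "")
  seqs <- toupper(gsub(".", "-", agg, fixed = TRUE))
  new_alignment(unique(ids), unname(seqs))
}

#' Write an alignment in relaxed Phylip format
#'
#' First line `<n_seqs> <n_cols>`, then one `id<space>sequence` row per
#' sequence.  Identifiers may exceed 10 characters (relaxed dialect) but
#' must not contain whitespace.
#'
#' @param aln An [alignment].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(aln, path) {
  stopifnot(inherits(aln, "alignment"))
  if (!length(aln$ids)) stop("cannot write an empty alignment")
  if (any(grepl("\\s", aln$ids)))
    stop("Phylip ids must not contain whitespace: ",
         paste(aln$ids[grepl("\\s", aln$ids)], collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(aln$ids), aln$n_columns), con)
  writeLines(paste(aln$ids, aln$seqs), con)
  invisible(path)
}

#' Read a relaxed Phylip alignment
#' @param path Path to a relaxed Phylip file written by [write_phylip()].
#' @return An [alignment].
#' @export
read_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2L || anyNA(hdr)) stop("bad Phylip header: ", lines[1])
  body <- strsplit(trimws(lines[-1]), "\\s+")
  ids <- vapply(body, `[[`, "", 1)
  seqs <- vapply(body, function(x) paste(x[-1], collapse = ""), "")
  if (length(ids) != hdr[1]) stop("Phylip row count disagrees with header")
  aln <- new_alignment(ids, seqs)
  if (aln$n_columns != hdr[2]) stop("Phylip column count disagrees with header")
  aln
}

#' Read a Newick tree
#'
#' Wraps [ape::read.tree()] with a balanced-parenthesis pre-check that
#' reports the character offset of the first imbalance.  Internal node
#' labels are interpreted as support values where numeric.
#'
#' @param path Path to a Newick file.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  chars <- strsplit(txt, "")[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0))
    stop("unbalanced parentheses in Newick at character ",
         which(depth < 0)[1])
  if (length(depth) && depth[length(depth)] != 0)
    stop("unbalanced parentheses in Newick: ", sum(chars == "("), " '(' vs ",
         sum(chars == ")"), " ')'")
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop("failed to parse Newick: ", path)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels in tree: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  tr
}

#' Write a tree in Newick format (branch lengths to 6 decimals)
#' @param tree An [ape::phylo] tree, optionally with `node.label` support
#'   values.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(tree$edge.length))
    tree$edge.length <- round(tree$edge.length, 6)
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a data.frame as a TSV report table
#' @noRd
write_tsv_report <- function(df, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
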