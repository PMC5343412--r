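# Hallmark-motif scanning, Kyte-Doolittle hydropathy, hydrophobic-region
# segmentation, motif/segment co-location, and sequence-logo information
# content.

#' Define a hallmark motif
#'
#' A motif is an ordered list of position groups; each group is a set of
#' allowed residues, optionally extended by tolerated substitutions
#' (accepted but annotated, e.g. the F->Y replacement known to leave some
#' DGAT2 enzymes active).  Optional spacer ranges `(min, max)` between
#' consecutive groups are enumerated exhaustively, e.g. the
#' H-X(3,5)-[DE] acyltransferase motif whose His and acidic residue are
#' separated by a few (most often four) residues.
#'
#' @param name Motif name.
#' @param positions List of character vectors: allowed residues per
#'   position group (single letters).
#' @param spacers Optional list (length `length(positions) - 1`) of
#'   2-vectors `c(min, max)`; `NULL` entries mean adjacency.
#' @param tolerated List parallel to `positions` of extra residues
#'   accepted with annotation (or `NULL`).
#' @param required Whether the motif is required during scrutiny.
#' @return A `motif_definition`.
#' @export
motif_definition <- function(name, positions, spacers = NULL,
                             tolerated = NULL, required = TRUE) {
  stopifnot(is.character(name), length(positions) >= 1L)
  if (any(!vapply(positions, length, 0L))) stop("empty position set in motif ", name)
  if (!is.null(spacers)) {
    stopifnot(length(spacers) == length(positions) - 1L)
    for (sp in spacers) if (!is.null(sp) && sp[1] > sp[2])
      stop("spacer min > max in motif ", name)
  }
  structure(list(name = name, positions = positions, spacers = spacers,
                 tolerated = tolerated, required = isTRUE(required)),
            class = "motif_definition")
}

#' Bundle motifs into a family screen
#' @param motifs List of [motif_definition()].
#' @param family Family name the screen belongs to.
#' @return A `motif_screen`.
#' @export
motif_screen <- function(motifs, family = "family") {
  stopifnot(length(motifs) >= 1L,
            all(vapply(motifs, inherits, TRUE, "motif_definition")))
  structure(list(motifs = motifs, family = family), class = "motif_screen")
}

#' Load a motif screen from a YAML definition file
#'
#' The bundled library under `system.file("extdata", "motifs",
#' package = "acylminer")` ships screens for the DGAT2 conserved-block,
#' DGAT3 putative-catalytic and LCAT/PDAT hallmark motifs.
#'
#' @param path YAML file path.
#' @return A [motif_screen()].
#' @export
read_motif_screen <- function(path) {
  y <- yaml::read_yaml(path)
  motifs <- lapply(y$motifs, function(m) {
    positions <- lapply(m$positions, function(p) strsplit(p, "")[[1]])
    spacers <- if (!is.null(m$spacers))
      lapply(m$spacers, function(s) if (is.null(s)) NULL else as.integer(unlist(s)))
    tolerated <- if (!is.null(m$tolerated))
      lapply(m$tolerated, function(p)
        if (is.null(p) || !nzchar(p)) character(0) else strsplit(p, "")[[1]])
    motif_definition(m$name, positions, spacers = spacers,
                     tolerated = tolerated,
                     required = m$required %||% TRUE)
  })
  motif_screen(motifs, family = y$family %||% "family")
}

#' Scan a sequence for hallmark motifs
#'
#' Reports all matches of every motif in the screen, leftmost first.
#' Tolerated substitutions are accepted and annotated; spacer ranges are
#' enumerated exhaustively.
#'
#' @param seq A `sequence_record` or residue string.
#' @param screen A [motif_screen()].
#' @return data.frame with columns `motif`, `start`, `end` (1-based
#'   inclusive), `span` (matched substring), `substitutions`
#'   (semicolon-separated `pos:residue` annotations, empty if none).
#' @export
scan_motifs <- function(seq, screen) {
  res <- if (inherits(seq, "sequence_record")) seq$residues else seq
  ch <- strsplit(res, "", fixed = TRUE)[[1]]
  out <- list()
  for (m in screen$motifs) {
    hits <- scan_one_motif(ch, m)
    if (length(hits)) out <- c(out, hits)
  }
  if (!length(out))
    return(data.frame(motif = character(0), start = integer(0),
                      end = integer(0), span = character(0),
                      substitutions = character(0), stringsAsFactors = FALSE))
  df <- do.call(rbind, lapply(out, as.data.frame, stringsAsFactors = FALSE))
  df <- df[order(df$motif, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

scan_one_motif <- function(ch, m) {
  L <- length(ch)
  ng <- length(m$positions)
  hits <- list()
  match_from <- function(start, g, subs) {
    # returns list of (end, subs) for matches of groups g..ng anchored at start
    if (start > L) return(list())
    a <- ch[start]
    ok_main <- a %in% m$positions[[g]]
    ok_tol <- !ok_main && !is.null(m$tolerated) &&
      length(m$tolerated[[g]]) && a %in% m$tolerated[[g]]
    if (!ok_main && !ok_tol) return(list())
    subs2 <- if (ok_tol) c(subs, paste0(start, ":", a)) else subs
    if (g == ng) return(list(list(end = start, subs = subs2)))
    sp <- if (!is.null(m$spacers)) m$spacers[[g]] else NULL
    rng <- if (is.null(sp)) 0L else sp[1]:sp[2]
    res <- list()
    for (gap in rng)
      res <- c(res, match_from(start + 1L + gap, g + 1L, subs2))
    res
  }
  for (s in seq_len(L)) {
    for (hit in match_from(s, 1L, character(0))) {
      hits[[length(hits) + 1L]] <- list(
        motif = m$name, start = s, end = hit$end,
        span = paste(ch[s:hit$end], collapse = ""),
        substitutions = paste(hit$subs, collapse = ";"))
    }
  }
  hits
}

#' Kyte-Doolittle hydropathy profile
#'
#' Mean hydropathy over a sliding window (default 9, the convention for
#' hydrophobic-region identification); one score per full window position,
#' so `length(scores) == nchar(seq) - window + 1`.  `X` contributes 0.
#'
#' @param seq A `sequence_record` or residue string.
#' @param window Odd window size (default 9).
#' @return An object of class `hydropathy_profile` with `id`, `window`,
#'   `scores`, `length` (sequence length).
#' @export
kd_profile <- function(seq, window = 9L) {
  res <- if (inherits(seq, "sequence_record")) seq$residues else seq
  id <- if (inherits(seq, "sequence_record")) seq$id else "seq"
  stopifnot(window %% 2L == 1L)
  L <- nchar(res)
  if (L < window)
    stop("sequence shorter than window (", L, " < ", window, "): ", id)
  sc <- kyte_doolittle_scale()
  vals <- sc[strsplit(res, "", fixed = TRUE)[[1]]]
  vals[is.na(vals)] <- 0  # X
  cs <- cumsum(c(0, vals))
  scores <- (cs[(window + 1L):(L + 1L)] - cs[1:(L - window + 1L)]) / window
  structure(list(id = id, window = as.integer(window),
                 scores = unname(scores), length = L),
            class = "hydropathy_profile")
}

#' Hydrophobic regions and hydrophobic fraction of a sequence
#'
#' A hydrophobic region is the residue span covered by a maximal run of
#' window positions whose mean hydropathy exceeds `cutoff` (default 0, the
#' conventional Kyte-Doolittle midline).  The hydrophobic fraction is the
#' percentage of residues covered by any region, rounded to the nearest
#' integer.
#'
#' @param profile A [kd_profile()].
#' @param cutoff Score cutoff (default 0; strictly greater counts).
#' @return List with `segments` (data.frame `start`, `end`, `mean_score`)
#'   and `fraction` (percent, 0-100).
#' @export
hydrophobic_segments <- function(profile, cutoff = 0) {
  stopifnot(inherits(profile, "hydropathy_profile"))
  pos <- profile$scores > cutoff
  w <- profile$window
  segs <- data.frame(start = integer(0), end = integer(0),
                     mean_score = numeric(0))
  if (any(pos)) {
    r <- rle(pos)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    raw <- data.frame(
      start = starts[runs],                       # window start = residue start
      end = pmin(ends[runs] + w - 1L, profile$length),
      wfirst = starts[runs], wlast = ends[runs])
    # expanded window spans of nearby runs can overlap; merge them so
    # segments are disjoint and coverage is a true union
    merged <- raw[1, , drop = FALSE]
    for (i in seq_len(nrow(raw))[-1]) {
      last <- nrow(merged)
      if (raw$start[i] <= merged$end[last]) {
        merged$end[last] <- max(merged$end[last], raw$end[i])
        merged$wlast[last] <- raw$wlast[i]
      } else merged <- rbind(merged, raw[i, ])
    }
    segs <- data.frame(
      start = merged$start, end = merged$end,
      mean_score = vapply(seq_len(nrow(merged)), function(i) {
        idx <- seq(merged$wfirst[i], merged$wlast[i])
        mean(profile$scores[idx][pos[idx]])
      }, 0))
  }
  covered <- 0L
  if (nrow(segs)) covered <- sum(segs$end - segs$start + 1L)
  list(segments = segs,
       fraction = round(100 * covered / profile$length))
}

#' Relate motif hits to hydrophobic segments
#'
#' Classifies each motif hit as `embedded` (overlapping a hydrophobic
#' segment), `flanking_hydrophobic` (a segment within `flank` residues of
#' either motif end) or `flanked_by_hydrophilic` — the distinction that
#' separates membrane-associated acyltransferase catalytic motifs from the
#' soluble-type arrangement.
#'
#' @param motif_hits data.frame from [scan_motifs()].
#' @param segments data.frame from [hydrophobic_segments()].
#' @param flank Distance (residues) within which a segment counts as
#'   flanking (default 5).
#' @return `motif_hits` with an added `relation` column.
#' @export
colocate <- function(motif_hits, segments, flank = 5L) {
  relation <- vapply(seq_len(nrow(motif_hits)), function(i) {
    s <- motif_hits$start[i]; e <- motif_hits$end[i]
    if (nrow(segments) == 0L) return("flanked_by_hydrophilic")
    overlap <- segments$start <= e & segments$end >= s
    if (any(overlap)) return("embedded")
    dist <- pmax(segments$start - e, s - segments$end)
    if (any(dist <= flank)) return("flanking_hydrophobic")
    "flanked_by_hydrophilic"
  }, "")
  motif_hits$relation <- relation
  motif_hits
}

#' Sequence-logo information content of alignment columns
#'
#' Per column, over non-gap residues: `R = log2(20) - H - e(n)` where `H`
#' is the Shannon entropy of the residue frequencies in bits and `e(n) =
#' 19 / (2 ln(2) n)` is the small-sample correction (off by default);
#' letter heights are `p_a * R`, clipped at 0.  All-gap columns are
#' reported as missing.
#'
#' @param aln An [alignment].
#' @param columns 1-based column indices (default: all).
#' @param small_sample_correction Apply `e(n)` (default `FALSE`).
#' @return List with `R` (bits per column, `NA` for all-gap columns) and
#'   `heights` (list of named height vectors).
#' @export
logo_bits <- function(aln, columns = seq_len(aln$n_columns),
                      small_sample_correction = FALSE) {
  stopifnot(all(columns >= 1L), all(columns <= aln$n_columns))
  m <- alignment_matrix(aln)[, columns, drop = FALSE]
  R <- numeric(ncol(m)); heights <- vector("list", ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    col <- col[col %in% AMINO_ACIDS]
    n <- length(col)
    if (n == 0L) { R[j] <- NA_real_; heights[[j]] <- NULL; next }
    p <- table(factor(col, levels = AMINO_ACIDS)) / n
    p <- as.numeric(p); names(p) <- AMINO_ACIDS
    H <- -sum(ifelse(p > 0, p * log2(p), 0))
    e_n <- if (small_sample_correction) 19 / (2 * log(2) * n) else 0
    R[j] <- max(log2(20) - H - e_n, 0)
    heights[[j]] <- pmax(p * R[j], 0)
  }
  list(R = R, heights = heights, columns = columns)
}

#' Derive a hallmark screen from conserved alignment windows
#'
#' Builds one required motif per anchor window: each motif position allows
#' exactly the residues observed in that alignment column.  Windows must
#' be gap-free across all rows, so matched residues are contiguous in
#' every member sequence.  Useful for deriving family-specific scrutiny
#' screens (e.g. terminal hallmarks that truncated gene models lack) from
#' a trusted member alignment.
#'
#' @param aln An [alignment].
#' @param anchors List of `c(start_column, length)` windows.
#' @param family Screen family name.
#' @return A [motif_screen()].
#' @export
consensus_screen <- function(aln, anchors, family = "family") {
  m <- alignment_matrix(aln)
  motifs <- lapply(seq_along(anchors), function(i) {
    a <- anchors[[i]]
    cols <- seq(a[1], a[1] + a[2] - 1L)
    stopifnot(max(cols) <= ncol(m))
    sub <- m[, cols, drop = FALSE]
    if (any(sub == GAP_CHAR))
      stop("anchor window ", i, " contains gaps; choose gap-free columns")
    positions <- lapply(seq_len(ncol(sub)), function(j)
      sort(unique(sub[sub[, j] %in% AMINO_ACIDS, j])))
    motif_definition(sprintf("%s_anchor%d", family, i), positions)
  })
  motif_screen(motifs, family = family)
}

#' Locate gap-free, low-entropy anchor windows in an alignment
#'
#' Finds one window of `len` consecutive gap-free columns inside each
#' requested column range (the window minimizing total column entropy),
#' for use with [consensus_screen()].
#'
#' @param aln An [alignment].
#' @param ranges List of `c(first_column, last_column)` ranges to search.
#' @param len Window length (default 8).
#' @return List of `c(start_column, length)` anchors.
#' @export
find_anchor_windows <- function(aln, ranges, len = 8L) {
  m <- alignment_matrix(aln)
  gapfree <- colSums(m == GAP_CHAR) == 0L
  ent <- apply(m, 2L, function(col) {
    p <- table(col[col %in% AMINO_ACIDS])
    p <- p / sum(p)
    -sum(p * log(p))
  })
  lapply(ranges, function(r) {
    starts <- seq(max(1L, r[1]), min(r[2], ncol(m)) - len + 1L)
    ok <- starts[vapply(starts, function(s) all(gapfree[s:(s + len - 1L)]), TRUE)]
    if (!length(ok))
      stop("no gap-free window of length ", len, " in columns ",
           r[1], "-", r[2])
    tot <- vapply(ok, function(s) sum(ent[s:(s + len - 1L)]), 0)
    c(ok[which.min(tot)], len)
  })
}

#' Attach externally produced annotations to a report table
#'
#' Subcellular-targeting and other predictions from external tools are not
#' computed here; this hook merges such labels (a data.frame with an `id`
#' column) onto any per-sequence report produced by the package, keeping
#' report rows without an annotation.
#'
#' @param report A data.frame with an `id` column (e.g. from
#'   [classify_batch()] or a census).
#' @param annotations A data.frame with `id` plus annotation columns.
#' @return `report` with the annotation columns merged in.
#' @export
attach_annotations <- function(report, annotations) {
  stopifnot("id" %in% names(report), "id" %in% names(annotations))
  merge(report, annotations, by = "id", all.x = TRUE, sort = FALSE)
}
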