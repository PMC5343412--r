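# BMGE-like alignment trimming: similarity-smoothed column entropy, gap
# content, minimum block length, and removal of gap-heavy sequences.

#' Trimming configuration
#'
#' Defaults mirror the conventional protein settings for entropy/gap/block
#' trimming: BLOSUM30 similarity smoothing, entropy cutoff 0.7, column gap
#' cutoff 0.2, sequence gap cutoff 0.4, minimum block of 3 columns.
#'
#' @param similarity_matrix Matrix name for [similarity_matrix()].
#' @param entropy_cutoff Columns with smoothed entropy above this are
#'   dropped (`h`, in `[0, 1]`).
#' @param column_gap_cutoff Columns with gap fraction above this are
#'   dropped.
#' @param sequence_gap_cutoff Sequences with gap proportion above this over
#'   the kept columns are removed.
#' @param min_block Minimum length of a kept column run (`b`).
#' @return A `trim_config` list.
#' @export
trim_config <- function(similarity_matrix = "BLOSUM30", entropy_cutoff = 0.7,
                        column_gap_cutoff = 0.2, sequence_gap_cutoff = 0.4,
                        min_block = 3L) {
  stopifnot(entropy_cutoff >= 0, entropy_cutoff <= 1,
            column_gap_cutoff >= 0, column_gap_cutoff <= 1,
            sequence_gap_cutoff >= 0, sequence_gap_cutoff <= 1,
            min_block >= 1L)
  structure(list(similarity_matrix = similarity_matrix,
                 entropy_cutoff = entropy_cutoff,
                 column_gap_cutoff = column_gap_cutoff,
                 sequence_gap_cutoff = sequence_gap_cutoff,
                 min_block = as.integer(min_block)),
            class = "trim_config")
}

#' Similarity-smoothed entropy and gap fraction per alignment column
#'
#' Per column, over the non-gap standard residues with frequency vector
#' `p`: the named similarity matrix is min-shifted to non-negative and
#' normalized to similarity coefficients `M[a,b] = s[a,b] /
#' sqrt(s[a,a] s[b,b])` (unit diagonal), and the smoothed entropy is the
#' von Neumann entropy of the density matrix
#' `rho = sqrt(p) M sqrt(p)` (trace 1):
#' `-sum lambda log lambda / log 20` over the eigenvalues `lambda` of
#' `rho`, clamped at 0 and renormalized.  A perfectly conserved column
#' scores 0 and a uniform column under the identity matrix scores 1;
#' mixtures of similar residues score lower than mixtures of dissimilar
#' ones, which is what makes a similarity matrix useful here at all —
#' a plain frequency smear through a low-identity matrix (BLOSUM30)
#' compresses every column into a narrow high-entropy band and cannot
#' separate conserved from random columns.  All-gap columns get `NA`.
#'
#' @param aln An [alignment].
#' @param matrix_name `"BLOSUM30"` (default) or `"identity"`.
#' @return data.frame with columns `column`, `smoothed_entropy`,
#'   `gap_fraction`.
#' @export
column_scores <- function(aln, matrix_name = "BLOSUM30") {
  stopifnot(inherits(aln, "alignment"), length(aln$ids) >= 1L)
  sigma <- similarity_matrix(matrix_name)
  sigma <- sigma - min(sigma)
  M <- sigma / sqrt(outer(diag(sigma), diag(sigma)))
  m <- alignment_matrix(aln)
  n_rows <- nrow(m)
  ent <- gapf <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    gapf[j] <- sum(col == GAP_CHAR) / n_rows
    res <- col[col %in% AMINO_ACIDS]
    if (!length(res)) { ent[j] <- NA_real_; next }
    p <- as.numeric(table(factor(res, levels = AMINO_ACIDS))) / length(res)
    sp <- sqrt(p)
    rho <- outer(sp, sp) * M
    rho <- rho / sum(diag(rho))
    lam <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
    lam <- pmax(lam, 0)
    lam <- lam / sum(lam)
    ent[j] <- -sum(ifelse(lam > 0, lam * log(lam), 0)) / log(20)
  }
  data.frame(column = seq_len(ncol(m)), smoothed_entropy = ent,
             gap_fraction = gapf)
}

#' Trim an alignment by entropy, gap content, block length and row gaps
#'
#' Steps: (1) drop columns with smoothed entropy above the cutoff; (2)
#' drop columns with gap fraction above the column cutoff; (3) drop kept
#' runs shorter than the minimum block; (4) remove sequences whose gap
#' proportion over the kept columns exceeds the sequence cutoff; (5) if
#' step 4 removed sequences, re-run steps 1-4 once on the reduced row set.
#'
#' @param aln An [alignment].
#' @param config A [trim_config()].
#' @return List with `mask` (data.frame: column, kept, smoothed_entropy,
#'   gap_fraction, block), `alignment` (trimmed), `removed_sequences`
#'   (data.frame: id, reason, gap_fraction).
#' @export
trim_alignment <- function(aln, config = trim_config()) {
  pass <- trim_pass(aln, config)
  if (nrow(pass$removed) > 0L && length(pass$kept_ids) >= 1L) {
    second <- trim_pass(subset_rows(aln, pass$kept_ids), config)
    second$removed <- rbind(pass$removed, second$removed)
    pass <- second
  }
  if (!any(pass$mask$kept))
    stop("trimming removed all columns; relax entropy/gap cutoffs")
  log_stage("trim", n_columns_in = aln$n_columns,
            n_columns_kept = sum(pass$mask$kept),
            n_sequences_removed = nrow(pass$removed))
  list(mask = pass$mask,
       alignment = pass$trimmed,
       removed_sequences = pass$removed)
}

trim_pass <- function(aln, config) {
  scores <- column_scores(aln, config$similarity_matrix)
  kept <- rep(TRUE, nrow(scores))
  kept[!is.na(scores$smoothed_entropy) &
         scores$smoothed_entropy > config$entropy_cutoff] <- FALSE
  kept[is.na(scores$smoothed_entropy)] <- FALSE       # all-gap columns
  kept[scores$gap_fraction > config$column_gap_cutoff] <- FALSE
  # minimum-block rule: kept runs shorter than b are dropped
  r <- rle(kept)
  r$values[r$values & r$lengths < config$min_block] <- FALSE
  kept <- inverse.rle(r)
  block <- integer(length(kept))
  if (any(kept)) {
    r2 <- rle(kept)
    block_ids <- cumsum(r2$values) * r2$values
    block <- inverse.rle(list(lengths = r2$lengths, values = block_ids))
  }
  mask <- data.frame(column = scores$column, kept = kept,
                     smoothed_entropy = scores$smoothed_entropy,
                     gap_fraction = scores$gap_fraction, block = block)
  if (!any(kept)) {
    return(list(mask = mask, trimmed = aln,
                removed = data.frame(id = character(0), reason = character(0),
                                     gap_fraction = numeric(0)),
                kept_ids = aln$ids))
  }
  trimmed <- subset_columns(aln, which(kept))
  m <- alignment_matrix(trimmed)
  row_gap <- rowMeans(m == GAP_CHAR)
  too_gappy <- row_gap > config$sequence_gap_cutoff
  removed <- data.frame(id = aln$ids[too_gappy],
                        reason = rep("gap_fraction_over_cutoff",
                                     sum(too_gappy)),
                        gap_fraction = unname(row_gap[too_gappy]),
                        stringsAsFactors = FALSE)
  list(mask = mask,
       trimmed = subset_rows(trimmed, aln$ids[!too_gappy]),
       removed = removed,
       kept_ids = aln$ids[!too_gappy])
}
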