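# Desk-scale phylogeny on trimmed alignments: Kimura-corrected protein
# distances, neighbor joining, nonparametric bootstrap support, midpoint
# rooting.

#' Kimura-corrected protein distance matrix from an alignment
#'
#' For each pair: `p` = mismatch fraction over shared non-gap columns
#' (positions where either sequence has `X` are excluded), corrected as
#' `d = -ln(1 - p - p^2/5)` (Kimura's approximation to PAM distance).
#'
#' @param aln An [alignment] with at least 3 rows.
#' @param min_overlap Minimum shared non-gap columns per pair (default 30).
#' @return Symmetric numeric matrix (substitutions/site) with zero
#'   diagonal, labelled by sequence id.
#' @export
protein_distance <- function(aln, min_overlap = 30L) {
  stopifnot(inherits(aln, "alignment"))
  n <- length(aln$ids)
  if (n < 3L) stop("need at least 3 sequences for a distance matrix")
  m <- alignment_matrix(aln)
  is_res <- matrix(m %in% AMINO_ACIDS, nrow = n)
  D <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- is_res[i, ] & is_res[j, ]
      if (sum(shared) < min_overlap)
        stop("insufficient overlap (", sum(shared), " < ", min_overlap,
             " columns) between ", aln$ids[i], " and ", aln$ids[j])
      p <- mean(m[i, shared] != m[j, shared])
      arg <- 1 - p - p^2 / 5
      if (arg <= 0)
        stop("distance saturated (p = ", round(p, 3), ") between ",
             aln$ids[i], " and ", aln$ids[j])
      D[i, j] <- D[j, i] <- -log(arg)
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (Q-criterion with Saitou-Nei branch lengths,
#' via [ape::nj()]); negative branch lengths are clamped to zero and the
#' clamped total is reported through the structured log.  The returned
#' tree is unrooted; use [midpoint_root()] for display.
#'
#' @param dm Symmetric distance matrix with zero diagonal.
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) >= 3L)
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(!is.finite(dm))) stop("distance matrix has non-finite entries")
  tr <- ape::nj(dm)
  neg <- tr$edge.length < 0
  if (any(neg)) {
    log_stage("nj_tree", clamped_edges = sum(neg),
              clamped_total = sum(tr$edge.length[neg]))
    tr$edge.length[neg] <- 0
  }
  tr
}

#' Midpoint-root a tree
#' @param tree An [ape::phylo].
#' @return A rooted [ape::phylo].
#' @export
midpoint_root <- function(tree) phangorn::midpoint(tree)

#' Neighbor-joining tree with nonparametric bootstrap support
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds
#' the distance matrix and NJ tree per replicate, and reports for each
#' internal edge of the original tree the fraction of replicates containing
#' the same bipartition.  Deterministic given `seed`.  Replicates whose
#' distances saturate are dropped (the support denominator is the number
#' of successful replicates; a warning reports drops).
#'
#' @param aln An [alignment].
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed RNG seed.
#' @param min_overlap Passed to [protein_distance()].
#' @return List with `tree` (original NJ tree; `node.label` holds support
#'   fractions in `[0, 1]`, `NA` for the root) and `n_effective`
#'   (successful replicates).
#' @export
bootstrap_support <- function(aln, n_reps = 100L, seed = 1L,
                              min_overlap = 30L) {
  stopifnot(n_reps >= 1L)
  tr <- nj_tree(protein_distance(aln, min_overlap))
  m <- alignment_matrix(aln)
  reps <- with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      tryCatch(
        nj_tree(protein_distance(alignment_from_matrix(
          m[, cols, drop = FALSE]), min_overlap)),
        error = function(e) NULL)
    })
  })
  ok <- !vapply(reps, is.null, TRUE)
  if (any(!ok))
    warning(sum(!ok), " bootstrap replicate(s) dropped (saturated distances)")
  reps <- reps[ok]
  counts <- ape::prop.clades(tr, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- counts / length(reps)
  tr$node.label <- formatC(support, format = "g")
  attr(tr, "support") <- support
  log_stage("bootstrap_support", n_reps = n_reps, n_effective = length(reps))
  list(tree = tr, support = support, n_effective = length(reps))
}

#' Bootstrap support for the bipartition defined by a set of leaves
#'
#' Finds the internal edge of `tree` that splits exactly `tips` from the
#' rest and returns its support fraction, or `NA` if the bipartition is
#' absent from the tree.
#'
#' @param btree Result of [bootstrap_support()].
#' @param tips Character vector of leaf labels on one side of the split.
#' @return Support fraction in `[0, 1]`, or `NA`.
#' @export
split_support <- function(btree, tips) {
  tr <- btree$tree
  support <- btree$support
  ntip <- length(tr$tip.label)
  target <- sort(match(tips, tr$tip.label))
  if (anyNA(target)) stop("tips not in tree")
  for (node in (ntip + 1L):(ntip + tr$Nnode)) {
    desc <- unlist(phangorn::Descendants(tr, node, type = "tips"))
    side <- sort(desc)
    other <- sort(setdiff(seq_len(ntip), desc))
    if (identical(side, target) || identical(other, target))
      return(unname(support[node - ntip]))
  }
  NA_real_
}
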