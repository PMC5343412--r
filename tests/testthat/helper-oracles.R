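# Independent oracles used by the tests.  These deliberately avoid the
# package's dynamic-programming / run-length machinery: the forward oracle
# enumerates every state path explicitly, and the trimming oracle is a
# direct loop-based transcription of the documented steps.

# Exhaustive path-enumeration forward score (bits) under the uni-local
# semantics: for every start flank length, every path B -> {M/I/D}* -> E
# is enumerated, with uniform begin->match entry (tr[B->M]/K), exit
# probability 1/K from every pre-terminal match state (its other
# transitions scaled by 1 - 1/K), transition probabilities and emission
# odds multiplied along the way; flanking residues contribute factor 1.
# Tractable for models with <= ~4 match states and sequences of <= ~6
# residues.
oracle_forward_bits <- function(hmm, residues) {
  ch <- strsplit(residues, "", fixed = TRUE)[[1]]
  L <- length(ch)
  K <- hmm$n_match
  tr <- hmm$transitions
  pexit <- function(node) if (node == K) tr[K + 1L, "MM"] else 1 / K
  mscale <- function(node) if (node == K) 1 else 1 - 1 / K
  odds <- function(node, a) {
    if (a == "X") return(1)
    hmm$match_emissions[node, a] / hmm$background[[a]]
  }
  total <- 0
  # state: "B","M","I","D"; node: current node index; i: residues consumed
  step <- function(state, node, i, w) {
    if (w == 0) return()
    row <- node + 1L
    if (state == "B") {
      for (j in seq_len(K)) {          # uniform entry into any match state
        if (i < L) step("M", j, i + 1L,
                        w * (tr[1L, "MM"] / K) * odds(j, ch[i + 1L]))
      }
      if (i < L) step("I", 0L, i + 1L, w * tr[1L, "MI"])
      step("D", 1L, i, w * tr[1L, "MD"])
    } else if (state == "M") {
      total <<- total + w * pexit(node)
      sc <- mscale(node)
      if (node < K && i < L) step("M", node + 1L, i + 1L,
                                  w * sc * tr[row, "MM"] *
                                    odds(node + 1L, ch[i + 1L]))
      if (i < L && !(node == K && tr[row, "MI"] == 0))
        step("I", node, i + 1L, w * sc * tr[row, "MI"])
      if (node < K) step("D", node + 1L, i, w * sc * tr[row, "MD"])
    } else if (state == "I") {
      if (node == K) total <<- total + w * tr[row, "IM"]
      else if (i < L) step("M", node + 1L, i + 1L,
                           w * tr[row, "IM"] * odds(node + 1L, ch[i + 1L]))
      if (i < L) step("I", node, i + 1L, w * tr[row, "II"])
    } else if (state == "D") {
      if (node == K) total <<- total + w * tr[row, "DM"]
      else if (i < L) step("M", node + 1L, i + 1L,
                           w * tr[row, "DM"] * odds(node + 1L, ch[i + 1L]))
      if (node < K) step("D", node + 1L, i, w * tr[row, "DD"])
    }
  }
  for (i0 in 0:L) step("B", 0L, i0, 1)
  unname(log2(total))
}

# Brute-force implementation of the documented trimming steps (entropy ->
# gap -> block -> gappy-sequence removal, one re-pass), written with plain
# loops and no shared code paths with the package beyond the matrix data.
oracle_trim <- function(aln, cfg) {
  sig <- acylminer::similarity_matrix(cfg$similarity_matrix)
  sig <- sig - min(sig)
  aas <- rownames(sig)
  simco <- matrix(0, nrow(sig), ncol(sig), dimnames = dimnames(sig))
  for (a in aas) for (b in aas)
    simco[a, b] <- sig[a, b] / sqrt(sig[a, a] * sig[b, b])

  one_pass <- function(ids, seqs) {
    mat <- do.call(rbind, strsplit(seqs, ""))
    nc <- ncol(mat); nr <- nrow(mat)
    keep <- rep(TRUE, nc)
    for (j in seq_len(nc)) {
      col <- mat[, j]
      gap_frac <- sum(col == "-") / nr
      res <- col[col %in% aas]
      if (length(res) == 0) { keep[j] <- FALSE; next }
      p <- rep(0, length(aas)); names(p) <- aas
      for (a in res) p[a] <- p[a] + 1
      p <- p / sum(p)
      rho <- matrix(0, length(aas), length(aas))
      for (ai in seq_along(aas)) for (bi in seq_along(aas))
        rho[ai, bi] <- sqrt(p[ai]) * simco[ai, bi] * sqrt(p[bi])
      rho <- rho / sum(diag(rho))
      lam <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
      lam[lam < 0] <- 0
      lam <- lam / sum(lam)
      h <- 0
      for (l in lam) if (l > 0) h <- h - l * log(l)
      h <- h / log(20)
      if (h > cfg$entropy_cutoff) keep[j] <- FALSE
      if (gap_frac > cfg$column_gap_cutoff) keep[j] <- FALSE
    }
    # block rule: walk runs explicitly
    j <- 1L
    while (j <= nc) {
      if (keep[j]) {
        k <- j
        while (k < nc && keep[k + 1L]) k <- k + 1L
        if (k - j + 1L < cfg$min_block) keep[j:k] <- FALSE
        j <- k + 1L
      } else j <- j + 1L
    }
    kept_cols <- which(keep)
    removed <- character(0)
    if (length(kept_cols)) {
      for (r in seq_len(nr)) {
        row <- mat[r, kept_cols]
        if (sum(row == "-") / length(row) > cfg$sequence_gap_cutoff)
          removed <- c(removed, ids[r])
      }
    }
    list(keep = keep, removed = removed)
  }

  p1 <- one_pass(aln$ids, aln$seqs)
  removed_all <- p1$removed
  keep_ids <- setdiff(aln$ids, removed_all)
  final <- p1
  if (length(p1$removed) > 0 && length(keep_ids) >= 1) {
    idx <- match(keep_ids, aln$ids)
    p2 <- one_pass(aln$ids[idx], aln$seqs[idx])
    removed_all <- c(removed_all, p2$removed)
    keep_ids <- setdiff(keep_ids, p2$removed)
    final <- p2
  }
  mat <- do.call(rbind, strsplit(aln$seqs, ""))
  rows <- match(keep_ids, aln$ids)
  out <- apply(mat[rows, which(final$keep), drop = FALSE], 1L,
               paste, collapse = "")
  list(keep = final$keep, removed = removed_all,
       ids = keep_ids, seqs = unname(out))
}

# Random gapped alignment generator for property tests.
random_alignment <- function(n_rows = 20L, n_cols = 60L, gap_prob = 0.15,
                             conserved_frac = 0.3) {
  aas <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")
  cons <- stats::runif(n_cols) < conserved_frac
  cons_res <- sample(aas, n_cols, replace = TRUE)
  rows <- vapply(seq_len(n_rows), function(i) {
    ch <- ifelse(cons & stats::runif(n_cols) < 0.9, cons_res,
                 sample(aas, n_cols, replace = TRUE))
    ch[stats::runif(n_cols) < gap_prob] <- "-"
    paste(ch, collapse = "")
  }, "")
  # keep at least one residue per row so degap is non-empty
  new_alignment(sprintf("r%02d", seq_len(n_rows)), rows)
}

# Random small profile for forward-oracle grids: build from a random
# ungapped alignment so all invariants hold by construction.
random_small_hmm <- function(K = 3L, n_rows = 4L) {
  aas <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")
  rows <- replicate(n_rows, paste(sample(aas, K, replace = TRUE),
                                  collapse = ""))
  build_profile(new_alignment(sprintf("s%d", seq_len(n_rows)), rows),
                pseudocount_weight = stats::runif(1, 0.2, 2))
}

random_residues <- function(L) {
  aas <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")
  paste(sample(aas, L, replace = TRUE), collapse = "")
}
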