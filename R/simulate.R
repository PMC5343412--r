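# Synthetic protein-superfamily generator.  Families evolve from a random
# root down a clade tree under the WAG substitution model with indels, and
# are mixed with background decoys, so every mining/classification stage can
# be scored against known labels.

#' Specify a synthetic protein family
#'
#' @param n_clades Number of clades (>= 1), arranged as a star of stem
#'   branches from the root.
#' @param seqs_per_clade Leaves per clade (>= 2), on a balanced topology.
#' @param root_length Root sequence length in residues (>= 30).
#' @param within_clade_divergence Expected substitutions/site on every
#'   within-clade branch.
#' @param between_clade_divergence Expected substitutions/site on each stem
#'   branch.
#' @param indel_rate Indel events per site per unit branch length
#'   (insertion/deletion equiprobable, geometric length of mean 3).
#' @param truncation_fraction Fraction of members emitted with one terminus
#'   truncated (a uniform 20-60% of the sequence removed).
#' @param duplicate_fraction Fraction of members re-emitted byte-identically
#'   under new ids (redundant gene models).
#' @param seed RNG seed; fixes the full output byte-for-byte.
#' @return A `family_spec` list.
#' @export
family_spec <- function(n_clades = 1L, seqs_per_clade = 10L,
                        root_length = 300L,
                        within_clade_divergence = 0.3,
                        between_clade_divergence = 0.8,
                        indel_rate = 0.01,
                        truncation_fraction = 0,
                        duplicate_fraction = 0,
                        seed = 1L) {
  stopifnot(n_clades >= 1L)
  if (seqs_per_clade < 2L) stop("seqs_per_clade must be >= 2")
  if (root_length < 30L) stop("root_length must be >= 30 (profiles degenerate)")
  stopifnot(within_clade_divergence >= 0, between_clade_divergence >= 0,
            indel_rate >= 0,
            truncation_fraction >= 0, truncation_fraction <= 1,
            duplicate_fraction >= 0, duplicate_fraction <= 1)
  structure(list(n_clades = as.integer(n_clades),
                 seqs_per_clade = as.integer(seqs_per_clade),
                 root_length = as.integer(root_length),
                 within_clade_divergence = within_clade_divergence,
                 between_clade_divergence = between_clade_divergence,
                 indel_rate = indel_rate,
                 truncation_fraction = truncation_fraction,
                 duplicate_fraction = duplicate_fraction,
                 seed = as.integer(seed)),
            class = "family_spec")
}

balanced_clade_newick <- function(labels, bl) {
  # balanced binary topology, every branch = bl
  build <- function(lab) {
    n <- length(lab)
    if (n == 1L) return(sprintf("%s:%g", lab, bl))
    h <- ceiling(n / 2)
    sprintf("(%s,%s):%g", build(lab[1:h]), build(lab[(h + 1):n]), bl)
  }
  build(labels)
}

#' Evolve a root sequence along an arbitrary tree
#'
#' Simulates amino-acid substitution (WAG) and indels along every branch of
#' `tree`, tracking the site-lineage history so the true multiple alignment
#' of the leaves can be reconstructed.  This is the engine behind
#' [simulate_family()]; call it directly to plant clades on custom
#' topologies.  Uses the current RNG state (seed management is the
#' caller's job).
#'
#' @param tree An [ape::phylo] tree with branch lengths in expected
#'   substitutions/site.
#' @param root_length Root sequence length.
#' @param indel_rate Indel events per site per unit branch length.
#' @return List with `records` (leaf `sequence_record`s in tip order) and
#'   `alignment` (the true leaf alignment implied by the indel history).
#' @export
evolve_along_tree <- function(tree, root_length, indel_rate = 0) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  freq <- wag_frequencies()
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  env <- new.env(parent = emptyenv())
  env$counter <- root_length
  env$order <- seq_len(root_length)

  root_seq <- list(ids = seq_len(root_length),
                   res = sample.int(20L, root_length, replace = TRUE,
                                    prob = freq))
  node_seqs <- vector("list", max(tree$edge))
  node_seqs[[root]] <- root_seq

  tree <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    node_seqs[[child]] <- evolve_branch(node_seqs[[parent]],
                                        tree$edge.length[e], indel_rate,
                                        freq, env)
  }

  records <- lapply(seq_len(ntip), function(i) {
    s <- node_seqs[[i]]
    sequence_record(tree$tip.label[i],
                    paste(AMINO_ACIDS[s$res], collapse = ""),
                    source = "simulator")
  })

  # true alignment: one column per surviving site lineage, in birth order
  leaf_ids <- lapply(seq_len(ntip), function(i) node_seqs[[i]]$ids)
  used <- sort(unique(unlist(leaf_ids)))
  cols <- env$order[env$order %in% used]
  rows <- vapply(seq_len(ntip), function(i) {
    s <- node_seqs[[i]]
    ch <- rep(GAP_CHAR, length(cols))
    hit <- match(s$ids, cols)
    ch[hit] <- AMINO_ACIDS[s$res]
    paste(ch, collapse = "")
  }, "")
  list(records = records,
       alignment = new_alignment(tree$tip.label, rows))
}

evolve_branch <- function(seq, t, indel_rate, freq, env) {
  res <- seq$res; ids <- seq$ids
  if (t > 0) {
    P <- wag_transition_matrix(t)
    for (a in unique(res)) {
      idx <- which(res == a)
      res[idx] <- sample.int(20L, length(idx), replace = TRUE, prob = P[a, ])
    }
    n_ev <- stats::rpois(1L, indel_rate * length(res) * t)
    for (ev in seq_len(n_ev)) {
      L <- length(res)
      len <- stats::rgeom(1L, 1 / 3) + 1L
      if (stats::runif(1) < 0.5 && L > 1L) {           # deletion
        pos <- sample.int(L, 1L)
        del <- pos:min(pos + len - 1L, L)
        res <- res[-del]; ids <- ids[-del]
      } else {                                          # insertion
        pos <- sample.int(L + 1L, 1L) - 1L              # after site `pos`
        new_res <- sample.int(20L, len, replace = TRUE, prob = freq)
        new_ids <- env$counter + seq_len(len)
        env$counter <- env$counter + len
        anchor <- if (pos == 0L) {
          if (L == 0L) length(env$order) else match(ids[1L], env$order) - 1L
        } else match(ids[pos], env$order)
        env$order <- append(env$order, new_ids, after = anchor)
        res <- append(res, new_res, after = pos)
        ids <- append(ids, new_ids, after = pos)
      }
    }
  }
  list(ids = ids, res = res)
}

#' Simulate a protein superfamily with known clade labels
#'
#' Draws a random root sequence from WAG background frequencies and evolves
#' it down a clade tree (balanced clades on a star of stem branches) with
#' substitutions and indels.  A chosen fraction of members is emitted
#' truncated (a uniform 20-60% of one terminus removed) and another
#' fraction re-emitted as byte-identical duplicates under new ids,
#' emulating fragmentary and redundant gene models.
#'
#' @param spec A [family_spec()].
#' @return List with `tree` (true tree), `records` (leaf sequences,
#'   truncated where labelled, plus duplicate re-emissions), `labels`
#'   (data.frame: id, clade, is_truncated, is_duplicate_of, is_decoy), and
#'   `alignment` (true alignment; truncated members have their removed
#'   residues gapped).
#' @export
simulate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  with_seed(spec$seed, {
    clade_names <- sprintf("c%d", seq_len(spec$n_clades))
    labels_by_clade <- lapply(clade_names, function(cn)
      sprintf("%s_s%02d", cn, seq_len(spec$seqs_per_clade)))
    sub <- vapply(labels_by_clade, balanced_clade_newick,
                  "", bl = spec$within_clade_divergence)
    nwk <- if (spec$n_clades == 1L) paste0(sub, ";") else
      paste0("(", paste(sprintf("%s:%g", sub, spec$between_clade_divergence),
                        collapse = ","), ");")
    # balanced_clade_newick wraps each clade in (...):bl; strip the outer
    # branch length for the single-clade case
    tree <- ape::read.tree(text = nwk)
    ev <- evolve_along_tree(tree, spec$root_length, spec$indel_rate)
    records <- ev$records
    aln <- ev$alignment
    ids <- vapply(records, `[[`, "", "id")
    clade <- sub("_s[0-9]+$", "", ids)

    n <- length(records)
    labels <- data.frame(id = ids, clade = clade,
                         is_truncated = FALSE,
                         is_duplicate_of = NA_character_,
                         is_decoy = FALSE, stringsAsFactors = FALSE)

    # truncation of a uniform 20-60% of one terminus
    n_trunc <- round(spec$truncation_fraction * n)
    if (n_trunc > 0) {
      pick <- sample(n, n_trunc)
      amat <- alignment_matrix(aln)
      for (i in pick) {
        res <- records[[i]]$residues
        L <- nchar(res)
        cut <- max(1L, round(stats::runif(1, 0.2, 0.6) * L))
        from_n <- stats::runif(1) < 0.5
        keep <- if (from_n) (cut + 1L):L else 1:(L - cut)
        records[[i]]$residues <- substr(res, min(keep), max(keep))
        labels$is_truncated[i] <- TRUE
        row <- amat[i, ]
        respos <- which(row != GAP_CHAR)
        row[respos[-keep]] <- GAP_CHAR
        amat[i, ] <- row
      }
      aln <- alignment_from_matrix(amat)
    }

    # byte-identical duplicate gene models
    n_dup <- round(spec$duplicate_fraction * n)
    if (n_dup > 0) {
      pick <- sample(n, n_dup)
      for (i in pick) {
        rec <- records[[i]]
        did <- paste0(rec$id, "_dup")
        records[[length(records) + 1L]] <-
          sequence_record(did, rec$residues, taxon = rec$taxon,
                          source = "simulator")
        labels <- rbind(labels, data.frame(
          id = did, clade = labels$clade[i], is_truncated = labels$is_truncated[i],
          is_duplicate_of = rec$id, is_decoy = FALSE, stringsAsFactors = FALSE))
      }
    }
    log_stage("simulate_family", n_clades = spec$n_clades,
              n_records = length(records), n_truncated = n_trunc,
              n_duplicates = n_dup)
    list(tree = tree, records = records, labels = labels, alignment = aln)
  })
}

#' Embed a simulated family in a decoy proteome
#'
#' Shuffles family members among unrelated decoy proteins drawn i.i.d.
#' from WAG background frequencies, extending the label table with
#' `is_decoy` rows.
#'
#' @param family Output of [simulate_family()].
#' @param n_decoys Number of decoy sequences (>= 0).
#' @param decoy_length_range Length range (uniform integer draw).
#' @param seed RNG seed.
#' @param taxon Optional taxon tags: a character vector recycled over the
#'   shuffled proteome (e.g. alternating group labels), or `NA`.
#' @return List with `records` (shuffled proteome) and `labels`.
#' @export
simulate_proteome <- function(family, n_decoys, decoy_length_range = c(200L, 500L),
                              seed = 1L, taxon = NA_character_) {
  stopifnot(n_decoys >= 0)
  with_seed(seed, {
    freq <- wag_frequencies()
    decoys <- lapply(seq_len(n_decoys), function(i) {
      L <- sample(seq(decoy_length_range[1], decoy_length_range[2]), 1L)
      sequence_record(sprintf("decoy_%03d", i),
                      paste(sample(AMINO_ACIDS, L, replace = TRUE, prob = freq),
                            collapse = ""),
                      source = "simulator")
    })
    labels <- rbind(family$labels,
                    if (n_decoys > 0) data.frame(
                      id = vapply(decoys, `[[`, "", "id"),
                      clade = NA_character_, is_truncated = FALSE,
                      is_duplicate_of = NA_character_, is_decoy = TRUE,
                      stringsAsFactors = FALSE))
    records <- c(family$records, decoys)
    records <- records[sample(length(records))]
    if (!all(is.na(taxon))) {
      tx <- rep_len(taxon, length(records))
      for (i in seq_along(records)) records[[i]]$taxon <- tx[i]
    }
    log_stage("simulate_proteome", n_family = length(family$records),
              n_decoys = n_decoys)
    list(records = records, labels = labels)
  })
}
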