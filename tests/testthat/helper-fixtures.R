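# Shared simulated fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# Standard mining fixture: one family of 10 members (2 truncated, 2
# byte-identical duplicates) among 200 background decoys, divergence 0.3
# on within-clade branches.
fixture_standard <- function() {
  memo("standard", {
    fam <- simulate_family(family_spec(
      n_clades = 1L, seqs_per_clade = 10L, root_length = 300L,
      within_clade_divergence = 0.3, indel_rate = 0.01,
      truncation_fraction = 0.2, duplicate_fraction = 0.2, seed = 7L))
    prot <- simulate_proteome(fam, n_decoys = 200L,
                              decoy_length_range = c(200L, 400L), seed = 8L)
    # family-specific hallmark screen from conserved windows near both
    # termini, derived from the full-length members (truncated rows carry
    # terminus gaps): truncated members lack one of the anchors
    full_ids <- fam$labels$id[!fam$labels$is_truncated &
                                is.na(fam$labels$is_duplicate_of)]
    full_aln <- subset_rows(fam$alignment, full_ids)
    anchors <- find_anchor_windows(
      full_aln,
      list(c(1L, round(full_aln$n_columns * 0.15)),
           c(round(full_aln$n_columns * 0.85), full_aln$n_columns)),
      len = 8L)
    screen <- consensus_screen(full_aln, anchors, family = "fixture_fam")
    list(family = fam, proteome = prot, screen = screen)
  })
}

# Unrelated family used as the competing clade when classifying
# quarantined sequences of the standard fixture.
fixture_other_family <- function() {
  memo("other_family", {
    fam <- simulate_family(family_spec(
      n_clades = 1L, seqs_per_clade = 8L, root_length = 280L,
      within_clade_divergence = 0.25, indel_rate = 0.01, seed = 99L))
    # move into a distinct id namespace so fixtures can share a proteome
    rename <- function(id) sub("^c1", "of", id)
    fam$records <- lapply(fam$records, function(r) { r$id <- rename(r$id); r })
    fam$labels$id <- rename(fam$labels$id)
    fam$alignment$ids <- rename(fam$alignment$ids)
    fam$tree$tip.label <- rename(fam$tree$tip.label)
    fam
  })
}

# Remote-clade fixture: clade A (the seed), clade B within single-profile
# reach, clade C beyond it but within reach of the A+B-enriched profile
# (chain topology, stems 0.8, clade radius 0.15).
fixture_remote <- function() {
  memo("remote", {
    a <- paste(sprintf("A%d:0.15", 1:6), collapse = ",")
    b <- paste(sprintf("B%d:0.15", 1:5), collapse = ",")
    cc <- paste(sprintf("C%d:0.15", 1:5), collapse = ",")
    nwk <- sprintf("(%s,(%s,(%s):0.8):0.8);", a, b, cc)
    tree <- ape::read.tree(text = nwk)
    ev <- with_seed(11L, evolve_along_tree(tree, root_length = 300L,
                                           indel_rate = 0.005))
    decoys <- simulate_proteome(list(records = ev$records,
                                     labels = data.frame()),
                                n_decoys = 100L,
                                decoy_length_range = c(250L, 350L),
                                seed = 12L)
    # superfamily-wide hallmark screen (conserved across all three
    # clades): the scrutiny step each mining cycle keeps borderline
    # background hits from drifting into the profile
    anchors <- find_anchor_windows(
      ev$alignment, list(c(1L, ev$alignment$n_columns)), len = 8L)
    screen <- consensus_screen(ev$alignment, anchors, family = "remote_fx")
    list(tree = tree, alignment = ev$alignment, records = ev$records,
         proteome = decoys$records, screen = screen)
  })
}

# Four-clade classification fixture: star clades (radius 0.3) on stems of
# 0.8; 10 training + 100 held-out members per clade.
fixture_clades4 <- function() {
  memo("clades4", {
    n_per <- 110L
    clades <- c("A", "B", "C", "D")
    sub <- vapply(clades, function(cl)
      sprintf("(%s):0.8", paste(sprintf("%s%03d:0.3", cl, seq_len(n_per)),
                                collapse = ",")), "")
    tree <- ape::read.tree(text = sprintf("(%s);", paste(sub, collapse = ",")))
    ev <- with_seed(21L, evolve_along_tree(tree, root_length = 300L,
                                           indel_rate = 0.005))
    ids <- vapply(ev$records, `[[`, "", "id")
    train <- unlist(lapply(clades, function(cl)
      sprintf("%s%03d", cl, 1:10)))
    heldout <- setdiff(ids, train)
    panel <- lapply(clades, function(cl) {
      aln <- subset_rows(ev$alignment, sprintf("%s%03d", cl, 1:10))
      clade_model(cl, aln, mean_length = 300L, seed = 31L)
    })
    list(records = ev$records, alignment = ev$alignment,
         train = train, heldout = heldout, panel = panel, clades = clades)
  })
}

with_seed <- acylminer:::with_seed

# End-to-end pipeline configuration over the standard + second-family
# fixtures, with alternating taxon groups.
pipeline_fixture_config <- function(out_dir) {
  fx <- fixture_standard()
  other <- fixture_other_family()
  proteome <- c(fx$proteome$records, other$records)
  proteome <- lapply(seq_along(proteome), function(i) {
    r <- proteome[[i]]
    r$taxon <- if (i %% 2 == 0) "group_even" else "group_odd"
    r
  })
  list(
    out_dir = out_dir,
    seed = 123L,
    proteome = proteome,
    families = list(
      fam_main = list(seed_msa = fx$family$alignment, scrutiny = fx$screen),
      fam_other = list(seed_msa = other$alignment)),
    mining = list(inclusion_evalue = 0.01, max_iterations = 10L),
    trim = list(entropy_cutoff = 0.9, column_gap_cutoff = 0.4,
                sequence_gap_cutoff = 0.6),
    phylo = list(bootstrap_reps = 20L))
}
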