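test_that("family spec validates its inputs", {
  expect_error(family_spec(seqs_per_clade = 1L), "seqs_per_clade")
  expect_error(family_spec(root_length = 20L), "root_length")
  expect_error(family_spec(truncation_fraction = 1.5), "truncation_fraction")
})

test_that("zero-rate limits: identical leaves, gap-free alignment, fixed length", {
  spec <- family_spec(n_clades = 2L, seqs_per_clade = 3L, root_length = 60L,
                      within_clade_divergence = 0, between_clade_divergence = 0,
                      indel_rate = 0, seed = 3L)
  fam <- simulate_family(spec)
  res <- vapply(fam$records, `[[`, "", "residues")
  expect_length(unique(res), 1L)
  expect_false(any(grepl("-", fam$alignment$seqs, fixed = TRUE)))
  # indels off, divergence on: lengths preserved
  fam2 <- simulate_family(family_spec(seqs_per_clade = 4L, root_length = 80L,
                                      within_clade_divergence = 0.3,
                                      indel_rate = 0, seed = 4L))
  expect_true(all(nchar(vapply(fam2$records, `[[`, "", "residues")) == 80L))
})

test_that("a seed fixes the full simulator output byte-for-byte", {
  spec <- family_spec(n_clades = 2L, seqs_per_clade = 4L, root_length = 100L,
                      indel_rate = 0.02, truncation_fraction = 0.25,
                      duplicate_fraction = 0.25, seed = 17L)
  a <- simulate_family(spec)
  b <- simulate_family(spec)
  expect_identical(vapply(a$records, `[[`, "", "residues"),
                   vapply(b$records, `[[`, "", "residues"))
  expect_identical(a$alignment$seqs, b$alignment$seqs)
  expect_identical(a$labels, b$labels)
})

test_that("true alignment rows de-gap to the emitted residues, truncation included", {
  fam <- simulate_family(family_spec(seqs_per_clade = 8L, root_length = 200L,
                                     within_clade_divergence = 0.2,
                                     indel_rate = 0.02,
                                     truncation_fraction = 0.25, seed = 5L))
  originals <- fam$labels[is.na(fam$labels$is_duplicate_of), ]
  for (i in seq_len(nrow(originals))) {
    rec <- Filter(function(r) r$id == originals$id[i], fam$records)[[1]]
    expect_equal(degap(fam$alignment, rec$id), rec$residues)
  }
  expect_equal(sum(originals$is_truncated), 2L)
  # truncated members lost 20-60% of their length
  for (id in originals$id[originals$is_truncated]) {
    rec <- Filter(function(r) r$id == id, fam$records)[[1]]
    full <- nchar(degap_full <- gsub("-", "", fam$alignment$seqs[
      match(id, fam$alignment$ids)]))
    expect_lt(nchar(rec$residues), 0.81 * 200)
  }
})

test_that("duplicates are byte-identical under new ids and labelled", {
  fam <- simulate_family(family_spec(seqs_per_clade = 8L, root_length = 100L,
                                     duplicate_fraction = 0.25, seed = 6L))
  dups <- fam$labels[!is.na(fam$labels$is_duplicate_of), ]
  expect_equal(nrow(dups), 2L)
  res_of <- function(id) Filter(function(r) r$id == id, fam$records)[[1]]$residues
  for (i in seq_len(nrow(dups)))
    expect_identical(res_of(dups$id[i]), res_of(dups$is_duplicate_of[i]))
})

test_that("proteome embedding keeps bookkeeping and decoy labels", {
  fam <- simulate_family(family_spec(seqs_per_clade = 5L, root_length = 60L,
                                     seed = 8L))
  p0 <- simulate_proteome(fam, n_decoys = 0L, seed = 9L)
  expect_length(p0$records, 5L)
  p <- simulate_proteome(fam, n_decoys = 100L, seed = 9L)
  expect_length(p$records, 105L)
  expect_equal(sum(p$labels$is_decoy), 100L)
  expect_equal(anyDuplicated(p$labels$id), 0L)
})

test_that("decoy composition matches the generating background frequencies", {
  fam <- simulate_family(family_spec(seqs_per_clade = 2L, root_length = 30L,
                                     seed = 10L))
  prot <- simulate_proteome(fam, n_decoys = 300L,
                            decoy_length_range = c(330L, 340L), seed = 13L)
  decoy_res <- paste(vapply(
    Filter(function(r) grepl("^decoy", r$id), prot$records),
    `[[`, "", "residues"), collapse = "")
  counts <- table(factor(strsplit(decoy_res, "")[[1]],
                         levels = names(wag_frequencies())))
  gof <- stats::chisq.test(as.numeric(counts), p = wag_frequencies())
  expect_gt(gof$p.value, 0.01)
  expect_gte(sum(counts), 1e5)
})

test_that("sister-leaf divergence tracks branch lengths at large root length", {
  # at small divergence, observed mismatch per site approximates twice the
  # branch length (law of large numbers; multiple hits negligible)
  bl <- 0.02
  tree <- ape::read.tree(text = sprintf("(s1:%g,s2:%g);", bl, bl))
  ev <- acylminer:::with_seed(14L, evolve_along_tree(tree, root_length = 3000L))
  a <- strsplit(ev$records[[1]]$residues, "")[[1]]
  b <- strsplit(ev$records[[2]]$residues, "")[[1]]
  p <- mean(a != b)
  expect_lt(abs(p - 2 * bl) / (2 * bl), 0.10)
})

test_that("decoys separate from family members under the true-alignment profile", {
  fx <- fixture_standard()
  hmm <- build_profile(fx$family$alignment)
  ids <- vapply(fx$proteome$records, `[[`, "", "id")
  bits <- forward_bits_batch(hmm, fx$proteome$records)
  is_fam <- ids %in% fx$proteome$labels$id[!fx$proteome$labels$is_decoy]
  ranks <- rank(bits)
  auc <- (mean(ranks[is_fam]) - (sum(is_fam) + 1) / 2) / sum(!is_fam)
  expect_gte(auc, 0.99)
})
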