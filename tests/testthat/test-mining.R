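test_that("dedupe collapses only byte-identical sequences and is idempotent", {
  s <- function(id, res) sequence_record(id, res)
  dd <- dedupe_identical(list(s("s1", "ACDE"), s("s2", "ACDE")))
  expect_equal(vapply(dd$kept, `[[`, "", "id"), "s1")
  expect_equal(dd$removed_map, c(s2 = "s1"))

  dd2 <- dedupe_identical(list(s("s1", "ACDE"), s("s2", "ACDEF")))
  expect_length(dd2$kept, 2L)

  set.seed(600)
  pool <- lapply(1:30, function(i)
    s(sprintf("p%d", i), random_residues(sample(c(5L, 6L), 1))))
  once <- dedupe_identical(pool)
  twice <- dedupe_identical(once$kept)
  expect_identical(vapply(twice$kept, `[[`, "", "id"),
                   vapply(once$kept, `[[`, "", "id"))
  expect_length(twice$removed_map, 0L)
})

test_that("scrutiny accepts hallmark carriers, tolerates known replacements", {
  vpfg <- motif_screen(list(motif_definition(
    "VPFG", list("V", "P", "F", "G"),
    tolerated = list(character(0), character(0), "Y", character(0)))),
    family = "DGAT2")
  sc <- scrutinize(list(sequence_record("hit", "AAAVPFGAAA"),
                        sequence_record("tol", "AAAVPYGAAA"),
                        sequence_record("miss", "AAAAAAAAAA")), vpfg)
  expect_equal(vapply(sc$accepted, `[[`, "", "id"), c("hit", "tol"))
  expect_equal(sc$quarantined$id, "miss")
  expect_equal(sc$quarantined$reason, "VPFG")

  empty <- structure(list(motifs = list(), family = "x"),
                     class = "motif_screen")
  expect_error(scrutinize(list(sequence_record("a", "AA")), empty), "required")
})

test_that("search returns members before decoys on the standard fixture", {
  fx <- fixture_standard()
  hmm <- build_profile(fx$family$alignment)
  cal <- calibrate_evalue(hmm, mean_length = 300L, seed = 77L)
  hits <- search_proteome(hmm, fx$proteome$records, cal, 0.01)
  lab <- fx$proteome$labels
  expect_true(all(!lab$is_decoy[match(hits$id, lab$id)]))
  full <- lab$id[!lab$is_decoy & !lab$is_truncated]
  expect_true(all(full %in% hits$id))
  expect_true(all(diff(hits$e_value) >= 0))

  # threshold 0 admits nothing
  expect_equal(nrow(search_proteome(hmm, fx$proteome$records, cal, 0)), 0L)

  # strict separation of scores
  bits <- forward_bits_batch(hmm, fx$proteome$records)
  ids <- vapply(fx$proteome$records, `[[`, "", "id")
  is_member <- ids %in% lab$id[!lab$is_decoy & !lab$is_truncated]
  expect_gt(min(bits[is_member]), max(bits[ids %in% lab$id[lab$is_decoy]]))
})

test_that("mining converges on the standard fixture with full recovery", {
  fx <- fixture_standard()
  cfg <- mining_config(scrutiny = fx$screen, seed = 5L)
  st <- mine_to_convergence(fx$family$alignment, fx$proteome$records, cfg)
  expect_true(st$converged)
  expect_lte(st$iteration, 3L)
  lab <- fx$proteome$labels
  full <- lab$id[!lab$is_decoy & !lab$is_truncated &
                   is.na(lab$is_duplicate_of)]
  expect_true(all(full %in% st$accepted_ids))              # sensitivity 100%
  expect_equal(sum(st$accepted_ids %in% lab$id[lab$is_decoy]), 0L) # precision
  # truncated members are quarantined by the terminal hallmark screen
  trunc <- lab$id[lab$is_truncated & is.na(lab$is_duplicate_of)]
  expect_true(all(trunc %in% st$quarantined$id))
  # state invariants
  expect_length(intersect(st$accepted_ids, st$quarantined$id), 0L)
  expect_equal(st$history$n_accepted[st$iteration - 1L],
               st$history$n_accepted[st$iteration])
})

test_that("mining is byte-for-byte deterministic for a fixed config", {
  fx <- fixture_standard()
  cfg <- mining_config(scrutiny = fx$screen, seed = 5L)
  s1 <- mine_to_convergence(fx$family$alignment, fx$proteome$records, cfg)
  s2 <- mine_to_convergence(fx$family$alignment, fx$proteome$records, cfg)
  expect_identical(s1$history, s2$history)
  expect_identical(s1$accepted_ids, s2$accepted_ids)
  expect_identical(s1$current_alignment$seqs, s2$current_alignment$seqs)
})

test_that("a proteome without family members converges to an empty set", {
  fx <- fixture_standard()
  decoys_only <- Filter(function(r) grepl("^decoy", r$id),
                        fx$proteome$records)
  st <- mine_to_convergence(fx$family$alignment, decoys_only,
                            mining_config(seed = 5L))
  expect_true(st$converged)
  expect_length(st$accepted_ids, 0L)
})

test_that("iterative enrichment recovers the remote clade in two stages", {
  fx <- fixture_remote()
  seed_aln <- subset_rows(fx$alignment, sprintf("A%d", 1:6))
  cfg <- mining_config(scrutiny = fx$screen, seed = 15L)
  st <- mine_to_convergence(seed_aln, fx$proteome, cfg)
  expect_true(st$converged)
  remote <- sprintf("C%d", 1:5)
  # reconstruct iteration-1 accepted set: a single search with the seed model
  hmm1 <- build_profile(seed_aln)
  cal1 <- calibrate_evalue(hmm1, n_samples = 200L,
                           mean_length = max(1L, round(mean(vapply(
                             fx$proteome, function(s) nchar(s$residues), 0)))),
                           seed = acylminer:::derive_seed(15L, "calibration", 1L))
  iter1 <- search_proteome(hmm1, fx$proteome, cal1, 0.01)
  expect_gte(length(setdiff(remote, iter1$id)), 1L)   # absent at iteration 1
  expect_true(all(remote %in% st$accepted_ids))       # present at convergence
  expect_equal(sum(st$accepted_ids %in% grep("^decoy", st$accepted_ids,
                                             value = TRUE)),
               length(grep("^decoy", st$accepted_ids)))
  expect_length(grep("^decoy", st$accepted_ids), 0L)
})

test_that("accepted sets grow monotonically when no scrutiny removes members", {
  fx <- fixture_remote()
  seed_aln <- subset_rows(fx$alignment, sprintf("A%d", 1:6))
  st <- mine_to_convergence(seed_aln, fx$proteome,
                            mining_config(scrutiny = fx$screen, seed = 15L))
  expect_true(all(st$history$n_removed == 0L))
  expect_true(all(diff(st$history$n_accepted) >= 0L))
})

test_that("group-specific mining honors the partition and keeps the union", {
  fx <- fixture_remote()
  # tag taxa by clade; decoys split between the groups
  prot <- lapply(fx$proteome, function(r) {
    r$taxon <- if (grepl("^A|^B", r$id)) "near" else "far"
    r
  })
  seed_aln <- subset_rows(fx$alignment, sprintf("A%d", 1:6))
  cfg <- mining_config(scrutiny = fx$screen, seed = 15L)
  st <- mine_to_convergence(seed_aln, prot, cfg)
  gs <- group_specific_mining(st, prot,
                              list(near = "near", far = "far"), cfg)
  expect_true(all(st$accepted_ids %in% gs$census_ids))
  # members recovered inside each group belong to that group's slice
  for (g in names(gs$groups)) {
    slice_ids <- vapply(Filter(function(r) r$taxon == g, prot), `[[`, "", "id")
    expect_true(all(gs$groups[[g]]$accepted_ids %in% slice_ids))
  }
  # degenerate partition: one group containing everything reproduces the
  # global result
  all_taxa <- unique(vapply(prot, function(r) r$taxon, ""))
  gs2 <- group_specific_mining(st, prot, list(all = all_taxa), cfg)
  expect_setequal(gs2$groups$all$accepted_ids, st$accepted_ids)
})
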