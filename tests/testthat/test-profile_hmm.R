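toy_forced_model <- function() {
  # one match state emitting A with probability ~1, begin->M->end forced,
  # uniform null
  structure(list(
    n_match = 1L,
    match_emissions = matrix(c(1, rep(1e-300, 19)), 1, 20,
                             dimnames = list(NULL, acylminer:::AMINO_ACIDS)),
    insert_emissions = rep(1 / 20, 20),
    background = stats::setNames(rep(1 / 20, 20), acylminer:::AMINO_ACIDS),
    transitions = matrix(c(1, 0, 0, 0, 0, 0, 0,
                           1, 0, 0, 1, 0, 1, 0), 2, 7, byrow = TRUE,
                         dimnames = list(NULL, acylminer:::TRANS_NAMES)),
    metadata = list(name = "forced")), class = "profile_hmm")
}

test_that("profile building: match-state selection and degenerate limits", {
  aln <- new_alignment(sprintf("s%d", 1:5), rep("ACDE", 5))
  hmm <- build_profile(aln, pseudocount_weight = 1e-9)
  expect_equal(hmm$n_match, 4L)
  expect_gt(hmm$match_emissions[1, "A"], 1 - 1e-6)

  # column of 3 residues + 7 gaps at threshold 0.5 is NOT a match state
  rows <- c(rep("AW", 3), rep("A-", 7))
  aln2 <- new_alignment(sprintf("t%d", 1:10), rows)
  hmm2 <- build_profile(aln2, match_threshold = 0.5)
  expect_equal(hmm2$n_match, 1L)

  expect_error(build_profile(new_alignment("a", "----"), 0.5), "gap fraction")
  expect_warning(build_profile(new_alignment("a", "ACDE")), "single")
})

test_that("emissions and transitions are proper distributions on random MSAs", {
  set.seed(500)
  for (i in 1:100) {
    aln <- random_alignment(n_rows = sample(2:10, 1), n_cols = sample(5:30, 1),
                            gap_prob = stats::runif(1, 0, 0.4))
    hmm <- tryCatch(build_profile(aln), error = function(e) NULL)
    if (is.null(hmm)) next
    expect_equal(unname(rowSums(hmm$match_emissions)),
                 rep(1, hmm$n_match), tolerance = 1e-9)
    expect_true(all(hmm$match_emissions > 0))
    tr <- hmm$transitions
    expect_equal(unname(rowSums(tr[, c("MM", "MI", "MD")])),
                 rep(1, nrow(tr)), tolerance = 1e-9)
    expect_equal(unname(rowSums(tr[, c("IM", "II")])),
                 rep(1, nrow(tr)), tolerance = 1e-9)
    dsum <- rowSums(tr[-1L, c("DM", "DD"), drop = FALSE])
    expect_equal(unname(dsum), rep(1, nrow(tr) - 1L), tolerance = 1e-9)
  }
})

test_that("forward bit score is analytic on the forced one-state model", {
  expect_equal(forward_bits(toy_forced_model(), "A"), log2(20),
               tolerance = 1e-12)
})

test_that("forward equals exhaustive path enumeration on small models", {
  aln <- new_alignment(c("a", "b"), c("ACDE", "ACDE"))
  hmm <- build_profile(aln)
  expect_equal(forward_bits(hmm, "ACDE"), oracle_forward_bits(hmm, "ACDE"),
               tolerance = 1e-9)

  set.seed(501)
  for (i in 1:40) {
    hmm <- random_small_hmm(K = sample(1:4, 1), n_rows = sample(2:5, 1))
    s <- random_residues(sample(1:6, 1))
    expect_equal(forward_bits(hmm, s), oracle_forward_bits(hmm, s),
                 tolerance = 1e-9)
  }
})

test_that("forward dominates Viterbi on random model/sequence pairs", {
  set.seed(502)
  for (i in 1:200) {
    hmm <- random_small_hmm(K = sample(2:6, 1), n_rows = sample(2:6, 1))
    s <- random_residues(sample(3:30, 1))
    expect_gte(forward_bits(hmm, s) - viterbi_bits(hmm, s), -1e-9)
  }
})

test_that("scores stay finite for long sequences and X-heavy input", {
  fx <- fixture_standard()
  hmm <- build_profile(fx$family$alignment)
  long_seq <- random_residues(10000L)
  expect_true(is.finite(forward_bits(hmm, long_seq)))
  xheavy <- paste0(strrep("X", 50), substr(long_seq, 1, 100), strrep("X", 50))
  expect_true(is.finite(forward_bits(hmm, xheavy)))
})

test_that("Viterbi alignment maps consensus gap-free and recovers inputs", {
  aln <- new_alignment(sprintf("s%d", 1:4), rep("ACDEFGHIKL", 4))
  hmm <- build_profile(aln, pseudocount_weight = 0.01)
  va <- viterbi_align(hmm, list(sequence_record("cons", "ACDEFGHIKL")))
  expect_equal(va$seqs, "ACDEFGHIKL")

  two <- list(sequence_record("x", "ACDEFGHIKL"),
              sequence_record("y", "ACDEFGHIKL"))
  va2 <- viterbi_align(hmm, two)
  expect_equal(va2$seqs[1], va2$seqs[2])

  # de-gapping recovers inputs even with inserts/deletes/flanks
  odd <- list(sequence_record("ins", "ACDEWWWFGHIKL"),
              sequence_record("del", "ACDEFGHI"),
              sequence_record("flank", "MMACDEFGHIKLMM"))
  va3 <- viterbi_align(hmm, odd)
  for (r in odd) expect_equal(degap(va3, r$id), r$residues)
})

test_that("aligning simulated members to the family profile recovers true columns", {
  fx <- fixture_standard()
  fam <- fx$family
  full_ids <- fam$labels$id[!fam$labels$is_truncated &
                              is.na(fam$labels$is_duplicate_of)]
  hmm <- build_profile(fam$alignment)
  recs <- Filter(function(r) r$id %in% full_ids, fam$records)
  va <- viterbi_align(hmm, recs)
  # column-pair recall: fraction of true homologous residue pairs placed in
  # a shared column of the inferred alignment
  pair_sets <- function(aln, ids) {
    m <- alignment_matrix(aln)[ids, , drop = FALSE]
    sets <- list()
    for (j in seq_len(ncol(m))) {
      rows <- which(m[, j] != "-")
      if (length(rows) < 2L) next
      # residue index within each ungapped sequence
      ridx <- vapply(rows, function(r) sum(m[r, 1:j] != "-"), 0L)
      prs <- t(utils::combn(seq_along(rows), 2L))
      sets[[length(sets) + 1L]] <- sprintf("%s:%d|%s:%d",
        ids[rows[prs[, 1]]], ridx[prs[, 1]],
        ids[rows[prs[, 2]]], ridx[prs[, 2]])
    }
    unlist(sets)
  }
  truth <- pair_sets(subset_rows(fam$alignment, full_ids), full_ids)
  inferred <- pair_sets(va, full_ids)
  recall <- mean(truth %in% inferred)
  expect_gte(recall, 0.90)
})

test_that("Gumbel E-value machinery is calibrated and monotone", {
  # closed form at s = mu, db_size 1
  cal <- structure(list(mu = 10, lam = 0.7, n_samples = 100L, seed = 1L),
                   class = "gumbel_calibration")
  expect_equal(evalue(cal, 10, 1), 1 - exp(-1), tolerance = 1e-12)
  s <- seq(-20, 60, length.out = 200)
  ev <- evalue(cal, s, 50)
  expect_true(all(diff(ev) <= 0))
  # strictly decreasing wherever the Gumbel tail is not saturated to
  # machine precision
  unsat <- ev < 50 * (1 - 1e-12)
  expect_true(all(diff(ev[unsat]) < 0))
  expect_true(all(ev >= 0))

  # ML fit recovers a known Gumbel scale
  set.seed(503)
  draws <- 10 - log(-log(stats::runif(5000))) / 0.7
  fit <- gumbel_ml(draws)
  expect_lt(abs(fit$lam - 0.7) / 0.7, 0.10)
  # the tail-censored variant used for calibration is consistent too
  fit_c <- gumbel_ml(draws, censor = 0.75)
  expect_lt(abs(fit_c$lam - 0.7) / 0.7, 0.10)
  expect_lt(abs(fit_c$mu - 10), 0.5)
  expect_error(gumbel_ml(rep(1, 50)), "degenerate")
})

test_that("calibration is reproducible for a fixed seed", {
  aln <- new_alignment(sprintf("s%d", 1:4), rep("ACDEFGHIKLNPQR", 4))
  hmm <- build_profile(aln)
  c1 <- calibrate_evalue(hmm, n_samples = 120L, mean_length = 80L, seed = 42L)
  c2 <- calibrate_evalue(hmm, n_samples = 120L, mean_length = 80L, seed = 42L)
  expect_identical(c1$mu, c2$mu)
  expect_identical(c1$lam, c2$lam)
  expect_gt(c1$lam, 0)
})

test_that("model serialization round-trips bit-exactly at the file level", {
  fx <- fixture_standard()
  hmm <- build_profile(fx$family$alignment)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_profile(hmm, f1)
  back <- read_profile(f1)
  write_profile(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(back$n_match, hmm$n_match)
  expect_equal(forward_bits(back, "ACDEFGHIKLNPQRSTVWYA"),
               forward_bits(hmm, "ACDEFGHIKLNPQRSTVWYA"), tolerance = 1e-4)
})

test_that("profile building is deterministic", {
  fx <- fixture_standard()
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_profile(build_profile(fx$family$alignment), f1)
  write_profile(build_profile(fx$family$alignment), f2)
  expect_identical(readLines(f1), readLines(f2))
})
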