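test_that("motif scanning finds spaced, tolerated and absent motifs", {
  hxde <- motif_screen(list(motif_definition(
    "HxDE", list("H", c("D", "E")), spacers = list(c(3L, 5L)))), "DGAT3")
  hits <- scan_motifs("MHAAAADKL", hxde)
  expect_equal(hits$start, 2L)
  expect_equal(hits$end, 7L)          # H..(4 spacers)..D

  vpfg <- motif_screen(list(motif_definition(
    "VPFG", list("V", "P", "F", "G"),
    tolerated = list(character(0), character(0), "Y", character(0)))))
  h2 <- scan_motifs("AVPYGA", vpfg)
  expect_equal(h2$start, 2L)
  expect_match(h2$substitutions, "4:Y")

  expect_equal(nrow(scan_motifs("AAAA", vpfg)), 0L)
})

test_that("motif results are independent of definition order", {
  m1 <- motif_definition("one", list("A", "C"))
  m2 <- motif_definition("two", list("C", "D"))
  s <- "AACDAA"
  a <- scan_motifs(s, motif_screen(list(m1, m2)))
  b <- scan_motifs(s, motif_screen(list(m2, m1)))
  expect_identical(a[order(a$motif, a$start), ],
                   b[order(b$motif, b$start), ])
})

test_that("bundled motif library loads and matches its hallmarks", {
  lib <- system.file("extdata", "motifs", package = "acylminer")
  dgat2 <- read_motif_screen(file.path(lib, "dgat2.yaml"))
  expect_gt(nrow(scan_motifs("AAVPFGAA", dgat2)), 0L)
  expect_gt(nrow(scan_motifs("AAVPYGAA", dgat2)), 0L)   # tolerated F->Y
  dgat3 <- read_motif_screen(file.path(lib, "dgat3.yaml"))
  expect_gt(nrow(scan_motifs("AHAAAAEAA", dgat3)), 0L)
  lcat <- read_motif_screen(file.path(lib, "lcat.yaml"))
  expect_gt(nrow(scan_motifs("ADARAA", lcat)), 0L)
})

test_that("hydropathy windows match hand-computed scale means", {
  expect_equal(kd_profile("IIIIIIIII")$scores, 4.5)
  expect_equal(kd_profile("RRRRRRRRR")$scores, -4.5)
  expect_equal(kd_profile("KDKDKDKDK")$scores,
               (5 * (-3.9) + 4 * (-3.5)) / 9, tolerance = 1e-12)
  p <- kd_profile(strrep("IR", 20))
  expect_length(p$scores, 40 - 9 + 1)
  expect_true(all(p$scores >= -4.5 & p$scores <= 4.5))
  expect_error(kd_profile("IIII"), "shorter")
})

test_that("hydropathy is shift-equivariant", {
  set.seed(800)
  s <- random_residues(60L)
  a <- kd_profile(s)$scores
  b <- kd_profile(paste0("A", s))$scores
  expect_equal(b[-1], a[seq_len(length(b) - 1L)], tolerance = 1e-12)
})

test_that("hydrophobic segmentation covers poly-I fully and poly-R not at all", {
  all_i <- hydrophobic_segments(kd_profile(strrep("I", 30)))
  expect_equal(all_i$fraction, 100)
  expect_equal(all_i$segments$start, 1L)
  expect_equal(all_i$segments$end, 30L)
  none <- hydrophobic_segments(kd_profile(strrep("R", 30)))
  expect_equal(none$fraction, 0)
  expect_equal(nrow(none$segments), 0L)
})

test_that("hydrophobic fraction is 0 exactly when no window is positive", {
  set.seed(801)
  for (i in 1:20) {
    s <- random_residues(sample(30:120, 1))
    pr <- kd_profile(s)
    hs <- hydrophobic_segments(pr)
    expect_gte(hs$fraction, 0); expect_lte(hs$fraction, 100)
    expect_identical(hs$fraction == 0, !any(pr$scores > 0))
    if (nrow(hs$segments) > 1L) {
      expect_true(all(diff(hs$segments$start) > 0))
      expect_true(all(hs$segments$start[-1] >
                        hs$segments$end[-nrow(hs$segments)]))
    }
  }
})

test_that("co-location distinguishes embedded, flanking and hydrophilic motifs", {
  hits <- data.frame(motif = c("m1", "m2", "m3"),
                     start = c(10L, 10L, 10L), end = c(15L, 15L, 15L))
  rel <- function(seg) colocate(hits[1, ], seg, flank = 5L)$relation
  expect_equal(rel(data.frame(start = 12L, end = 30L)), "embedded")
  expect_equal(rel(data.frame(start = 18L, end = 30L)), "flanking_hydrophobic")
  expect_equal(rel(data.frame(start = 40L, end = 60L)),
               "flanked_by_hydrophilic")
  expect_equal(colocate(hits[1, ], data.frame(start = integer(0),
                                              end = integer(0)))$relation,
               "flanked_by_hydrophilic")
})

test_that("logo information content matches the closed forms", {
  w_col <- new_alignment(sprintf("s%d", 1:10), rep("W", 10))
  expect_equal(logo_bits(w_col)$R, log2(20), tolerance = 1e-12)
  uni <- new_alignment(sprintf("s%d", 1:20), acylminer:::AMINO_ACIDS)
  expect_equal(logo_bits(uni)$R, 0, tolerance = 1e-12)
  half <- new_alignment(sprintf("s%d", 1:20),
                        rep(c("A", "V"), each = 10))
  expect_equal(logo_bits(half)$R, log2(20) - 1, tolerance = 1e-12)
  # heights are p * R
  lb <- logo_bits(half)
  expect_equal(unname(lb$heights[[1]][c("A", "V")]),
               rep(0.5 * (log2(20) - 1), 2), tolerance = 1e-12)
  # small-sample correction subtracts 19/(2 ln2 n)
  lb2 <- logo_bits(w_col, small_sample_correction = TRUE)
  expect_equal(lb2$R, log2(20) - 19 / (2 * log(2) * 10), tolerance = 1e-12)
  # all-gap column reported missing
  gap_col <- new_alignment(c("a", "b"), c("A-", "C-"))
  expect_true(is.na(logo_bits(gap_col)$R[2]))
})

test_that("consensus screens quarantine exactly the terminus-truncated members", {
  fx <- fixture_standard()
  fam <- fx$family
  sc <- scrutinize(Filter(function(r) is.na(
    fam$labels$is_duplicate_of[match(r$id, fam$labels$id)]), fam$records),
    fx$screen)
  lab <- fam$labels[is.na(fam$labels$is_duplicate_of), ]
  expect_setequal(sc$quarantined$id, lab$id[lab$is_truncated])
})

test_that("external annotations merge onto reports by id", {
  rep <- data.frame(id = c("a", "b", "c"), best = c("x", "y", "x"))
  ann <- data.frame(id = c("c", "a"), localization = c("chloroplast", "ER"))
  out <- attach_annotations(rep, ann)
  expect_equal(out$localization[match(c("a", "b", "c"), out$id)],
               c("ER", NA, "chloroplast"))
  expect_equal(nrow(out), 3L)
})
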