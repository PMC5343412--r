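TRANS_NAMES <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")

#' Build a profile HMM from a multiple sequence alignment
#'
#' Alignment columns whose gap fraction is below `match_threshold` become
#' match states, in order.  Match emissions are observed residue counts
#' plus background-proportional pseudocounts
#' (`count + pseudocount_weight * background`, normalized).  Transition
#' probabilities are counted from each row's implied match/insert/delete
#' path, with a pseudocount of 1 on every structurally allowed transition.
#' Insert states emit at background frequencies.
#'
#' The architecture is Plan-7-like: nodes 0..K with transitions
#' M->M/I/D, I->M/I, D->M/D; node 0 is the begin state (with an insert
#' state for residues preceding the first match), node K feeds the end
#' state.  Scoring is uni-local (one hit per sequence): local in the
#' target sequence (unscored flanks) and local in the model — the begin
#' state enters any match state uniformly and every pre-terminal match
#' state can exit with probability 1/K, so truncated gene models pay
#' roughly `log2(K)` bits instead of a delete-wing penalty proportional
#' to the missing length.  The two transitions a Plan-7 path cannot
#' represent (I->D, D->I) are counted on the nearest allowed transition
#' (M->D, M->I); with unit pseudocounts this estimation convention has
#' negligible effect.
#'
#' @param aln An [alignment].
#' @param match_threshold Columns with gap fraction `< match_threshold`
#'   become match states (default 0.5).
#' @param pseudocount_weight Weight of the background-proportional emission
#'   pseudocount (default 1).
#' @param background Background amino-acid frequencies (default: WAG
#'   stationary frequencies, matching the simulator).
#' @param name Model name stored in the metadata.
#' @return An object of class `profile_hmm`.
#' @export
build_profile <- function(aln, match_threshold = 0.5, pseudocount_weight = 1,
                          background = wag_frequencies(), name = "profile") {
  stopifnot(inherits(aln, "alignment"), length(aln$ids) >= 1L)
  stopifnot(match_threshold > 0, match_threshold <= 1, pseudocount_weight > 0)
  if (length(aln$ids) == 1L)
    warning("building a profile from a single sequence; ",
            "emissions are dominated by pseudocounts")
  m <- alignment_matrix(aln)
  gapfrac <- colMeans(m == GAP_CHAR)
  match_cols <- which(gapfrac < match_threshold)
  K <- length(match_cols)
  if (K == 0L)
    stop("no column has gap fraction below match_threshold = ",
         match_threshold)

  bg <- background / sum(background)
  names(bg) <- AMINO_ACIDS

  # --- emissions -----------------------------------------------------------
  em <- matrix(0, K, length(AMINO_ACIDS), dimnames = list(NULL, AMINO_ACIDS))
  for (k in seq_len(K)) {
    col <- m[, match_cols[k]]
    cnt <- table(factor(col[col %in% AMINO_ACIDS], levels = AMINO_ACIDS))
    em[k, ] <- as.numeric(cnt) + pseudocount_weight * bg
  }
  em <- em / rowSums(em)

  # --- transitions ---------------------------------------------------------
  counts <- matrix(0, K + 1L, 7L, dimnames = list(NULL, TRANS_NAMES))
  col_kind <- integer(ncol(m))            # 0 = insert column, else match index
  col_kind[match_cols] <- seq_len(K)
  for (r in seq_len(nrow(m))) {
    row <- m[r, ]
    prev_type <- "M"; prev_node <- 0L     # begin state
    for (cc in seq_along(row)) {
      k <- col_kind[cc]
      if (k > 0L) {
        type <- if (row[cc] == GAP_CHAR) "D" else "M"
        counts <- add_transition(counts, prev_type, prev_node, type, k)
        prev_type <- type; prev_node <- k
      } else if (row[cc] != GAP_CHAR) {
        counts <- add_transition(counts, prev_type, prev_node, "I", prev_node)
        prev_type <- "I"
      }
    }
    counts <- add_transition(counts, prev_type, prev_node, "M", K + 1L) # -> E
  }

  allowed <- matrix(TRUE, K + 1L, 7L, dimnames = list(NULL, TRANS_NAMES))
  allowed[1L, c("DM", "DD")] <- FALSE     # no delete state at the begin node
  allowed[K + 1L, c("MD", "DD")] <- FALSE # node K cannot enter D_{K+1}
  counts <- counts + 1 * allowed

  trans <- counts
  for (grp in list(c("MM", "MI", "MD"), c("IM", "II"), c("DM", "DD"))) {
    s <- rowSums(counts[, grp, drop = FALSE])
    trans[, grp] <- counts[, grp, drop = FALSE] / ifelse(s > 0, s, 1)
  }
  trans[!allowed] <- 0

  structure(list(
    n_match = K,
    match_emissions = em,
    insert_emissions = bg,
    background = bg,
    transitions = trans,
    metadata = list(name = name, n_seqs = length(aln$ids),
                    match_columns = match_cols,
                    match_threshold = match_threshold,
                    pseudocount_weight = pseudocount_weight)),
    class = "profile_hmm")
}

add_transition <- function(counts, from_type, from_node, to_type, to_node) {
  # Resolve the Plan-7 transition label for a step in an implied path.
  row <- from_node + 1L
  col <- switch(to_type,
    M = c(M = "MM", I = "IM", D = "DM")[[from_type]],
    I = if (from_type == "D") "MI" else c(M = "MI", I = "II")[[from_type]],
    D = if (from_type == "I") "MD" else c(M = "MD", D = "DD")[[from_type]])
  if (to_type == "I" && from_type == "D") row <- from_node + 1L
  counts[row, col] <- counts[row, col] + 1
  counts
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("<profile_hmm '%s': %d match states, built from %d sequence(s)>\n",
              x$metadata$name, x$n_match, x$metadata$n_seqs))
  invisible(x)
}

# DP kernels: emission odds ratios / transition probabilities for the
# scaled forward pass, and their logs for Viterbi.  The X column is
# score-neutral (odds 1, log-odds 0).
#
# Uni-local semantics in the model dimension: the begin-state mass going
# to match states (the estimated B->M1 probability) is spread uniformly
# over all K match states, and every pre-terminal match state exits to
# the end state with probability 1/K (its remaining transitions scaled by
# 1 - 1/K).  Truncated proteins therefore pay ~log2(K) bits to enter or
# leave mid-model instead of a delete-wing penalty proportional to the
# missing length.  For K = 1 this reduces exactly to the glocal model.
hmm_kernel <- function(hmm) {
  em <- sweep(hmm$match_emissions, 2L, hmm$background, "/")
  em <- cbind(em, X = 1)
  K <- hmm$n_match
  tr <- hmm$transitions
  entry <- rep(tr[1L, "MM"] / K, K)
  exitp <- c(rep(1 / K, K - 1L), tr[K + 1L, "MM"])
  if (K > 1L) {
    rows <- 2L:K                      # source nodes 1..K-1
    tr[rows, c("MM", "MI", "MD")] <- tr[rows, c("MM", "MI", "MD")] *
      (1 - 1 / K)
  }
  list(em = em, tr = tr, entry = entry, exit = exitp,
       lm = log(em), ltr = suppressWarnings(log(tr)),
       lentry = log(entry), lexit = suppressWarnings(log(exitp)))
}

#' Forward-algorithm bit score of a sequence against a profile HMM
#'
#' Computes `log2 [ P(seq | model, sequence-local alignment) /
#' P(seq | background) ]` by the forward algorithm in log space.  The
#' forward score is always at least the Viterbi score for the same pair.
#' `X` residues are score-neutral.
#'
#' @param hmm A [build_profile()] model.
#' @param seq A `sequence_record` or a plain residue string.
#' @return Bit score (log2 odds), a finite scalar.
#' @export
forward_bits <- function(hmm, seq) {
  res <- if (inherits(seq, "sequence_record")) seq$residues else seq
  stopifnot(nzchar(res))
  kern <- hmm_kernel(hmm)
  phmm_forward_nats(kern$em, kern$tr, kern$entry, kern$exit,
                    encode_residues(res)) / log(2)
}

#' Forward bit scores for many sequences (vectorized)
#' @param hmm A [build_profile()] model.
#' @param seqs List of `sequence_record` (or residue strings).
#' @return Numeric vector of bit scores.
#' @export
forward_bits_batch <- function(hmm, seqs) {
  kern <- hmm_kernel(hmm)
  enc <- lapply(seqs, function(s)
    encode_residues(if (inherits(s, "sequence_record")) s$residues else s))
  phmm_forward_batch_nats(kern$em, kern$tr, kern$entry, kern$exit,
                          enc) / log(2)
}

#' Viterbi bit score (maximum-probability single path)
#' @inheritParams forward_bits
#' @return Bit score of the best path.
#' @export
viterbi_bits <- function(hmm, seq) {
  res <- if (inherits(seq, "sequence_record")) seq$residues else seq
  kern <- hmm_kernel(hmm)
  phmm_viterbi_nats(kern$lm, kern$ltr, kern$lentry, kern$lexit,
                    encode_residues(res))$score / log(2)
}

#' Align sequences to a profile HMM (Viterbi state paths to columns)
#'
#' Each sequence's maximum-probability state path is mapped to alignment
#' columns: match states form shared columns; insert runs (and unscored
#' sequence flanks, assigned to the terminal insert blocks) are padded
#' with gaps in the other rows.  De-gapping any row recovers the input
#' residues.
#'
#' @param hmm A [build_profile()] model.
#' @param seqs List of `sequence_record`.
#' @return An [alignment] with one row per input sequence.
#' @export
viterbi_align <- function(hmm, seqs) {
  stopifnot(length(seqs) >= 1L)
  kern <- hmm_kernel(hmm)
  K <- hmm$n_match
  parsed <- lapply(seqs, function(s) {
    res <- s$residues
    ch <- strsplit(res, "", fixed = TRUE)[[1]]
    vt <- phmm_viterbi_nats(kern$lm, kern$ltr, kern$lentry, kern$lexit,
                            encode_residues(res))
    ins <- rep(list(character(0)), K + 1L)   # insert blocks for nodes 0..K
    match_char <- rep(GAP_CHAR, K)
    consumed <- vt$residue[vt$residue > 0L]
    first <- if (length(consumed)) min(consumed) else nchar(res) + 1L
    last <- if (length(consumed)) max(consumed) else 0L
    if (first > 1L) ins[[1L]] <- ch[seq_len(first - 1L)]
    for (step in seq_along(vt$state)) {
      stt <- vt$state[step]; nodep <- vt$node[step]; ri <- vt$residue[step]
      if (stt == 0L) match_char[nodep] <- ch[ri]
      else if (stt == 1L) ins[[nodep + 1L]] <- c(ins[[nodep + 1L]], ch[ri])
    }
    if (last < nchar(res) && last > 0L)
      ins[[K + 1L]] <- c(ins[[K + 1L]], ch[seq(last + 1L, nchar(res))])
    list(ins = ins, match_char = match_char)
  })
  ins_len <- vapply(seq_len(K + 1L), function(j)
    max(vapply(parsed, function(p) length(p$ins[[j]]), 0L)), 0L)
  rows <- vapply(parsed, function(p) {
    parts <- character(0)
    for (j in seq_len(K + 1L)) {
      blk <- c(p$ins[[j]], rep(GAP_CHAR, ins_len[j] - length(p$ins[[j]])))
      if (j == 1L)  # right-justify the amino-terminal block
        blk <- c(rep(GAP_CHAR, ins_len[j] - length(p$ins[[j]])), p$ins[[j]])
      parts <- c(parts, blk, if (j <= K) p$match_char[j])
    }
    paste(parts, collapse = "")
  }, "")
  new_alignment(vapply(seqs, `[[`, "", "id"), rows)
}

#' Calibrate an E-value null distribution for a model
#'
#' Scores the model against `n_samples` i.i.d. background sequences of
#' length `mean_length` and fits a Gumbel distribution to the bit-score
#' sample by tail-censored maximum likelihood (lowest three quarters
#' censored, see
#' [gumbel_ml()]): E-value accuracy depends on the right tail, and the
#' bulk of local-alignment forward scores is narrower than a Gumbel.
#' Deterministic given `seed`.
#'
#' @param hmm A [build_profile()] model.
#' @param n_samples Number of background sequences (>= 100).
#' @param mean_length Length of each background sequence (typically the
#'   mean length of the database to be searched).
#' @param seed RNG seed.
#' @param censor Censored fraction for the tail fit (default 0.75).
#' @return An object of class `gumbel_calibration` with fields `mu`
#'   (location, bits), `lam` (scale, 1/bits), `n_samples`, `seed`.
#' @export
calibrate_evalue <- function(hmm, n_samples = 200L, mean_length = 350L,
                             seed = 1L, censor = 0.75) {
  stopifnot(n_samples >= 100L, mean_length >= 1L)
  bg <- hmm$background
  scores <- with_seed(seed, {
    seqs <- replicate(n_samples, paste(
      sample(AMINO_ACIDS, mean_length, replace = TRUE, prob = bg),
      collapse = ""), simplify = TRUE)
    forward_bits_batch(hmm, as.list(seqs))
  })
  fit <- gumbel_ml(scores, censor = censor)
  structure(list(mu = fit$mu, lam = fit$lam, n_samples = n_samples,
                 seed = seed),
            class = "gumbel_calibration")
}

#' Maximum-likelihood Gumbel fit, optionally tail-censored
#'
#' Fits location `mu` and scale `beta` (reported as `lam = 1/beta`) of a
#' Gumbel (type-I extreme value) distribution to a numeric sample by
#' maximum likelihood.  With `censor = 0` the full-sample profile
#' likelihood is solved with [stats::uniroot()].  With `censor > 0` the
#' lowest `censor` fraction of the sample is treated as left-censored at
#' its upper boundary and the censored likelihood is maximized with
#' [stats::optim()]: this weights the fit towards the right tail, which
#' is what E-values depend on when the score distribution is only
#' approximately Gumbel in its bulk.
#'
#' @param x Numeric sample (must have positive variance).
#' @param censor Fraction of the lowest scores to censor (default 0).
#' @return List with `mu` and `lam`.
#' @export
gumbel_ml <- function(x, censor = 0) {
  stopifnot(is.numeric(x), length(x) >= 2L, censor >= 0, censor < 1)
  if (stats::sd(x) == 0)
    stop("degenerate score sample (zero variance); cannot fit Gumbel")
  b0 <- stats::sd(x) * sqrt(6) / pi
  mu0 <- mean(x) - 0.5772156649 * b0
  if (censor == 0) {
    xbar <- mean(x)
    g <- function(b) {
      w <- exp(-(x - min(x)) / b)
      b - xbar + sum(x * w) / sum(w)
    }
    hi <- stats::sd(x) * 5 + 1
    while (g(hi) < 0) hi <- hi * 2
    b <- stats::uniroot(g, c(1e-8, hi), tol = 1e-12)$root
    mu <- min(x) - b * log(mean(exp(-(x - min(x)) / b)))
    return(list(mu = mu, lam = 1 / b))
  }
  cpt <- stats::quantile(x, censor, names = FALSE)
  keep <- x[x > cpt]
  n_cens <- sum(x <= cpt)
  if (length(keep) < 10L)
    stop("too few uncensored scores for a tail fit")
  nll <- function(par) {
    mu <- par[1]; b <- exp(par[2])
    z <- (keep - mu) / b
    zc <- (cpt - mu) / b
    -(sum(-log(b) - z - exp(-z)) + n_cens * (-exp(-zc)))
  }
  fit <- stats::optim(c(mu0, log(b0)), nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  list(mu = fit$par[1], lam = 1 / exp(fit$par[2]))
}

#' E-value of a bit score under a Gumbel calibration
#'
#' `E = db_size * (1 - exp(-exp(-lam * (s - mu))))`: the expected number of
#' database sequences scoring at least `s` under the null.  Strictly
#' decreasing in `s`.
#'
#' @param cal A [calibrate_evalue()] object.
#' @param bit_score Bit score(s).
#' @param db_size Number of sequences in the searched database.
#' @return E-value(s), same length as `bit_score`.
#' @export
evalue <- function(cal, bit_score, db_size) {
  stopifnot(inherits(cal, "gumbel_calibration"), db_size >= 0)
  # -expm1(-x) = 1 - exp(-x) without underflowing to 0 for strong scores,
  # keeping E-values strictly decreasing in the bit score
  db_size * (-expm1(-exp(-cal$lam * (bit_score - cal$mu))))
}

#' Serialize a profile HMM to a plain-text model file
#'
#' Header with model name, number of match states and background; one line
#' per node carrying emissions and transitions at 6 significant digits.
#' Writing a model read back from a file reproduces the file byte for byte.
#'
#' @param hmm A [build_profile()] model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(hmm, path) {
  fmt <- function(x) sprintf("%.6g", x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ACYLMINER_PHMM 1",
               paste("NAME", hmm$metadata$name),
               paste("NMATCH", hmm$n_match),
               paste("ALPHABET", paste(AMINO_ACIDS, collapse = "")),
               paste("BACKGROUND", paste(fmt(hmm$background), collapse = " "))),
             con)
  writeLines(paste("NODE 0 TRANS",
                   paste(fmt(hmm$transitions[1L, ]), collapse = " ")), con)
  for (k in seq_len(hmm$n_match)) {
    writeLines(paste("NODE", k, "EMIT",
                     paste(fmt(hmm$match_emissions[k, ]), collapse = " "),
                     "TRANS",
                     paste(fmt(hmm$transitions[k + 1L, ]), collapse = " ")),
               con)
  }
  invisible(path)
}

#' Read a profile HMM from a model file written by [write_profile()]
#' @param path Path to a model file.
#' @return A `profile_hmm`.
#' @export
read_profile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^ACYLMINER_PHMM", lines[1])) stop("not a profile model file: ", path)
  name <- sub("^NAME ", "", lines[2])
  K <- as.integer(sub("^NMATCH ", "", lines[3]))
  bg <- as.numeric(strsplit(sub("^BACKGROUND ", "", lines[5]), " ")[[1]])
  names(bg) <- AMINO_ACIDS
  node0 <- as.numeric(strsplit(sub("^NODE 0 TRANS ", "", lines[6]), " ")[[1]])
  em <- matrix(0, K, 20L, dimnames = list(NULL, AMINO_ACIDS))
  trans <- matrix(0, K + 1L, 7L, dimnames = list(NULL, TRANS_NAMES))
  trans[1L, ] <- node0
  for (k in seq_len(K)) {
    parts <- strsplit(lines[6L + k], " ")[[1]]
    em[k, ] <- as.numeric(parts[4:23])
    trans[k + 1L, ] <- as.numeric(parts[25:31])
  }
  structure(list(n_match = K, match_emissions = em, insert_emissions = bg,
                 background = bg, transitions = trans,
                 metadata = list(name = name, n_seqs = NA_integer_,
                                 match_columns = NULL,
                                 match_threshold = NA_real_,
                                 pseudocount_weight = NA_real_)),
            class = "profile_hmm")
}
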