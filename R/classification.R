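# Competitive clade assignment: confront a sequence with every
# clade-specific profile HMM and assign by the highest bit score.

#' Build a clade model (profile HMM plus calibration) from a member alignment
#'
#' @param name Clade name (unique within a panel).
#' @param aln Trimmed member [alignment].
#' @param mean_length Background sequence length for calibration.
#' @param seed Calibration seed.
#' @param ... Passed to [build_profile()].
#' @return A `clade_model` list (`name`, `hmm`, `calibration`).
#' @export
clade_model <- function(name, aln, mean_length = 350L, seed = 1L, ...) {
  hmm <- build_profile(aln, name = name, ...)
  cal <- calibrate_evalue(hmm, mean_length = mean_length,
                          seed = derive_seed(seed, "clade", name))
  structure(list(name = name, hmm = hmm, calibration = cal),
            class = "clade_model")
}

#' Classify a sequence against a panel of clade models
#'
#' Scores the sequence with the forward algorithm against every model and
#' assigns the clade with the highest bit score.  Ties are broken by
#' lexicographic clade name and flagged ambiguous; assignments whose
#' score margin over the runner-up falls below `margin_threshold` bits are
#' flagged ambiguous with both clade names reported.  A sequence whose
#' score is not significant against any model (per-model Gumbel P-value
#' above 0.01 for every clade) sets `low_score`: probably not a
#' superfamily member at all.
#'
#' @param seq A `sequence_record` or residue string.
#' @param panel List of [clade_model()] (unique names).
#' @param margin_threshold Ambiguity margin in bits (default 2).
#' @return A `clade_assignment`: `id`, `scores` (named bit scores),
#'   `best`, `second`, `margin`, `ambiguous`, `low_score`.
#' @export
classify <- function(seq, panel, margin_threshold = 2) {
  if (!length(panel)) stop("empty clade panel")
  nms <- vapply(panel, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate clade names in panel")
  id <- if (inherits(seq, "sequence_record")) seq$id else "seq"
  scores <- vapply(panel, function(cm) forward_bits(cm$hmm, seq), 0)
  names(scores) <- nms
  pvals <- vapply(seq_along(panel), function(i)
    evalue(panel[[i]]$calibration, scores[i], 1), 0)
  ord <- order(-scores, nms)        # argmax; ties broken lexicographically
  best <- nms[ord[1]]
  second <- if (length(nms) > 1L) nms[ord[2]] else NA_character_
  margin <- if (length(nms) > 1L) scores[ord[1]] - scores[ord[2]] else Inf
  structure(list(id = id, scores = scores, best = best, second = second,
                 margin = unname(margin),
                 ambiguous = margin < margin_threshold,
                 low_score = all(pvals > 0.01)),
            class = "clade_assignment")
}

#' @export
print.clade_assignment <- function(x, ...) {
  cat(sprintf("<clade_assignment %s -> %s (margin %.2f bits%s%s)>\n",
              x$id, x$best, x$margin,
              if (x$ambiguous) sprintf(", ambiguous with %s", x$second) else "",
              if (x$low_score) ", low score" else ""))
  invisible(x)
}

#' Classify many sequences; return a tidy report
#' @param seqs List of `sequence_record`.
#' @inheritParams classify
#' @return data.frame with per-clade score columns plus `best`, `second`,
#'   `margin`, `ambiguous`, `low_score`.
#' @export
classify_batch <- function(seqs, panel, margin_threshold = 2) {
  rows <- lapply(seqs, function(s) {
    a <- classify(s, panel, margin_threshold)
    cbind(data.frame(id = a$id, stringsAsFactors = FALSE),
          as.data.frame(as.list(a$scores)),
          data.frame(best = a$best, second = a$second, margin = a$margin,
                     ambiguous = a$ambiguous, low_score = a$low_score,
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify the quarantined (e.g. truncated) sequences of a mining state
#'
#' Every quarantined sequence — typically truncated gene models that fail
#' hallmark scrutiny — is confronted with the clade panel and assigned by
#' highest score, mirroring how fragmentary sequences excluded from tree
#' building are still placed in their closest phylogenetic group.
#'
#' @param state A [mine_to_convergence()] state.
#' @param panel List of [clade_model()].
#' @param margin_threshold Ambiguity margin in bits.
#' @return data.frame as in [classify_batch()], plus the quarantine
#'   `reason`; zero rows if nothing is quarantined.
#' @export
classify_quarantined <- function(state, panel, margin_threshold = 2) {
  stopifnot(inherits(state, "mining_state"))
  if (!length(state$quarantined_records))
    return(data.frame(id = character(0), best = character(0),
                      margin = numeric(0), ambiguous = logical(0),
                      low_score = logical(0), reason = character(0),
                      stringsAsFactors = FALSE))
  rep <- classify_batch(state$quarantined_records, panel, margin_threshold)
  rep$reason <- state$quarantined$reason[match(rep$id, state$quarantined$id)]
  rep
}
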