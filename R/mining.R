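# Iterative profile-HMM data mining: search -> retrieve above E-value
# threshold -> dedupe -> motif scrutiny -> realign -> rebuild profile,
# repeated until the accepted id set stops changing.

#' Mining configuration
#'
#' @param inclusion_evalue E-value inclusion threshold for eukaryote-style
#'   searches (default 0.01).
#' @param prokaryote_evalue Stricter threshold used when a search set is
#'   tagged prokaryotic (default 1e-8).
#' @param max_iterations Iteration cap (default 20).
#' @param match_threshold,pseudocount_weight Profile-building parameters,
#'   see [build_profile()].
#' @param calibration_samples Background sequences per E-value calibration
#'   (default 200; recalibrated every iteration because the model changes).
#' @param scrutiny Optional [motif_screen()] of required hallmark motifs;
#'   sequences failing it are quarantined, not deleted, so they can later
#'   be classified by HMM score.
#' @param group_labels Optional named list partitioning taxon tags for
#'   group-specific mining.
#' @param seed Base seed; per-iteration calibration seeds are derived from
#'   it.
#' @return A `mining_config` list.
#' @export
mining_config <- function(inclusion_evalue = 0.01, prokaryote_evalue = 1e-8,
                          max_iterations = 20L, match_threshold = 0.5,
                          pseudocount_weight = 1, calibration_samples = 200L,
                          scrutiny = NULL, group_labels = NULL, seed = 1L) {
  stopifnot(inclusion_evalue > 0, prokaryote_evalue > 0, max_iterations >= 1L)
  structure(list(inclusion_evalue = inclusion_evalue,
                 prokaryote_evalue = prokaryote_evalue,
                 max_iterations = as.integer(max_iterations),
                 match_threshold = match_threshold,
                 pseudocount_weight = pseudocount_weight,
                 calibration_samples = as.integer(calibration_samples),
                 scrutiny = scrutiny, group_labels = group_labels,
                 seed = as.integer(seed)),
            class = "mining_config")
}

#' Search a proteome with a calibrated profile HMM
#'
#' Scores every sequence with the forward algorithm and returns hits with
#' E-value at or below the threshold, sorted by ascending E-value.
#'
#' @param hmm A [build_profile()] model.
#' @param proteome List of `sequence_record`.
#' @param cal A [calibrate_evalue()] calibration.
#' @param evalue_threshold Inclusion threshold.
#' @param db_size Database size for the E-value (default: number of
#'   sequences searched).
#' @return data.frame with columns `id`, `bit_score`, `e_value`, `model`.
#' @export
search_proteome <- function(hmm, proteome, cal, evalue_threshold,
                            db_size = length(proteome)) {
  if (!length(proteome)) {
    warning("empty proteome; no hits")
    return(data.frame(id = character(0), bit_score = numeric(0),
                      e_value = numeric(0), model = character(0)))
  }
  bits <- forward_bits_batch(hmm, proteome)
  ev <- evalue(cal, bits, db_size)
  # E-values are strictly positive in exact arithmetic (they can print as
  # 0 only through floating-point underflow), so a threshold of 0 admits
  # nothing
  keep <- if (evalue_threshold <= 0) integer(0) else
    which(ev <= evalue_threshold)
  out <- data.frame(id = vapply(proteome, `[[`, "", "id")[keep],
                    bit_score = bits[keep], e_value = ev[keep],
                    model = rep(hmm$metadata$name, length(keep)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$e_value, out$id), , drop = FALSE]
  rownames(out) <- NULL
  log_stage("search_proteome", model = hmm$metadata$name,
            n_db = length(proteome), n_hits = nrow(out),
            threshold = evalue_threshold)
  out
}

#' Collapse 100%-identical sequences
#'
#' Sequences with byte-identical residue strings are collapsed to the first
#' occurrence in input order.  Substrings are not duplicates.
#'
#' @param seqs List of `sequence_record`.
#' @return List with `kept` (records) and `removed_map` (named character
#'   vector: removed id -> representative id).
#' @export
dedupe_identical <- function(seqs) {
  res <- vapply(seqs, `[[`, "", "residues")
  first <- !duplicated(res)
  removed <- which(!first)
  rep_idx <- match(res[removed], res)
  removed_map <- stats::setNames(
    vapply(seqs[rep_idx], `[[`, "", "id"),
    vapply(seqs[removed], `[[`, "", "id"))
  log_stage("dedupe_identical", n_in = length(seqs), n_removed = length(removed))
  list(kept = seqs[first], removed_map = removed_map)
}

#' Scrutinize sequences against required hallmark motifs
#'
#' A sequence is accepted iff every required motif of the screen matches
#' (see [scan_motifs()]); failures are quarantined with the first failing
#' motif's name, and retained for later score-based classification.
#'
#' @param seqs List of `sequence_record`.
#' @param screen A [motif_screen()].
#' @return List with `accepted` (records) and `quarantined` (data.frame
#'   `id`, `reason`) plus `quarantined_records`.
#' @export
scrutinize <- function(seqs, screen) {
  stopifnot(inherits(screen, "motif_screen"))
  required <- Filter(function(m) isTRUE(m$required), screen$motifs)
  if (!length(required)) stop("motif screen defines no required motif")
  reasons <- vapply(seqs, function(s) {
    for (m in required) {
      if (nrow(scan_motifs(s, motif_screen(list(m), family = screen$family))) == 0L)
        return(m$name)
    }
    NA_character_
  }, "")
  ok <- is.na(reasons)
  log_stage("scrutinize", n_in = length(seqs), n_quarantined = sum(!ok))
  list(accepted = seqs[ok],
       quarantined = data.frame(
         id = vapply(seqs[!ok], `[[`, "", "id"),
         reason = reasons[!ok], stringsAsFactors = FALSE),
       quarantined_records = seqs[!ok])
}

#' Iterative profile-HMM mining to convergence
#'
#' Per iteration: build a profile from the current alignment, calibrate its
#' E-value null, search the proteome, retrieve hits at or below the
#' inclusion threshold, collapse identical sequences, quarantine sequences
#' failing motif scrutiny, realign the accepted set to the profile, and
#' repeat.  Converged when the accepted id set equals the previous
#' iteration's.  Deterministic given the config seed.
#'
#' @param seed_aln Seed [alignment].
#' @param proteome List of `sequence_record` to search.
#' @param config A [mining_config()].
#' @param evalue_threshold Inclusion threshold; defaults to
#'   `config$inclusion_evalue`.
#' @return A `mining_state` list: `iteration`, `accepted` (records),
#'   `accepted_ids`, `quarantined` (data.frame), `quarantined_records`,
#'   `current_alignment`, `current_model`, `calibration`, `converged`,
#'   `history` (per-iteration data.frame).
#' @export
mine_to_convergence <- function(seed_aln, proteome, config = mining_config(),
                                evalue_threshold = config$inclusion_evalue) {
  stopifnot(inherits(seed_aln, "alignment"))
  current_aln <- seed_aln
  prev_ids <- NULL
  history <- data.frame()
  accepted <- list(); quarantined <- data.frame(
    id = character(0), reason = character(0), stringsAsFactors = FALSE)
  quarantined_records <- list()
  model <- NULL; cal <- NULL
  converged <- FALSE
  mean_len <- max(1L, round(mean(vapply(proteome, function(s)
    nchar(s$residues), 0))))

  for (iter in seq_len(config$max_iterations)) {
    model <- build_profile(current_aln,
                           match_threshold = config$match_threshold,
                           pseudocount_weight = config$pseudocount_weight,
                           name = sprintf("iter%02d", iter))
    cal <- calibrate_evalue(model, n_samples = config$calibration_samples,
                            mean_length = mean_len,
                            seed = derive_seed(config$seed, "calibration", iter))
    hits <- search_proteome(model, proteome, cal, evalue_threshold)
    hit_records <- proteome[match(hits$id, vapply(proteome, `[[`, "", "id"))]
    dd <- dedupe_identical(hit_records)
    if (!is.null(config$scrutiny)) {
      sc <- scrutinize(dd$kept, config$scrutiny)
      accepted <- sc$accepted
      quarantined <- sc$quarantined
      quarantined_records <- sc$quarantined_records
    } else {
      accepted <- dd$kept
      quarantined <- data.frame(id = character(0), reason = character(0),
                                stringsAsFactors = FALSE)
      quarantined_records <- list()
    }
    ids <- sort(vapply(accepted, `[[`, "", "id"))
    n_new <- length(setdiff(ids, prev_ids))
    n_removed <- length(setdiff(prev_ids, ids))
    history <- rbind(history, data.frame(
      iteration = iter, n_hits = nrow(hits), n_accepted = length(ids),
      n_new = n_new, n_removed = n_removed,
      n_quarantined = nrow(quarantined)))
    log_stage("mine_iteration", iteration = iter, n_hits = nrow(hits),
              n_accepted = length(ids), n_new = n_new)
    if (!is.null(prev_ids) && identical(ids, prev_ids)) {
      converged <- TRUE
      break
    }
    prev_ids <- ids
    if (!length(accepted)) { converged <- TRUE; break }
    current_aln <- viterbi_align(model, accepted)
  }
  if (!converged)
    warning("mining did not converge within ", config$max_iterations,
            " iterations")
  structure(list(iteration = iter, accepted = accepted,
                 accepted_ids = sort(vapply(accepted, `[[`, "", "id")),
                 quarantined = quarantined,
                 quarantined_records = quarantined_records,
                 current_alignment = current_aln, current_model = model,
                 calibration = cal, converged = converged, history = history),
            class = "mining_state")
}

#' @export
print.mining_state <- function(x, ...) {
  cat(sprintf(
    "<mining_state: %d accepted, %d quarantined, %d iteration(s), %sconverged>\n",
    length(x$accepted), nrow(x$quarantined), x$iteration,
    if (x$converged) "" else "NOT "))
  invisible(x)
}

#' Group-specific re-mining from a converged global state
#'
#' For each taxon group, the globally accepted members carrying that
#' group's tags are realigned and mined again against the group's proteome
#' slice, which can recover group-specific members a global profile misses.
#' The final census is the union of global and group-specific accepted
#' sets (group mining never removes a globally accepted id).
#'
#' @param state A converged [mine_to_convergence()] state.
#' @param proteome The full proteome searched globally.
#' @param taxon_partition Named list: group name -> character vector of
#'   taxon tags.
#' @param config A [mining_config()].
#' @return List with `groups` (named list of `mining_state`) and
#'   `census_ids` (union of accepted ids).
#' @export
group_specific_mining <- function(state, proteome, taxon_partition,
                                  config = mining_config()) {
  stopifnot(inherits(state, "mining_state"))
  if (!state$converged) stop("group-specific mining requires a converged state")
  taxa <- vapply(proteome, function(s) s$taxon %||% NA_character_, "")
  groups <- list()
  for (g in names(taxon_partition)) {
    in_group <- taxa %in% taxon_partition[[g]]
    members <- Filter(function(s)
      (s$taxon %||% NA_character_) %in% taxon_partition[[g]], state$accepted)
    if (length(members) < 2L) {
      warning("group '", g, "' has fewer than 2 accepted members; skipped")
      next
    }
    seed_aln <- viterbi_align(state$current_model, members)
    groups[[g]] <- mine_to_convergence(seed_aln, proteome[in_group], config)
  }
  census <- sort(unique(c(state$accepted_ids,
                          unlist(lapply(groups, `[[`, "accepted_ids")))))
  list(groups = groups, census_ids = census)
}
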