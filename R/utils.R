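#' @useDynLib acylminer, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# 20 standard amino acids, alphabetical; 'X' (unknown) is tolerated everywhere
# and scored as neutral.
AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GAP_CHAR <- "-"

#' Encode residues as 0-based integers (X = 20) for the C++ kernels
#' @noRd
encode_residues <- function(residues) {
  ch <- strsplit(residues, "", fixed = TRUE)[[1]]
  idx <- match(ch, AMINO_ACIDS)
  idx[is.na(idx)] <- 21L  # X
  as.integer(idx - 1L)
}

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible sub-seed from a base seed and stream labels
#'
#' Distinct stages of the pipeline draw from independent streams derived
#' from one user seed; the derivation is a small deterministic hash kept
#' below 2^31.
#' @noRd
derive_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "/")
  raw <- utf8ToInt(parts)
  h <- 0
  for (v in raw) h <- (h * 31 + v) %% 2147483563
  as.integer(h + 1L)
}

#' Structured stage logging
#'
#' Emits one `key=value` line per pipeline stage to stderr when
#' `options(acylminer.verbose = TRUE)`.
#' @noRd
log_stage <- function(stage, ...) {
  if (!isTRUE(getOption("acylminer.verbose", FALSE))) return(invisible(NULL))
  kv <- list(...)
  txt <- paste(vapply(seq_along(kv), function(i)
    paste0(names(kv)[i], "=", paste(kv[[i]], collapse = ",")), ""),
    collapse = " ")
  message(sprintf("[acylminer] stage=%s %s", stage, txt))
  invisible(NULL)
}

#' log-sum-exp of a numeric vector
#' @noRd
logsumexp <- function(x) {
  x <- x[x > -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
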