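# Substitution models and scoring matrices used across the package.

# phangorn stores amino acids in ARNDCQEGHILKMFPSTWYV order; remap to the
# package's alphabetical order.
PHANGORN_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.model_cache <- new.env(parent = emptyenv())

#' WAG amino-acid rate matrix and stationary frequencies
#'
#' Returns the WAG (Whelan & Goldman) instantaneous rate matrix `Q`, scaled
#' to one expected substitution per site per unit time, together with its
#' stationary frequencies, both in alphabetical amino-acid order.
#' Exchangeabilities and frequencies are taken from phangorn's built-in
#' model tables; the same model drives the simulator and supplies the
#' default background frequencies of the profile-HMM scorer, so simulated
#' families and their profiles are mutually consistent.
#'
#' @return List with `Q` (20x20 rate matrix), `freq` (length-20 stationary
#'   distribution), and the symmetric eigen-decomposition used to compute
#'   transition matrices.
#' @export
wag_model <- function() {
  if (!is.null(.model_cache$wag)) return(.model_cache$wag)
  tab <- get(".WAG", environment(phangorn::pml))
  S <- matrix(0, 20L, 20L, dimnames = list(PHANGORN_AA, PHANGORN_AA))
  S[lower.tri(S)] <- tab$Q
  S <- S + t(S)
  freq <- tab$bf
  names(freq) <- PHANGORN_AA
  ord <- match(AMINO_ACIDS, PHANGORN_AA)
  S <- S[ord, ord]
  freq <- freq[ord] / sum(freq)
  Q <- S * rep(freq, each = 20L)
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freq * diag(Q))
  Q <- Q / scale
  # symmetrized eigen-decomposition for fast expm(Q t)
  d <- sqrt(freq)
  B <- diag(d) %*% Q %*% diag(1 / d)
  ev <- eigen((B + t(B)) / 2, symmetric = TRUE)
  .model_cache$wag <- list(Q = Q, freq = freq, d = d, values = ev$values,
                           vectors = ev$vectors)
  .model_cache$wag
}

#' WAG stationary amino-acid frequencies (alphabetical order)
#' @return Named numeric vector of length 20 summing to 1.
#' @export
wag_frequencies <- function() wag_model()$freq

#' Amino-acid transition probability matrix P(t) = expm(Q t) under WAG
#' @param t Branch length in expected substitutions per site.
#' @return 20x20 row-stochastic matrix in alphabetical amino-acid order.
#' @export
wag_transition_matrix <- function(t) {
  stopifnot(t >= 0)
  w <- wag_model()
  P <- diag(1 / w$d) %*% (w$vectors %*% (exp(w$values * t) * t(w$vectors))) %*%
    diag(w$d)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(AMINO_ACIDS, AMINO_ACIDS)
  P
}

#' Load a residue similarity matrix by name
#'
#' `"BLOSUM30"` loads the bundled NCBI BLOSUM30 table (the matrix used to
#' smooth column residue frequencies before computing trimming entropies);
#' `"identity"` returns the 20x20 identity matrix (useful for exact checks).
#'
#' @param name Matrix name, `"BLOSUM30"` or `"identity"`.
#' @return A 20x20 numeric matrix in alphabetical amino-acid order.
#' @export
similarity_matrix <- function(name = "BLOSUM30") {
  if (identical(tolower(name), "identity")) {
    m <- diag(20L)
    dimnames(m) <- list(AMINO_ACIDS, AMINO_ACIDS)
    return(m)
  }
  if (!identical(toupper(name), "BLOSUM30"))
    stop("unknown similarity matrix: ", name)
  if (!is.null(.model_cache$blosum30)) return(.model_cache$blosum30)
  path <- system.file("extdata", "BLOSUM30.tab", package = "acylminer")
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  cols <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  vals <- lapply(strsplit(trimws(lines[-1]), "\\s+"), function(x)
    as.numeric(x[-1]))
  m <- do.call(rbind, vals)
  dimnames(m) <- list(cols, cols)
  m <- m[AMINO_ACIDS, AMINO_ACIDS]
  .model_cache$blosum30 <- m
  m
}

#' Kyte-Doolittle hydropathy scale
#'
#' The published per-residue hydropathy values (range -4.5 for Arg to +4.5
#' for Ile); `X` contributes 0 in windowed averages.
#'
#' @return Named numeric vector over the 20 standard amino acids.
#' @export
kyte_doolittle_scale <- function() {
  c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
    I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
    R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)
}
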