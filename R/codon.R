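# Universal genetic code tables and the GY94 (M0) codon substitution model.
# Codons are ordered with the first position slowest and bases in T,C,A,G
# order, the conventional codon-model layout.

CODON_BASES <- c("T", "C", "A", "G")

.codon_tables <- local({
  # 64 codons in T/C/A/G nested order (third position fastest)
  cod <- character(64)
  idx <- 1L
  for (p1 in CODON_BASES) for (p2 in CODON_BASES) for (p3 in CODON_BASES) {
    cod[idx] <- paste0(p1, p2, p3)
    idx <- idx + 1L
  }
  aa <- strsplit("FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
                 "")[[1L]]
  names(aa) <- cod
  sense <- cod[aa != "*"]
  list(codons = cod, aa = aa, sense = sense)
})

#' Universal genetic code
#'
#' Amino-acid (one-letter) translation of the 64 codons, named by codon;
#' `"*"` marks stop codons.
#' @export
GENETIC_CODE_AA <- .codon_tables$aa

#' The 61 sense codons of the universal code
#' @export
SENSE_CODONS <- .codon_tables$sense

is_stop_codon <- function(codon) GENETIC_CODE_AA[codon] == "*"

# single-nucleotide neighbor structure over the 61 sense codons:
# for each ordered sense pair differing at exactly one position, whether the
# change is a transition and whether it is synonymous
.sense_neighbors <- local({
  s <- SENSE_CODONS
  n <- length(s)
  mat <- do.call(rbind, strsplit(s, ""))
  from <- integer(0); to <- integer(0); ts <- logical(0); syn <- logical(0)
  is_ts <- function(a, b) (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "T") && b %in% c("C", "T"))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- which(mat[i, ] != mat[j, ])
    if (length(d) != 1L) next
    from <- c(from, i); to <- c(to, j)
    ts <- c(ts, is_ts(mat[i, d], mat[j, d]))
    syn <- c(syn, GENETIC_CODE_AA[s[i]] == GENETIC_CODE_AA[s[j]])
  }
  list(from = from, to = to, transition = ts, synonymous = syn)
})

#' F3x4 codon frequencies from position-specific base frequencies
#'
#' Codon frequencies proportional to the product of the base frequencies at
#' the three codon positions, with stop codons removed and the remainder
#' renormalized over the 61 sense codons.
#'
#' @param pos_freqs 3 x 4 numeric matrix of base frequencies (rows = codon
#'   positions, columns = A, C, G, T), each row summing to 1.
#' @return Named numeric vector over [SENSE_CODONS] summing to 1.
#' @export
f3x4_frequencies <- function(pos_freqs) {
  stopifnot(is.matrix(pos_freqs), nrow(pos_freqs) == 3L, ncol(pos_freqs) == 4L)
  if (any(pos_freqs < 0) || any(abs(rowSums(pos_freqs) - 1) > 1e-9))
    stop("each row of pos_freqs must be non-negative and sum to 1")
  colnames(pos_freqs) <- c("A", "C", "G", "T")
  f <- vapply(SENSE_CODONS, function(cd) {
    b <- strsplit(cd, "")[[1L]]
    pos_freqs[1L, b[1L]] * pos_freqs[2L, b[2L]] * pos_freqs[3L, b[3L]]
  }, 0)
  f / sum(f)
}

# GY94/M0 rate matrix over the 61 sense codons, scaled so branch lengths are
# expected substitutions per codon at stationarity
gy94_rate_matrix <- function(kappa, omega, codon_freqs) {
  stopifnot(kappa > 0, omega > 0, length(codon_freqs) == 61L)
  if (abs(sum(codon_freqs) - 1) > 1e-9) stop("codon frequencies must sum to 1")
  nb <- .sense_neighbors
  Q <- matrix(0, 61L, 61L, dimnames = list(SENSE_CODONS, SENSE_CODONS))
  rate <- codon_freqs[nb$to] *
    ifelse(nb$transition, kappa, 1) *
    ifelse(nb$synonymous, 1, omega)
  Q[cbind(nb$from, nb$to)] <- rate
  diag(Q) <- -rowSums(Q)
  scale <- -sum(codon_freqs * diag(Q))
  Q / scale
}

# Transition-probability function for a reversible rate matrix via
# symmetrized eigendecomposition; returns function(t) -> 61 x 61 matrix.
codon_transition_fn <- function(Q, codon_freqs) {
  sq <- sqrt(codon_freqs)
  S <- outer(sq, 1 / sq) * Q  # D^{1/2} Q D^{-1/2}, symmetric for reversible Q
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  V <- e$vectors
  left <- V / sq          # row-scaled: D^{-1/2} V
  right <- t(V * sq)      # t(V) D^{1/2}
  function(t) {
    P <- left %*% (exp(e$values * t) * right)
    P[P < 0] <- 0
    P / rowSums(P)
  }
}

# split a character matrix alignment into an integer codon matrix
# (values index SENSE_CODONS; NA for gaps/N/stops/partial codons)
codon_index_matrix <- function(aln) {
  m <- unclass(aln)
  L <- ncol(m)
  if (L %% 3L != 0L) stop("alignment length ", L, " not divisible by 3")
  nc <- L %/% 3L
  p1 <- m[, seq(1L, L, by = 3L), drop = FALSE]
  p2 <- m[, seq(2L, L, by = 3L), drop = FALSE]
  p3 <- m[, seq(3L, L, by = 3L), drop = FALSE]
  cods <- matrix(paste0(p1, p2, p3), nrow = nrow(m),
                 dimnames = list(rownames(m), NULL))
  idx <- match(cods, SENSE_CODONS)
  matrix(idx, nrow = nrow(m), dimnames = list(rownames(m), NULL))
}
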