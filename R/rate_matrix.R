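#' Goldman-Yang-style codon rate matrix
#'
#' Instantaneous rate matrix over the 61 sense codons. The rate from codon i
#' to codon j is zero when the codons differ at more than one position, and
#' otherwise `pi_j * kappa^[transition] * omega^[nonsynonymous]`. The
#' diagonal makes rows sum to zero; with `scale = TRUE` the matrix is
#' rescaled so the expected number of substitutions per codon site per unit
#' branch length equals 1 at stationarity.
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega nonsynonymous/synonymous rate ratio dN/dS (>= 0).
#' @param codon_freqs stationary frequencies of the 61 sense codons
#'   (summing to 1).
#' @param scale rescale to one expected substitution per unit branch length.
#' @return 61 x 61 rate matrix with rows summing to zero.
#' @export
build_rate_matrix <- function(kappa, omega, codon_freqs, scale = TRUE) {
  stopifnot(kappa > 0, omega >= 0, length(codon_freqs) == N_CODON)
  if (any(codon_freqs < 0) || abs(sum(codon_freqs) - 1) > 1e-8)
    stop("codon_freqs must be non-negative and sum to 1")
  mult <- matrix(0, N_CODON, N_CODON)
  mult[STEP_TYPE == 1L] <- 1
  mult[STEP_TYPE == 2L] <- kappa
  mult[STEP_TYPE == 3L] <- omega
  mult[STEP_TYPE == 4L] <- kappa * omega
  Q <- mult * rep(codon_freqs, each = N_CODON)
  diag(Q) <- -rowSums(Q)
  if (scale) {
    r <- -sum(codon_freqs * diag(Q))
    if (r <= 0) stop("degenerate rate matrix (zero total rate)")
    Q <- Q / r
  }
  Q
}

# Eigen-decomposition of a reversible generator via its symmetrized form;
# P(t) = U diag(exp(lambda t)) Uinv.
rate_matrix_eigen <- function(Q, codon_freqs) {
  sq <- sqrt(codon_freqs)
  A <- Q * (sq / rep(sq, each = N_CODON))   # diag(sq) Q diag(1/sq), A_ij = sq_i Q_ij / sq_j
  A <- (A + t(A)) / 2
  es <- eigen(A, symmetric = TRUE)
  list(U = es$vectors / sq, Uinv = t(es$vectors) * rep(sq, each = N_CODON),
       lambda = es$values)
}

transition_matrix <- function(eig, t) {
  P <- eig$U %*% (exp(eig$lambda * t) * eig$Uinv)
  # eigen-reconstruction noise can push tiny probabilities slightly
  # negative; floor keeps the pruning partials strictly positive
  P[P < 1e-16] <- 1e-16
  P
}

#' Empirical codon frequencies (F3x4)
#'
#' Position-specific nucleotide frequencies pooled over all taxa, multiplied
#' across the three codon positions and renormalized over the 61 sense
#' codons. With `model = "f61"` the empirical sense-codon frequencies are
#' used directly (floored at 1e-6 and renormalized so every state stays
#' reachable).
#'
#' @param alignment a [codon_alignment()].
#' @param model `"f3x4"` (default) or `"f61"`.
#' @return Numeric vector of 61 frequencies summing to 1.
#' @export
codon_frequencies <- function(alignment, model = c("f3x4", "f61")) {
  model <- match.arg(model)
  states <- alignment$codons[!is.na(alignment$codons)]
  if (!length(states)) stop("alignment has no usable codons")
  if (model == "f61") {
    f <- tabulate(states, nbins = N_CODON) / length(states)
  } else {
    f <- rep(1, N_CODON)
    for (pos in 1:3) {
      nf <- tabulate(CODON_NUC[states, pos], nbins = 4L)
      nf <- nf / sum(nf)
      f <- f * nf[CODON_NUC[, pos]]
    }
  }
  f <- pmax(f, 1e-6)
  f / sum(f)
}

# Site-pattern compression: returns 0-based tip-state matrix of unique
# columns (-1 = missing) plus multiplicities.
compress_patterns <- function(alignment, taxa_order) {
  m <- alignment$codons[taxa_order, , drop = FALSE]
  m[is.na(m)] <- 0L
  m <- m - 1L
  key <- apply(m, 2L, paste, collapse = ".")
  idx <- match(key, unique(key))
  list(tips = m[, !duplicated(key), drop = FALSE],
       weights = as.numeric(tabulate(idx, nbins = max(idx))))
}
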