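# Genetic-code constants shared by every module. The universal nuclear code
# is the only code supported (spider nuclear loci); it is a fixed constant,
# not a configuration knob.

NUC <- c("T", "C", "A", "G")

# 64 codons in TCAG order with the classic one-letter translation string.
ALL_CODONS <- as.vector(t(outer(
  as.vector(t(outer(NUC, NUC, paste0))), NUC, paste0
)))
AA64 <- strsplit(
  "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG", ""
)[[1]]
names(AA64) <- ALL_CODONS

STOP_CODONS <- ALL_CODONS[AA64 == "*"]
SENSE_CODONS <- ALL_CODONS[AA64 != "*"]
N_CODON <- length(SENSE_CODONS) # 61
CODON_AA <- AA64[SENSE_CODONS]
CODON_INDEX <- stats::setNames(seq_len(N_CODON), SENSE_CODONS)

# nucleotide index (1..4 in TCAG order) of each sense codon at each position
CODON_NUC <- t(vapply(
  strsplit(SENSE_CODONS, ""),
  function(x) match(x, NUC),
  integer(3)
))

.is_transition <- function(a, b) {
  # purine A/G, pyrimidine C/T (indices in NUC: T=1, C=2, A=3, G=4)
  purine <- c(FALSE, FALSE, TRUE, TRUE)
  purine[a] == purine[b]
}

# Single-nucleotide-step classification between sense codons:
# 0 = identical or >1 difference; 1 = syn transversion; 2 = syn transition;
# 3 = nonsyn transversion; 4 = nonsyn transition.
STEP_TYPE <- local({
  m <- matrix(0L, N_CODON, N_CODON)
  for (i in seq_len(N_CODON)) {
    for (j in seq_len(N_CODON)) {
      if (i == j) next
      diff <- which(CODON_NUC[i, ] != CODON_NUC[j, ])
      if (length(diff) != 1L) next
      ts <- .is_transition(CODON_NUC[i, diff], CODON_NUC[j, diff])
      syn <- CODON_AA[i] == CODON_AA[j]
      m[i, j] <- 1L + 2L * (!syn) + ts
    }
  }
  m
})

# Synonymous-family structure for ENC (Wright's scheme): single-codon amino
# acids (Met, Trp) are excluded; Ile is the one 3-fold family; Leu, Ser and
# Arg are kept whole as 6-fold families.
ENC_FAMILIES <- local({
  fam <- split(seq_len(N_CODON), CODON_AA)
  fam[lengths(fam) > 1L]
})
ENC_DEGENERACY <- lengths(ENC_FAMILIES)

# NG86 site counting: fraction of the three single-nucleotide changes at each
# codon position that are synonymous; changes creating a stop codon are
# skipped (not counted as synonymous nor nonsynonymous).
NG86_SYN_SITES <- local({
  s <- numeric(N_CODON)
  for (i in seq_len(N_CODON)) {
    nsyn <- 0
    for (pos in 1:3) {
      for (alt in 1:4) {
        if (alt == CODON_NUC[i, pos]) next
        nuc <- CODON_NUC[i, ]
        nuc[pos] <- alt
        codon <- paste0(NUC[nuc], collapse = "")
        if (AA64[codon] == "*") next
        if (AA64[codon] == CODON_AA[i]) nsyn <- nsyn + 1
      }
    }
    s[i] <- nsyn / 3
  }
  s
})

# NG86 difference counting: for every ordered codon pair, the expected number
# of synonymous and nonsynonymous differences averaged with equal weight over
# minimal mutational pathways. Pathways through stop codons are discarded; in
# the rare case every pathway is blocked, all pathways are used with steps
# into/out of a stop scored as nonsynonymous.
.ng86_pair_diffs <- local({
  perms1 <- list(1L)
  perms2 <- list(c(1L, 2L), c(2L, 1L))
  perms3 <- list(
    c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
    c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)
  )
  function(i, j) {
    diff <- which(CODON_NUC[i, ] != CODON_NUC[j, ])
    k <- length(diff)
    if (k == 0L) return(c(0, 0))
    perms <- switch(k, perms1, perms2, perms3)
    paths <- matrix(NA_real_, length(perms), 2L)
    blocked <- logical(length(perms))
    for (p in seq_along(perms)) {
      ord <- diff[perms[[p]]]
      cur <- CODON_NUC[i, ]
      sd <- nd <- 0
      for (pos in ord) {
        nxt <- cur
        nxt[pos] <- CODON_NUC[j, pos]
        a <- AA64[paste0(NUC[cur], collapse = "")]
        b <- AA64[paste0(NUC[nxt], collapse = "")]
        if (b == "*" && !all(nxt == CODON_NUC[j, ])) blocked[p] <- TRUE
        if (a != "*" && a == b) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      paths[p, ] <- c(sd, nd)
    }
    keep <- if (all(blocked)) rep(TRUE, length(perms)) else !blocked
    colMeans(paths[keep, , drop = FALSE])
  }
})

NG86_SYN_DIFF <- matrix(0, N_CODON, N_CODON)
NG86_NONSYN_DIFF <- matrix(0, N_CODON, N_CODON)
for (.i in seq_len(N_CODON)) {
  for (.j in seq_len(N_CODON)) {
    if (.i == .j) next
    d <- .ng86_pair_diffs(.i, .j)
    NG86_SYN_DIFF[.i, .j] <- d[1]
    NG86_NONSYN_DIFF[.i, .j] <- d[2]
  }
}
rm(.i, .j, d)
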