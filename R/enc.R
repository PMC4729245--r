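#' Effective number of codons (ENC)
#'
#' Wright's Nc computed from a single species' codon states. Synonymous
#' families follow the universal code with Met and Trp excluded, Ile as the
#' sole 3-fold family and Leu/Ser/Arg kept whole as 6-fold families, giving
#' ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6 with Fk the mean codon homozygosity
#' of the degeneracy-k families.
#'
#' Two homozygosity estimators are supported: the default bias-corrected
#' F = (n * sum(p^2) - 1)/(n - 1), and the plain F = sum(p^2)
#' (`plain_f = TRUE`), which realises the analytic endpoints exactly:
#' one codon per amino acid gives ENC = 20, perfectly even synonymous usage
#' gives ENC = 61. Families observed fewer than twice contribute nothing; a
#' degeneracy class with no usable family is imputed from the observed
#' classes (the 3-fold class from the mean of the 2- and 4-fold classes when
#' both exist). Each class's effective-codon contribution is capped at its
#' degeneracy, and the final value is clamped to [20, 61].
#'
#' @param x integer vector of codon states (indices into the 61 sense
#'   codons; `NA` = missing), or a character vector of codons.
#' @param plain_f use the plain homozygosity estimator `sum(p^2)`.
#' @return ENC value in `[20, 61]`.
#' @export
enc <- function(x, plain_f = FALSE) {
  if (is.character(x)) x <- CODON_INDEX[toupper(x)]
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("no usable codons (all missing)")
  counts <- tabulate(x, nbins = N_CODON)
  fam_f <- fam_k <- numeric(0)
  for (i in seq_along(ENC_FAMILIES)) {
    cnt <- counts[ENC_FAMILIES[[i]]]
    n <- sum(cnt)
    if (n < 2L) next
    p <- cnt / n
    f <- if (plain_f) sum(p^2) else (n * sum(p^2) - 1) / (n - 1)
    fam_f <- c(fam_f, f)
    fam_k <- c(fam_k, ENC_DEGENERACY[i])
  }
  if (length(fam_f) == 0L) stop("no synonymous family observed at least twice")
  kclass <- c(2, 3, 4, 6)
  nfam <- c(9, 1, 5, 3)
  fbar <- vapply(kclass, function(k) {
    f <- fam_f[fam_k == k]
    if (length(f)) mean(f) else NA_real_
  }, numeric(1))
  # impute absent classes from observed ones (3-fold from 2- and 4-fold)
  if (is.na(fbar[2]) && !is.na(fbar[1]) && !is.na(fbar[3]))
    fbar[2] <- (fbar[1] + fbar[3]) / 2
  fbar[is.na(fbar)] <- mean(fbar, na.rm = TRUE)
  contrib <- ifelse(fbar > 0, pmin(1 / fbar, kclass), kclass)
  min(61, max(20, 2 + sum(nfam * contrib)))
}

#' Per-species ENC on an alignment
#'
#' @param alignment a [codon_alignment()].
#' @inheritParams enc
#' @return Named numeric vector, one ENC per taxon.
#' @export
enc_per_species <- function(alignment, plain_f = FALSE) {
  apply(alignment$codons, 1L, enc, plain_f = plain_f)
}

.group_mean_enc <- function(codons, labels, plain_f) {
  vals <- apply(codons, 1L, enc, plain_f = plain_f)
  c(social = mean(vals[labels[rownames(codons)] == "social"]),
    subsocial = mean(vals[labels[rownames(codons)] == "subsocial"]))
}

#' Bootstrap confidence intervals for group-mean ENC
#'
#' Resamples codon columns with replacement to the original alignment
#' length; for each replicate the mean ENC of the social and subsocial
#' species is recomputed, and percentile confidence bounds are taken per
#' group.
#'
#' @param alignment a [codon_alignment()].
#' @param labels named species -> social/subsocial vector.
#' @param n_boot number of bootstrap replicates (paper design: 1000).
#' @param seed RNG seed.
#' @param conf confidence level (default 0.95, i.e. 2.5/97.5 percentiles).
#' @inheritParams enc
#' @return List with `point` (observed group means), `ci` (2 x 2 matrix,
#'   rows social/subsocial, columns lower/upper), `replicates` (n_boot x 2),
#'   `n_boot` and `seed`.
#' @export
bootstrap_group_ci <- function(alignment, labels, n_boot = 1000L,
                               seed = 1L, conf = 0.95, plain_f = FALSE) {
  stopifnot(n_boot >= 1L)
  labels <- validate_mating_labels(labels)
  nc <- ncol(alignment$codons)
  if (nc < 2L) warning("single-column alignment: bootstrap CI is degenerate")
  point <- .group_mean_enc(alignment$codons, labels, plain_f)
  set.seed(seed)
  reps <- matrix(NA_real_, n_boot, 2L,
                 dimnames = list(NULL, c("social", "subsocial")))
  for (b in seq_len(n_boot)) {
    cols <- sample.int(nc, nc, replace = TRUE)
    reps[b, ] <- .group_mean_enc(
      alignment$codons[, cols, drop = FALSE], labels, plain_f
    )
  }
  a <- (1 - conf) / 2
  ci <- t(apply(reps, 2L, stats::quantile, probs = c(a, 1 - a), names = FALSE))
  colnames(ci) <- c("lower", "upper")
  list(point = point, ci = ci, replicates = reps,
       n_boot = n_boot, seed = seed, conf = conf)
}

#' Permutation test for a group difference in ENC
#'
#' The observed statistic is mean(social ENC) - mean(subsocial ENC). Under
#' the null the species values are repeatedly split at random into groups of
#' the observed sizes and the statistic recomputed. The p-value is one-sided
#' in the direction "social mean higher" (the biological expectation under
#' reduced selection in the inbreeding species). When the number of distinct
#' splits `choose(n, n_social)` does not exceed `n_perm`, all splits are
#' enumerated and the exact fraction is reported; otherwise `n_perm` random
#' splits are drawn and the add-one-corrected estimate
#' `(1 + #(null >= observed))/(1 + n_perm)` is used.
#'
#' @param enc_values named numeric vector of per-species ENC.
#' @param labels named species -> social/subsocial vector.
#' @param n_perm number of random splits when sampling (paper design: 1000).
#' @param seed RNG seed (unused in exhaustive mode).
#' @param mode `"auto"` (exhaustive when the split count allows it),
#'   `"exhaustive"` or `"sampled"`.
#' @return List with `observed`, `p_value`, `null` (null statistics),
#'   `mode` ("exhaustive" or "sampled"), `n_perm` and `seed`.
#' @export
permutation_group_test <- function(enc_values, labels, n_perm = 1000L,
                                   seed = 1L,
                                   mode = c("auto", "exhaustive",
                                            "sampled")) {
  mode <- match.arg(mode)
  stopifnot(n_perm >= 1L)
  labels <- validate_mating_labels(labels)[names(enc_values)]
  if (anyNA(labels)) stop("every species needs a mating-system label")
  n <- length(enc_values)
  k <- sum(labels == "social")
  if (k < 1L || k >= n) stop("need at least one species per group")
  observed <- mean(enc_values[labels == "social"]) -
    mean(enc_values[labels == "subsocial"])
  stat <- function(idx) mean(enc_values[idx]) - mean(enc_values[-idx])
  exhaustive <- switch(mode, auto = choose(n, k) <= n_perm,
                       exhaustive = TRUE, sampled = FALSE)
  if (exhaustive) {
    splits <- utils::combn(n, k)
    null <- apply(splits, 2L, stat)
    p <- mean(null >= observed - 1e-12)
    mode <- "exhaustive"
    n_used <- ncol(splits)
  } else {
    set.seed(seed)
    null <- replicate(n_perm, stat(sample.int(n, k)))
    p <- (1 + sum(null >= observed - 1e-12)) / (1 + n_perm)
    mode <- "sampled"
    n_used <- n_perm
  }
  list(observed = observed, p_value = p, null = null, mode = mode,
       n_perm = n_used, seed = seed)
}

#' Base composition by codon position
#'
#' Nucleotide frequencies at each of the three codon positions, per species,
#' over non-missing codons.
#'
#' @param alignment a [codon_alignment()].
#' @return 3-dimensional array `[species, position, nucleotide]` with
#'   nucleotides ordered A, C, G, T; each position's four frequencies sum
#'   to 1.
#' @export
base_composition <- function(alignment) {
  taxa <- alignment$taxa
  out <- array(
    0, dim = c(length(taxa), 3L, 4L),
    dimnames = list(taxa, paste0("pos", 1:3), c("A", "C", "G", "T"))
  )
  # CODON_NUC is in TCAG order; report in ACGT order
  acgt <- match(c("A", "C", "G", "T"), NUC)
  for (i in seq_along(taxa)) {
    states <- alignment$codons[i, ]
    states <- states[!is.na(states)]
    if (!length(states)) stop("taxon '", taxa[i], "' has no usable codons")
    for (pos in 1:3) {
      cnt <- tabulate(CODON_NUC[states, pos], nbins = 4L)
      out[i, pos, ] <- (cnt / sum(cnt))[acgt]
    }
  }
  out
}

#' Full codon-usage-bias report
#'
#' Runs [enc_per_species()], [bootstrap_group_ci()] and
#' [permutation_group_test()] on one alignment and collects the results.
#'
#' @inheritParams bootstrap_group_ci
#' @param n_perm permutation count for the group test.
#' @return List of class `enc_report`.
#' @export
enc_report <- function(alignment, labels, n_boot = 1000L, n_perm = 1000L,
                       seed = 1L, plain_f = FALSE) {
  per_species <- enc_per_species(alignment, plain_f = plain_f)
  boot <- bootstrap_group_ci(alignment, labels, n_boot = n_boot,
                             seed = seed, plain_f = plain_f)
  perm <- permutation_group_test(per_species, labels, n_perm = n_perm,
                                 seed = seed + 1L)
  structure(
    list(per_species_enc = per_species, group_means = boot$point,
         group_ci = boot$ci, permutation = perm, n_bootstrap = n_boot,
         n_permutations = perm$n_perm, seed = seed, plain_f = plain_f),
    class = "enc_report"
  )
}

#' @export
print.enc_report <- function(x, ...) {
  cat("ENC report\n")
  print(round(x$per_species_enc, 2))
  cat(sprintf(
    "social mean %.2f (%.2f-%.2f), subsocial mean %.2f (%.2f-%.2f)\n",
    x$group_means["social"], x$group_ci["social", 1], x$group_ci["social", 2],
    x$group_means["subsocial"], x$group_ci["subsocial", 1],
    x$group_ci["subsocial", 2]
  ))
  cat(sprintf("permutation test (%s): diff = %.3f, P = %.4g\n",
              x$permutation$mode, x$permutation$observed,
              x$permutation$p_value))
  invisible(x)
}
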