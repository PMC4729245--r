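#' Specification for simulating a codon alignment along a tree
#'
#' @param tree a [labeled_tree()] providing topology, branch lengths
#'   (expected substitutions per codon site) and branch classes.
#' @param omega dN/dS: a single value, or a named vector over branch
#'   classes (`internal`, `external_social`, `external_subsocial`, or
#'   `external` for both external classes).
#' @param kappa transition/transversion ratio.
#' @param codon_freqs stationary codon frequencies (default uniform over
#'   the 61 sense codons).
#' @param n_codons alignment length in codons.
#' @param locus_lengths optional per-locus codon counts summing to
#'   `n_codons` (recorded as partitions).
#' @param seed RNG seed.
#' @return List of class `simulation_spec`.
#' @export
simulation_spec <- function(tree, omega, kappa = 2,
                            codon_freqs = rep(1 / N_CODON, N_CODON),
                            n_codons, locus_lengths = NULL, seed = 1L) {
  stopifnot(inherits(tree, "labeled_tree"), n_codons >= 1L, kappa > 0,
            all(omega >= 0))
  if (abs(sum(codon_freqs) - 1) > 1e-8)
    stop("codon_freqs must sum to 1")
  if (!is.null(locus_lengths) && sum(locus_lengths) != n_codons)
    stop("locus lengths must sum to n_codons")
  structure(
    list(tree = tree, omega = omega, kappa = kappa,
         codon_freqs = codon_freqs, n_codons = as.integer(n_codons),
         locus_lengths = locus_lengths, seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

.omega_for_class <- function(omega, cl) {
  if (length(omega) == 1L && is.null(names(omega))) return(unname(omega))
  if (cl %in% names(omega)) return(omega[[cl]])
  if (grepl("^external", cl) && "external" %in% names(omega))
    return(omega[["external"]])
  stop("no omega supplied for branch class '", cl, "'")
}

#' Simulate a codon alignment under a branch-class codon model
#'
#' Root codons are drawn from the stationary frequencies; each branch then
#' evolves states through the transition probabilities of its class's rate
#' matrix. Reproducible for a fixed seed.
#'
#' @param spec a [simulation_spec()].
#' @return List with `alignment` (a [codon_alignment()]) and `truth` (the
#'   generating parameters).
#' @export
simulate_codon_alignment <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  tree <- spec$tree
  phy <- ape::reorder.phylo(tree$phy, "cladewise")
  classes <- edge_classes(phy, tree$labels)
  ntip <- length(phy$tip.label)
  nnode_total <- ntip + phy$Nnode
  n <- spec$n_codons
  pi <- spec$codon_freqs

  per_edge_omega <- vapply(classes, .omega_for_class, numeric(1),
                           omega = spec$omega)
  uo <- unique(per_edge_omega)
  eigs <- lapply(uo, function(w)
    rate_matrix_eigen(build_rate_matrix(spec$kappa, w, pi), pi))

  states <- matrix(NA_integer_, nnode_total, n)
  root <- ntip + 1L
  states[root, ] <- sample.int(N_CODON, n, replace = TRUE, prob = pi)
  for (e in seq_len(nrow(phy$edge))) {
    par <- phy$edge[e, 1]
    ch <- phy$edge[e, 2]
    P <- transition_matrix(eigs[[match(per_edge_omega[e], uo)]],
                           phy$edge.length[e])
    out <- integer(n)
    for (s in unique(states[par, ])) {
      idx <- which(states[par, ] == s)
      out[idx] <- sample.int(N_CODON, length(idx), replace = TRUE,
                             prob = pmax(P[s, ], 0))
    }
    states[ch, ] <- out
  }
  codons <- states[seq_len(ntip), , drop = FALSE]
  rownames(codons) <- phy$tip.label
  parts <- NULL
  if (!is.null(spec$locus_lengths)) {
    ends <- cumsum(spec$locus_lengths)
    parts <- data.frame(
      locus = paste0("locus", seq_along(ends)),
      start = c(1L, utils::head(ends, -1) + 1L), end = ends
    )
  }
  list(
    alignment = codon_alignment(codons, partitions = parts),
    truth = list(omega = spec$omega, kappa = spec$kappa,
                 codon_freqs = spec$codon_freqs, seed = spec$seed,
                 branch_lengths = phy$edge.length)
  )
}

# Fixed study topology: three independently placed social tips, each sister
# to a subsocial tip, with short social terminal branches (about a quarter
# of the subsocial terminal lengths). Taxon names follow the model table of
# the study design this emulates.
.study_newick <- function(include_undescribed = FALSE) {
  core <- paste0(
    "((((S_dumicola:0.02,S_tentoriicola:0.08):0.05,",
    "(S_mimosarum:0.02,S_africanus:0.08):0.05):0.03,",
    "((S_sarasinorum:0.02,S_pacificus:0.08):0.05,",
    "(S_dufuori:0.07,S_bicolor:0.07):0.04):0.03):0.04,"
  )
  tail <- if (include_undescribed) {
    "(S_lineatus:0.05,(S_tibialis:0.06,S_undescribed:0.06):0.02):0.05);"
  } else {
    "(S_lineatus:0.07,S_tibialis:0.09):0.05);"
  }
  paste0(core, tail)
}

#' Synthetic study fixture: alignment, tree and mating-system labels
#'
#' Generates the desk-scale stand-in for the study data: a 10-taxon rooted
#' tree (3 social species, each sister to a subsocial species, with short
#' social terminal branches), a codon alignment of 13 loci totalling 1583
#' codons (4749 coding nucleotides) simulated under the 3-class branch
#' model, and the species labels. All defaults mirror the study design:
#' omega 0.17 internal / 0.25 external-social / 0.10 external-subsocial,
#' kappa 2. Optionally adds an 11th (undescribed, subsocial) taxon.
#'
#' @param seed RNG seed.
#' @param n_codons alignment length (default 1583).
#' @param omega named branch-class dN/dS vector.
#' @param kappa transition/transversion ratio.
#' @param include_undescribed add the 11th taxon.
#' @param codon_freqs stationary codon frequencies (default uniform).
#' @return List with `alignment`, `tree` (a [labeled_tree()]), `labels`,
#'   `truth` and the `spec` used.
#' @export
make_study_fixture <- function(seed = 1L, n_codons = 1583L,
                               omega = c(internal = 0.17,
                                         external_social = 0.25,
                                         external_subsocial = 0.10),
                               kappa = 2, include_undescribed = FALSE,
                               codon_freqs = rep(1 / N_CODON, N_CODON)) {
  phy <- ape::read.tree(text = .study_newick(include_undescribed))
  social <- c("S_dumicola", "S_mimosarum", "S_sarasinorum")
  labels <- stats::setNames(
    ifelse(phy$tip.label %in% social, "social", "subsocial"),
    phy$tip.label
  )
  tree <- labeled_tree(phy, labels)
  n_loci <- 13L
  base <- n_codons %/% n_loci
  locus_lengths <- c(rep(base, n_loci - 1L),
                     n_codons - base * (n_loci - 1L))
  spec <- simulation_spec(tree, omega = omega, kappa = kappa,
                          codon_freqs = codon_freqs, n_codons = n_codons,
                          locus_lengths = locus_lengths, seed = seed)
  sim <- simulate_codon_alignment(spec)
  list(alignment = sim$alignment, tree = tree, labels = labels,
       truth = sim$truth, spec = spec)
}

#' Write a study fixture to plain-text files
#'
#' Writes `alignment.fasta`, `tree.nwk`, `labels.tsv` and a `truth.yaml`
#' record of the generating parameters.
#'
#' @param fixture result of [make_study_fixture()].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_study_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_codon_alignment(fixture$alignment, file.path(dir, "alignment.fasta"))
  write_labeled_tree(fixture$tree, file.path(dir, "tree.nwk"))
  utils::write.table(
    data.frame(species = names(fixture$labels), label = fixture$labels),
    file.path(dir, "labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  truth <- fixture$truth
  truth$omega <- as.list(truth$omega)
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}

#' Skew synonymous codon usage of selected taxa
#'
#' Within each synonymous family, every codon of the target taxa is
#' replaced by the family's preferred codon with probability
#' `skew_strength`, leaving the amino-acid sequence untouched. Used to
#' induce a known group difference in ENC.
#'
#' @param alignment a [codon_alignment()].
#' @param skew_strength replacement probability in `[0, 1]`.
#' @param target_taxa taxa to skew.
#' @param seed RNG seed.
#' @return The modified [codon_alignment()].
#' @export
simulate_skewed_codon_usage <- function(alignment, skew_strength,
                                        target_taxa, seed = 1L) {
  stopifnot(skew_strength >= 0, skew_strength <= 1)
  missing <- setdiff(target_taxa, alignment$taxa)
  if (length(missing))
    stop("unknown taxa: ", paste(missing, collapse = ", "))
  if (skew_strength == 0) return(alignment)
  preferred <- stats::setNames(rep(NA_integer_, N_CODON), NULL)
  for (fam in ENC_FAMILIES) preferred[fam] <- fam[1]
  preferred[is.na(preferred)] <- which(is.na(preferred)) # Met, Trp
  set.seed(seed)
  codons <- alignment$codons
  for (tx in target_taxa) {
    row <- codons[tx, ]
    ok <- !is.na(row)
    flip <- ok & stats::runif(length(row)) < skew_strength
    codons[tx, flip] <- preferred[row[flip]]
  }
  codon_alignment(codons, partitions = alignment$partitions)
}

#' Convert clock time to codon branch length
#'
#' Maps a time span to the branch length (expected substitutions per codon
#' site) under which the codon model accumulates synonymous divergence at
#' exactly `mu` per synonymous site per generation: length =
#' `mu * years / generation_time * S / s_rate`, where `S` is the expected
#' number of Nei-Gojobori synonymous sites per codon and `s_rate` the
#' expected synonymous substitutions per codon per unit branch length at
#' stationarity. Used to build clock trees whose true node ages are known
#' in years.
#'
#' @param years time span in years.
#' @param mu mutation rate per site per generation.
#' @param generation_time years per generation.
#' @param kappa,omega,codon_freqs codon-model parameters of the intended
#'   simulation.
#' @return Branch length in expected substitutions per codon site.
#' @export
years_to_branch_length <- function(years, mu = 8.4e-8, generation_time = 1,
                                   kappa = 1, omega = 1,
                                   codon_freqs = rep(1 / N_CODON, N_CODON)) {
  Q <- build_rate_matrix(kappa, omega, codon_freqs)
  syn <- STEP_TYPE == 1L | STEP_TYPE == 2L
  s_rate <- sum(codon_freqs * rowSums(Q * syn))
  S <- sum(codon_freqs * NG86_SYN_SITES)
  mu * years / generation_time * S / s_rate
}

#' Simulate an unconstrained non-coding partition
#'
#' Jukes-Cantor nucleotide evolution along the tree, used to emulate the
#' intronic partition that accompanies the coding data.
#'
#' @param tree a [labeled_tree()].
#' @param n_sites number of nucleotide sites.
#' @param seed RNG seed.
#' @return Character matrix (taxa x sites) of nucleotides.
#' @export
simulate_noncoding <- function(tree, n_sites, seed = 1L) {
  set.seed(seed)
  phy <- ape::reorder.phylo(tree$phy, "cladewise")
  ntip <- length(phy$tip.label)
  states <- matrix(NA_integer_, ntip + phy$Nnode, n_sites)
  states[ntip + 1L, ] <- sample.int(4L, n_sites, replace = TRUE)
  for (e in seq_len(nrow(phy$edge))) {
    t <- phy$edge.length[e]
    p_same <- 0.25 + 0.75 * exp(-4 * t / 3)
    par_states <- states[phy$edge[e, 1], ]
    change <- stats::runif(n_sites) >= p_same
    out <- par_states
    shift <- sample.int(3L, sum(change), replace = TRUE)
    out[change] <- 1L + (par_states[change] - 1L + shift) %% 4L
    states[phy$edge[e, 2], ] <- out
  }
  m <- matrix(c("A", "C", "G", "T")[states[seq_len(ntip), ]], ntip, n_sites)
  rownames(m) <- phy$tip.label
  m
}
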