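#' Nei-Gojobori synonymous and nonsynonymous distances
#'
#' Counting-method estimates for one sequence pair: synonymous and
#' nonsynonymous site counts by degeneracy averaging over the two sequences,
#' differences averaged with equal weight over minimal mutational pathways
#' (pathways through stop codons excluded), and Jukes-Cantor correction of
#' the proportions. Codons missing or ambiguous in either sequence are
#' dropped pairwise.
#'
#' @param seq_a,seq_b equal-length codon-state vectors (indices into the 61
#'   sense codons, `NA` = missing) or character vectors of codons.
#' @return List with `dS`, `dN` (Jukes-Cantor corrected; `Inf` with a
#'   `saturated` flag when the raw proportion reaches 3/4), raw proportions
#'   `pS`, `pN`, site counts `S`, `N`, difference counts `Sd`, `Nd`, and the
#'   number of compared codons.
#' @export
nei_gojobori <- function(seq_a, seq_b) {
  if (is.character(seq_a)) seq_a <- CODON_INDEX[toupper(seq_a)]
  if (is.character(seq_b)) seq_b <- CODON_INDEX[toupper(seq_b)]
  if (length(seq_a) != length(seq_b))
    stop("sequences differ in length")
  ok <- !is.na(seq_a) & !is.na(seq_b)
  a <- seq_a[ok]
  b <- seq_b[ok]
  n <- length(a)
  if (n == 0L) stop("no pairwise-complete codons")
  S <- (sum(NG86_SYN_SITES[a]) + sum(NG86_SYN_SITES[b])) / 2
  N <- 3 * n - S
  idx <- cbind(a, b)
  Sd <- sum(NG86_SYN_DIFF[idx])
  Nd <- sum(NG86_NONSYN_DIFF[idx])
  pS <- Sd / S
  pN <- Nd / N
  jc <- function(p) {
    if (p >= 0.75) return(Inf)
    -0.75 * log(1 - 4 * p / 3)
  }
  list(dS = jc(pS), dN = jc(pN), pS = pS, pN = pN, S = S, N = N,
       Sd = Sd, Nd = Nd, n_codons = n,
       saturated = pS >= 0.75 || pN >= 0.75, method = "NG86")
}

#' Pairwise synonymous-distance matrix
#'
#' @param alignment a [codon_alignment()].
#' @param value `"dS"` (default) or `"dN"`.
#' @return Symmetric taxa x taxa matrix with zero diagonal and attribute
#'   `method = "NG86"`.
#' @export
ds_matrix <- function(alignment, value = c("dS", "dN")) {
  value <- match.arg(value)
  taxa <- alignment$taxa
  n <- length(taxa)
  m <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- nei_gojobori(alignment$codons[i, ], alignment$codons[j, ])
      m[i, j] <- m[j, i] <- d[[value]]
    }
  }
  attr(m, "method") <- "NG86"
  m
}

#' Mean synonymous distance back to each internal node
#'
#' For each internal node of the rooted tree, the mean pairwise distance
#' over all tip pairs whose most recent common ancestor is that node.
#'
#' @param tree a [labeled_tree()] (rooted).
#' @param ds symmetric pairwise distance matrix covering the tree's tips.
#' @return Data frame with `node` (internal node id), `n_pairs` and
#'   `mean_ds`, ordered with the root first.
#' @export
node_mean_ds <- function(tree, ds) {
  phy <- tree$phy
  tips <- phy$tip.label
  if (!all(tips %in% rownames(ds)))
    stop("distance matrix does not cover all tree tips")
  ntip <- length(tips)
  mrca <- ape::mrca(phy)
  pairs <- utils::combn(ntip, 2L)
  anc <- mrca[cbind(pairs[1, ], pairs[2, ])]
  vals <- ds[cbind(tips[pairs[1, ]], tips[pairs[2, ]])]
  nodes <- sort(unique(anc))
  out <- data.frame(
    node = nodes,
    n_pairs = vapply(nodes, function(v) sum(anc == v), integer(1)),
    mean_ds = vapply(nodes, function(v) mean(vals[anc == v]), numeric(1))
  )
  root <- ntip + 1L
  out[order(out$node != root, out$node), , drop = FALSE]
}

#' Strict-clock node ages from synonymous distances
#'
#' Ages assume synonymous sites evolve neutrally at the mutation rate `mu`
#' per site per generation, so a node's mean pairwise synonymous distance
#' accumulates along two diverging lineages: age in generations =
#' dS / (2 * mu), converted to years by `generation_time`.
#'
#' @param node_ds data frame from [node_mean_ds()] (or any data frame with
#'   `node` and `mean_ds` columns).
#' @param mu mutation rate per site per generation (default 8.4e-8, the
#'   Drosophila estimate).
#' @param generation_time years per generation (default 1).
#' @return Data frame of class `node_dating` with `age_years` and `age_my`
#'   added; saturated (infinite) distances yield `NA` ages. A warning is
#'   emitted when a clock violation puts a child node older than the root.
#' @export
date_nodes <- function(node_ds, mu = 8.4e-8, generation_time = 1) {
  stopifnot(mu > 0, generation_time > 0)
  ds <- node_ds$mean_ds
  age <- ifelse(is.finite(ds), ds / (2 * mu) * generation_time, NA_real_)
  out <- node_ds
  out$age_years <- age
  out$age_my <- age / 1e6
  root_age <- age[1]
  if (any(!is.na(age[-1]) & age[-1] > root_age + 1e-9))
    warning("clock violation: an internal node is dated older than the root")
  class(out) <- c("node_dating", class(out))
  out
}

#' Date all internal nodes of a labeled tree from an alignment
#'
#' Convenience wrapper chaining [ds_matrix()], [node_mean_ds()] and
#' [date_nodes()].
#'
#' @inheritParams node_mean_ds
#' @param alignment a [codon_alignment()] over the tree's tips.
#' @inheritParams date_nodes
#' @return A `node_dating` data frame.
#' @export
date_tree <- function(tree, alignment, mu = 8.4e-8, generation_time = 1) {
  date_nodes(node_mean_ds(tree, ds_matrix(alignment)),
             mu = mu, generation_time = generation_time)
}
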