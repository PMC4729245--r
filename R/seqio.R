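#' In-frame codon alignment
#'
#' A `codon_alignment` stores an aligned set of protein-coding sequences as
#' codon states: an integer matrix (taxa x codon columns) holding indices
#' into the 61 sense codons of the universal code, with `NA` marking a codon
#' that is missing or ambiguous (any non-ACGT character, including gaps).
#' Codon columns are 1-based in every report.
#'
#' @param codons integer matrix, taxa x codon columns, values in `1:61` or
#'   `NA`; rownames are the taxon identifiers.
#' @param partitions optional data frame with columns `locus`, `start`, `end`
#'   recording per-locus codon spans.
#' @return An object of class `codon_alignment`.
#' @export
codon_alignment <- function(codons, partitions = NULL) {
  stopifnot(is.matrix(codons), !is.null(rownames(codons)))
  if (anyDuplicated(rownames(codons)))
    stop("duplicate taxon names in alignment")
  vals <- codons[!is.na(codons)]
  if (length(vals) && (any(vals < 1L) || any(vals > N_CODON)))
    stop("codon states must be indices into the 61 sense codons")
  if (!is.null(partitions)) {
    stopifnot(all(c("locus", "start", "end") %in% names(partitions)))
  }
  structure(
    list(taxa = rownames(codons), codons = codons, partitions = partitions),
    class = "codon_alignment"
  )
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf(
    "codon_alignment: %d taxa x %d codons (%d nt)%s\n",
    nrow(x$codons), ncol(x$codons), 3L * ncol(x$codons),
    if (!is.null(x$partitions))
      sprintf(", %d loci", nrow(x$partitions)) else ""
  ))
  invisible(x)
}

#' @export
dim.codon_alignment <- function(x) dim(x$codons)

.char_matrix_to_codons <- function(mat, mask_stops, what = "alignment") {
  n_nt <- ncol(mat)
  if (n_nt %% 3L != 0L)
    stop(sprintf("framing error: %s length %d nt is not a multiple of 3",
                 what, n_nt))
  n_cod <- n_nt %/% 3L
  mat <- toupper(mat)
  mat[mat == "U"] <- "T"
  out <- matrix(NA_integer_, nrow(mat), n_cod,
                dimnames = list(rownames(mat), NULL))
  for (k in seq_len(n_cod)) {
    trip <- mat[, (3L * k - 2L):(3L * k), drop = FALSE]
    ok <- trip[, 1] %in% NUC & trip[, 2] %in% NUC & trip[, 3] %in% NUC
    cod <- rep(NA_character_, nrow(mat))
    cod[ok] <- paste0(trip[ok, 1], trip[ok, 2], trip[ok, 3])
    stops <- !is.na(cod) & cod %in% STOP_CODONS
    if (any(stops)) {
      if (!mask_stops)
        stop(sprintf(
          "in-frame stop codon %s in taxon '%s' at codon column %d",
          cod[which(stops)[1]], rownames(mat)[which(stops)[1]], k
        ))
      cod[stops] <- NA_character_
    }
    out[, k] <- CODON_INDEX[cod]
  }
  out
}

#' Read an in-frame codon alignment from FASTA
#'
#' Sequences are validated to share one length that is a multiple of three
#' after trimming `frame_offset` leading nucleotides. A codon containing any
#' non-ACGT character becomes a single ambiguous (missing) state. In-frame
#' stop codons abort the read unless `mask_stops = TRUE`, in which case they
#' are masked to missing.
#'
#' @param path FASTA file of aligned coding sequence.
#' @param frame_offset number of leading nucleotides to discard before
#'   framing (default 0).
#' @param mask_stops replace in-frame stops with the missing state instead of
#'   raising an error.
#' @return A [codon_alignment()].
#' @export
read_codon_alignment <- function(path, frame_offset = 0L,
                                 mask_stops = FALSE) {
  seqs <- ape::read.FASTA(path)
  if (length(seqs) == 0L) stop("no sequences in ", path)
  if (anyDuplicated(names(seqs)))
    stop("duplicate taxon name in ", path, ": ",
         names(seqs)[duplicated(names(seqs))][1])
  chars <- lapply(as.character(seqs), function(x) {
    if (frame_offset > 0L) x <- x[-seq_len(frame_offset)]
    x
  })
  lens <- lengths(chars)
  if (length(unique(lens)) != 1L)
    stop("sequences have unequal lengths: ",
         paste(range(lens), collapse = "-"), " nt")
  mat <- do.call(rbind, chars)
  rownames(mat) <- names(seqs)
  codon_alignment(.char_matrix_to_codons(mat, mask_stops))
}

#' Write a codon alignment to FASTA
#'
#' Missing codons are written as `---`.
#'
#' @param x a [codon_alignment()].
#' @param path output file.
#' @export
write_codon_alignment <- function(x, path) {
  txt <- apply(x$codons, 1L, function(row) {
    cod <- ifelse(is.na(row), "---", SENSE_CODONS[row])
    paste0(cod, collapse = "")
  })
  writeLines(paste0(">", x$taxa, "\n", txt), path)
  invisible(path)
}

#' Concatenate per-locus codon alignments
#'
#' All loci must contain the same taxa (row order follows the first locus);
#' the returned alignment records each locus span in `partitions`.
#'
#' @param alignments list of [codon_alignment()] objects, optionally named.
#' @return A [codon_alignment()] with per-locus partitions.
#' @export
concatenate_loci <- function(alignments) {
  stopifnot(length(alignments) >= 1L)
  taxa <- alignments[[1]]$taxa
  for (i in seq_along(alignments)) {
    miss <- union(setdiff(taxa, alignments[[i]]$taxa),
                  setdiff(alignments[[i]]$taxa, taxa))
    if (length(miss))
      stop("taxa mismatch between loci: ", paste(miss, collapse = ", "))
  }
  mats <- lapply(alignments, function(a) a$codons[taxa, , drop = FALSE])
  widths <- vapply(mats, ncol, integer(1))
  nm <- names(alignments)
  if (is.null(nm)) nm <- paste0("locus", seq_along(alignments))
  parts <- data.frame(
    locus = nm,
    start = cumsum(c(1L, widths[-length(widths)])),
    end = cumsum(widths)
  )
  codon_alignment(do.call(cbind, mats), partitions = parts)
}

#' Read a species -> mating-system label map
#'
#' Two-column tab-separated text: species identifier, then `social` or
#' `subsocial`.
#'
#' @param path label file.
#' @return Named character vector of labels.
#' @export
read_mating_labels <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("species", "label"),
                           stringsAsFactors = FALSE)
  validate_mating_labels(stats::setNames(tab$label, tab$species))
}

validate_mating_labels <- function(labels) {
  if (!all(labels %in% c("social", "subsocial")))
    stop("labels must be 'social' or 'subsocial'")
  if (anyDuplicated(names(labels))) stop("duplicate species in label map")
  labels
}

#' Phylogeny with mating-system branch classes
#'
#' Wraps a rooted bifurcating `ape::phylo` tree whose tips carry
#' social/subsocial labels. Each edge is classed `internal`,
#' `external_social` or `external_subsocial`; terminal edges take their class
#' from the tip label, all other edges are internal.
#'
#' @param phy rooted `phylo` object with branch lengths in expected
#'   substitutions per codon site.
#' @param labels named character vector mapping every tip to `social` or
#'   `subsocial`.
#' @param resolve_polytomies resolve multifurcations arbitrarily with
#'   zero-length branches instead of rejecting them.
#' @return An object of class `labeled_tree` with elements `phy`, `labels`
#'   and per-edge `classes` (aligned with `phy$edge`).
#' @export
labeled_tree <- function(phy, labels, resolve_polytomies = FALSE) {
  stopifnot(inherits(phy, "phylo"))
  labels <- validate_mating_labels(labels)
  missing <- setdiff(phy$tip.label, names(labels))
  if (length(missing))
    stop("tip(s) absent from label map: ", paste(missing, collapse = ", "))
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  if (!ape::is.binary(phy)) {
    if (!resolve_polytomies)
      stop("tree contains polytomies; set resolve_polytomies = TRUE")
    phy <- ape::multi2di(phy)
    phy$edge.length[is.na(phy$edge.length)] <- 0
  }
  if (is.null(phy$edge.length)) phy$edge.length <- rep(0.1, nrow(phy$edge))
  structure(
    list(phy = phy, labels = labels[phy$tip.label],
         classes = edge_classes(phy, labels)),
    class = "labeled_tree"
  )
}

edge_classes <- function(phy, labels) {
  ntip <- length(phy$tip.label)
  child <- phy$edge[, 2]
  cls <- rep("internal", nrow(phy$edge))
  tip_edge <- child <= ntip
  cls[tip_edge] <- paste0("external_", labels[phy$tip.label[child[tip_edge]]])
  cls
}

#' Read a rooted Newick tree and attach branch classes
#'
#' @param path Newick file.
#' @param labels named species -> social/subsocial vector covering all tips.
#' @param resolve_polytomies see [labeled_tree()].
#' @return A [labeled_tree()].
#' @export
read_labeled_tree <- function(path, labels, resolve_polytomies = FALSE) {
  labeled_tree(ape::read.tree(path), labels,
               resolve_polytomies = resolve_polytomies)
}

#' Write a labeled tree to Newick
#' @param x a [labeled_tree()].
#' @param path output file.
#' @export
write_labeled_tree <- function(x, path) {
  ape::write.tree(x$phy, path)
  invisible(path)
}

#' @export
print.labeled_tree <- function(x, ...) {
  cat(sprintf(
    "labeled_tree: %d tips (%d social, %d subsocial), %d edges (%d internal)\n",
    length(x$phy$tip.label), sum(x$labels == "social"),
    sum(x$labels == "subsocial"), nrow(x$phy$edge),
    sum(x$classes == "internal")
  ))
  invisible(x)
}

# Unrooted working copy used by the likelihood machinery: the reversible
# codon model is root-invariant and the rooted tree's two root edges are both
# internal-class, so classes are preserved by unrooting.
unrooted_fit_tree <- function(tree) {
  phy <- if (length(tree$phy$tip.label) > 2L) ape::unroot(tree$phy)
         else tree$phy
  phy <- ape::reorder.phylo(phy, "postorder")
  list(phy = phy, classes = edge_classes(phy, tree$labels))
}
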