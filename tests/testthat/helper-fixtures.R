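# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except files the tests themselves write to tempdirs.

# integer codon states for a character vector of codons
codon_states <- function(...) {
  unname(socialsel:::CODON_INDEX[toupper(c(...))])
}

# tiny alignment from per-taxon codon strings (character, one codon = 3 nt)
tiny_alignment <- function(seqs) {
  mats <- lapply(seqs, function(s) {
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    codon_states(codons)
  })
  m <- do.call(rbind, mats)
  rownames(m) <- names(seqs)
  codon_alignment(m)
}

# small rooted 4-taxon labeled tree
tiny_tree <- function(bl = 0.1) {
  nwk <- sprintf("((A:%g,B:%g):%g,(C:%g,D:%g):%g);", bl, bl, bl, bl, bl, bl)
  labeled_tree(ape::read.tree(text = nwk),
               c(A = "social", B = "subsocial", C = "subsocial",
                 D = "subsocial"))
}

# 6-taxon subtree of the study fixture (2 social, 4 subsocial), used where a
# scaled-down tree keeps replicated fits affordable
small_study_tree <- function() {
  fx <- make_study_fixture(seed = 1, n_codons = 10)
  keep <- c("S_dumicola", "S_tentoriicola", "S_mimosarum", "S_africanus",
            "S_lineatus", "S_tibialis")
  labeled_tree(ape::keep.tip(fx$tree$phy, keep), fx$labels[keep])
}

# 6-taxon tree with equal terminal branch lengths, used for likelihood-ratio
# calibration experiments: every omega class carries enough expected
# substitutions that the asymptotic chi-square null applies
calibration_tree <- function() {
  nwk <- paste0("((A:0.08,B:0.08):0.05,((C:0.08,D:0.08):0.05,",
                "(E:0.08,F:0.08):0.05):0.03);")
  labeled_tree(ape::read.tree(text = nwk),
               c(A = "social", B = "subsocial", C = "social",
                 D = "subsocial", E = "subsocial", F = "subsocial"))
}

# write a FASTA file of plain character sequences, return the path
write_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}
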