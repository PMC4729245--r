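test_that("FASTA codon alignments read with validation and round-trip", {
  p <- write_fasta(c(t1 = "ATGTTTGGA", t2 = "ATGTTCGGG"))
  aln <- read_codon_alignment(p)
  expect_s3_class(aln, "codon_alignment")
  expect_equal(dim(aln), c(2L, 3L))
  expect_equal(aln$taxa, c("t1", "t2"))
  expect_equal(aln$codons[1, ], codon_states("ATG", "TTT", "GGA"))

  # minimal valid input: two identical 6-nt sequences
  aln2 <- read_codon_alignment(write_fasta(c(a = "ATGTTT", b = "ATGTTT")))
  expect_equal(dim(aln2), c(2L, 2L))

  # round trip preserves content, including missing codons
  aln$codons[2, 3] <- NA
  aln3 <- codon_alignment(aln$codons)
  out <- tempfile(fileext = ".fasta")
  write_codon_alignment(aln3, out)
  back <- read_codon_alignment(out)
  expect_identical(back$codons, aln3$codons)

  # frame_offset trims leading nucleotides before framing
  off <- read_codon_alignment(write_fasta(c(a = "GATGTTT", b = "GATGTTT")),
                              frame_offset = 1L)
  expect_equal(off$codons[1, ], codon_states("ATG", "TTT"))
})

test_that("framing, stop-codon and naming violations are rejected", {
  expect_error(read_codon_alignment(write_fasta(c(a = "ATGTT", b = "ATGTT"))),
               "multiple of 3")
  expect_error(read_codon_alignment(write_fasta(c(a = "ATGTTT", b = "ATGT"))),
               "unequal length")
  # in-frame stop names the taxon and 1-based codon column
  expect_error(read_codon_alignment(write_fasta(c(a = "ATGTAA", b = "ATGTTT"))),
               "stop codon TAA in taxon 'a' at codon column 2")
  masked <- read_codon_alignment(
    write_fasta(c(a = "ATGTAA", b = "ATGTTT")), mask_stops = TRUE
  )
  expect_true(is.na(masked$codons["a", 2]))
  expect_false(anyNA(masked$codons["b", ]))
  p <- write_fasta(c(a = "ATGTTT", a = "ATGTTT"))
  expect_error(read_codon_alignment(p), "duplicate")
  # ambiguous characters become missing codons
  amb <- read_codon_alignment(write_fasta(c(a = "ATGN-T", b = "ATGTTT")))
  expect_true(is.na(amb$codons["a", 2]))
})

test_that("locus concatenation is additive, order-preserving and recorded", {
  mk <- function(n, shift = 0) {
    m <- matrix(rep(codon_states("ATG"), 2 * n) + shift, 2, n)
    rownames(m) <- c("a", "b")
    codon_alignment(m)
  }
  cc <- concatenate_loci(list(l1 = mk(100), l2 = mk(50, shift = 1)))
  expect_equal(ncol(cc$codons), 150L)
  expect_equal(cc$partitions$start, c(1L, 101L))
  expect_equal(cc$partitions$end, c(100L, 150L))
  expect_equal(unique(cc$codons[, 1:100][1, ]), codon_states("ATG"))

  single <- concatenate_loci(list(only = mk(7)))
  expect_equal(single$codons, mk(7)$codons)

  # associativity over columns
  abc <- concatenate_loci(list(mk(3), mk(4, 1), mk(5, 2)))
  ab_c <- concatenate_loci(list(
    concatenate_loci(list(mk(3), mk(4, 1))), mk(5, 2)
  ))
  expect_equal(abc$codons, ab_c$codons)

  # 13-locus fixture records 13 spans
  fx <- make_study_fixture(seed = 1, n_codons = 130)
  expect_equal(nrow(fx$alignment$partitions), 13L)
  expect_equal(fx$alignment$partitions$end[13], 130L)

  bad <- mk(3)
  rownames(bad$codons) <- c("a", "zzz")
  bad$taxa <- c("a", "zzz")
  expect_error(concatenate_loci(list(mk(3), bad)), "taxa mismatch.*zzz")
})

test_that("labeled trees classify branches and enforce the label map", {
  fx <- make_study_fixture(seed = 1, n_codons = 10)
  tr <- fx$tree
  # unrooted 10-tip bifurcating tree: 2n - 3 = 17 branches, 7 internal
  u <- socialsel:::unrooted_fit_tree(tr)
  expect_equal(nrow(u$phy$edge), 17L)
  expect_equal(sum(u$classes == "external_social"), 3L)
  expect_equal(sum(u$classes == "external_subsocial"), 7L)
  expect_equal(sum(u$classes == "internal"), 7L)

  # two-tip tree has no internal branches
  two <- labeled_tree(ape::read.tree(text = "(x:0.1,y:0.1);"),
                      c(x = "social", y = "subsocial"))
  expect_equal(sum(two$classes == "internal"), 0L)

  expect_error(
    labeled_tree(tr$phy, fx$labels[-1]),
    "absent from label map"
  )
  expect_error(
    labeled_tree(tr$phy, replace(fx$labels, 1, "colonial")),
    "social"
  )

  # polytomies rejected unless resolution is requested
  poly <- ape::read.tree(text = "((a:1,b:1,c:1):1,d:1);")
  labs <- c(a = "social", b = "subsocial", c = "subsocial", d = "subsocial")
  expect_error(labeled_tree(poly, labs), "polytomies")
  res <- labeled_tree(poly, labs, resolve_polytomies = TRUE)
  expect_true(ape::is.binary(res$phy))

  # Newick round trip preserves topology and classes
  path <- tempfile(fileext = ".nwk")
  write_labeled_tree(tr, path)
  back <- read_labeled_tree(path, fx$labels)
  expect_equal(sort(back$phy$tip.label), sort(tr$phy$tip.label))
  expect_equal(table(back$classes), table(tr$classes))
})
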