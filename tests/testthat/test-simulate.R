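test_that("simulation respects degenerate branch lengths and seeding", {
  tr <- tiny_tree(bl = 1e-12)
  sim <- simulate_codon_alignment(
    simulation_spec(tr, omega = 0.2, kappa = 2, n_codons = 200, seed = 2)
  )
  # zero branch lengths: all taxa identical to the root draw
  m <- sim$alignment$codons
  expect_true(all(m == rep(m[1, ], each = 4)))

  # seeded runs are bit-reproducible
  s1 <- simulate_codon_alignment(
    simulation_spec(tiny_tree(), omega = 0.3, kappa = 2, n_codons = 150,
                    seed = 7)
  )
  s2 <- simulate_codon_alignment(
    simulation_spec(tiny_tree(), omega = 0.3, kappa = 2, n_codons = 150,
                    seed = 7)
  )
  expect_identical(s1$alignment$codons, s2$alignment$codons)
  s3 <- simulate_codon_alignment(
    simulation_spec(tiny_tree(), omega = 0.3, kappa = 2, n_codons = 150,
                    seed = 8)
  )
  expect_false(identical(s1$alignment$codons, s3$alignment$codons))
})

test_that("a long branch converges to the stationary distribution", {
  two <- labeled_tree(ape::read.tree(text = "(x:25,y:25);"),
                      c(x = "social", y = "subsocial"))
  set.seed(1)
  f <- rgamma(61, 5, 1)
  f <- f / sum(f)
  sim <- simulate_codon_alignment(
    simulation_spec(two, omega = 0.5, kappa = 2, codon_freqs = f,
                    n_codons = 30000, seed = 11)
  )
  counts <- tabulate(sim$alignment$codons["x", ], nbins = 61)
  gof <- stats::chisq.test(counts, p = f)
  expect_gt(gof$p.value, 0.001)
})

test_that("the study fixture encodes the intended design", {
  fx <- make_study_fixture(seed = 1, n_codons = 130)
  expect_equal(sum(fx$tree$classes == "external_social"), 3L)
  expect_equal(sum(fx$labels == "social"), 3L)
  expect_equal(sum(fx$labels == "subsocial"), 7L)
  expect_equal(ncol(fx$alignment$codons), 130L)
  expect_equal(nrow(fx$alignment$partitions), 13L)
  # social terminal branches are short relative to subsocial terminals
  phy <- fx$tree$phy
  tip_bl <- function(cls) {
    mean(phy$edge.length[fx$tree$classes == cls])
  }
  expect_lt(tip_bl("external_social"), tip_bl("external_subsocial") / 3)

  # the optional 11th (undescribed, subsocial) taxon leaves the 10-taxon
  # branch classes unchanged
  fx11 <- make_study_fixture(seed = 1, n_codons = 20,
                             include_undescribed = TRUE)
  expect_equal(sum(fx11$tree$classes == "external_social"), 3L)
  expect_equal(length(fx11$tree$phy$tip.label), 11L)
  cls10 <- stats::setNames(
    fx$tree$classes[fx$tree$phy$edge[, 2] <= 10],
    fx$tree$phy$tip.label[fx$tree$phy$edge[fx$tree$phy$edge[, 2] <= 10, 2]]
  )
  cls11 <- stats::setNames(
    fx11$tree$classes[fx11$tree$phy$edge[, 2] <= 11],
    fx11$tree$phy$tip.label[
      fx11$tree$phy$edge[fx11$tree$phy$edge[, 2] <= 11, 2]]
  )
  expect_identical(cls11[names(cls10)], cls10)
})

test_that("fixture files round-trip through the plain-text writers", {
  fx <- make_study_fixture(seed = 3, n_codons = 40)
  dir <- tempfile("fixture")
  write_study_fixture(fx, dir)
  expect_setequal(list.files(dir),
                  c("alignment.fasta", "tree.nwk", "labels.tsv",
                    "truth.yaml"))
  aln <- read_codon_alignment(file.path(dir, "alignment.fasta"))
  labs <- read_mating_labels(file.path(dir, "labels.tsv"))
  tr <- read_labeled_tree(file.path(dir, "tree.nwk"), labs)
  expect_identical(aln$codons[fx$alignment$taxa, ], fx$alignment$codons)
  expect_identical(sort(names(labs)), sort(names(fx$labels)))
  truth <- yaml::read_yaml(file.path(dir, "truth.yaml"))
  expect_equal(truth$kappa, 2)
  expect_equal(table(tr$classes), table(fx$tree$classes))
})

test_that("codon-usage skew preserves the amino-acid sequence exactly", {
  fx <- make_study_fixture(seed = 5, n_codons = 400)
  social <- names(fx$labels)[fx$labels == "social"]
  for (s in c(0, 0.5, 1)) {
    sk <- simulate_skewed_codon_usage(fx$alignment, s, social, seed = 9)
    expect_identical(
      matrix(socialsel:::CODON_AA[sk$codons], nrow(sk$codons)),
      matrix(socialsel:::CODON_AA[fx$alignment$codons],
             nrow(fx$alignment$codons))
    )
    if (s == 0) expect_identical(sk$codons, fx$alignment$codons)
  }
  sk1 <- simulate_skewed_codon_usage(fx$alignment, 1, social, seed = 9)
  expect_true(all(enc_per_species(sk1, plain_f = TRUE)[social] == 20))
  # intermediate skew lands strictly between the endpoints
  skm <- simulate_skewed_codon_usage(fx$alignment, 0.5, social, seed = 9)
  mid <- enc_per_species(skm, plain_f = TRUE)[social]
  expect_true(all(mid > 20 & mid < enc_per_species(fx$alignment,
                                                   plain_f = TRUE)[social]))
  expect_error(simulate_skewed_codon_usage(fx$alignment, 0.5, "nope"),
               "unknown taxa")
})

test_that("null ENC calibration: uniform usage gives a centered group test", {
  # under uniform codon usage the social-minus-subsocial ENC difference
  # should be small and the permutation test should not reject
  ps <- vapply(1:5, function(s) {
    fx <- make_study_fixture(seed = 100 + s, n_codons = 400)
    vals <- enc_per_species(fx$alignment)
    permutation_group_test(vals, fx$labels)$p_value
  }, numeric(1))
  expect_gt(mean(ps > 0.05), 0.5)
})

test_that("non-coding simulation produces aligned nucleotide sequence", {
  fx <- make_study_fixture(seed = 2, n_codons = 10)
  nc <- simulate_noncoding(fx$tree, 589, seed = 4)
  expect_equal(dim(nc), c(10L, 589L))
  expect_true(all(nc %in% c("A", "C", "G", "T")))
  expect_setequal(rownames(nc), fx$tree$phy$tip.label)
})
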