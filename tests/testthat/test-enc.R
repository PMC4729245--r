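# one representative codon per amino acid (maximal bias), and the full
# sense-codon set (uniform usage)
one_codon_per_aa <- function() {
  unlist(lapply(split(seq_len(61), socialsel:::CODON_AA), `[`, 1))
}

test_that("ENC hits the analytic endpoints under the plain estimator", {
  expect_identical(enc(rep(one_codon_per_aa(), 10), plain_f = TRUE), 20)
  expect_identical(enc(rep(seq_len(61), 10), plain_f = TRUE), 61)
})

test_that("ENC matches independent family-homozygosity arithmetic", {
  # all families at even usage except Phe (TTT/TTC) at counts (3, 1):
  # plain F for that family = 0.75^2 + 0.25^2 = 0.625, the other eight
  # 2-fold families stay at 0.5
  counts <- rep(4L, 61)
  counts[codon_states("TTT")] <- 6L
  counts[codon_states("TTC")] <- 2L
  x <- rep(seq_len(61), counts)
  f2 <- mean(c((0.75^2 + 0.25^2), rep(0.5, 8)))
  expected <- 2 + 9 / f2 + 1 / (1 / 3) + 5 / (1 / 4) + 3 / (1 / 6)
  expect_equal(enc(x, plain_f = TRUE), expected, tolerance = 1e-12)
})

test_that("ENC is column-order invariant and row-deterministic", {
  set.seed(5)
  x <- sample.int(61, 3000, replace = TRUE)
  expect_equal(enc(x), enc(sample(x)))
  m <- rbind(a = x, b = x, c = x)
  vals <- enc_per_species(codon_alignment(m))
  expect_true(all(vals == vals[1]))
})

test_that("skewing synonymous usage lowers ENC monotonically", {
  set.seed(8)
  base <- codon_alignment(rbind(sp = sample.int(61, 4000, replace = TRUE)))
  encs <- vapply(c(0, 0.3, 0.6, 1), function(s) {
    enc_per_species(
      simulate_skewed_codon_usage(base, s, "sp", seed = 3), plain_f = TRUE
    )
  }, numeric(1))
  expect_true(all(diff(encs) < 0))
  expect_identical(encs[[4]], 20)     # full skew: one codon per family
  expect_gt(encs[[1]], 60)            # uniform usage at large n sits near 61
})

test_that("neutral uniform usage converges to ENC = 61", {
  set.seed(10)
  m <- matrix(sample.int(61, 3 * 1e5, replace = TRUE), 3)
  rownames(m) <- paste0("s", 1:3)
  vals <- enc_per_species(codon_alignment(m), plain_f = TRUE)
  expect_true(all(abs(vals - 61) < 0.5))
})

test_that("bootstrap CI degenerates on constant columns and is seeded", {
  aln <- codon_alignment(matrix(rep(codon_states("GGT"), 36), 3, 12,
                                dimnames = list(c("a", "b", "c"), NULL)))
  labs <- c(a = "social", b = "subsocial", c = "subsocial")
  res <- bootstrap_group_ci(aln, labs, n_boot = 50, seed = 4)
  expect_equal(unname(res$ci[, "upper"] - res$ci[, "lower"]), c(0, 0))

  fx <- make_study_fixture(seed = 2, n_codons = 120)
  b1 <- bootstrap_group_ci(fx$alignment, fx$labels, n_boot = 40, seed = 7)
  b2 <- bootstrap_group_ci(fx$alignment, fx$labels, n_boot = 40, seed = 7)
  expect_identical(b1$replicates, b2$replicates)
  expect_true(all(b1$ci[, "lower"] <= b1$ci[, "upper"]))
  # Monte-Carlo stability: two independent large-replicate runs agree
  fx2 <- make_study_fixture(seed = 2, n_codons = 600)
  b3 <- bootstrap_group_ci(fx2$alignment, fx2$labels, n_boot = 500,
                           seed = 8)
  b4 <- bootstrap_group_ci(fx2$alignment, fx2$labels, n_boot = 1500,
                           seed = 9)
  expect_lt(max(abs(b3$ci - b4$ci)), 0.5)
  expect_lt(max(abs(colMeans(b3$replicates) - colMeans(b4$replicates))),
            0.25)
})

test_that("permutation test: exhaustive mode equals brute-force enumeration", {
  set.seed(2)
  vals <- stats::setNames(rnorm(10, 50), paste0("s", 1:10))
  labs <- stats::setNames(rep(c("social", "subsocial"), c(3, 7)),
                          names(vals))
  res <- permutation_group_test(vals, labs, n_perm = 1000)
  expect_identical(res$mode, "exhaustive")
  # independent brute force over all C(10,3) splits
  obs <- mean(vals[1:3]) - mean(vals[4:10])
  splits <- combn(10, 3)
  null <- apply(splits, 2, function(i) mean(vals[i]) - mean(vals[-i]))
  expect_equal(res$p_value, mean(null >= obs))
  expect_equal(length(res$null), 120L)

  same <- permutation_group_test(rep(50, 10) + vals * 0, labs)
  expect_equal(same$p_value, 1)
  expect_equal(same$observed, 0)
})

test_that("base composition counts nucleotides by codon position", {
  aln <- tiny_alignment(c(a = "ATGATGATG", b = "ATGATGGGA"))
  bc <- base_composition(aln)
  expect_equal(unname(bc["a", "pos1", ]), c(1, 0, 0, 0))  # all A
  expect_equal(unname(bc["a", "pos2", ]), c(0, 0, 0, 1))  # all T
  expect_equal(unname(bc["a", "pos3", ]), c(0, 0, 1, 0))  # all G
  expect_true(all(abs(apply(bc, c(1, 2), sum) - 1) < 1e-12))
  # large-n frequencies approach the generating composition
  set.seed(3)
  m <- matrix(sample.int(61, 2e4, replace = TRUE), 1,
              dimnames = list("s", NULL))
  bc2 <- base_composition(codon_alignment(m))
  freq <- prop.table(table(factor(
    socialsel:::NUC[t(socialsel:::CODON_NUC[m, ])],
    levels = c("A", "C", "G", "T")
  )))
  expect_equal(mean(abs(apply(bc2["s", , ], 2, mean) - as.numeric(freq))),
               0, tolerance = 0.01)
})
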