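random_freqs <- function(seed) {
  set.seed(seed)
  f <- rgamma(61, 2, 1)
  f / sum(f)
}

test_that("rate matrix generator properties hold for random parameters", {
  for (seed in 1:3) {
    pi <- random_freqs(seed)
    kappa <- runif(1, 0.5, 5)
    omega <- runif(1, 0.02, 2)
    Q <- build_rate_matrix(kappa, omega, pi)
    expect_lt(max(abs(rowSums(Q))), 1e-12)
    # detailed balance: pi_i q_ij = pi_j q_ji
    flux <- pi * Q
    expect_lt(max(abs(flux - t(flux))) / max(abs(flux)), 1e-12)
    # scaling: one expected substitution per unit branch length
    expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)
    # multi-step rates are zero
    expect_true(all(Q[socialsel:::STEP_TYPE == 0L & diag(61) == 0] == 0))
  }
  # omega = kappa = 1 with equal frequencies: all single-step rates equal
  Q1 <- build_rate_matrix(1, 1, rep(1 / 61, 61), scale = FALSE)
  vals <- Q1[socialsel:::STEP_TYPE != 0L]
  expect_lt(diff(range(vals)), 1e-15)
  expect_error(build_rate_matrix(2, 0.5, rep(1, 61)), "sum to 1")
})

test_that("transition matrices are stochastic over a range of lengths", {
  pi <- random_freqs(4)
  eig <- socialsel:::rate_matrix_eigen(build_rate_matrix(2.5, 0.3, pi), pi)
  for (t in c(0, 1e-4, 0.1, 1, 10)) {
    P <- socialsel:::transition_matrix(eig, t)
    expect_true(all(P >= 0))
    expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
  }
})

test_that("pruning likelihood matches degenerate and saturated limits", {
  aln <- tiny_alignment(c(A = "ATGTTTGGAACC", B = "ATGTTTGGAACC",
                          C = "ATGTTTGGAACC", D = "ATGTTTGGAACC"))
  pi <- random_freqs(1)
  # zero branch lengths, identical sequences: logL = sum log pi(codon)
  tr0 <- tiny_tree(bl = 1e-9)
  ll <- codon_loglik(tr0, aln, list(kappa = 2, omega = 0.3,
                                    codon_freqs = pi))
  expect_equal(ll, sum(log(pi[aln$codons[1, ]])), tolerance = 1e-5)
  # saturation: logL tends to the independence limit
  trL <- tiny_tree(bl = 60)
  llL <- codon_loglik(trL, aln, list(kappa = 2, omega = 0.3,
                                     codon_freqs = pi))
  expect_equal(llL, sum(log(pi[aln$codons])), tolerance = 1e-3)
})

test_that("likelihood is invariant to re-rooting under the reversible model", {
  fx <- make_study_fixture(seed = 6, n_codons = 50)
  params <- list(kappa = 1.8,
                 omega = c(internal = 0.2, external_social = 0.3,
                           external_subsocial = 0.1),
                 codon_freqs = codon_frequencies(fx$alignment))
  ll1 <- codon_loglik(fx$tree, fx$alignment, params)
  re <- ape::root(ape::unroot(fx$tree$phy), outgroup = "S_lineatus",
                  resolve.root = TRUE)
  ll2 <- codon_loglik(labeled_tree(re, fx$labels), fx$alignment, params)
  expect_equal(ll1, ll2, tolerance = 1e-8)
})

test_that("ambiguous codons marginalize over states", {
  aln <- tiny_alignment(c(A = "ATGTTT", B = "ATGTTC", C = "ATGTTT",
                          D = "ATGCTT"))
  aln$codons[1, 2] <- NA
  params <- list(kappa = 2, omega = 0.5,
                 codon_freqs = rep(1 / 61, 61))
  ll <- codon_loglik(tiny_tree(), aln, params)
  # marginal likelihood of a missing state equals the sum over all 61
  # resolutions of that cell
  parts <- vapply(seq_len(61), function(s) {
    a2 <- aln
    a2$codons[1, 2] <- s
    codon_loglik(tiny_tree(), a2, params)
  }, numeric(1))
  expect_equal(ll, log(sum(exp(parts - max(parts)))) + max(parts),
               tolerance = 1e-8)
})

test_that("model A recovers a known omega from simulated data", {
  tr <- small_study_tree()
  sim <- simulate_codon_alignment(
    simulation_spec(tr, omega = 0.15, kappa = 2, n_codons = 2000, seed = 21)
  )
  fit <- fit_branch_model(tr, sim$alignment, "A", n_starts = 1)
  expect_true(fit$converged)
  expect_lt(abs(unname(fit$omega_by_class) - 0.15), 0.03)
  expect_lt(abs(fit$kappa - 2), 0.3)
  expect_equal(fit$n_free_params, nrow(fit$edges) + 2L)
})

test_that("model D collapses to model A on a two-taxon tree", {
  two <- labeled_tree(ape::read.tree(text = "(x:0.2,y:0.2);"),
                      c(x = "social", y = "subsocial"))
  aln <- simulate_codon_alignment(
    simulation_spec(two, omega = 0.3, kappa = 2, n_codons = 400, seed = 3)
  )$alignment
  fa <- fit_branch_model(two, aln, "A", n_starts = 1)
  fd <- fit_branch_model(two, aln, "D", init = fa, n_starts = 1)
  # a 2-tip tree has one unrooted branch worth of information; the D fit
  # cannot improve on A beyond optimizer tolerance
  expect_equal(fa$loglik, fd$loglik, tolerance = 1e-4)
})

test_that("M8 constrained to p0 = 1 reproduces the M7 likelihood", {
  fx <- make_study_fixture(seed = 9, n_codons = 120)
  fa <- fit_branch_model(fx$tree, fx$alignment, "A", n_starts = 1,
                         iter_max = 60)
  m7 <- fit_site_model(fx$tree, fx$alignment, "M7", ncat = 6, bl_fit = fa,
                       n_starts = 1, iter_max = 60)
  ll8 <- site_model_loglik(
    fx$tree, fx$alignment, "M8", kappa = m7$kappa,
    p = m7$site_params$p, q = m7$site_params$q, p0 = 1, omega_s = 3,
    ncat = 6, branch_lengths = m7$branch_lengths,
    codon_freqs = m7$codon_freqs
  )
  expect_equal(ll8, m7$loglik, tolerance = 1e-9)
})

test_that("M7-vs-M8 screen has power against pervasive positive selection", {
  tr <- calibration_tree()
  # 15% of sites at omega = 3, the rest purifying. The hot partition's
  # branch lengths are scaled by the relative total rate of the omega = 3
  # generator so the selected sites also evolve faster overall, as the
  # mixture model assumes.
  pi <- rep(1 / 61, 61)
  total_rate <- function(w) {
    Q <- build_rate_matrix(2, w, pi, scale = FALSE)
    -sum(pi * diag(Q))
  }
  phy_hot <- tr$phy
  phy_hot$edge.length <- phy_hot$edge.length *
    total_rate(3) / total_rate(0.1)
  tr_hot <- labeled_tree(phy_hot, tr$labels)
  set.seed(31)
  n <- 400
  pos <- rbinom(n, 1, 0.15) == 1
  sim_neu <- simulate_codon_alignment(
    simulation_spec(tr, omega = 0.1, kappa = 2, n_codons = n, seed = 32)
  )$alignment
  sim_pos <- simulate_codon_alignment(
    simulation_spec(tr_hot, omega = 3, kappa = 2, n_codons = n, seed = 33)
  )$alignment
  mixed <- sim_neu$codons
  mixed[, pos] <- sim_pos$codons[, pos]
  aln <- codon_alignment(mixed)
  fa <- fit_branch_model(tr, aln, "A", n_starts = 1, iter_max = 80)
  m7 <- fit_site_model(tr, aln, "M7", ncat = 8, bl_fit = fa,
                       n_starts = 1, iter_max = 80)
  m8 <- fit_site_model(tr, aln, "M8", ncat = 8, bl_fit = fa, m7_fit = m7,
                       n_starts = 1, iter_max = 80)
  lrt <- likelihood_ratio_test(m7, m8)
  expect_equal(lrt$df, 2L)
  expect_lt(lrt$p_value, 0.01)
  expect_gt(m8$site_params$omega_s, 1)
})

test_that("likelihood_ratio_test enforces nesting and degenerate cases", {
  fx <- make_study_fixture(seed = 12, n_codons = 80)
  fa <- fit_branch_model(fx$tree, fx$alignment, "A", n_starts = 1,
                         iter_max = 60)
  fb <- fit_branch_model(fx$tree, fx$alignment, "B", init = fa,
                         n_starts = 1, iter_max = 60)
  lrt <- likelihood_ratio_test(fa, fb)
  expect_equal(lrt$df, 1L)
  expect_gte(lrt$statistic, 0)
  expect_true(lrt$p_value > 0 && lrt$p_value <= 1)
  # identical log-likelihoods: statistic 0, p = 1
  fa_as_b <- fa
  fa_as_b$model <- "B"
  fa_as_b$n_free_params <- fa$n_free_params + 1L
  self <- likelihood_ratio_test(fa, fa_as_b)
  expect_equal(self$statistic, 0)
  expect_equal(self$p_value, 1)
  expect_error(likelihood_ratio_test(fb, fa), "not a nested")
  expect_error(likelihood_ratio_test(fa, fa), "not a nested")
})

test_that("regrouping the focal tip with the other social tips matches model C", {
  fx <- make_study_fixture(seed = 14, n_codons = 250)
  fa <- fit_branch_model(fx$tree, fx$alignment, "A", n_starts = 1)
  fc <- fit_branch_model(fx$tree, fx$alignment, "C", init = fa, n_starts = 1)
  rg <- regroup_branch_test(
    fx$tree, fx$alignment, "S_dumicola",
    partner_sets = list(c("S_mimosarum", "S_sarasinorum")), fit_a = fa
  )
  # grouping the three social tips reproduces the model-C class partition
  expect_equal(rg$table$loglik, fc$loglik, tolerance = 1e-4)
  expect_equal(unname(rg$table$omega_focal_group),
               unname(fc$omega_by_class["external_social"]),
               tolerance = 0.01)
  # every regrouped 3-class fit nests model A
  expect_true(all(rg$table$loglik >= fa$loglik - 1e-6))
  expect_error(regroup_branch_test(fx$tree, fx$alignment, "nope",
                                   partner_sets = list("S_lineatus")),
               "not a tip")
})
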