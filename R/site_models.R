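# M7/M8 beta site models: omega varies across alignment columns as a
# mixture over discretized categories; M8 appends one extra class with
# omega > 1. The M7-vs-M8 likelihood-ratio test is the positive-selection
# screen.

.site_categories <- function(model, p, q, ncat, p0 = NULL, omega_s = NULL) {
  mid <- (seq_len(ncat) - 0.5) / ncat
  omegas <- stats::qbeta(mid, p, q)
  weights <- rep(1 / ncat, ncat)
  if (model == "M8") {
    omegas <- c(omegas, omega_s)
    weights <- c(p0 * weights, 1 - p0)
  }
  list(omegas = omegas, weights = weights)
}

.logsumexp_rows <- function(m, logw) {
  # m: ncat x npat matrix of per-category site log-likelihoods
  m <- m + logw
  mx <- apply(m, 2L, max)
  log(colSums(exp(sweep(m, 2L, mx)))) + mx
}

.site_mixture_loglik <- function(setup, kappa, cats, pi, t) {
  # one common scaling so branch lengths are expected substitutions per
  # codon averaged over the site classes
  Qs <- lapply(cats$omegas, function(w)
    build_rate_matrix(kappa, w, pi, scale = FALSE))
  rates <- vapply(Qs, function(Q) -sum(pi * diag(Q)), numeric(1))
  common <- sum(cats$weights * rates)
  sl <- matrix(NA_real_, length(Qs), ncol(setup$tips))
  for (k in seq_along(Qs)) {
    eig <- rate_matrix_eigen(Qs[[k]] / common, pi)
    P <- array(0, dim = c(N_CODON, N_CODON, nrow(setup$edge)))
    for (e in seq_len(nrow(setup$edge)))
      P[, , e] <- transition_matrix(eig, t[e])
    sl[k, ] <- .pruning(setup, P, pi)$site_loglik
  }
  site <- .logsumexp_rows(sl, log(cats$weights))
  sum(site * setup$weights)
}

#' Site-model mixture log-likelihood
#'
#' Log-likelihood of an alignment under the M7 (beta) or M8 (beta plus a
#' class with omega > 1) site model, with the omega distribution discretized
#' into `ncat` equal-probability categories (beta quantile midpoints).
#'
#' @inheritParams codon_loglik
#' @param model `"M7"` or `"M8"`.
#' @param kappa transition/transversion ratio.
#' @param p,q beta shape parameters of the omega distribution on (0, 1).
#' @param p0 (M8) proportion of sites drawn from the beta.
#' @param omega_s (M8) omega of the extra class (> 1).
#' @param ncat number of discretization categories (default 10).
#' @param branch_lengths per postorder-edge lengths (default: the tree's).
#' @param codon_freqs 61 codon frequencies (default F3x4).
#' @return Log-likelihood.
#' @export
site_model_loglik <- function(tree, alignment, model = c("M7", "M8"),
                              kappa, p, q, p0 = NULL, omega_s = NULL,
                              ncat = 10L, branch_lengths = NULL,
                              codon_freqs = NULL) {
  model <- match.arg(model)
  setup <- .lik_setup(tree, alignment)
  pi <- codon_freqs %||% codon_frequencies(alignment)
  t <- branch_lengths %||% setup$phy$edge.length
  cats <- .site_categories(model, p, q, ncat, p0, omega_s)
  .site_mixture_loglik(setup, kappa, cats, pi, t)
}

#' Fit an M7 or M8 site model
#'
#' Branch lengths are first estimated under the single-ratio branch model
#' (model A) and then held fixed while kappa and the omega-distribution
#' parameters are optimized (the standard two-step site-model workflow);
#' pass `bl_fit` to reuse an existing model-A fit.
#'
#' @inheritParams site_model_loglik
#' @param freq_model `"f3x4"` or `"f61"`.
#' @param bl_fit optional `codon_model_fit` providing branch lengths and the
#'   kappa start (fitted internally when missing).
#' @param m7_fit (M8 only) optional fitted M7 model; adds a start at the M7
#'   optimum with the extra class switched off, which guarantees the M8
#'   optimum is no worse than M7's.
#' @param n_starts optimizer starts (extra starts are jittered).
#' @param iter_max maximum optimizer iterations per start.
#' @return A `codon_model_fit` with `site_params`
#'   (kappa, p, q and for M8 p0, omega_s), the fixed branch lengths, the
#'   discretized categories at the optimum, log-likelihood and convergence
#'   information.
#' @export
fit_site_model <- function(tree, alignment, model = c("M7", "M8"),
                           ncat = 10L, freq_model = c("f3x4", "f61"),
                           bl_fit = NULL, m7_fit = NULL, n_starts = 2L,
                           iter_max = 150L) {
  model <- match.arg(model)
  stopifnot(ncat >= 2L)
  freq_model <- match.arg(freq_model)
  setup <- .lik_setup(tree, alignment)
  pi <- codon_frequencies(alignment, freq_model)
  if (is.null(bl_fit))
    bl_fit <- fit_branch_model(tree, alignment, "A", freq_model = freq_model,
                               n_starts = 1L, iter_max = 100L)
  t <- bl_fit$edges$length

  unpack <- function(theta) {
    out <- list(kappa = exp(theta[1]), p = exp(theta[2]), q = exp(theta[3]))
    if (model == "M8") {
      out$p0 <- stats::plogis(theta[4])
      out$omega_s <- 1 + exp(theta[5])
    }
    out
  }
  fn <- function(theta) {
    pr <- unpack(theta)
    cats <- .site_categories(model, pr$p, pr$q, ncat, pr$p0, pr$omega_s)
    -.site_mixture_loglik(setup, pr$kappa, cats, pi, t)
  }

  npar <- if (model == "M8") 5L else 3L
  lower <- c(log(0.05), log(0.005), log(0.005), -7, log(1e-4))[seq_len(npar)]
  upper <- c(log(100), log(25), log(25), 7, log(49))[seq_len(npar)]
  start0 <- c(log(bl_fit$kappa), log(0.5), log(1.5), 2, log(0.5))[seq_len(npar)]

  starts <- list(start0)
  if (model == "M8" && !is.null(m7_fit) && m7_fit$model == "M7") {
    sp <- m7_fit$site_params
    starts <- c(starts, list(c(log(m7_fit$kappa), log(sp$p), log(sp$q),
                               6.9, log(0.5))))
  }
  best <- NULL
  trace <- list()
  for (s in seq_len(max(n_starts, length(starts)))) {
    start <- if (s <= length(starts)) starts[[s]] else {
      set.seed(2000L + s)
      pmin(pmax(start0 + stats::rnorm(npar, 0, 0.5), lower), upper)
    }
    opt <- stats::nlminb(start, fn, lower = lower, upper = upper,
                         control = list(iter.max = iter_max,
                                        eval.max = 4L * iter_max))
    trace[[s]] <- data.frame(start = s, loglik = -opt$objective,
                             convergence = opt$convergence,
                             iterations = opt$iterations,
                             message = opt$message)
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  pr <- unpack(best$par)
  cats <- .site_categories(model, pr$p, pr$q, ncat, pr$p0, pr$omega_s)
  structure(
    list(model = model, loglik = -best$objective, kappa = pr$kappa,
         site_params = pr, categories = cats, ncat = ncat,
         codon_freqs = pi, branch_lengths = t,
         n_free_params = npar,
         converged = best$convergence == 0L ||
           grepl("relative convergence|X-convergence|both X", best$message),
         optimizer_trace = do.call(rbind, trace),
         n_sites = setup$n_sites, n_patterns = ncol(setup$tips),
         note = if (model == "M8")
           paste("M7-vs-M8 LRT referred to chi-square(2) is conservative:",
                 "p0 and omega_s lie on the boundary under the null",
                 "(mixture alternative would be less conservative)")),
    class = "codon_model_fit"
  )
}
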