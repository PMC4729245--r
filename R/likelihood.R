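# Maximum-likelihood machinery for branch-class and site codon models.
# The reversible model makes the likelihood root-invariant, so all fits work
# on the unrooted postorder tree; analytic branch-length gradients come from
# the two-pass pruning pass in C++, rate-parameter gradients from central
# finite differences on the log scale.

.lik_setup <- function(tree, alignment) {
  stopifnot(inherits(tree, "labeled_tree"),
            inherits(alignment, "codon_alignment"))
  if (!setequal(tree$phy$tip.label, alignment$taxa))
    stop("tree tips and alignment taxa differ")
  u <- unrooted_fit_tree(tree)
  pat <- compress_patterns(alignment, u$phy$tip.label)
  list(phy = u$phy, edge = u$phy$edge, classes = u$classes,
       tips = pat$tips, weights = pat$weights,
       ntip = length(u$phy$tip.label), n_sites = ncol(alignment$codons))
}

.empty_cube <- function() array(0, dim = c(N_CODON, N_CODON, 0))

.pruning <- function(setup, P, pi, dP = NULL, dP_edge = integer(0),
                     dP_param = integer(0), npar = 0L) {
  want <- !is.null(dP)
  pruning_loglik_cpp(
    setup$tips, setup$weights, setup$edge, P, pi,
    want, if (want) dP else .empty_cube(),
    as.integer(dP_edge), as.integer(dP_param), as.integer(npar)
  )
}

# omega-class index per edge for the four branch models
.model_classes <- function(setup, model) {
  cls <- setup$classes
  tip_of_edge <- ifelse(setup$edge[, 2] <= setup$ntip,
                        setup$phy$tip.label[setup$edge[, 2]], NA)
  switch(model,
    A = list(idx = rep(1L, length(cls)), names = "all"),
    B = {
      ext <- cls != "internal"
      list(idx = ifelse(ext, 2L, 1L), names = c("internal", "external"))
    },
    C = {
      nm <- c("internal", "external_social", "external_subsocial")
      list(idx = match(cls, nm), names = nm)
    },
    D = {
      nm <- c("internal", tip_of_edge[!is.na(tip_of_edge)])
      idx <- ifelse(cls == "internal", 1L, match(tip_of_edge, nm))
      list(idx = as.integer(idx), names = nm)
    },
    stop("unknown branch model '", model, "'")
  )
}

# initial branch lengths: -log(1 - p) on pairwise codon mismatch, projected
# onto the topology by non-negative least squares
.init_branch_lengths <- function(setup, alignment) {
  taxa <- setup$phy$tip.label
  m <- alignment$codons[taxa, , drop = FALSE]
  n <- length(taxa)
  dm <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(m[i, ]) & !is.na(m[j, ])
      p <- if (any(ok)) mean(m[i, ok] != m[j, ok]) else 0
      dm[i, j] <- dm[j, i] <- -log(max(1 - p, 0.05))
    }
  }
  bl <- tryCatch({
    phy2 <- phangorn::nnls.tree(dm, setup$phy, method = "unrooted")
    key <- paste(setup$edge[, 1], setup$edge[, 2])
    bl <- phy2$edge.length[match(key, paste(phy2$edge[, 1], phy2$edge[, 2]))]
    if (anyNA(bl)) stop("edge mismatch")
    bl
  }, error = function(e) rep(mean(dm[upper.tri(dm)]) / 2, nrow(setup$edge)))
  pmax(bl, 1e-4)
}

# cached objective/gradient pair over theta = c(log t, log kappa, log omega)
.branch_objective <- function(setup, class_idx, n_omega, pi) {
  nE <- nrow(setup$edge)
  cache <- new.env(parent = emptyenv())
  cache$theta <- NULL

  lik_parts <- function(t, kappa, omegas) {
    Qs <- lapply(omegas, function(w) build_rate_matrix(kappa, w, pi))
    eigs <- lapply(Qs, rate_matrix_eigen, codon_freqs = pi)
    P <- array(0, dim = c(N_CODON, N_CODON, nE))
    for (e in seq_len(nE))
      P[, , e] <- transition_matrix(eigs[[class_idx[e]]], t[e])
    list(Q = Qs, P = P)
  }

  plain_loglik <- function(t, kappa, omegas) {
    parts <- lik_parts(t, kappa, omegas)
    .pruning(setup, parts$P, pi)$loglik
  }

  # recompute only the omega class touched by a finite-difference step
  perturbed_loglik <- function(t, kappa, omegas, base, class_j = NULL) {
    if (is.null(class_j)) return(plain_loglik(t, kappa, omegas))
    Qj <- build_rate_matrix(kappa, omegas[class_j], pi)
    eig <- rate_matrix_eigen(Qj, pi)
    P <- base$P
    for (e in which(class_idx == class_j))
      P[, , e] <- transition_matrix(eig, t[e])
    .pruning(setup, P, pi)$loglik
  }

  compute <- function(theta) {
    t <- exp(theta[seq_len(nE)])
    kappa <- exp(theta[nE + 1L])
    omegas <- exp(theta[nE + 1L + seq_len(n_omega)])
    parts <- lik_parts(t, kappa, omegas)
    dP <- array(0, dim = c(N_CODON, N_CODON, nE))
    for (e in seq_len(nE))
      dP[, , e] <- parts$Q[[class_idx[e]]] %*% parts$P[, , e]
    res <- .pruning(setup, parts$P, pi, dP = dP,
                    dP_edge = seq_len(nE), dP_param = seq_len(nE),
                    npar = nE)
    grad <- numeric(length(theta))
    grad[seq_len(nE)] <- res$grad * t      # d/d log t
    h <- 1e-4
    for (j in seq_len(1L + n_omega)) {
      gpm <- vapply(c(h, -h), function(d) {
        k2 <- kappa
        o2 <- omegas
        if (j == 1L) k2 <- kappa * exp(d) else o2[j - 1L] <- o2[j - 1L] * exp(d)
        perturbed_loglik(t, k2, o2, parts,
                         class_j = if (j > 1L) j - 1L else NULL)
      }, numeric(1))
      grad[nE + j] <- (gpm[1] - gpm[2]) / (2 * h)
    }
    list(value = res$loglik, grad = grad)
  }

  get <- function(theta) {
    if (is.null(cache$theta) || !identical(theta, cache$theta)) {
      cache$theta <- theta
      cache$res <- compute(theta)
    }
    cache$res
  }
  list(
    fn = function(theta) -get(theta)$value,
    gr = function(theta) -get(theta)$grad
  )
}

.fit_generic_branch <- function(setup, class_idx, class_names, pi,
                                init, n_starts, iter_max, model_tag) {
  nE <- nrow(setup$edge)
  n_omega <- length(class_names)
  obj <- .branch_objective(setup, class_idx, n_omega, pi)
  lower <- c(rep(log(1e-7), nE), log(0.05), rep(log(1e-4), n_omega))
  upper <- c(rep(log(20), nE), log(100), rep(log(50), n_omega))
  start0 <- c(log(init$branch_lengths), log(init$kappa), log(init$omega))
  start0 <- pmin(pmax(start0, lower), upper)

  best <- NULL
  trace <- list()
  for (s in seq_len(n_starts)) {
    start <- start0
    if (s > 1L) {
      set.seed(1000L + s)
      start <- pmin(pmax(start0 + stats::rnorm(length(start0), 0, 0.3),
                         lower), upper)
    }
    opt <- stats::nlminb(start, obj$fn, gradient = obj$gr,
                         lower = lower, upper = upper,
                         control = list(iter.max = iter_max,
                                        eval.max = 3L * iter_max,
                                        rel.tol = 1e-10))
    trace[[s]] <- data.frame(start = s, loglik = -opt$objective,
                             convergence = opt$convergence,
                             iterations = opt$iterations,
                             message = opt$message)
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }

  theta <- best$par
  t_hat <- exp(theta[seq_len(nE)])
  omega <- stats::setNames(exp(theta[nE + 1L + seq_len(n_omega)]),
                           class_names)
  edges <- data.frame(
    parent = setup$edge[, 1], child = setup$edge[, 2],
    length = t_hat, class = setup$classes,
    omega_class = class_names[class_idx],
    tip = ifelse(setup$edge[, 2] <= setup$ntip,
                 setup$phy$tip.label[setup$edge[, 2]], NA)
  )
  structure(
    list(model = model_tag, loglik = -best$objective,
         kappa = exp(theta[nE + 1L]), omega_by_class = omega,
         codon_freqs = pi, edges = edges,
         n_free_params = nE + 1L + n_omega,
         converged = best$convergence == 0L ||
           grepl("relative convergence|X-convergence|both X", best$message),
         optimizer_trace = do.call(rbind, trace),
         n_sites = setup$n_sites, n_patterns = ncol(setup$tips)),
    class = "codon_model_fit"
  )
}

#' @export
print.codon_model_fit <- function(x, ...) {
  cat(sprintf("codon model %s: lnL = %.6f, kappa = %.3f%s\n", x$model,
              x$loglik, x$kappa,
              if (!x$converged) " (NOT converged)" else ""))
  if (!is.null(x$omega_by_class)) {
    cat("  dN/dS:",
        paste(sprintf("%s = %.4f", names(x$omega_by_class),
                      x$omega_by_class), collapse = ", "), "\n")
  }
  if (!is.null(x$site_params)) {
    cat("  site params:",
        paste(sprintf("%s = %.4f", names(x$site_params),
                      unlist(x$site_params)), collapse = ", "), "\n")
  }
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Codon-model log-likelihood on a fixed tree
#'
#' Felsenstein-pruning log-likelihood of a codon alignment under the
#' branch-class model, summing over ancestral codon states; ambiguous
#' codons are marginalized over all 61 states.
#'
#' @param tree a [labeled_tree()].
#' @param alignment a [codon_alignment()] over the same taxa.
#' @param params list with `kappa`, `omega` (single value, or named by
#'   branch class: `internal`, `external`, `external_social`,
#'   `external_subsocial`), `codon_freqs` (61 frequencies; default F3x4 from
#'   the alignment) and optional `branch_lengths` (per postorder edge;
#'   default: the tree's own).
#' @return Log-likelihood (a single number, <= 0).
#' @export
codon_loglik <- function(tree, alignment, params) {
  setup <- .lik_setup(tree, alignment)
  pi <- params$codon_freqs %||% codon_frequencies(alignment)
  t <- params$branch_lengths %||% setup$phy$edge.length
  stopifnot(length(t) == nrow(setup$edge))
  omega <- params$omega
  per_edge <- if (length(omega) == 1L && is.null(names(omega))) {
    rep(unname(omega), length(setup$classes))
  } else {
    vapply(setup$classes, function(cl) {
      if (cl %in% names(omega)) return(omega[[cl]])
      if (grepl("^external", cl) && "external" %in% names(omega))
        return(omega[["external"]])
      stop("no omega supplied for branch class '", cl, "'")
    }, numeric(1))
  }
  uo <- unique(per_edge)
  eigs <- lapply(uo, function(w)
    rate_matrix_eigen(build_rate_matrix(params$kappa, w, pi), pi))
  P <- array(0, dim = c(N_CODON, N_CODON, nrow(setup$edge)))
  for (e in seq_len(nrow(setup$edge)))
    P[, , e] <- transition_matrix(eigs[[match(per_edge[e], uo)]], t[e])
  res <- .pruning(setup, P, pi)
  if (!is.finite(res$loglik)) {
    bad <- which(!is.finite(res$site_loglik))[1]
    stop("non-finite likelihood at site pattern ", bad)
  }
  res$loglik
}

# per-edge omega vector of a fit (used for warm starts and regrouping)
.edge_omegas <- function(fit) {
  unname(fit$omega_by_class[fit$edges$omega_class])
}

.warm_init <- function(fit, class_idx, class_names) {
  per_edge <- .edge_omegas(fit)
  omega <- vapply(seq_along(class_names),
                  function(c) mean(per_edge[class_idx == c]), numeric(1))
  omega[!is.finite(omega)] <- mean(per_edge)   # class with no edges
  list(branch_lengths = fit$edges$length, kappa = fit$kappa,
       omega = pmax(omega, 1e-4))
}

#' Fit a branch-class dN/dS codon model
#'
#' Maximum-likelihood fit of one of four nested branch models on a fixed
#' labeled topology: `"A"` one dN/dS ratio for every branch; `"B"` separate
#' internal and external ratios; `"C"` internal, external-social and
#' external-subsocial ratios; `"D"` one internal ratio plus a free ratio for
#' every external branch. Kappa, all branch lengths and the model's omega
#' set are optimized jointly (bounded quasi-Newton on log-transformed
#' parameters, with optional jittered restarts).
#'
#' @inheritParams codon_loglik
#' @param model one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param freq_model codon frequency model, `"f3x4"` (default) or `"f61"`.
#' @param init optional warm start: a `codon_model_fit` on the same tree, or
#'   a list with `branch_lengths`, `kappa`, `omega`.
#' @param n_starts number of optimizer starts (first from `init`, others
#'   jittered).
#' @param iter_max maximum optimizer iterations per start.
#' @return A `codon_model_fit` with the ML parameters, log-likelihood,
#'   per-edge table, convergence flag and optimizer trace.
#' @export
fit_branch_model <- function(tree, alignment, model = c("C", "A", "B", "D"),
                             freq_model = c("f3x4", "f61"), init = NULL,
                             n_starts = 3L, iter_max = 200L) {
  model <- match.arg(model)
  setup <- .lik_setup(tree, alignment)
  pi <- codon_frequencies(alignment, match.arg(freq_model))
  mc <- .model_classes(setup, model)
  if (inherits(init, "codon_model_fit")) {
    init <- .warm_init(init, mc$idx, mc$names)
  } else if (is.null(init)) {
    init <- list(branch_lengths = .init_branch_lengths(setup, alignment),
                 kappa = 2, omega = rep(0.2, length(mc$names)))
  }
  if (length(init$omega) == 1L)
    init$omega <- rep(init$omega, length(mc$names))
  .fit_generic_branch(setup, mc$idx, mc$names, pi, init,
                      n_starts, iter_max, model)
}

#' Likelihood-ratio test between nested codon-model fits
#'
#' @param fit_null,fit_alt `codon_model_fit` objects for nested models
#'   (branch models follow the chain A within B within C within D; a
#'   regrouped 3-class fit nests model A; site model M7 nests in M8).
#' @return List of class `lrt_result` with `statistic` (`-2 dlnL`, clamped
#'   at 0), `df` and `p_value` from the chi-square upper tail.
#' @export
likelihood_ratio_test <- function(fit_null, fit_alt) {
  rank <- c(A = 1, B = 2, C = 3, D = 4, M7 = 1, M8 = 2, regroup = 3)
  bm_pair <- fit_null$model %in% c("A", "B", "C", "D") &&
    fit_alt$model %in% c("A", "B", "C", "D", "regroup")
  site_pair <- fit_null$model == "M7" && fit_alt$model == "M8"
  ok <- (bm_pair || site_pair) && rank[fit_null$model] < rank[fit_alt$model]
  if (!ok || fit_alt$model == "regroup" && fit_null$model != "A")
    stop("models '", fit_null$model, "' and '", fit_alt$model,
         "' are not a nested null/alternative pair")
  df <- fit_alt$n_free_params - fit_null$n_free_params
  if (df <= 0L) stop("alternative model has no extra free parameters")
  stat <- max(0, 2 * (fit_alt$loglik - fit_null$loglik))
  structure(
    list(statistic = stat, df = df,
         p_value = stats::pchisq(stat, df, lower.tail = FALSE),
         null_model = fit_null$model, alt_model = fit_alt$model),
    class = "lrt_result"
  )
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT %s vs %s: -2dlnL = %.2f, df = %d, P = %.4g\n",
              x$null_model, x$alt_model, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Re-class a focal branch with alternative partners and refit
#'
#' For each partner set, the external branch of `focal_species` is grouped
#' with the partners' external branches into one dN/dS class, all remaining
#' external branches form a second class, and internal branches a third; the
#' 3-class model is refit and tested against the single-ratio model A.
#'
#' @inheritParams fit_branch_model
#' @param focal_species tip whose branch is re-classed.
#' @param partner_sets list of character vectors of partner tips; default:
#'   all singletons and pairs of subsocial tips other than the focal.
#' @param fit_a optional pre-computed model-A fit (computed if missing).
#' @return List with `fits` and a `table` data frame (partners, lnL, the
#'   three omega estimates, LRT statistic and p-value vs model A).
#' @export
regroup_branch_test <- function(tree, alignment, focal_species,
                                partner_sets = NULL, fit_a = NULL,
                                freq_model = c("f3x4", "f61"),
                                n_starts = 1L, iter_max = 200L) {
  setup <- .lik_setup(tree, alignment)
  if (!focal_species %in% setup$phy$tip.label)
    stop("focal species '", focal_species, "' is not a tip of the tree")
  if (is.null(partner_sets)) {
    subsoc <- names(tree$labels)[tree$labels == "subsocial"]
    subsoc <- setdiff(subsoc, focal_species)
    partner_sets <- c(as.list(subsoc),
                      utils::combn(subsoc, 2L, simplify = FALSE))
  }
  freq_model <- match.arg(freq_model)
  pi <- codon_frequencies(alignment, freq_model)
  if (is.null(fit_a))
    fit_a <- fit_branch_model(tree, alignment, "A", freq_model = freq_model,
                              n_starts = n_starts, iter_max = iter_max)
  tip_of_edge <- ifelse(setup$edge[, 2] <= setup$ntip,
                        setup$phy$tip.label[setup$edge[, 2]], NA)
  fits <- list()
  rows <- list()
  for (i in seq_along(partner_sets)) {
    grp <- c(focal_species, partner_sets[[i]])
    idx <- ifelse(setup$classes == "internal", 1L,
                  ifelse(tip_of_edge %in% grp, 2L, 3L))
    nm <- c("internal", "focal_group", "other_external")
    fit <- .fit_generic_branch(
      setup, as.integer(idx), nm, pi,
      .warm_init(fit_a, as.integer(idx), nm),
      n_starts, iter_max, "regroup"
    )
    lrt <- likelihood_ratio_test(fit_a, fit)
    fits[[i]] <- fit
    rows[[i]] <- data.frame(
      partners = paste(partner_sets[[i]], collapse = "+"),
      loglik = fit$loglik,
      omega_internal = fit$omega_by_class["internal"],
      omega_focal_group = fit$omega_by_class["focal_group"],
      omega_other = fit$omega_by_class["other_external"],
      lrt_stat = lrt$statistic, df = lrt$df, p_value = lrt$p_value,
      row.names = NULL
    )
  }
  list(fit_a = fit_a, fits = fits, table = do.call(rbind, rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
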