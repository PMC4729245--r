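# Orchestration: the full comparative analysis on one alignment + labeled
# tree, in the study's stage order (codon usage, positive-selection screen,
# branch models, regrouping, dating), with every stage's output collected
# into one machine-readable bundle and optional TSV reports.

.stars <- function(p) {
  ifelse(p < 0.01, "P < 0.01", ifelse(p < 0.05, "P < 0.05", "NS"))
}

#' Render the branch-model comparison table
#'
#' Formats the four branch-model fits and their pairwise likelihood-ratio
#' tests as the familiar model-comparison table: one row per model with
#' -lnL (6 decimals), the dN/dS estimates by class (4 decimals; one entry
#' per external species for the unconstrained model) and the LRTs against
#' every poorer nested model, annotated at the 0.05/0.01 levels with no
#' multiple-testing correction.
#'
#' @param fits named list of `codon_model_fit` objects for models
#'   `A`, `B`, `C`, `D` (missing entries yield a placeholder row with a
#'   warning).
#' @param lrts named list of `lrt_result` objects keyed like `"A_vs_C"`
#'   (computed from `fits` when `NULL`).
#' @return Data frame with columns `model`, `minus_lnL`, `dn_ds`, `lrt`.
#' @export
render_table1 <- function(fits, lrts = NULL) {
  order <- c("A", "B", "C", "D")
  pairs <- list(B = "A", C = c("A", "B"), D = c("A", "B", "C"))
  if (is.null(lrts)) {
    lrts <- list()
    for (alt in names(pairs)) {
      for (null in pairs[[alt]]) {
        if (!is.null(fits[[null]]) && !is.null(fits[[alt]]))
          lrts[[paste0(null, "_vs_", alt)]] <-
            likelihood_ratio_test(fits[[null]], fits[[alt]])
      }
    }
  }
  rows <- lapply(order, function(m) {
    fit <- fits[[m]]
    if (is.null(fit)) {
      warning("no fit for model ", m, "; placeholder row emitted")
      return(data.frame(model = m, minus_lnL = NA_character_,
                        dn_ds = "(missing)", lrt = ""))
    }
    om <- fit$omega_by_class
    dn_ds <- if (length(om) == 1L) {
      sprintf("%.4f", om)
    } else {
      paste(sprintf("%.4f (%s)", om, names(om)), collapse = " ")
    }
    lrt_txt <- ""
    if (m %in% names(pairs)) {
      keys <- paste0(pairs[[m]], "_vs_", m)
      keys <- keys[keys %in% names(lrts)]
      lrt_txt <- paste(vapply(keys, function(k) {
        l <- lrts[[k]]
        sprintf("%s vs. %s: %.2f %s", l$null_model, l$alt_model,
                l$statistic, .stars(l$p_value))
      }, character(1)), collapse = " ")
    }
    data.frame(model = m, minus_lnL = sprintf("%.6f", -fit$loglik),
               dn_ds = dn_ds, lrt = lrt_txt)
  })
  out <- do.call(rbind, rows)
  attr(out, "lrts") <- lrts
  out
}

.as_alignment <- function(x) {
  if (inherits(x, "codon_alignment")) x else read_codon_alignment(x)
}

#' Run the full comparative selection-effectiveness analysis
#'
#' Executes, in order: input validation; per-species ENC with codon-column
#' bootstrap confidence intervals and the social-vs-subsocial permutation
#' test, plus base composition by codon position; the M7-vs-M8 site-model
#' screen for positive selection (a warning is raised if the screen
#' rejects); the four branch-class dN/dS models with all nested
#' likelihood-ratio tests; the focal-taxon regrouping test; and
#' Nei-Gojobori synonymous distances with strict-clock node dating.
#'
#' @param alignment a [codon_alignment()] or FASTA path.
#' @param tree a [labeled_tree()] or Newick path.
#' @param labels named species -> social/subsocial vector or label-file path
#'   (required when `tree` is a path).
#' @param out_dir optional directory for TSV/JSON reports and the run log.
#' @param n_boot,n_perm bootstrap and permutation replicate counts.
#' @param seed RNG seed governing every resampling stream.
#' @param mu mutation rate per site per generation for dating.
#' @param generation_time years per generation.
#' @param plain_f use the plain ENC homozygosity estimator.
#' @param freq_model codon frequency model for all ML fits.
#' @param ncat site-model discretization categories.
#' @param focal_species tip for the regrouping test (default: the social
#'   tip with the highest unconstrained-model dN/dS).
#' @param partner_sets partner sets for the regrouping test (default: all
#'   subsocial singletons and pairs; see [regroup_branch_test()]).
#' @param n_starts,iter_max optimizer settings forwarded to the fits.
#' @param verbose print stage progress.
#' @return List of class `socialsel_run` with all stage results.
#' @export
run_full_analysis <- function(alignment, tree, labels = NULL,
                              out_dir = NULL, n_boot = 1000L,
                              n_perm = 1000L, seed = 1L, mu = 8.4e-8,
                              generation_time = 1, plain_f = FALSE,
                              freq_model = c("f3x4", "f61"), ncat = 10L,
                              focal_species = NULL, partner_sets = NULL,
                              n_starts = 1L, iter_max = 200L,
                              verbose = TRUE) {
  freq_model <- match.arg(freq_model)
  t0 <- Sys.time()
  log_lines <- character(0)
  say <- function(...) {
    line <- sprintf("[%5.1fs] %s", as.numeric(Sys.time() - t0, units = "secs"),
                    sprintf(...))
    if (verbose) message(line)
    log_lines <<- c(log_lines, line)
  }

  say("validate: loading inputs (seed = %d)", seed)
  if (is.character(labels) && is.null(names(labels)))
    labels <- read_mating_labels(labels)
  alignment <- .as_alignment(alignment)
  if (is.character(tree)) tree <- read_labeled_tree(tree, labels)
  if (is.null(labels)) labels <- tree$labels
  stopifnot(inherits(tree, "labeled_tree"))
  if (!setequal(tree$phy$tip.label, alignment$taxa))
    stop("stage validate: tree tips and alignment taxa differ")

  say("codon usage: ENC, bootstrap (n = %d), permutation (n = %d)",
      n_boot, n_perm)
  enc_rep <- enc_report(alignment, labels, n_boot = n_boot, n_perm = n_perm,
                        seed = seed, plain_f = plain_f)
  base_comp <- base_composition(alignment)

  say("site models: fitting shared branch lengths (model A)")
  fit_a <- fit_branch_model(tree, alignment, "A", freq_model = freq_model,
                            n_starts = n_starts, iter_max = iter_max)
  say("site models: M7 and M8 (%d categories)", ncat)
  fit_m7 <- fit_site_model(tree, alignment, "M7", ncat = ncat,
                           freq_model = freq_model, bl_fit = fit_a)
  fit_m8 <- fit_site_model(tree, alignment, "M8", ncat = ncat,
                           freq_model = freq_model, bl_fit = fit_a,
                           m7_fit = fit_m7)
  lrt_sites <- likelihood_ratio_test(fit_m7, fit_m8)
  if (lrt_sites$p_value < 0.05)
    warning(sprintf(
      "site-model screen suggests sites under positive selection (M7 vs M8: %.2f, P = %.3g)",
      lrt_sites$statistic, lrt_sites$p_value))

  say("branch models: B, C, D (warm-started from A)")
  fit_b <- fit_branch_model(tree, alignment, "B", freq_model = freq_model,
                            init = fit_a, n_starts = n_starts,
                            iter_max = iter_max)
  fit_c <- fit_branch_model(tree, alignment, "C", freq_model = freq_model,
                            init = fit_b, n_starts = n_starts,
                            iter_max = iter_max)
  fit_d <- fit_branch_model(tree, alignment, "D", freq_model = freq_model,
                            init = fit_c, n_starts = n_starts,
                            iter_max = iter_max)
  fits <- list(A = fit_a, B = fit_b, C = fit_c, D = fit_d)
  table1 <- render_table1(fits)
  lrts <- attr(table1, "lrts")

  if (is.null(focal_species)) {
    d_ext <- fit_d$omega_by_class[names(fit_d$omega_by_class) != "internal"]
    social_tips <- names(tree$labels)[tree$labels == "social"]
    cand <- d_ext[names(d_ext) %in% social_tips]
    focal_species <- names(cand)[which.max(cand)]
  }
  say("regrouping test: focal taxon %s", focal_species)
  regroup <- regroup_branch_test(tree, alignment, focal_species,
                                 partner_sets = partner_sets, fit_a = fit_a,
                                 freq_model = freq_model,
                                 n_starts = n_starts, iter_max = iter_max)

  say("dating: NG86 distances and strict-clock node ages (mu = %g)", mu)
  ds <- ds_matrix(alignment)
  dating <- date_nodes(node_mean_ds(tree, ds), mu = mu,
                       generation_time = generation_time)

  say("done")
  run <- structure(
    list(enc = enc_rep, base_composition = base_comp,
         site_fits = list(M7 = fit_m7, M8 = fit_m8),
         site_lrt = lrt_sites, fits = fits, lrts = lrts, table1 = table1,
         regroup = regroup, ds_matrix = ds, dating = dating,
         config = list(n_boot = n_boot, n_perm = n_perm, seed = seed,
                       mu = mu, generation_time = generation_time,
                       plain_f = plain_f, freq_model = freq_model,
                       ncat = ncat, focal_species = focal_species,
                       n_starts = n_starts, iter_max = iter_max),
         log = log_lines),
    class = "socialsel_run"
  )
  if (!is.null(out_dir)) write_run_reports(run, out_dir)
  run
}

#' Run the full analysis from a YAML configuration file
#'
#' The YAML file holds any arguments of [run_full_analysis()] by name, e.g.
#' `alignment`, `tree`, `labels` (file paths), `out_dir`, `n_boot`,
#' `n_perm`, `seed`, `mu`, `generation_time`. Relative paths are resolved
#' against the config file's directory.
#'
#' @param path YAML config file.
#' @return The `socialsel_run` result.
#' @export
run_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- names(formals(run_full_analysis))
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  base <- dirname(normalizePath(path))
  for (f in c("alignment", "tree", "labels", "out_dir")) {
    if (!is.null(cfg[[f]]) && is.character(cfg[[f]]) &&
        !startsWith(cfg[[f]], "/"))
      cfg[[f]] <- file.path(base, cfg[[f]])
  }
  do.call(run_full_analysis, cfg)
}

#' Write the report bundle of a full analysis run
#'
#' Emits six TSV reports (ENC, base composition, site models, branch
#' models, regrouping, node dating), a machine-readable `bundle.json` from
#' which every rendered number is re-derivable, and the run log.
#'
#' @param run a `socialsel_run` from [run_full_analysis()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run_reports <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(d, f) utils::write.table(
    d, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE
  )
  enc <- run$enc
  tsv(rbind(
    data.frame(row = "species", id = names(enc$per_species_enc),
               value = sprintf("%.4f", enc$per_species_enc),
               lower = "", upper = ""),
    data.frame(row = "group_mean", id = names(enc$group_means),
               value = sprintf("%.4f", enc$group_means),
               lower = sprintf("%.4f", enc$group_ci[, "lower"]),
               upper = sprintf("%.4f", enc$group_ci[, "upper"])),
    data.frame(row = "permutation", id = enc$permutation$mode,
               value = sprintf("%.4f", enc$permutation$observed),
               lower = sprintf("p=%.4g", enc$permutation$p_value),
               upper = sprintf("seed=%d", enc$seed))
  ), "enc_report.tsv")

  bc <- run$base_composition
  bc_df <- do.call(rbind, lapply(dimnames(bc)[[1]], function(sp) {
    data.frame(species = sp, position = rep(1:3, each = 4),
               nucleotide = rep(dimnames(bc)[[3]], 3),
               frequency = as.vector(t(bc[sp, , ])))
  }))
  tsv(bc_df, "base_composition.tsv")

  sf <- run$site_fits
  tsv(data.frame(
    model = c("M7", "M8"),
    lnL = c(sf$M7$loglik, sf$M8$loglik),
    kappa = c(sf$M7$kappa, sf$M8$kappa),
    p = c(sf$M7$site_params$p, sf$M8$site_params$p),
    q = c(sf$M7$site_params$q, sf$M8$site_params$q),
    p0 = c(NA, sf$M8$site_params$p0),
    omega_s = c(NA, sf$M8$site_params$omega_s),
    lrt = c(NA, run$site_lrt$statistic),
    p_value = c(NA, run$site_lrt$p_value)
  ), "site_models.tsv")

  tsv(run$table1, "branch_models.tsv")
  tsv(run$regroup$table, "regroup.tsv")
  tsv(run$dating, "node_dating.tsv")

  bundle <- list(
    config = run$config,
    enc = list(per_species = as.list(enc$per_species_enc),
               group_means = as.list(enc$group_means),
               group_ci = list(social = unname(enc$group_ci["social", ]),
                               subsocial = unname(enc$group_ci["subsocial", ])),
               permutation = run$enc$permutation[
                 c("observed", "p_value", "mode", "n_perm", "seed")]),
    site_models = list(
      M7 = c(list(loglik = sf$M7$loglik), sf$M7$site_params),
      M8 = c(list(loglik = sf$M8$loglik), sf$M8$site_params),
      lrt = run$site_lrt[c("statistic", "df", "p_value")]
    ),
    branch_models = lapply(run$fits, function(f)
      list(loglik = f$loglik, kappa = f$kappa,
           omega = as.list(f$omega_by_class),
           n_free_params = f$n_free_params, converged = f$converged)),
    lrts = lapply(run$lrts, function(l)
      l[c("statistic", "df", "p_value", "null_model", "alt_model")]),
    regroup = run$regroup$table,
    dating = run$dating
  )
  jsonlite::write_json(bundle, file.path(out_dir, "bundle.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  writeLines(run$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.socialsel_run <- function(x, ...) {
  cat("Full selection-effectiveness analysis\n\n")
  print(x$enc)
  cat(sprintf("\nsite screen M7 vs M8: %.2f (df %d), P = %.3g\n",
              x$site_lrt$statistic, x$site_lrt$df, x$site_lrt$p_value))
  cat("\nbranch models:\n")
  print(x$table1, row.names = FALSE)
  cat(sprintf("\nroot age: %.2f My (mu = %g)\n",
              x$dating$age_my[1], x$config$mu))
  invisible(x)
}
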