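#' Orchestrated analyses: fit, null test, reconciliation
#'
#' High-level drivers that run the full pipeline from a configuration
#' (an R list or a YAML file; see [read_run_config()]) and optionally
#' write reports into an output directory along with a reproducibility
#' manifest ([write_manifest()]). They are thin layers over
#' [fit_bd()], [run_null_test()] and [lca_reconcile()]; use those
#' directly for interactive work.
#'
#' Recognised configuration fields: `tree` (Newick path), `counts`
#' (TSV path), `focal_taxa` (character vector), `include_stem`
#' (default `TRUE`), `models` (default the four nested structures),
#' `gene_trees` (named list of Newick strings/paths, per family),
#' `observed` (named list of `c(D, L, k)` per family, overrides
#' reconciliation), `N` (replicates, default 1000), `alpha` (default
#' 0.05), `seed` (default 1), `n_starts`, `out_dir`.
#'
#' @param config A list or path to a YAML file.
#' @return [run_fit_analysis()]: a tibble in model-comparison-table
#'   layout (rates scaled by 1000 for display, `-lnL`, parameter
#'   counts, LR against the previous nested model, chi-square p, fold
#'   change, AIC). [run_null_analysis()]: a tibble with one row per
#'   family (observed D, L, k and empirical p-values), with the
#'   `null_distribution` objects in attribute `"details"`.
#'   [run_reconciliation()]: a tibble of per-family event totals with
#'   reconciliations in attribute `"details"`.
#' @export
run_fit_analysis <- function(config) {
  cfg <- read_run_config(config)
  tree <- read_chronogram(cfg$tree)
  counts <- read_counts(cfg$counts, tree = tree)
  branches <- focal_branches(cfg, tree)
  models <- cfg$models %||% c("single_lambda", "multi_lambda",
                              "single_lambda_mu", "multi_lambda_mu")
  report <- purrr::map_dfr(counts$family, function(fam) {
    fits <- purrr::map(models, function(mod) {
      fit_bd(counts[counts$family == fam, ], tree, model = mod,
             branches = if (grepl("^multi", mod)) branches else NULL,
             n_starts = cfg$n_starts %||% 5,
             seed = derive_seed(cfg$seed %||% 1, paste0("fit:", fam, mod)))
    })
    fit_report(setNames(fits, models), family = fam)
  })
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(report, file.path(cfg$out_dir, "fit_report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(report, file.path(cfg$out_dir, "fit_report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    write_manifest(cfg$out_dir, cfg)
  }
  report
}

#' Model-comparison table from a set of fits
#'
#' Arranges fitted models for one family into the conventional
#' reporting layout: rates multiplied by 1000 for display, `-lnL`,
#' parameter count, AIC, and — for each model nested in the previous
#' row — the LR statistic, its chi-square p-value (df = difference in
#' parameter count) and the focal/background fold change.
#'
#' @param fits Named list of `bd_fit` objects, ordered null first.
#' @param family Family label for the output.
#' @return A tibble, one row per model.
#' @export
fit_report <- function(fits, family = "family") {
  stopifnot(length(fits) >= 1)
  rows <- purrr::imap_dfr(fits, function(f, name) {
    lam <- f$params$lambda
    mu <- f$params$mu
    tibble::tibble(
      family = family, model = name,
      lambda_bg_x1000 = lam[1] * 1000,
      lambda_focal_x1000 = if (length(lam) > 1) lam[2] * 1000 else NA_real_,
      mu_bg_x1000 = if (f$params$tied) NA_real_ else mu[1] * 1000,
      mu_focal_x1000 = if (!f$params$tied && length(mu) > 1) mu[2] * 1000
                       else NA_real_,
      minus_lnL = -f$lnL, n_params = f$n_params,
      AIC = aic_score(f$lnL, f$n_params),
      fold_lambda = if (length(lam) > 1) round(fold_change(lam[2], lam[1]), 2)
                    else NA_real_
    )
  })
  rows$LR <- NA_real_
  rows$df <- NA_integer_
  rows$p_chisq <- NA_real_
  for (i in seq_along(fits)[-1]) {
    if (fits[[i]]$n_params > fits[[i - 1]]$n_params) {
      lt <- lr_test(fits[[i - 1]], fits[[i]])
      rows$LR[i] <- round(lt$lr, 2)
      rows$df[i] <- lt$df
      rows$p_chisq[i] <- round(lt$p_chisq, 3)
    }
  }
  rows
}

#' @rdname run_fit_analysis
#' @export
run_null_analysis <- function(config) {
  cfg <- read_run_config(config)
  tree <- read_chronogram(cfg$tree)
  counts <- read_counts(cfg$counts, tree = tree)
  branches <- focal_branches(cfg, tree)
  alpha <- cfg$alpha %||% 0.05
  N <- cfg$N %||% 1000
  seed <- cfg$seed %||% 1

  fams <- counts$family
  details <- list()
  report <- purrr::map_dfr(fams, function(fam) {
    obs <- if (!is.null(cfg$observed[[fam]])) {
      as.list(cfg$observed[[fam]])
    } else if (!is.null(cfg$gene_trees[[fam]])) {
      rec <- lca_reconcile(read_gene_tree(cfg$gene_trees[[fam]]), tree)
      as.list(clade_summary(rec, branches))
    } else {
      abort(paste0("no observed statistics or gene tree for family ", fam))
    }
    fit <- fit_bd(counts[counts$family == fam, ], tree,
                  model = "single_lambda",
                  seed = derive_seed(seed, paste0("nullfit:", fam)))
    nd <- run_null_test(tree, fit$params$lambda, fit$params$mu, branches,
                        observed = obs, N = N,
                        seed = derive_seed(seed, paste0("null:", fam)))
    details[[fam]] <<- nd
    g <- glance(nd)
    g$family <- fam
    g$lambda_null <- fit$params$lambda
    g$significant_k <- g$p_k_upper <= alpha
    g
  })
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(
      purrr::map_dfr(details, tidy, .id = "family"),
      file.path(cfg$out_dir, "null_replicates.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(report, file.path(cfg$out_dir, "null_report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    for (fam in names(details)) {
      ggplot2::ggsave(file.path(cfg$out_dir, paste0("null_", fam, ".png")),
                      autoplot(details[[fam]]), width = 9, height = 3.2,
                      dpi = 150)
    }
    write_manifest(cfg$out_dir, cfg)
  }
  attr(report, "details") <- details
  report
}

#' @rdname run_fit_analysis
#' @export
run_reconciliation <- function(config) {
  cfg <- read_run_config(config)
  tree <- read_chronogram(cfg$tree)
  if (is.null(cfg$gene_trees)) abort("`gene_trees` must be provided")
  branches <- tryCatch(focal_branches(cfg, tree), error = function(e) NULL)
  details <- purrr::map(cfg$gene_trees,
                        function(g) lca_reconcile(read_gene_tree(g), tree))
  report <- purrr::imap_dfr(details, function(rec, fam) {
    out <- glance(rec)
    out$family <- fam
    if (!is.null(branches)) {
      cs <- clade_summary(rec, branches)
      out$clade_D <- cs$D; out$clade_L <- cs$L; out$clade_k <- cs$k
    }
    out
  })
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(
      purrr::map_dfr(details, tidy, .id = "family"),
      file.path(cfg$out_dir, "reconciliation_branches.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(report,
                         file.path(cfg$out_dir, "reconciliation.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    write_manifest(cfg$out_dir, cfg)
  }
  attr(report, "details") <- details
  report
}

#' @rdname run_fit_analysis
#' @export
read_run_config <- function(config) {
  cfg <- if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    yaml::read_yaml(config)
  } else if (is.list(config)) {
    config
  } else {
    abort("`config` must be a list or a YAML file path")
  }
  if (!is.null(cfg$alpha) && (cfg$alpha <= 0 || cfg$alpha >= 1)) {
    abort("`alpha` must lie in (0, 1)")
  }
  if (!is.null(cfg$N) && cfg$N < 100) abort("`N` must be at least 100")
  for (f in c("tree", "counts")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      abort(paste0("configured ", f, " file not found: ", cfg[[f]]))
    }
  }
  cfg
}

focal_branches <- function(cfg, tree) {
  if (is.null(cfg$focal_taxa)) abort("`focal_taxa` must be configured")
  mrca_branches(tree, cfg$focal_taxa,
                include_stem = cfg$include_stem %||% TRUE)
}

#' @rdname run_fit_analysis
#' @param out_dir Output directory.
#' @param cfg A validated configuration list.
#' @export
write_manifest <- function(out_dir, cfg) {
  inputs <- purrr::compact(cfg[c("tree", "counts")])
  manifest <- list(
    package = "famshift",
    version = as.character(utils::packageVersion("famshift")),
    config = cfg[setdiff(names(cfg), "out_dir")],
    input_md5 = as.list(tools::md5sum(unlist(inputs)))
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yml"))
  invisible(manifest)
}
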