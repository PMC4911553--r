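#' Run the full multi-environment analysis pipeline
#'
#' Drives all stages for one trait: per-site mixed models (variance
#' components, heritability), the factor-analytic combined analysis
#' (between-site genetic variances/correlations and biplot coordinates),
#' and the requested prediction schemes for each requested model; writes
#' every result table as delimited text into `out_dir`. All randomness is
#' driven by per-stage seeds derived from the master seed, so identical
#' configurations give identical outputs.
#'
#' @param data a `"met_data"` bundle, from [simulate_met()] or
#'   [read_met_inputs()].
#' @param models character vector of [rnm_models()] names.
#' @param schemes subset of `c("CV1", "CV2", "pairwise", "loso")`.
#' @param out_dir output directory; created if needed.
#' @param n_replicates random partitions for CV1/CV2.
#' @param control an [mcmc_control()]; its seed is overridden by the
#'   derived stage seed.
#' @param seed master seed.
#' @param trait response column (default `"y"`).
#' @return list with `site_summary`, `fa`, `correlations`, `biplot`,
#'   `accuracy` (long/wide/best), invisibly; side effect: files in
#'   `out_dir`.
#' @export
run_pipeline <- function(data, models = c("E+W+G", "E+W+G+A"),
                         schemes = c("CV1", "CV2"), out_dir = tempfile("met"),
                         n_replicates = 10, control = mcmc_control(),
                         seed = 1, trait = "y") {
  stopifnot(length(models) >= 1, length(schemes) >= 1)
  bad <- setdiff(models, rnm_models())
  if (length(bad)) stop("unknown model(s): ", paste(bad, collapse = ", "))
  needs_g <- any(grepl("G", models))
  if (needs_g && is.null(data$markers)) {
    stop("models ", paste(grep("G", models, value = TRUE), collapse = ", "),
         " need a marker matrix, none supplied")
  }
  if (any(grepl("A", models)) && is.null(data$pedigree)) {
    stop("models with a pedigree term need a pedigree, none supplied")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_seeds <- .with_seed(seed, sample.int(.Machine$integer.max - 1L, 4L))

  t0 <- proc.time()[3]
  say <- function(...) message(sprintf("[%6.1fs] ", proc.time()[3] - t0), ...)

  say("stage 1: per-site mixed models")
  ss <- fit_all_sites(data$pheno, trait = trait)
  .write_delim(ss$summary, file.path(out_dir, "site_summary.csv"))

  fa <- NULL
  if (!is.null(data$markers)) {
    say("stage 2: factor-analytic combined analysis")
    G <- genomic_relationship(data$markers)
    fa <- fit_factor_analytic(data$pheno, G, trait = trait)
    gc_tab <- genetic_correlations(fa)
    .write_delim(data.frame(site = rownames(gc_tab), gc_tab,
                            check.names = FALSE),
                 file.path(out_dir, "genetic_correlations.csv"))
    bp <- biplot_coordinates(fa)
    .write_delim(data.frame(site = rownames(bp$sites), bp$sites),
                 file.path(out_dir, "biplot_sites.csv"))
    .write_delim(data.frame(line = rownames(bp$scores), bp$scores),
                 file.path(out_dir, "biplot_scores.csv"))
  }

  say("stage 3: prediction schemes")
  reports <- list()
  for (sc in schemes) {
    plan <- make_cv_plan(sc, data$pheno, n_replicates = n_replicates,
                         seed = stage_seeds[3])
    for (md in models) {
      say("  scheme ", sc, ", model ", md)
      ctl <- control
      ctl$seed <- stage_seeds[4]
      reports[[paste(sc, md)]] <- run_scheme(md, data, plan, control = ctl)
    }
  }
  acc <- summarize_reports(reports)
  .write_delim(acc$long, file.path(out_dir, "accuracy_long.csv"))
  for (sc in names(acc$wide)) {
    .write_delim(data.frame(site = rownames(acc$wide[[sc]]),
                            acc$wide[[sc]], check.names = FALSE),
                 file.path(out_dir, paste0("accuracy_wide_", sc, ".csv")))
  }
  .write_delim(acc$best, file.path(out_dir, "best_models.csv"))
  say("done; outputs in ", out_dir)

  invisible(list(site_summary = ss$summary, fa = fa,
                 correlations = if (!is.null(fa)) genetic_correlations(fa),
                 biplot = if (!is.null(fa)) biplot_coordinates(fa),
                 accuracy = acc, out_dir = out_dir))
}
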