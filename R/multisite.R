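#' Single-site mixed-model analysis
#'
#' Fits, for one site, a mixed linear model with random accession and block
#' effects and a fixed entry-group effect separating checks from accessions
#' (each check gets its own fixed level, so check effects are estimated
#' separately from the G-indexed random accessions). Returns REML variance
#' components, accession BLUPs, and line-mean broad-sense heritability
#' \deqn{H^2 = \sigma^2_L / (\sigma^2_L + \sigma^2_\varepsilon / \bar r)}
#' with \eqn{\bar r} the mean replication of accessions in the site — the
#' p-rep-aware effective replication.
#'
#' @param pheno plot-level phenotype table (`site`, `line`, `block`,
#'   `check`, response).
#' @param site site identifier to analyze.
#' @param trait name of the response column (default `"y"`).
#' @return object of class `"site_fit"`: variance components, `H2`, line
#'   BLUPs, check effects, mean replication and the underlying `lme4` fit.
#' @export
fit_single_site <- function(pheno, site, trait = "y") {
  d <- as.data.frame(pheno)
  d <- d[as.character(d$site) == site, , drop = FALSE]
  if (!nrow(d)) stop("no records for site ", site)
  if (!trait %in% names(d)) stop("no trait column '", trait, "'")
  d$..y <- d[[trait]]
  d <- d[is.finite(d$..y), , drop = FALSE]
  if (!"check" %in% names(d)) d$check <- FALSE
  if (length(unique(d$block)) < 2L) {
    stop("site ", site, " has fewer than 2 blocks; cannot separate block ",
         "and residual variance")
  }
  ## fixed entry group: pooled accessions vs each check; random accession
  ## effect uses a single dummy level for all check plots
  d$entry <- ifelse(d$check, as.character(d$line), "accession")
  d$line_r <- ifelse(d$check, ".checks", as.character(d$line))
  d$entry <- factor(d$entry)
  d$block <- factor(d$block)
  d$line_r <- factor(d$line_r)

  fit <- lme4::lmer(..y ~ 0 + entry + (1 | line_r) + (1 | block), data = d,
                    REML = TRUE,
                    control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                                calc.derivs = FALSE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2 <- stats::setNames(vc$vcov, vc$grp)
  sigma2_L <- unname(s2["line_r"])
  sigma2_B <- unname(s2["block"])
  sigma2_e <- unname(s2["Residual"])
  acc <- d[!d$check, , drop = FALSE]
  r_bar <- mean(table(acc$line))
  H2 <- sigma2_L / (sigma2_L + sigma2_e / r_bar)

  re <- lme4::ranef(fit)$line_r
  blups <- stats::setNames(re[[1]], rownames(re))
  blups <- blups[names(blups) != ".checks"]
  fe <- lme4::fixef(fit)
  structure(list(site = site, trait = trait,
                 variance_components = c(line = sigma2_L, block = sigma2_B,
                                         residual = sigma2_e),
                 H2 = H2, r_bar = r_bar, blups = blups,
                 group_effects = fe, n_plots = nrow(d), fit = fit),
            class = "site_fit")
}

#' @export
print.site_fit <- function(x, ...) {
  cat("Site", x$site, "-", x$n_plots, "plots, mean replication",
      round(x$r_bar, 2), "\n")
  vc <- x$variance_components
  cat(sprintf("  var(line) = %.4g  var(block) = %.4g  var(resid) = %.4g\n",
              vc["line"], vc["block"], vc["residual"]))
  cat(sprintf("  broad-sense H2 (line-mean) = %.3f\n", x$H2))
  invisible(x)
}

#' Per-site analyses for every site of a trial
#'
#' @param pheno plot-level phenotype table.
#' @param trait response column name.
#' @return named list of [fit_single_site()] results plus a `summary`
#'   data frame (variance components and H2 per site).
#' @export
fit_all_sites <- function(pheno, trait = "y") {
  sites <- unique(as.character(pheno$site))
  fits <- lapply(sites, function(s) fit_single_site(pheno, s, trait))
  names(fits) <- sites
  smry <- do.call(rbind, lapply(fits, function(f) {
    data.frame(site = f$site, H2 = f$H2, r_bar = f$r_bar,
               var_line = f$variance_components["line"],
               var_block = f$variance_components["block"],
               var_residual = f$variance_components["residual"],
               row.names = NULL)
  }))
  list(fits = fits, summary = smry)
}
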