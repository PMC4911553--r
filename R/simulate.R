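## Synthetic multi-environment trial generator.  All operations are pure
## functions of their arguments including the seed: the caller's RNG state is
## saved and restored around every draw.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration of a simulated multi-environment trial
#'
#' Captures the trial dimensions, the partially replicated (p-rep) design
#' fractions, and the generative variance components of the full
#' reaction-norm model (site, covariable regression, genomic, pedigree, the
#' two Hadamard interactions, and residual).
#'
#' Defaults emulate a 803-line, 5-site spring wheat trial genotyped on a
#' DArTseq-scale panel: 81% of accessions appear once per site, 15% twice,
#' 4% three times, 6% of plots carry one of 3 repeated checks, and five
#' temperature covariables describe the sites. The default variance
#' components put the between-site genetic correlation
#' \eqn{(\sigma^2_g+\sigma^2_a)/(\sigma^2_g+\sigma^2_a+\sigma^2_{gE}+\sigma^2_{aE})}
#' near 0.65, in line with grain-yield trials across temperate sites.
#'
#' @param n_lines,n_markers,n_sites,n_covariables,n_checks trial dimensions.
#' @param prep_fractions length-3 proportions of accessions replicated
#'   once / twice / three-plus times per site; must sum to 1.
#' @param check_plot_fraction proportion of plots occupied by checks.
#' @param variance_components named non-negative numeric; recognized names
#'   `E`, `L`, `w`, `g`, `a`, `gE`, `aE`, `eps` (unnamed terms default to 0).
#' @param mu grand mean of the trait (default 6, a grain-yield scale in
#'   t/ha).
#' @param seed master seed; per-stage seeds are derived from it.
#' @return object of class `"sim_config"`.
#' @export
sim_config <- function(n_lines = 803, n_markers = 2000, n_sites = 5,
                       n_covariables = 5, n_checks = 3,
                       prep_fractions = c(0.81, 0.15, 0.04),
                       check_plot_fraction = 0.06,
                       variance_components = c(E = 2, w = 0.5, g = 0.8,
                                               a = 0.4, gE = 0.45, aE = 0.2,
                                               eps = 1),
                       mu = 6, seed = 1) {
  stopifnot(n_lines >= 2, n_markers >= 1, n_sites >= 2, n_covariables >= 1,
            n_checks >= 0)
  if (abs(sum(prep_fractions) - 1) > 1e-8) {
    stop("prep_fractions must sum to 1 (got ", sum(prep_fractions), ")")
  }
  if (any(prep_fractions < 0)) stop("prep_fractions must be non-negative")
  if (check_plot_fraction < 0 || check_plot_fraction >= 1) {
    stop("check_plot_fraction must be in [0, 1)")
  }
  vc <- c(E = 0, L = 0, w = 0, g = 0, a = 0, gE = 0, aE = 0, eps = 0)
  bad <- setdiff(names(variance_components), names(vc))
  if (length(bad)) stop("unknown variance component(s): ",
                        paste(bad, collapse = ", "))
  vc[names(variance_components)] <- variance_components
  if (any(vc < 0)) stop("variance components must be non-negative")
  structure(list(n_lines = n_lines, n_markers = n_markers, n_sites = n_sites,
                 n_covariables = n_covariables, n_checks = n_checks,
                 prep_fractions = prep_fractions,
                 check_plot_fraction = check_plot_fraction,
                 variance_components = vc, mu = mu, seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulated MET configuration:", x$n_lines, "lines x", x$n_sites,
      "sites,", x$n_markers, "markers,", x$n_covariables, "covariables\n")
  cat("  p-rep fractions:", paste(x$prep_fractions, collapse = "/"),
      " checks:", x$n_checks,
      sprintf(" (%.0f%% of plots)\n", 100 * x$check_plot_fraction))
  vc <- x$variance_components
  cat("  variance components:",
      paste(names(vc)[vc > 0], round(vc[vc > 0], 3), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a biallelic marker panel
#'
#' Draws marker codes for each line with per-marker allele frequencies
#' uniform over `allele_freq_range`. Coding is presence/absence \{0,1\}
#' (DArTseq PAV-style, the default) or SNP dosage \{0,1,2\}. Monomorphic
#' columns are redrawn, and realized column frequencies are resampled toward
#' the requested range where the range permits.
#'
#' @param n_lines,n_markers panel dimensions (`n_lines >= 2`).
#' @param allele_freq_range length-2 numeric in (0,1), lower <= upper.
#' @param coding `"pav"` (0/1) or `"dosage"` (0/1/2).
#' @param seed integer seed.
#' @param line_ids optional rownames; default `L0001`, ...
#' @return numeric matrix lines x markers with a `coding` attribute.
#' @export
simulate_markers <- function(n_lines, n_markers,
                             allele_freq_range = c(0.05, 0.95),
                             coding = c("pav", "dosage"), seed = 1,
                             line_ids = NULL) {
  coding <- match.arg(coding)
  stopifnot(n_lines >= 2, n_markers >= 1)
  lo <- allele_freq_range[1]; hi <- allele_freq_range[2]
  if (!(lo > 0)) stop("allele frequency lower bound must be > 0 (got ", lo, ")")
  if (!(hi < 1)) stop("allele frequency upper bound must be < 1 (got ", hi, ")")
  if (lo > hi) stop("allele frequency range is empty: lower ", lo,
                    " > upper ", hi)
  if (is.null(line_ids)) line_ids <- sprintf("L%04d", seq_len(n_lines))
  ploidy <- if (coding == "pav") 1L else 2L
  .with_seed(seed, {
    X <- matrix(0, n_lines, n_markers,
                dimnames = list(line_ids,
                                sprintf("M%05d", seq_len(n_markers))))
    for (m in seq_len(n_markers)) {
      for (attempt in 1:100) {
        p <- stats::runif(1, lo, hi)
        col <- stats::rbinom(n_lines, ploidy, p)
        mono <- length(unique(col)) == 1L
        freq <- mean(col) / ploidy
        if (!mono && (freq >= lo && freq <= hi || attempt >= 50)) break
      }
      if (mono) stop("could not draw a polymorphic column for marker ", m)
      X[, m] <- col
    }
    attr(X, "coding") <- coding
    X
  })
}

#' Simulate a multi-generation pedigree
#'
#' Founders (unknown parents) are crossed in random disjoint pairs; each
#' cross yields `offspring_per_cross` full-sib offspring, and each subsequent
#' generation is produced the same way from the previous one. Parents always
#' precede offspring, so the result is valid input for
#' [additive_relationship()].
#'
#' @param n_founders number of founders (>= 2).
#' @param n_generations generations of crossing after the founders.
#' @param offspring_per_cross offspring per mating pair.
#' @param seed integer seed.
#' @return data frame with columns `id`, `parent1`, `parent2` (`NA` parents
#'   for founders).
#' @export
simulate_pedigree <- function(n_founders, n_generations = 3,
                              offspring_per_cross = 4, seed = 1) {
  stopifnot(n_founders >= 2, n_generations >= 0, offspring_per_cross >= 1)
  .with_seed(seed, {
    ped <- data.frame(id = sprintf("F%03d", seq_len(n_founders)),
                      parent1 = NA_character_, parent2 = NA_character_,
                      stringsAsFactors = FALSE)
    prev <- ped$id
    for (g in seq_len(n_generations)) {
      if (length(prev) < 2L) break
      pairs <- matrix(sample(prev, 2L * (length(prev) %/% 2L)), nrow = 2L)
      kid <- 0L
      recs <- vector("list", ncol(pairs))
      for (cx in seq_len(ncol(pairs))) {
        ids <- sprintf("G%d_%04d", g, kid + seq_len(offspring_per_cross))
        kid <- kid + offspring_per_cross
        recs[[cx]] <- data.frame(id = ids, parent1 = pairs[1, cx],
                                 parent2 = pairs[2, cx],
                                 stringsAsFactors = FALSE)
      }
      new <- do.call(rbind, recs)
      ped <- rbind(ped, new)
      prev <- new$id
    }
    ped
  })
}

#' Simulate site-level environmental covariables
#'
#' Continuous covariables with between-site spread, emulating temperature
#' summaries over crop growth phases (minimum/mean/maximum temperature over
#' the vegetative stage, grain filling and the full cycle). Each covariable
#' gets its own climatological mean and 3-degree between-site spread.
#'
#' @param n_sites,n_covariables table dimensions (sites >= 2, Q >= 1).
#' @param seed integer seed.
#' @return numeric matrix sites x Q with site ids `S1`, ... as rownames.
#' @export
simulate_env_covariates <- function(n_sites, n_covariables = 5, seed = 1) {
  stopifnot(n_sites >= 2, n_covariables >= 1)
  nm <- c("tmin_veg", "tmin_cycle", "tmax_fill", "tmax_cycle", "tmean_cycle")
  cn <- if (n_covariables <= 5L) nm[seq_len(n_covariables)] else
    c(nm, sprintf("ec%d", seq_len(n_covariables - 5L)))
  .with_seed(seed, {
    mu <- stats::runif(n_covariables, 8, 30)
    W <- sapply(seq_len(n_covariables),
                function(q) mu[q] + stats::rnorm(n_sites, 0, 3))
    W <- matrix(W, n_sites, n_covariables,
                dimnames = list(sprintf("S%d", seq_len(n_sites)), cn))
    W
  })
}

#' Simulate markers by gene dropping along a pedigree
#'
#' Founders draw two independent alleles per marker with frequencies uniform
#' over `allele_freq_range`; every descendant inherits one random allele
#' from each parent. Marker codes are therefore heritable: relatives share
#' codes in proportion to their additive relationship, which is what lets
#' genomic prediction carry information to untested lines. Codes are
#' presence/absence (dominant scoring of the two alleles, default) or
#' dosage. Columns monomorphic across `keep_ids` (or all individuals) are
#' redropped with fresh founder alleles.
#'
#' @param pedigree data frame (`id`, `parent1`, `parent2`) with parents
#'   preceding offspring, e.g. from [simulate_pedigree()].
#' @param n_markers panel size.
#' @param allele_freq_range founder allele-frequency range in (0,1).
#' @param coding `"pav"` or `"dosage"`.
#' @param seed integer seed.
#' @param keep_ids individuals whose rows are returned (default all); also
#'   the set over which polymorphism is enforced.
#' @return numeric code matrix with a `coding` attribute.
#' @export
simulate_markers_pedigree <- function(pedigree, n_markers,
                                      allele_freq_range = c(0.1, 0.9),
                                      coding = c("pav", "dosage"), seed = 1,
                                      keep_ids = NULL) {
  coding <- match.arg(coding)
  stopifnot(n_markers >= 1)
  ids <- as.character(pedigree$id)
  n <- length(ids)
  f <- match(as.character(pedigree$parent1), ids)
  m <- match(as.character(pedigree$parent2), ids)
  if (any(stats::na.omit(f >= seq_len(n))) ||
      any(stats::na.omit(m >= seq_len(n)))) {
    stop("pedigree must list parents before offspring")
  }
  if (is.null(keep_ids)) keep_ids <- ids
  krows <- match(keep_ids, ids)
  if (anyNA(krows)) stop("keep_ids not all present in the pedigree")
  lo <- allele_freq_range[1]; hi <- allele_freq_range[2]
  stopifnot(lo > 0, hi < 1, lo <= hi)
  founder <- is.na(f) & is.na(m)
  .with_seed(seed, {
    drop_col <- function() {
      p <- stats::runif(1, lo, hi)
      a1 <- integer(n); a2 <- integer(n)
      a1[founder] <- stats::rbinom(sum(founder), 1, p)
      a2[founder] <- stats::rbinom(sum(founder), 1, p)
      pick <- stats::runif(2 * n) < 0.5   # which parental allele transmits
      for (i in which(!founder)) {
        a1[i] <- if (is.na(f[i])) stats::rbinom(1, 1, p) else
          if (pick[2 * i - 1]) a1[f[i]] else a2[f[i]]
        a2[i] <- if (is.na(m[i])) stats::rbinom(1, 1, p) else
          if (pick[2 * i]) a1[m[i]] else a2[m[i]]
      }
      a1 + a2
    }
    X <- matrix(0, length(krows), n_markers,
                dimnames = list(keep_ids, sprintf("M%05d", seq_len(n_markers))))
    for (mm in seq_len(n_markers)) {
      for (attempt in 1:50) {
        dos <- drop_col()[krows]
        col <- if (coding == "pav") as.integer(dos > 0) else dos
        if (length(unique(col)) > 1L) break
      }
      X[, mm] <- col
    }
    attr(X, "coding") <- coding
    X
  })
}

## exact integer split of n into categories by largest-remainder rounding
.split_counts <- function(n, fractions) {
  cum <- round(cumsum(fractions) * n)
  diff(c(0L, cum))
}

#' Simulate a p-rep augmented trial design (phenotype skeleton)
#'
#' Builds plot records per site: each accession appears 1, 2, or 3 times per
#' site according to `prep_fractions`, plots are grouped in augmented blocks,
#' and every check appears once in every block so that checks occupy about
#' `check_plot_fraction` of the plots.
#'
#' @param config a [sim_config()].
#' @param seed seed (default `config$seed`).
#' @param line_ids optional accession identifiers (default `L0001`, ...).
#' @return data frame with columns `site`, `line`, `block`, `check`, `rep`
#'   and an all-`NA` response column `y`.
#' @export
simulate_design <- function(config, seed = config$seed, line_ids = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_lines
  if (is.null(line_ids)) line_ids <- sprintf("L%04d", seq_len(n))
  stopifnot(length(line_ids) == n)
  counts <- .split_counts(n, config$prep_fractions)
  reps_per_cat <- seq_along(counts)   # 1, 2, 3+ (3 used for the last)
  n_acc_plots <- sum(counts * reps_per_cat)
  f <- config$check_plot_fraction
  if (f > 0 && config$n_checks == 0L) {
    stop("check_plot_fraction = ", f, " but n_checks = 0: ",
         "cannot place any check plots")
  }
  check_ids <- if (config$n_checks > 0L)
    sprintf("CHK%d", seq_len(config$n_checks)) else character(0)
  n_blocks <- if (f > 0) {
    max(2L, round(n_acc_plots * f / (1 - f) / config$n_checks))
  } else {
    max(2L, ceiling(n_acc_plots / 50))
  }
  .with_seed(seed, {
    per_site <- lapply(seq_len(config$n_sites), function(si) {
      site <- sprintf("S%d", si)
      perm <- sample(line_ids)                 # which lines fall in which
      cnt <- rep(reps_per_cat, counts)         # replication category varies
      acc <- data.frame(site = site, line = rep(perm, cnt),
                        check = FALSE, stringsAsFactors = FALSE)
      acc <- acc[sample(nrow(acc)), , drop = FALSE]
      acc$block <- sprintf("%s_B%02d",
                           site, rep_len(seq_len(n_blocks), nrow(acc)))
      chk <- if (length(check_ids)) {
        expand.grid(line = check_ids, b = seq_len(n_blocks),
                    stringsAsFactors = FALSE)
      } else NULL
      out <- acc[, c("site", "line", "block", "check")]
      if (!is.null(chk)) {
        out <- rbind(out,
                     data.frame(site = site, line = chk$line,
                                block = sprintf("%s_B%02d", site, chk$b),
                                check = TRUE, stringsAsFactors = FALSE))
      }
      out <- out[order(out$block, out$line), , drop = FALSE]
      out$rep <- stats::ave(seq_len(nrow(out)),
                            out$line, FUN = seq_along)
      out
    })
    skel <- do.call(rbind, per_site)
    rownames(skel) <- NULL
    skel$y <- NA_real_
    skel
  })
}

## MVN draw with covariance sigma2 * K via eigendecomposition (PSD-safe)
.rmvn_kernel <- function(K, sigma2) {
  if (sigma2 == 0) return(stats::setNames(numeric(nrow(K)), rownames(K)))
  ee <- eigen((K + t(K)) / 2, symmetric = TRUE)
  lam <- pmax(ee$values, 0)
  z <- stats::rnorm(length(lam))
  stats::setNames(drop(ee$vectors %*% (sqrt(sigma2 * lam) * z)), rownames(K))
}

#' Simulate trait values on a design skeleton
#'
#' Fills the response of a [simulate_design()] skeleton from the full
#' reaction-norm generative model: the phenotype of line j in site i is the
#' grand mean plus a site effect, a covariable-regression site effect (with
#' covariance proportional to the environmental kernel), genomic and pedigree
#' line effects (covariances G and A), their site-specific interaction
#' deviations (Hadamard-structured: independent across sites, G- or
#' A-correlated within a site), and IID plot error. Genomic terms are built
#' from explicit per-marker effects so the ground truth records them. Terms
#' with zero variance in the configuration are identically zero. Checks
#' receive their own persistent line effects outside G and A.
#'
#' @param skeleton design skeleton from [simulate_design()].
#' @param markers marker matrix covering every accession in the skeleton.
#' @param pedigree pedigree data frame covering every accession.
#' @param env_covariates site covariable table covering every site.
#' @param config the [sim_config()] holding variance components and `mu`.
#' @param seed seed (default `config$seed + 1`).
#' @return list with elements `pheno` (skeleton with `y` filled) and `truth`
#'   (realized effects, line-by-site genetic values, marker effects, variance
#'   components, seed).
#' @export
simulate_phenotypes <- function(skeleton, markers, pedigree, env_covariates,
                                config, seed = config$seed + 1) {
  stopifnot(inherits(config, "sim_config"))
  vc <- config$variance_components
  acc <- sort(unique(skeleton$line[!skeleton$check]))
  sites <- unique(skeleton$site)
  need_mark <- vc["g"] > 0 || vc["gE"] > 0
  need_ped <- vc["a"] > 0 || vc["aE"] > 0
  if (need_mark) {
    miss <- setdiff(acc, rownames(markers))
    if (length(miss)) stop("accessions missing from markers: ",
                           paste(utils::head(miss, 10L), collapse = ", "))
  }
  if (need_ped) {
    miss <- setdiff(acc, as.character(pedigree$id))
    if (length(miss)) stop("accessions missing from pedigree: ",
                           paste(utils::head(miss, 10L), collapse = ", "))
  }
  miss <- setdiff(sites, rownames(env_covariates))
  if (length(miss) && vc["w"] > 0) {
    stop("sites missing from covariable table: ", paste(miss, collapse = ", "))
  }

  nL <- length(acc); nS <- length(sites)
  Xc <- NULL
  if (need_mark) {
    X <- markers[acc, , drop = FALSE]
    Xc <- sweep(X, 2L, colMeans(X), "-")
  }
  A <- if (need_ped) {
    additive_relationship(pedigree)[acc, acc, drop = FALSE]
  } else NULL
  Om <- if (vc["w"] > 0) env_kernel(env_covariates)[sites, sites] else NULL

  .with_seed(seed, {
    p <- config$n_markers
    E_eff <- stats::setNames(stats::rnorm(nS, 0, sqrt(vc["E"])), sites)
    w_eff <- if (vc["w"] > 0) .rmvn_kernel(Om, vc["w"]) else
      stats::setNames(numeric(nS), sites)
    L_eff <- stats::setNames(stats::rnorm(nL, 0, sqrt(vc["L"])), acc)
    b <- if (vc["g"] > 0) stats::rnorm(ncol(Xc), 0, sqrt(vc["g"] / ncol(Xc)))
      else NULL
    g_eff <- if (!is.null(b)) stats::setNames(drop(Xc %*% b), acc) else
      stats::setNames(numeric(nL), acc)
    a_eff <- if (vc["a"] > 0) .rmvn_kernel(A, vc["a"]) else
      stats::setNames(numeric(nL), acc)
    gE <- matrix(0, nL, nS, dimnames = list(acc, sites))
    bE <- NULL
    if (vc["gE"] > 0) {
      bE <- matrix(stats::rnorm(ncol(Xc) * nS, 0, sqrt(vc["gE"] / ncol(Xc))),
                   ncol(Xc), nS)
      gE <- Xc %*% bE
      dimnames(gE) <- list(acc, sites)
    }
    aE <- matrix(0, nL, nS, dimnames = list(acc, sites))
    if (vc["aE"] > 0) {
      for (s in sites) aE[, s] <- .rmvn_kernel(A, vc["aE"])
    }
    chk_ids <- unique(skeleton$line[skeleton$check])
    chk_eff <- stats::setNames(
      stats::rnorm(length(chk_ids), 0, sqrt(vc["g"] + vc["a"] + vc["L"])),
      chk_ids)

    eps <- stats::rnorm(nrow(skeleton), 0, sqrt(vc["eps"]))
    y <- config$mu + E_eff[skeleton$site] + w_eff[skeleton$site] + eps
    ia <- !skeleton$check
    li <- skeleton$line[ia]; si <- skeleton$site[ia]
    y[ia] <- y[ia] + L_eff[li] + g_eff[li] + a_eff[li] +
      gE[cbind(li, si)] + aE[cbind(li, si)]
    y[!ia] <- y[!ia] + chk_eff[skeleton$line[!ia]]

    pheno <- skeleton
    pheno$y <- unname(y)
    gv <- outer(g_eff + a_eff + L_eff, stats::setNames(numeric(nS), sites),
                "+") + gE + aE
    truth <- list(
      genetic_values = gv,
      marker_effects = b,
      effects = list(E = E_eff, w = w_eff, L = L_eff, g = g_eff, a = a_eff,
                     gE = gE, aE = aE, check = chk_eff),
      variance_components = vc,
      mu = config$mu,
      seed = seed)
    list(pheno = pheno, truth = truth)
  })
}

#' Simulate a complete multi-environment trial dataset
#'
#' Orchestrates the generator: pedigree, markers (rownames matched to the
#' most recent pedigree individuals), site covariables, p-rep design, and
#' phenotypes with ground truth. Per-stage seeds are derived
#' deterministically from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return object of class `"met_data"`: list with `pheno`, `markers`,
#'   `pedigree`, `env_covariates`, `truth`, `config`.
#' @examples
#' met <- simulate_met(sim_config(n_lines = 60, n_markers = 200, n_sites = 3))
#' met
#' @export
simulate_met <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- .with_seed(config$seed, sample.int(.Machine$integer.max - 1L, 5L))
  growth <- max(2, 4 / 2)  # offspring_per_cross / 2 per generation
  n_found <- max(4L, ceiling(config$n_lines / growth^3))
  ped <- simulate_pedigree(n_found, n_generations = 3,
                           offspring_per_cross = 4, seed = seeds[1])
  if (nrow(ped) < config$n_lines) {
    stop("pedigree too small for ", config$n_lines, " lines")
  }
  ids <- utils::tail(ped$id, config$n_lines)
  ## gene-dropped markers: relatives share codes, so G carries family
  ## information to untested lines (as in a real breeding panel)
  markers <- simulate_markers_pedigree(ped, config$n_markers,
                                       seed = seeds[2], keep_ids = ids)
  env <- simulate_env_covariates(config$n_sites, config$n_covariables,
                                 seed = seeds[3])
  skel <- simulate_design(config, seed = seeds[4], line_ids = ids)
  sim <- simulate_phenotypes(skel, markers, ped, env, config, seed = seeds[5])
  structure(list(pheno = sim$pheno, markers = markers, pedigree = ped,
                 env_covariates = env, truth = sim$truth, config = config),
            class = "met_data")
}

#' @export
print.met_data <- function(x, ...) {
  cat("Multi-environment trial data:",
      length(unique(x$pheno$line[!x$pheno$check])), "accessions,",
      length(unique(x$pheno$site)), "sites,", nrow(x$pheno), "plots\n")
  cat("  markers:", ncol(x$markers), " pedigree records:", nrow(x$pedigree),
      " covariables:", ncol(x$env_covariates), "\n")
  if (!is.null(x$truth)) cat("  simulated (ground truth attached)\n")
  invisible(x)
}
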