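#' Cross-validation / site-prediction plan
#'
#' Builds the hold-out plan for one of the four prediction problems:
#' * `CV1` — random 80/20 splits at the line level: all plot records of a
#'   test line are held out everywhere (untested lines);
#' * `CV2` — random 80/20 splits at the plot level: a line can be observed
#'   in some sites and held out in others (sparse testing);
#' * `pairwise` — every ordered site pair: one site trains, the other is
#'   predicted;
#' * `loso` — leave-one-site-out: each site in turn is fully held out and
#'   predicted from the remaining sites (its covariable row stays in W).
#'
#' Check plots never enter test sets; they are design infrastructure.
#'
#' @param scheme `"CV1"`, `"CV2"`, `"pairwise"` or `"loso"`.
#' @param pheno plot-level phenotype table.
#' @param test_fraction held-out fraction for CV1/CV2 (default 0.2).
#' @param n_replicates number of random partitions for CV1/CV2 (default 50).
#' @param seed integer seed; plans are deterministic given the seed.
#' @return object of class `"cv_plan"`: list of replicates, each with the
#'   accession-record indices to mask (indices refer to the accession-only
#'   subset of `pheno`, in its row order) and, for the site schemes, the
#'   train/test site labels.
#' @export
make_cv_plan <- function(scheme = c("CV1", "CV2", "pairwise", "loso"),
                         pheno, test_fraction = 0.2, n_replicates = 50,
                         seed = 1) {
  scheme <- match.arg(scheme)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must be in (0, 1), got ", test_fraction)
  }
  d <- as.data.frame(pheno)
  if (!"check" %in% names(d)) d$check <- FALSE
  acc <- d[!d$check, , drop = FALSE]
  rownames(acc) <- NULL
  lines <- unique(as.character(acc$line))
  sites <- unique(as.character(acc$site))
  reps <- switch(scheme,
    CV1 = {
      if (length(lines) < 5L) stop("CV1 needs at least 5 lines")
      .with_seed(seed, lapply(seq_len(n_replicates), function(r) {
        tl <- sample(lines, round(test_fraction * length(lines)))
        list(replicate = r,
             test = which(as.character(acc$line) %in% tl),
             test_lines = tl)
      }))
    },
    CV2 = .with_seed(seed, lapply(seq_len(n_replicates), function(r) {
      list(replicate = r,
           test = sample(nrow(acc), round(test_fraction * nrow(acc))))
    })),
    pairwise = {
      pairs <- expand.grid(train_site = sites, test_site = sites,
                           stringsAsFactors = FALSE)
      pairs <- pairs[pairs$train_site != pairs$test_site, , drop = FALSE]
      lapply(seq_len(nrow(pairs)), function(i) {
        list(replicate = i, train_site = pairs$train_site[i],
             test_site = pairs$test_site[i],
             test = which(as.character(acc$site) == pairs$test_site[i]))
      })
    },
    loso = lapply(seq_along(sites), function(i) {
      list(replicate = i, test_site = sites[i],
           test = which(as.character(acc$site) == sites[i]))
    })
  )
  structure(list(scheme = scheme, replicates = reps,
                 test_fraction = test_fraction, seed = seed,
                 n_records = nrow(acc), sites = sites, lines = lines),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat("Prediction plan:", x$scheme, "-", length(x$replicates),
      "replicate(s) over", x$n_records, "accession records\n")
  invisible(x)
}

## per-site Pearson correlation between observed and predicted test values
.site_correlations <- function(obs_tab, y_obs, y_pred, min_n = 3L,
                               by_line = FALSE) {
  sites <- unique(as.character(obs_tab$site))
  out <- lapply(sites, function(s) {
    idx <- as.character(obs_tab$site) == s
    o <- y_obs[idx]; p <- y_pred[idx]
    if (by_line) {
      ln <- as.character(obs_tab$line)[idx]
      o <- tapply(o, ln, mean); p <- tapply(p, ln, mean)
    }
    r <- if (length(o) >= min_n && stats::sd(o) > 0 && stats::sd(p) > 0) {
      stats::cor(o, p)
    } else NA_real_
    data.frame(site = s, cor = r, n_test = length(o))
  })
  do.call(rbind, out)
}

#' Run one prediction scheme for one model
#'
#' For every replicate of the plan: masks the test responses, fits the named
#' reaction-norm model on the remaining records, predicts the masked
#' records, and computes the per-site Pearson correlation between observed
#' and predicted test values. Pairwise replicates fit on the two sites'
#' records only (training site observed, test site masked); leave-one-site-
#' out fits all sites with the held-out site masked, so its information
#' enters only through the covariable, genomic and pedigree kernels.
#'
#' @param model one of [rnm_models()].
#' @param data a `"met_data"` bundle (or compatible list).
#' @param plan a [make_cv_plan()] result built from `data$pheno`.
#' @param control an [mcmc_control()]; replicate r is fitted with seed
#'   `control$seed + r` when a seed is set.
#' @param observed `"plot"` correlates raw plot records; `"line_mean"`
#'   averages observed and predicted values per line within site first.
#' @return object of class `"accuracy_report"`: a data frame with one row
#'   per replicate x test site (`scheme`, `model`, `replicate`,
#'   `train_site`, `site`, `cor`, `n_test`).
#' @export
run_scheme <- function(model, data, plan, control = mcmc_control(),
                       observed = c("plot", "line_mean")) {
  observed <- match.arg(observed)
  stopifnot(inherits(plan, "cv_plan"))
  pheno <- as.data.frame(data$pheno)
  if (!"check" %in% names(pheno)) pheno$check <- FALSE
  acc <- pheno[!pheno$check, , drop = FALSE]
  rownames(acc) <- NULL
  if (nrow(acc) != plan$n_records) {
    stop("plan was built for ", plan$n_records,
         " accession records, data has ", nrow(acc))
  }
  by_line <- observed == "line_mean"
  rows <- lapply(plan$replicates, function(rp) {
    ctl <- control
    if (!is.null(ctl$seed)) ctl$seed <- ctl$seed + rp$replicate
    if (plan$scheme == "pairwise") {
      keep <- as.character(acc$site) %in% c(rp$train_site, rp$test_site)
      sub <- acc[keep, , drop = FALSE]
      mask <- as.character(sub$site) == rp$test_site
      fit <- rnm(model, list(pheno = sub, markers = data$markers,
                             pedigree = data$pedigree,
                             env_covariates = data$env_covariates),
                 mask = mask, control = ctl)
      tab <- .site_correlations(sub[mask, , drop = FALSE],
                                sub$y[mask], fit$yhat[mask],
                                by_line = by_line)
      tab$train_site <- rp$train_site
    } else {
      mask <- rep(FALSE, nrow(acc))
      mask[rp$test] <- TRUE
      fit <- rnm(model, list(pheno = acc, markers = data$markers,
                             pedigree = data$pedigree,
                             env_covariates = data$env_covariates),
                 mask = mask, control = ctl)
      tab <- .site_correlations(acc[mask, , drop = FALSE],
                                acc$y[mask], fit$yhat[mask],
                                by_line = by_line)
      tab$train_site <- NA_character_
    }
    tab$replicate <- rp$replicate
    tab
  })
  out <- do.call(rbind, rows)
  out$scheme <- plan$scheme
  out$model <- model
  out <- out[, c("scheme", "model", "replicate", "train_site", "site",
                 "cor", "n_test")]
  class(out) <- c("accuracy_report", class(out))
  out
}

#' Aggregate accuracy reports into per-site summary tables
#'
#' Produces the long summary (mean correlation and its SD across replicates
#' per model x scheme x site; the SD is omitted for single-replicate site
#' schemes) and wide tables shaped like published accuracy tables: one row
#' per site, one column per model, plus the best model per site.
#'
#' @param reports an `"accuracy_report"` or list of them.
#' @return list with `long` (data frame), `wide` (named list of site x
#'   model matrices, one per scheme), and `best` (best model per scheme x
#'   site).
#' @export
summarize_reports <- function(reports) {
  if (inherits(reports, "data.frame")) reports <- list(reports)
  all <- do.call(rbind, lapply(reports, as.data.frame))
  key <- interaction(all$scheme, all$model, all$site, drop = TRUE)
  long <- do.call(rbind, lapply(split(all, key), function(g) {
    reps <- g$cor[!is.na(g$cor)]
    data.frame(scheme = g$scheme[1], model = g$model[1], site = g$site[1],
               mean_cor = if (length(reps)) mean(reps) else NA_real_,
               sd_cor = if (length(reps) > 1) stats::sd(reps) else NA_real_,
               n_replicates = length(reps), row.names = NULL)
  }))
  long <- long[order(long$scheme, long$model, long$site), , drop = FALSE]
  rownames(long) <- NULL
  wide <- lapply(split(long, long$scheme), function(g) {
    sites <- sort(unique(g$site)); models <- unique(g$model)
    m <- matrix(NA_real_, length(sites), length(models),
                dimnames = list(sites, models))
    m[cbind(g$site, g$model)] <- g$mean_cor
    m
  })
  best <- do.call(rbind, lapply(split(long, interaction(long$scheme,
                                                        long$site,
                                                        drop = TRUE)),
    function(g) {
      i <- which.max(g$mean_cor)
      if (!length(i)) return(NULL)
      data.frame(scheme = g$scheme[1], site = g$site[1],
                 best_model = g$model[i], mean_cor = g$mean_cor[i],
                 row.names = NULL)
    }))
  rownames(best) <- NULL
  list(long = long, wide = wide, best = best)
}
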