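#' MCMC settings for the reaction-norm sampler
#'
#' @param n_iter total Gibbs iterations (default 12000).
#' @param burn_in discarded initial iterations (must be `< n_iter`).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param df prior degrees of freedom of every scaled-inverse-chi-square
#'   variance prior.
#' @param r2_residual prior proportion of phenotypic variance assigned to the
#'   residual; the remainder is split equally among the model terms to set
#'   the prior scales (prior mode = variance share).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return list of class `"mcmc_control"`.
#' @export
mcmc_control <- function(n_iter = 12000, burn_in = 2000, thin = 5, df = 5,
                         r2_residual = 0.5, seed = NULL) {
  stopifnot(n_iter >= 1, burn_in >= 0, burn_in < n_iter, thin >= 1,
            df > 0, r2_residual > 0, r2_residual < 1)
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin, df = df,
                 r2_residual = r2_residual, seed = seed),
            class = "mcmc_control")
}

## effective sample size from the initial positive sequence of
## autocorrelations (single chain)
.ess <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1]
  s <- 0
  for (r in ac) {
    if (r <= 0) break
    s <- s + r
  }
  max(1, n / (1 + 2 * s))
}

## factorize kernels as Phi Phi'; prefer the structured factors stored by
## build_kernel_set, fall back to a dense eigendecomposition.
.kernel_factors <- function(ks) {
  out <- vector("list", length(ks$kernels))
  names(out) <- names(ks$kernels)
  for (nm in names(ks$kernels)) {
    if (!is.null(ks$factors[[nm]])) {
      out[[nm]] <- unname(ks$factors[[nm]])
    } else {
      K <- ks$kernels[[nm]]
      ee <- eigen((K + t(K)) / 2, symmetric = TRUE)
      lmax <- max(ee$values, 0)
      if (min(ee$values) < -1e-8 * max(lmax, 1e-300)) {
        stop("kernel '", nm, "' is not PSD (min eigenvalue ",
             format(min(ee$values)), ")")
      }
      keep <- ee$values > 1e-10 * lmax
      out[[nm]] <- ee$vectors[, keep, drop = FALSE] %*%
        diag(sqrt(ee$values[keep]), sum(keep))
    }
  }
  out
}

#' Fit a multi-kernel reaction-norm model by Gibbs sampling
#'
#' Bayesian fit of \eqn{y = \mu + \sum_t u_t + \varepsilon} with
#' \eqn{u_t \sim N(0, \sigma^2_t K_t)} for the kernels of a
#' [build_kernel_set()] result. Each term is sampled in a factor basis of its
#' kernel (\eqn{K_t = \Phi_t\Phi_t'}) with conjugate normal coordinate
#' updates and scaled-inverse-chi-square variance updates. Masked records do
#' not enter the likelihood but receive posterior predicted values through
#' the kernel rows linking them to the training records.
#'
#' @param kernel_set a `"kernel_set"`.
#' @param y response vector in the kernel observation order; defaults to the
#'   `y` column of the observation table. `NA` responses are masked.
#' @param mask optional logical vector flagging records to hold out.
#' @param control an [mcmc_control()].
#' @param fixed_variances optional named numeric fixing selected variance
#'   components (kernel names, plus `"eps"` for the residual) instead of
#'   sampling them.
#' @param use_factors use the structured low-rank kernel factors when
#'   available (default); `FALSE` forces the dense eigendecomposition path.
#' @return object of class `"rnm"`; see [coef.rnm()], [predict.rnm()],
#'   [summary.rnm()].
#' @export
fit_rnm <- function(kernel_set, y = NULL, mask = NULL,
                    control = mcmc_control(), fixed_variances = NULL,
                    use_factors = TRUE) {
  stopifnot(inherits(kernel_set, "kernel_set"),
            inherits(control, "mcmc_control"))
  obs <- kernel_set$obs
  n_obs <- nrow(obs)
  if (is.null(y)) y <- obs$y
  if (length(y) != n_obs) stop("y has length ", length(y), ", expected ", n_obs)
  if (is.null(mask)) mask <- rep(FALSE, n_obs)
  mask <- mask | is.na(y)
  if (all(mask)) stop("all responses are masked; nothing to fit")
  train <- which(!mask)
  y_train <- y[train]

  ks <- kernel_set
  if (!use_factors) ks$factors <- NULL
  Phi <- .kernel_factors(ks)
  terms <- names(Phi)

  ## drop coordinates without training support: they are data-independent,
  ## have posterior-mean contribution exactly zero, and would only add noise
  for (t in seq_along(Phi)) {
    P <- Phi[[t]]
    xtx <- colSums(P[train, , drop = FALSE]^2)
    keep <- xtx > 1e-12 * max(xtx, 1)
    Phi[[t]] <- P[, keep, drop = FALSE]
  }

  vy <- stats::var(y_train)
  if (!is.finite(vy) || vy == 0) vy <- 1e-6   # constant response: prior floor
  nu <- control$df
  r2_terms <- (1 - control$r2_residual) / length(Phi)
  prior_mode <- rep(vy * r2_terms, length(Phi))
  prior_S <- prior_mode * (nu + 2)
  prior_S_e <- control$r2_residual * vy * (nu + 2)

  fixed <- rep(-1, length(Phi))
  fixed_e <- -1
  if (!is.null(fixed_variances)) {
    bad <- setdiff(names(fixed_variances), c(terms, "eps"))
    if (length(bad)) stop("fixed_variances names not in the model: ",
                          paste(bad, collapse = ", "))
    for (nm in names(fixed_variances)) {
      if (nm == "eps") fixed_e <- fixed_variances[[nm]]
      else fixed[match(nm, terms)] <- fixed_variances[[nm]]
    }
  }

  run <- function() .gibbs_multikernel(
    y_train, unname(Phi), train - 1L, prior_S, rep(nu, length(Phi)),
    prior_S_e, nu, fixed, fixed_e,
    control$n_iter, control$burn_in, control$thin)
  res <- if (is.null(control$seed)) run() else .with_seed(control$seed, run())

  var_chain <- res$var_chain
  colnames(var_chain) <- c(terms, "eps")
  vc <- data.frame(
    term = c(terms, "eps"),
    mean = colMeans(var_chain),
    sd = apply(var_chain, 2L, stats::sd),
    ess = apply(var_chain, 2L, .ess),
    row.names = NULL)
  effects <- stats::setNames(lapply(res$u_mean, drop), terms)
  effects_sd <- stats::setNames(lapply(res$u_sd, drop), terms)

  structure(list(
    model = kernel_set$model, terms = terms, obs = obs, y = y, mask = mask,
    mu = mean(res$mu_chain), mu_sd = stats::sd(res$mu_chain),
    variance_components = vc,
    effects = effects, effects_sd = effects_sd,
    yhat = drop(res$yhat_mean), yhat_sd = drop(res$yhat_sd),
    chains = list(mu = drop(res$mu_chain), var = var_chain),
    control = control, n_saved = res$n_saved),
    class = "rnm")
}

#' Fit one of the eight named reaction-norm models
#'
#' Convenience wrapper composing [build_kernel_set()] and [fit_rnm()] on a
#' data bundle (a `"met_data"` object or a list with `pheno` and, as the
#' model requires, `markers`, `pedigree`, `env_covariates`). Check plots are
#' dropped before fitting; `mask` indexes the accession plot records in
#' `data$pheno` order after that drop.
#'
#' @param model one of [rnm_models()].
#' @param data data bundle.
#' @param mask optional logical over accession plot records.
#' @param control an [mcmc_control()].
#' @param ... passed to [build_kernel_set()].
#' @return an `"rnm"` fit.
#' @export
rnm <- function(model, data, mask = NULL, control = mcmc_control(), ...) {
  pheno <- as.data.frame(data$pheno)
  if ("check" %in% names(pheno)) pheno <- pheno[!pheno$check, , drop = FALSE]
  ks <- build_kernel_set(model, pheno, markers = data$markers,
                         pedigree = data$pedigree,
                         env_covariates = data$env_covariates, ...)
  fit_rnm(ks, mask = mask, control = control)
}

#' @export
print.rnm <- function(x, ...) {
  cat("Reaction-norm kernel model:", x$model, "\n")
  cat("  ", sum(!x$mask), " training records, ", sum(x$mask),
      " masked, ", x$n_saved, " posterior draws\n", sep = "")
  cat("  mu =", signif(x$mu, 4), "\n")
  vc <- x$variance_components
  cat("  variance components:\n")
  print(data.frame(term = vc$term, mean = signif(vc$mean, 4),
                   sd = signif(vc$sd, 3)), row.names = FALSE)
  invisible(x)
}

#' Summarize a reaction-norm fit
#'
#' @param object an `"rnm"` fit.
#' @param ... unused.
#' @return list with the variance-component table (posterior mean, SD,
#'   effective sample size), the grand mean, and fit dimensions.
#' @export
summary.rnm <- function(object, ...) {
  out <- list(model = object$model,
              n_train = sum(!object$mask), n_masked = sum(object$mask),
              mu = object$mu, mu_sd = object$mu_sd,
              variance_components = object$variance_components,
              n_saved = object$n_saved)
  class(out) <- "summary.rnm"
  out
}

#' @export
print.summary.rnm <- function(x, ...) {
  cat("Model", x$model, "-", x$n_train, "training records,",
      x$n_masked, "masked\n")
  cat("mu:", signif(x$mu, 5), "(posterior SD", signif(x$mu_sd, 3), ")\n")
  cat("Variance components (posterior):\n")
  vc <- x$variance_components
  print(data.frame(term = vc$term, mean = signif(vc$mean, 4),
                   sd = signif(vc$sd, 3), ess = round(vc$ess)),
        row.names = FALSE)
  invisible(x)
}

#' Level-indexed posterior-mean effects of a fit
#'
#' Collapses the observation-level posterior-mean effect vectors to their
#' natural indexing: site vectors for `E` and `W`, line vectors for `L`, `G`
#' and `A`, and line-by-site matrices for `GE` and `AE`.
#'
#' @param object an `"rnm"` fit.
#' @param ... unused.
#' @return named list of effect vectors/matrices.
#' @export
coef.rnm <- function(object, ...) {
  obs <- object$obs
  site <- as.character(obs$site)
  line <- as.character(obs$line)
  out <- list()
  for (tm in object$terms) {
    u <- object$effects[[tm]]
    if (tm %in% c("E", "W")) {
      keep <- !duplicated(site)
      out[[tm]] <- stats::setNames(u[keep], site[keep])
    } else if (tm %in% c("L", "G", "A")) {
      keep <- !duplicated(line)
      out[[tm]] <- stats::setNames(u[keep], line[keep])
    } else {
      key <- paste(line, site, sep = "\r")
      keep <- !duplicated(key)
      m <- matrix(NA_real_, length(unique(line)), length(unique(site)),
                  dimnames = list(unique(line), unique(site)))
      m[cbind(line[keep], site[keep])] <- u[keep]
      out[[tm]] <- m
    }
  }
  c(list(mu = object$mu), out)
}

#' @export
fitted.rnm <- function(object, ...) {
  f <- object$yhat
  f
}

#' @export
residuals.rnm <- function(object, ...) {
  r <- object$y - object$yhat
  r[object$mask] <- NA_real_
  r
}

#' Predicted values for held-out records
#'
#' Returns the posterior-mean predicted response of masked (or any
#' requested) records in the kernel observation index. For a record in a
#' site absent from training, site-indicator and interaction terms carry no
#' information by construction and the prediction flows through the
#' covariable, genomic and pedigree kernels only.
#'
#' @param object an `"rnm"` fit.
#' @param targets integer indices into the observation table; default all
#'   masked records.
#' @param ... unused.
#' @return named numeric vector of predictions.
#' @export
predict.rnm <- function(object, targets = NULL, ...) {
  n <- length(object$yhat)
  if (is.null(targets)) targets <- which(object$mask)
  targets <- as.integer(targets)
  bad <- targets[targets < 1L | targets > n]
  if (length(bad)) {
    stop("target record(s) not in the kernel index: ",
         paste(bad, collapse = ", "))
  }
  stats::setNames(object$yhat[targets], targets)
}

#' Contribution of one model term to fitted/predicted values
#'
#' @param object an `"rnm"` fit.
#' @param term one of the fit's kernel names.
#' @return observation-level posterior-mean effect vector.
#' @export
term_effect <- function(object, term) {
  stopifnot(inherits(object, "rnm"))
  if (!term %in% object$terms) {
    stop("term '", term, "' not in model ", object$model)
  }
  object$effects[[term]]
}
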