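#' Factor-analytic model of between-site genetic covariance
#'
#' Fits, by EM, a two-factor (by default) factor-analytic model for
#' genotype-within-site effects whose covariance is
#' \eqn{(\Lambda\Lambda' + \Psi) \otimes G}: \eqn{\Lambda} is the sites-by-
#' factors loading matrix, \eqn{\Psi} a diagonal of site-specific genetic
#' variances, and G the marker-based relationship between accessions. The
#' model borrows information between correlated sites and yields the
#' between-site genetic covariance \eqn{\Sigma = \Lambda\Lambda' + \Psi},
#' genetic correlations, and biplot coordinates.
#'
#' Fitting works on line-by-site cell means (checks excluded). Site means
#' are treated as fixed and removed; the residual variance of each site's
#' cell means is held at a plug-in value (pooled within-cell replicate
#' variance divided by mean replication, or `R` if supplied) so EM estimates
#' the genetic parameters only. Transforming to the eigenbasis of G makes
#' lines independent, giving a standard per-line factor model with
#' line-specific scaling; the EM updates are exact and the log-likelihood is
#' non-decreasing.
#'
#' @param pheno plot-level phenotype table covering >= 3 sites.
#' @param G genomic relationship matrix covering all accessions.
#' @param n_factors number of factors (default 2).
#' @param trait response column name.
#' @param R optional numeric vector of per-site residual variances of the
#'   cell means.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return object of class `"fa_fit"` with loadings, `psi`, `Sigma`,
#'   genetic correlations, factor scores, the log-likelihood trace and a
#'   convergence flag.
#' @export
fit_factor_analytic <- function(pheno, G, n_factors = 2, trait = "y",
                                R = NULL, max_iter = 2000, tol = 1e-7) {
  d <- as.data.frame(pheno)
  if (!"check" %in% names(d)) d$check <- FALSE
  d <- d[!d$check & is.finite(d[[trait]]), , drop = FALSE]
  sites <- sort(unique(as.character(d$site)))
  s <- length(sites)
  if (s < 3L) stop("factor-analytic model needs >= 3 sites (got ", s, ")")
  lines <- sort(unique(as.character(d$line)))
  miss <- setdiff(lines, rownames(G))
  if (length(miss)) stop("accessions missing from G: ",
                         paste(utils::head(miss, 10L), collapse = ", "))

  ## line x site cell means
  agg <- stats::aggregate(d[[trait]],
                          by = list(line = as.character(d$line),
                                    site = as.character(d$site)), FUN = mean)
  Y <- matrix(NA_real_, length(lines), s, dimnames = list(lines, sites))
  Y[cbind(agg$line, agg$site)] <- agg$x
  if (anyNA(Y)) {
    stop("factor-analytic fit requires complete line x site coverage; ",
         sum(is.na(Y)), " empty cells")
  }
  n <- nrow(Y)

  if (is.null(R)) {
    R <- sapply(sites, function(si) {
      ds <- d[d$site == si, , drop = FALSE]
      tab <- table(ds$line)
      repl <- names(tab)[tab >= 2]
      if (length(repl) >= 5) {
        ssq <- 0; df <- 0
        for (ln in repl) {
          v <- ds[[trait]][ds$line == ln]
          ssq <- ssq + sum((v - mean(v))^2)
          df <- df + length(v) - 1L
        }
        ## residual variance of a cell mean averaged over cells: E[1/r]
        (ssq / df) * mean(1 / tab)
      } else {
        0.25 * stats::var(Y[, si])
      }
    })
  }
  R <- pmax(as.numeric(R), 1e-8)

  site_means <- colMeans(Y)
  Yc <- sweep(Y, 2L, site_means, "-")
  Gs <- (G[lines, lines] + t(G[lines, lines])) / 2
  eg <- eigen(Gs, symmetric = TRUE)
  dvec <- pmax(eg$values, 0)
  U <- eg$vectors
  Yt <- crossprod(U, Yc)                       # rows ~ N(0, d_j Sigma + R)

  ## moment initialization: sum_j E[y y'] = sum(d) Sigma + n R
  C0 <- (crossprod(Yt) - n * diag(R, s)) / max(sum(dvec), 1e-12)
  C0 <- (C0 + t(C0)) / 2
  e0 <- eigen(C0, symmetric = TRUE)
  k <- n_factors
  lam0 <- pmax(e0$values[seq_len(k)], 1e-4 * max(abs(e0$values)))
  Lambda <- e0$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lam0), k)
  Psi <- pmax(diag(C0) - rowSums(Lambda^2), 0.05 * pmax(diag(C0), 1e-8))

  ll_trace <- numeric(0)
  converged <- FALSE
  Fhat <- matrix(0, n, k)
  for (iter in seq_len(max_iter)) {
    Sig <- tcrossprod(Lambda) + diag(Psi, s)
    Czf <- matrix(0, s, k)
    Cff <- matrix(0, k, k)
    Czz <- numeric(s)
    ll <- 0
    for (j in seq_len(n)) {
      V <- dvec[j] * Sig + diag(R, s)
      ch <- chol(V)
      z <- backsolve(ch, Yt[j, ], transpose = TRUE)
      ll <- ll - 0.5 * (s * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
      Vi <- chol2inv(ch)
      sdj <- sqrt(dvec[j])
      SVi <- Sig %*% Vi
      LVi <- crossprod(Lambda, Vi)
      Ez <- sdj * drop(SVi %*% Yt[j, ])
      Ef <- sdj * drop(LVi %*% Yt[j, ])
      Fhat[j, ] <- Ef
      Czf <- Czf + (Lambda - dvec[j] * SVi %*% Lambda) + tcrossprod(Ez, Ef)
      Cff <- Cff + (diag(k) - dvec[j] * LVi %*% Lambda) + tcrossprod(Ef)
      Czz <- Czz + diag(Sig) - dvec[j] * rowSums(SVi * Sig) + Ez^2
    }
    ## ll is the likelihood of the CURRENT (Lambda, Psi), computed inside
    ## the E-step pass; EM guarantees it is non-decreasing over iterations
    ll_trace <- c(ll_trace, ll)
    if (iter > 1L) {
      prev <- ll_trace[iter - 1L]
      if (ll < prev - 1e-8 * (abs(prev) + 1)) {
        warning("EM log-likelihood decreased at iteration ", iter)
      }
      if (abs(ll - prev) < tol * (abs(prev) + 1)) {
        converged <- TRUE
        break
      }
    }
    Lambda_new <- Czf %*% solve(Cff)
    Psi_new <- pmax((Czz - rowSums(Lambda_new * Czf)) / n, 1e-8)
    Lambda <- Lambda_new
    Psi <- Psi_new
  }
  if (!converged) {
    warning("factor-analytic EM did not converge in ", max_iter,
            " iterations; returning the best iterate")
  }

  Sigma <- tcrossprod(Lambda) + diag(Psi, s)
  dimnames(Sigma) <- list(sites, sites)
  rownames(Lambda) <- sites
  names(Psi) <- sites
  dg <- diag(Sigma)
  corr <- matrix(NA_real_, s, s, dimnames = dimnames(Sigma))
  ok <- dg > 1e-12
  corr[ok, ok] <- stats::cov2cor(Sigma[ok, ok, drop = FALSE])
  scores <- U %*% Fhat
  rownames(scores) <- lines

  structure(list(loadings = Lambda, psi = Psi, R = stats::setNames(R, sites),
                 Sigma = Sigma, correlations = corr, scores = scores,
                 site_means = site_means, loglik = ll_trace,
                 converged = converged, n_factors = k, sites = sites,
                 lines = lines),
            class = "fa_fit")
}

#' @export
print.fa_fit <- function(x, ...) {
  cat("Factor-analytic fit:", length(x$sites), "sites,", length(x$lines),
      "lines,", x$n_factors, "factors",
      if (x$converged) "(converged)\n" else "(NOT converged)\n")
  cat("Between-site genetic correlations (variances on the diagonal):\n")
  print(round(genetic_correlations(x), 3))
  invisible(x)
}

#' Between-site genetic variances and correlations
#'
#' Formats the factor-analytic covariance as a site-by-site table with the
#' genetic variances on the diagonal and correlations
#' \eqn{D^{-1/2}\Sigma D^{-1/2}} off the diagonal. Sites with zero genetic
#' variance get `NA` correlations.
#'
#' @param fa an `"fa_fit"`.
#' @return site-by-site numeric matrix.
#' @export
genetic_correlations <- function(fa) {
  stopifnot(inherits(fa, "fa_fit"))
  out <- fa$correlations
  diag(out) <- diag(fa$Sigma)
  out
}

#' Biplot coordinates from a factor-analytic fit
#'
#' Rotates the loading matrix to its principal axes (singular-value
#' orientation) and applies the matching rotation to the genotype factor
#' scores. The cosine of the angle between two site vectors approximates
#' their genetic correlation; a site's distance from the origin reflects its
#' genetic variance, i.e. its power to discriminate genotypes.
#'
#' @param fa a two-factor `"fa_fit"`.
#' @return list with `sites` (sites x 2 rotated loadings) and `scores`
#'   (lines x 2 rotated factor scores).
#' @export
biplot_coordinates <- function(fa) {
  stopifnot(inherits(fa, "fa_fit"))
  if (fa$n_factors < 2L) stop("biplot needs a 2-factor fit")
  sv <- svd(fa$loadings)
  sites <- sv$u[, 1:2, drop = FALSE] %*% diag(sv$d[1:2], 2)
  rownames(sites) <- fa$sites
  scores <- fa$scores %*% sv$v[, 1:2, drop = FALSE]
  rownames(scores) <- fa$lines
  list(sites = sites, scores = scores)
}

#' Biplot of a factor-analytic fit
#'
#' @param x an `"fa_fit"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fa_fit <- function(x, ...) {
  bp <- biplot_coordinates(x)
  rng <- range(bp$scores, bp$sites)
  graphics::plot(bp$scores, pch = 16, cex = 0.5, col = "grey50",
                 xlab = "Factor 1", ylab = "Factor 2",
                 xlim = rng, ylim = rng, ...)
  graphics::abline(h = 0, v = 0, col = "grey80", lty = 2)
  graphics::arrows(0, 0, bp$sites[, 1], bp$sites[, 2],
                   length = 0.08, col = "red3")
  graphics::text(bp$sites, labels = rownames(bp$sites), pos = 3,
                 col = "red3")
  invisible(bp)
}
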