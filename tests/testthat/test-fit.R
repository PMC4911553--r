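quick_ctl <- function(seed = 1, n_iter = 1500, burn_in = 300, thin = 3) {
  mcmc_control(n_iter = n_iter, burn_in = burn_in, thin = thin, seed = seed)
}

test_that("IID-kernel variance recovery at large n", {
  ## single IID line kernel observed with two plots per line, so the
  ## genetic and residual variances are separately identified;
  ## truth sigma2_g = sigma2_e = 1
  n_lines <- 300
  lines <- sprintf("L%03d", seq_len(n_lines))
  obs <- data.frame(site = "S1", line = rep(lines, each = 2), y = NA)
  K <- expand_to_observations(
    `dimnames<-`(diag(n_lines), list(lines, lines)), obs$line)
  ks <- kernel_set(list(G = K), obs)
  est <- matrix(NA_real_, 10, 2)
  calibrated <- 0
  for (s in 1:10) {
    set.seed(100 + s)
    g <- rnorm(n_lines)
    y <- 3 + g[rep(seq_len(n_lines), each = 2)] + rnorm(2 * n_lines)
    ks$obs$y <- y
    fit <- fit_rnm(ks, control = quick_ctl(seed = s, n_iter = 2500,
                                           burn_in = 500))
    vc <- fit$variance_components
    est[s, ] <- vc$mean[match(c("G", "eps"), vc$term)]
    z <- abs(est[s, ] - 1) / vc$sd[match(c("G", "eps"), vc$term)]
    calibrated <- calibrated + all(z <= 3)
  }
  ## unbiased across seeds at the 15% tolerance, calibrated within seeds
  expect_lt(abs(mean(est[, 1]) - 1), 0.15)
  expect_lt(abs(mean(est[, 2]) - 1), 0.15)
  expect_gte(calibrated, 9)
})

test_that("constant response degenerates gracefully", {
  obs <- data.frame(site = "S1", line = paste0("L", 1:20), y = 4)
  ks <- kernel_set(list(G = diag(20)), obs)
  fit <- fit_rnm(ks, control = quick_ctl())
  expect_equal(fit$mu, 4, tolerance = 1e-3)
  expect_true(all(fit$variance_components$mean < 1e-4))
  expect_true(all(fit$variance_components$mean > 0))
})

test_that("fits are deterministic given the seed", {
  met <- small_met(seed = 55, n_lines = 30, n_markers = 80)
  f1 <- rnm("E+W+G", met, control = quick_ctl(seed = 99))
  f2 <- rnm("E+W+G", met, control = quick_ctl(seed = 99))
  expect_identical(f1$yhat, f2$yhat)
  expect_identical(f1$variance_components, f2$variance_components)
  f3 <- rnm("E+W+G", met, control = quick_ctl(seed = 100))
  expect_false(identical(f1$yhat, f3$yhat))
})

test_that("fitted values reconstruct from posterior-mean components", {
  met <- small_met(seed = 56, n_lines = 30, n_markers = 80)
  fit <- rnm("E+W+G+A", met, control = quick_ctl(seed = 5))
  recon <- fit$mu + Reduce(`+`, fit$effects)
  expect_lt(max(abs(recon - fit$yhat)), 1e-8)
  expect_true(all(fit$variance_components$mean > 0))
  r <- residuals(fit)
  expect_equal(r, fit$y - fitted(fit))
})

test_that("factor-basis path agrees with dense eigendecomposition path", {
  met <- small_met(seed = 57, n_lines = 16, n_sites = 3, n_markers = 50)
  acc <- met$pheno[!met$pheno$check, ]
  ks <- build_kernel_set("E+W+G", acc, met$markers,
                         env_covariates = met$env_covariates)
  ctl <- mcmc_control(n_iter = 6000, burn_in = 1000, thin = 2, seed = 8)
  f1 <- fit_rnm(ks, control = ctl, use_factors = TRUE)
  f2 <- fit_rnm(ks, control = ctl, use_factors = FALSE)
  ## same posterior up to Monte-Carlo error
  expect_lt(max(abs(f1$yhat - f2$yhat)), 0.2)
  expect_gt(cor(f1$yhat, f2$yhat), 0.995)
})

test_that("posterior mean gBLUP matches the closed form at fixed variances", {
  set.seed(42)
  n <- 30
  X <- simulate_markers(n, 120, seed = 5)
  G <- genomic_relationship(X)
  y <- drop(t(chol(G + diag(1e-8, n))) %*% rnorm(n)) + rnorm(n, 0, 0.5) + 5
  obs <- data.frame(site = "S1", line = rownames(X), y = y)
  ks <- kernel_set(list(G = G), obs)
  fit <- fit_rnm(ks, control = mcmc_control(n_iter = 12000, burn_in = 2000,
                                            thin = 2, seed = 7),
                 fixed_variances = c(G = 1, eps = 0.25))
  ghat <- drop(G %*% solve(G + diag(0.25, n), y - fit$mu))
  dev <- abs(fit$effects$G - ghat) / pmax(fit$effects_sd$G, 1e-12)
  expect_lt(max(dev), 3)
})

test_that("prediction interface handles masked and out-of-range targets", {
  met <- small_met(seed = 58, n_lines = 40, n_markers = 80,
                   vc = c(E = 1, w = 0.3, g = 1, eps = 0.01))
  acc <- met$pheno[!met$pheno$check, ]
  ## mask one plot of a line replicated within a site: with tiny residual
  ## variance the prediction should sit near the observed duplicate
  key <- paste(acc$site, acc$line)
  dupkey <- names(which(table(key) >= 2))[1]
  idx <- which(key == dupkey)
  mask <- rep(FALSE, nrow(acc))
  mask[idx[1]] <- TRUE
  ks <- build_kernel_set("E+W+G", acc, met$markers,
                         env_covariates = met$env_covariates)
  fit <- fit_rnm(ks, mask = mask, control = quick_ctl(seed = 2,
                                                      n_iter = 3000,
                                                      burn_in = 600))
  pred <- predict(fit)
  expect_named(pred, as.character(idx[1]))
  expect_lt(abs(pred - acc$y[idx[2]]), 0.35)
  expect_error(predict(fit, targets = nrow(acc) + 5), "not in the kernel")
})

test_that("errors: all-masked responses and unknown fixed variances", {
  obs <- data.frame(site = "S1", line = paste0("L", 1:5), y = rnorm(5))
  ks <- kernel_set(list(G = diag(5)), obs)
  expect_error(fit_rnm(ks, mask = rep(TRUE, 5)), "all responses are masked")
  expect_error(fit_rnm(ks, fixed_variances = c(H = 1)), "fixed_variances")
  expect_error(kernel_set(list(G = matrix(1:25, 5)), obs), "not symmetric")
})

test_that("a line with no genomic relationship is predicted from site terms", {
  met <- small_met(seed = 59, n_lines = 30, n_markers = 60,
                   vc = c(E = 1, w = 0.3, g = 1, eps = 0.3))
  acc <- met$pheno[!met$pheno$check, ]
  ks <- build_kernel_set("E+W+G", acc, met$markers,
                         env_covariates = met$env_covariates)
  ## zero out the G rows of one line: no information flows to it through G
  ln <- acc$line[1]
  rows <- which(acc$line == ln)
  ks$kernels$G[rows, ] <- 0
  ks$kernels$G[, rows] <- 0
  ks$factors <- NULL   # force dense path on the edited kernel
  mask <- seq_len(nrow(acc)) %in% rows
  fit <- fit_rnm(ks, mask = mask, control = quick_ctl(seed = 3))
  expected <- fit$mu + fit$effects$E[rows] + fit$effects$W[rows]
  expect_equal(unname(predict(fit, rows)), expected, tolerance = 1e-8)
})
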