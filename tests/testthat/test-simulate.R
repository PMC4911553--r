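test_that("simulated markers respect frequency bounds, polymorphism, seed", {
  X <- simulate_markers(200, 300, c(0.1, 0.9), seed = 42)
  expect_equal(dim(X), c(200, 300))
  f <- colMeans(X)
  expect_true(all(f >= 0.1 & f <= 0.9))
  expect_true(all(apply(X, 2, function(v) length(unique(v))) > 1))
  expect_identical(X, simulate_markers(200, 300, c(0.1, 0.9), seed = 42))

  ## degenerate (equal-bound) range: column still polymorphic
  X2 <- simulate_markers(2, 1, c(0.5, 0.5), seed = 3)
  expect_gt(length(unique(X2[, 1])), 1)

  Xd <- simulate_markers(50, 20, coding = "dosage", seed = 1)
  expect_true(all(Xd %in% 0:2))
  expect_error(simulate_markers(10, 5, c(0, 0.9)), "lower bound")
  expect_error(simulate_markers(10, 5, c(0.1, 1)), "upper bound")
  expect_error(simulate_markers(10, 5, c(0.8, 0.2)), "empty")
})

test_that("simulated pedigrees are acyclic with correct relationships", {
  ped <- simulate_pedigree(10, 3, 4, seed = 7)
  ## parents precede offspring
  pos <- seq_len(nrow(ped))
  names(pos) <- ped$id
  ok <- is.na(ped$parent1) | pos[ped$parent1] < pos
  expect_true(all(ok, na.rm = TRUE))
  A <- additive_relationship(ped)
  expect_equal(unname(diag(A)[1:10]), rep(1, 10))  # non-inbred founders

  ped1 <- simulate_pedigree(2, 1, 1, seed = 1)
  A1 <- additive_relationship(ped1)
  off <- ped1$id[3]
  expect_equal(unname(A1[off, ped1$id[1]]), 0.5)

  ## full sibs from non-inbred unrelated parents have A = 0.5
  ped2 <- simulate_pedigree(50, 4, 2, seed = 3)
  A2 <- additive_relationship(ped2)
  g1 <- ped2[grepl("^G1_", ped2$id), ]
  fs <- g1[g1$parent1 == g1$parent1[1] & g1$parent2 == g1$parent2[1], "id"]
  expect_equal(unname(A2[fs[1], fs[2]]), 0.5)
  expect_identical(ped2, simulate_pedigree(50, 4, 2, seed = 3))
})

test_that("environmental covariables have spread and are seed-stable", {
  W <- simulate_env_covariates(5, 5, seed = 2)
  expect_equal(dim(W), c(5, 5))
  expect_true(all(apply(W, 2, var) > 0))
  expect_identical(W, simulate_env_covariates(5, 5, seed = 2))

  ## two sites standardize to a symmetric pair (+-1 on the population
  ## scale, +-1/sqrt(2) with the sample-sd denominator R uses)
  W2 <- simulate_env_covariates(2, 1, seed = 9)
  expect_equal(sort(as.numeric(scale(W2))), c(-1, 1) / sqrt(2))
})

test_that("p-rep design hits the target replication and check fractions", {
  cfg <- sim_config(n_lines = 803, n_sites = 2, seed = 4)
  skel <- simulate_design(cfg)
  for (s in unique(skel$site)) {
    d <- skel[skel$site == s, ]
    acc <- d[!d$check, ]
    reps <- table(table(acc$line))
    prop <- as.numeric(reps) / length(unique(acc$line))
    expect_lt(abs(prop[1] - 0.81), 0.02)
    expect_lt(abs(prop[2] - 0.15), 0.02)
    expect_lt(abs(prop[3] - 0.04), 0.02)
    expect_lt(abs(mean(d$check) - 0.06), 0.02)
  }
  ## every skeleton line is registered
  expect_true(all(grepl("^(L\\d+|CHK\\d)$", skel$line)))

  cfg1 <- sim_config(n_lines = 40, n_sites = 2, n_checks = 0,
                     prep_fractions = c(1, 0, 0), check_plot_fraction = 0,
                     seed = 1)
  skel1 <- simulate_design(cfg1)
  expect_true(all(table(skel1$line, skel1$site) == 1))

  expect_error(simulate_design(
    sim_config(n_lines = 40, n_checks = 0, check_plot_fraction = 0.06)),
    "n_checks = 0")
})

test_that("phenotype generator honours its variance structure", {
  ## pure noise: sample variance close to 1
  cfg <- sim_config(n_lines = 150, n_sites = 3, n_markers = 50, n_checks = 0,
                    check_plot_fraction = 0,
                    variance_components = c(eps = 1), seed = 8)
  met <- simulate_met(cfg)
  n <- nrow(met$pheno)
  v <- var(met$pheno$y)
  ## chi-square bounds on the sample variance at this n
  expect_gt(v, qchisq(0.0005, n - 1) / (n - 1))
  expect_lt(v, qchisq(0.9995, n - 1) / (n - 1))
  expect_equal(mean(met$pheno$y), cfg$mu, tolerance = 0.1)

  ## line-level genetic effect identical across plots of a line in a site
  cfg2 <- sim_config(n_lines = 40, n_sites = 2, n_markers = 60, n_checks = 0,
                     check_plot_fraction = 0, prep_fractions = c(0, 1, 0),
                     variance_components = c(g = 1), seed = 9)
  met2 <- simulate_met(cfg2)
  ph <- met2$pheno
  sp <- split(ph$y, paste(ph$site, ph$line))
  expect_true(all(sapply(sp, function(v) diff(range(v)) < 1e-12)))
  ## and the realized values match the recorded truth
  gv <- met2$truth$effects$g
  one <- ph[ph$site == "S1", ]
  expect_equal(one$y - cfg2$mu, unname(gv[one$line]))
})

test_that("interaction term covariance converges to the Hadamard kernel", {
  ## Monte-Carlo check: with only sigma2_gE active, cov(y_r, y_s) over
  ## replicate simulations approximates G_jj' within site and 0 across
  cfg <- sim_config(n_lines = 6, n_sites = 2, n_markers = 80, n_checks = 0,
                    check_plot_fraction = 0, prep_fractions = c(1, 0, 0),
                    variance_components = c(gE = 1), seed = 30)
  skel <- simulate_design(cfg, seed = 1)
  X <- simulate_markers(6, 80, seed = 2, line_ids = sort(unique(skel$line)))
  ped <- data.frame(id = sort(unique(skel$line)), parent1 = NA, parent2 = NA)
  W <- simulate_env_covariates(2, 3, seed = 3)
  n <- nrow(skel)
  Y <- matrix(0, 500, n)
  for (r in seq_len(500)) {
    Y[r, ] <- simulate_phenotypes(skel, X, ped, W, cfg, seed = 1000 + r)$pheno$y
  }
  emp <- cov(Y)
  G <- genomic_relationship(X)
  K <- interaction_kernel(expand_to_observations(G, skel$line),
                          outer(skel$site, skel$site, "==") * 1)
  ## elementwise within 3 Monte-Carlo standard errors (var of a covariance
  ## of bivariate normals ~ (K_rr K_ss + K_rs^2)/R)
  se <- sqrt((outer(diag(K), diag(K)) + K^2) / 500)
  expect_true(all(abs(emp - K) <= pmax(3 * se, 0.05)))
})

test_that("whole-trial generator is deterministic and cross-referenced", {
  met <- small_met(seed = 77)
  met2 <- small_met(seed = 77)
  expect_identical(met$pheno, met2$pheno)
  expect_identical(met$markers, met2$markers)
  acc <- unique(met$pheno$line[!met$pheno$check])
  expect_true(all(acc %in% rownames(met$markers)))
  expect_true(all(acc %in% met$pedigree$id))
  expect_true(all(unique(met$pheno$site) %in% rownames(met$env_covariates)))
  ## zero-variance terms identically zero
  expect_true(all(met$truth$effects$L == 0))
})
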