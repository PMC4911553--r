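test_that("genomic relationship matches hand computation and loop oracle", {
  ## 2x2 identity-coded matrix, centered: Xc = [[.5,-.5],[-.5,.5]],
  ## G = Xc Xc' / 2 = [[0.25,-0.25],[-0.25,0.25]]
  X <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("a", "b"), NULL))
  G <- genomic_relationship(X)
  expect_equal(unname(G), matrix(c(0.25, -0.25, -0.25, 0.25), 2, 2))

  set.seed(7)
  X <- matrix(rbinom(20 * 100, 1, 0.4), 20, 100,
              dimnames = list(sprintf("L%02d", 1:20), NULL))
  expect_lt(max(abs(genomic_relationship(X, center = FALSE, scale_mode = "p") -
                      loop_gmat(X, center = FALSE))), 1e-12)
  expect_lt(max(abs(genomic_relationship(X) - loop_gmat(X))), 1e-12)

  G <- genomic_relationship(X)
  expect_true(isSymmetric(G))
  expect_gte(sum(diag(G)), 0)
  expect_error(genomic_relationship(X[, 0]), "p = 0")
  expect_error(genomic_relationship(X[1, , drop = FALSE]), "2 lines")
})

test_that("additive relationship reproduces tabular-method results", {
  founders <- data.frame(id = c("f1", "f2"), parent1 = NA, parent2 = NA)
  expect_equal(unname(additive_relationship(founders)), diag(2))

  trio <- rbind(founders,
                data.frame(id = "kid", parent1 = "f1", parent2 = "f2"))
  A <- additive_relationship(trio)
  expect_equal(A["kid", "kid"], 1)
  expect_equal(A["kid", "f1"], 0.5)
  expect_equal(A["kid", "f2"], 0.5)

  sibs <- rbind(trio,
                data.frame(id = "kid2", parent1 = "f1", parent2 = "f2"))
  A <- additive_relationship(sibs)
  expect_equal(A["kid", "kid2"], 0.5)

  ## generated pedigree vs the independent tabular oracle
  ped <- simulate_pedigree(12, n_generations = 3, offspring_per_cross = 3,
                           seed = 5)
  A <- additive_relationship(ped)
  expect_lt(max(abs(A - tabular_A(ped)[rownames(A), rownames(A)])), 1e-12)

  cyc <- data.frame(id = c("x", "y"), parent1 = c("y", "x"),
                    parent2 = NA)
  expect_error(additive_relationship(cyc), "cycle")
})

test_that("environmental kernel matches its loop oracle and flags constants", {
  W <- diag(2); rownames(W) <- c("s1", "s2")
  expect_equal(unname(env_kernel(W, standardize = FALSE)), 0.5 * diag(2))

  set.seed(3)
  W <- matrix(rnorm(25, 20, 4), 5, 5,
              dimnames = list(paste0("s", 1:5), paste0("ec", 1:5)))
  expect_lt(max(abs(env_kernel(W) - loop_env(W))), 1e-12)

  ## identical covariable rows => perfect similarity
  W2 <- rbind(W, W[5, , drop = FALSE])
  rownames(W2)[6] <- "s6"
  Om <- env_kernel(W2)
  expect_equal(Om["s5", "s6"], Om["s5", "s5"])

  Wc <- cbind(W, const = 1)
  expect_error(env_kernel(Wc), "zero-variance")
})

test_that("observation expansion and Hadamard products match loop oracles", {
  set.seed(11)
  lines <- paste0("L", 1:6)
  K <- crossprod(matrix(rnorm(36), 6, 6)) / 6
  dimnames(K) <- list(lines, lines)
  map <- sample(lines, 25, replace = TRUE)
  expect_equal(expand_to_observations(K, map), loop_expand(K, map))
  expect_error(expand_to_observations(K, c(map, "Lx")), "Lx")

  ## identity line kernel, two plots of one line -> block of ones
  I2 <- diag(2); dimnames(I2) <- list(c("u", "v"), c("u", "v"))
  Ko <- expand_to_observations(I2, c("u", "u", "v"))
  expect_equal(Ko[1:2, 1:2], matrix(1, 2, 2))

  Kobs <- expand_to_observations(K, map)
  ones <- matrix(1, 25, 25)
  expect_equal(interaction_kernel(Kobs, ones), Kobs)
  expect_equal(interaction_kernel(Kobs, diag(25)),
               diag(diag(Kobs)))
  expect_error(interaction_kernel(Kobs, diag(10)), "mismatch")

  ## 4-observation hand case: 2 lines x 2 sites, one plot each;
  ## GE entry is G_jj' within site, 0 across sites
  site <- c("s1", "s1", "s2", "s2")
  line <- c("L1", "L2", "L1", "L2")
  Gs <- K[1:2, 1:2]
  Gobs <- expand_to_observations(Gs, line)
  Eobs <- outer(site, site, "==") * 1
  GE <- interaction_kernel(Gobs, Eobs)
  expect_equal(GE[1, 2], Gs["L1", "L2"])
  expect_equal(GE[1, 3], 0)   # same line, different site
  expect_equal(GE[2, 3], 0)
})

test_that("build_kernel_set assembles exactly the named model's kernels", {
  met <- small_met()
  expect_setequal(rnm_models(),
                  c("E+L", "L+E+W", "E+W+G", "E+W+G+GE", "E+W+A",
                    "E+W+A+AE", "E+W+G+A", "E+W+G+A+GE+AE"))
  cases <- list("E+L" = c("E", "L"),
                "L+E+W" = c("E", "L", "W"),
                "E+W+G" = c("E", "W", "G"),
                "E+W+G+A" = c("E", "W", "G", "A"),
                "E+W+G+A+GE+AE" = c("E", "W", "G", "A", "GE", "AE"))
  for (nm in names(cases)) {
    ks <- suppressMessages(
      build_kernel_set(nm, met$pheno, met$markers, met$pedigree,
                       met$env_covariates))
    expect_named(ks$kernels, cases[[nm]])
  }
  expect_error(build_kernel_set("E+G", met$pheno, met$markers),
               "E\\+W\\+G\\+A\\+GE\\+AE")
  expect_error(suppressMessages(
    build_kernel_set("E+W+G", met$pheno, markers = NULL,
                     env_covariates = met$env_covariates)), "marker")
})

test_that("every emitted kernel is symmetric PSD and factor-consistent", {
  met <- small_met(seed = 202, n_lines = 15, n_sites = 3, n_markers = 60)
  ks <- suppressMessages(
    build_kernel_set("E+W+G+A+GE+AE", met$pheno, met$markers, met$pedigree,
                     met$env_covariates))
  for (nm in names(ks$kernels)) {
    expect_true(check_kernel(ks$kernels[[nm]]), label = nm)
    expect_lt(max(abs(tcrossprod(ks$factors[[nm]]) - ks$kernels[[nm]])),
              1e-10)
  }
})

test_that("kernels are invariant to line-order permutation of the inputs", {
  set.seed(23)
  X <- matrix(rbinom(10 * 50, 1, 0.5), 10, 50,
              dimnames = list(paste0("L", 1:10), NULL))
  G1 <- genomic_relationship(X)
  perm <- sample(10)
  G2 <- genomic_relationship(X[perm, ])
  expect_equal(G2[rownames(G1), rownames(G1)], G1)

  ped <- simulate_pedigree(8, 2, 3, seed = 9)
  A1 <- additive_relationship(ped)
  ped2 <- ped[c(nrow(ped):1), ]   # reversed record order, still acyclic
  A2 <- additive_relationship(ped2)
  expect_equal(A2[rownames(A1), colnames(A1)], A1)
})
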