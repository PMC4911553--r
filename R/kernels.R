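#' Genomic relationship matrix from marker codes
#'
#' Computes the marker-based relationship matrix \eqn{G = X_c X_c' / p} from a
#' lines-by-markers matrix of numeric codes (presence/absence 0/1 or SNP
#' dosages 0/1/2), where \eqn{p} is the number of markers and \eqn{X_c} is the
#' (optionally column-centered) code matrix.
#'
#' @param X numeric matrix, lines in rows (rownames are the line identifiers),
#'   markers in columns. Missing codes must be imputed beforehand (see
#'   [read_met_inputs()]).
#' @param center center marker columns before forming the cross-product
#'   (default `TRUE`). Centering removes allele-frequency mean effects while
#'   keeping the \eqn{1/p} denominator.
#' @param scale_mode `"p"` divides by the number of markers; `"vanraden"`
#'   divides by \eqn{2\sum_q p_q(1-p_q)} with \eqn{p_q} the allele frequency
#'   of marker \eqn{q} (dosage coding assumed); `"none"` applies no
#'   denominator.
#' @return symmetric positive semidefinite matrix of dimension
#'   `nrow(X)` with the line identifiers as dimnames.
#' @seealso [additive_relationship()], [env_kernel()], [build_kernel_set()]
#' @export
genomic_relationship <- function(X, center = TRUE,
                                 scale_mode = c("p", "vanraden", "none")) {
  scale_mode <- match.arg(scale_mode)
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("genomic_relationship() needs at least 2 lines")
  if (ncol(X) == 0L) stop("marker matrix has p = 0 columns")
  if (anyNA(X)) stop("marker matrix contains missing codes; impute first")
  freq <- colMeans(X) / max(1, max(X))   # allele frequency on the coding scale
  Xc <- if (center) sweep(X, 2L, colMeans(X), "-") else X
  denom <- switch(scale_mode,
    p        = ncol(X),
    vanraden = 2 * sum((colMeans(X) / 2) * (1 - colMeans(X) / 2)),
    none     = 1
  )
  if (denom <= 0) stop("degenerate denominator in scale_mode = ", scale_mode)
  G <- tcrossprod(Xc) / denom
  dimnames(G) <- list(rownames(X), rownames(X))
  (G + t(G)) / 2
}

#' Pedigree-based additive relationship matrix
#'
#' Builds the numerator (additive) relationship matrix A by the recursive
#' tabular method: \eqn{A_{ii} = 1 + \frac{1}{2}A_{fm}} and
#' \eqn{A_{ij} = \frac{1}{2}(A_{jf} + A_{jm})} where f, m are the parents of
#' i. Unknown parents contribute zero relationship.
#'
#' @param pedigree data frame with columns `id`, `parent1`, `parent2`
#'   (character; `NA` for unknown parents). Records may appear in any order as
#'   long as the pedigree is acyclic.
#' @return symmetric PSD matrix over all pedigree members, in topological
#'   (ancestors-first) order, with ids as dimnames. Subset rows/columns to
#'   restrict to the lines of interest.
#' @export
additive_relationship <- function(pedigree) {
  ped <- as.data.frame(pedigree)
  need <- c("id", "parent1", "parent2")
  if (!all(need %in% names(ped))) {
    stop("pedigree needs columns: ", paste(need, collapse = ", "))
  }
  id <- as.character(ped$id)
  if (anyDuplicated(id)) {
    stop("duplicate pedigree ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  p1 <- as.character(ped$parent1)
  p2 <- as.character(ped$parent2)
  p1[!(p1 %in% id)] <- NA   # parents outside the file are treated as unknown
  p2[!(p2 %in% id)] <- NA

  ## Kahn topological sort; leftover individuals participate in a cycle.
  n <- length(id)
  ord <- integer(0)
  placed <- logical(n)
  repeat {
    ready <- which(!placed &
                     (is.na(p1) | p1 %in% id[placed]) &
                     (is.na(p2) | p2 %in% id[placed]))
    if (!length(ready)) break
    ord <- c(ord, ready)
    placed[ready] <- TRUE
  }
  if (!all(placed)) {
    stop("pedigree contains a cycle involving: ",
         paste(id[!placed], collapse = ", "))
  }

  ids <- id[ord]
  f <- match(p1[ord], ids)
  m <- match(p2[ord], ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    afm <- if (!is.na(f[i]) && !is.na(m[i])) A[f[i], m[i]] else 0
    A[i, i] <- 1 + 0.5 * afm
    if (i > 1L) {
      j <- seq_len(i - 1L)
      av <- numeric(i - 1L)
      if (!is.na(f[i])) av <- av + A[j, f[i]]
      if (!is.na(m[i])) av <- av + A[j, m[i]]
      A[j, i] <- A[i, j] <- 0.5 * av
    }
  }
  A
}

#' Environmental similarity kernel from site covariables
#'
#' Forms \eqn{\Omega = W_s W_s' / Q} from a sites-by-Q table of environmental
#' covariables (e.g. temperature summaries over growth phases). The covariance
#' of a random regression on the covariables with IID coefficient effects is
#' proportional to \eqn{W W'}; dividing by Q and standardizing columns puts
#' the associated variance component on the scale of the other model terms.
#'
#' @param W numeric matrix or data frame, sites in rows (rownames are site
#'   identifiers), covariables in columns.
#' @param standardize center and scale each covariable column (default
#'   `TRUE`). A constant column is an error under standardization.
#' @return symmetric PSD site-level matrix with site ids as dimnames.
#' @export
env_kernel <- function(W, standardize = TRUE) {
  W <- as.matrix(W)
  if (nrow(W) < 2L) stop("env_kernel() needs at least 2 sites")
  if (ncol(W) < 1L) stop("env_kernel() needs at least 1 covariable")
  if (any(!is.finite(W))) stop("covariable table has non-finite values")
  if (standardize) {
    sds <- apply(W, 2L, stats::sd)
    if (any(sds == 0)) {
      stop("zero-variance covariable column(s) under standardization: ",
           paste(colnames(W)[sds == 0], collapse = ", "))
    }
    W <- scale(W)
  }
  Om <- tcrossprod(W) / ncol(W)
  dimnames(Om) <- list(rownames(W), rownames(W))
  (Om + t(Om)) / 2
}

#' Expand a level-indexed kernel to the observation level
#'
#' Given a kernel over the levels of a factor (lines or sites) and the level
#' of each observation, returns the observation-level kernel
#' \eqn{K_{obs}[r,s] = K[level(r), level(s)]}, i.e. \eqn{Z K Z'} for the
#' incidence matrix Z. PSD is preserved.
#'
#' @param K level-indexed symmetric matrix with level names as dimnames.
#' @param map character (or factor) vector mapping each observation to a level
#'   of `K`.
#' @return `length(map)` square matrix.
#' @export
expand_to_observations <- function(K, map) {
  map <- as.character(map)
  miss <- setdiff(unique(map), rownames(K))
  if (length(miss)) {
    stop("observations map to levels absent from the kernel: ",
         paste(miss, collapse = ", "))
  }
  idx <- match(map, rownames(K))
  Ko <- K[idx, idx, drop = FALSE]
  dimnames(Ko) <- NULL
  Ko
}

#' Hadamard interaction kernel
#'
#' Elementwise (cell-by-cell) product of two observation-level covariance
#' structures; the covariance a reaction-norm interaction term induces is the
#' Hadamard product of the main-effect structures. PSD of the factors implies
#' PSD of the product (Schur product theorem).
#'
#' @param K1,K2 observation-level kernels of identical dimension sharing one
#'   observation ordering.
#' @return elementwise product `K1 * K2`.
#' @export
interaction_kernel <- function(K1, K2) {
  if (!all(dim(K1) == dim(K2))) {
    stop("interaction_kernel(): dimension mismatch (",
         paste(dim(K1), collapse = "x"), " vs ",
         paste(dim(K2), collapse = "x"), ")")
  }
  K1 * K2
}

#' @keywords internal
.rnm_model_names <- c("E+L", "L+E+W", "E+W+G", "E+W+G+GE", "E+W+A",
                      "E+W+A+AE", "E+W+G+A", "E+W+G+A+GE+AE")

#' Model names available to [build_kernel_set()] and [rnm()]
#' @return character vector of the eight supported model names.
#' @export
rnm_models <- function() .rnm_model_names

## Kernel membership per model: E and L are IID level-indicator structures,
## W the environmental-covariable kernel, G genomic, A pedigree, GE/AE their
## Hadamard interactions with the site-indicator structure.
.model_terms <- function(model) {
  switch(model,
    "E+L"            = c("E", "L"),
    "L+E+W"          = c("E", "L", "W"),
    "E+W+G"          = c("E", "W", "G"),
    "E+W+G+GE"       = c("E", "W", "G", "GE"),
    "E+W+A"          = c("E", "W", "A"),
    "E+W+A+AE"       = c("E", "W", "A", "AE"),
    "E+W+G+A"        = c("E", "W", "G", "A"),
    "E+W+G+A+GE+AE"  = c("E", "W", "G", "A", "GE", "AE"),
    stop("unknown model '", model, "'; valid names: ",
         paste(.rnm_model_names, collapse = ", "))
  )
}

#' Build the kernel set of a named reaction-norm model
#'
#' Assembles the observation-level covariance structures of one of the eight
#' supported models. `E` and `L` are site- and line-indicator structures (IID
#' level effects), `W` the expansion of the environmental kernel
#' \eqn{\Omega}, `G`/`A` expansions of the genomic/pedigree relationship
#' matrices, and `GE`/`AE` Hadamard products of the latter with the
#' site-indicator structure.
#'
#' Check plots are design infrastructure without marker or pedigree rows;
#' they are dropped from the observation set (with a message) before kernels
#' are formed.
#'
#' @param model one of [rnm_models()].
#' @param pheno plot-level phenotype data frame with columns `site`, `line`,
#'   optionally `check` (logical) and a response column; its row order fixes
#'   the observation ordering of every kernel.
#' @param markers,pedigree,env_covariates inputs needed by the named model:
#'   a marker matrix for G/GE, a pedigree data frame for A/AE, a site
#'   covariable table for W. Unused inputs may be `NULL`.
#' @param g_center,g_scale_mode passed to [genomic_relationship()].
#' @param standardize_env passed to [env_kernel()].
#' @return object of class `"kernel_set"`: list with elements `kernels`
#'   (named list of n_obs x n_obs matrices), `obs` (the retained phenotype
#'   rows), `model`, and `factors` (low-rank factorizations used by the
#'   sampler).
#' @export
build_kernel_set <- function(model, pheno, markers = NULL, pedigree = NULL,
                             env_covariates = NULL, g_center = TRUE,
                             g_scale_mode = "p", standardize_env = TRUE) {
  terms <- .model_terms(model)
  pheno <- as.data.frame(pheno)
  if (!all(c("site", "line") %in% names(pheno))) {
    stop("pheno needs 'site' and 'line' columns")
  }
  if ("check" %in% names(pheno) && any(pheno$check)) {
    message("dropping ", sum(pheno$check), " check plots from the kernel set")
    pheno <- pheno[!pheno$check, , drop = FALSE]
  }
  rownames(pheno) <- NULL
  n <- nrow(pheno)
  site <- as.character(pheno$site)
  line <- as.character(pheno$line)

  missing_input <- function(what, term) {
    stop("model '", model, "' requires ", what, " (term ", term, ")")
  }
  kernels <- list()
  factors <- list()

  ind_factor <- function(f) {
    lev <- unique(f)
    Z <- matrix(0, n, length(lev), dimnames = list(NULL, lev))
    Z[cbind(seq_len(n), match(f, lev))] <- 1
    Z
  }
  ## factorize a PSD level kernel as Phi Phi' via its eigendecomposition
  level_factor <- function(K, map) {
    ee <- eigen(K, symmetric = TRUE)
    keep <- ee$values > 1e-12 * max(ee$values, 0)
    Phi <- ee$vectors[, keep, drop = FALSE] %*%
      diag(sqrt(ee$values[keep]), sum(keep))
    rownames(Phi) <- rownames(K)
    Phi[map, , drop = FALSE]
  }

  G_line <- NULL
  A_line <- NULL
  if (any(c("G", "GE") %in% terms)) {
    if (is.null(markers)) missing_input("a marker matrix", "G")
    miss <- setdiff(unique(line), rownames(markers))
    if (length(miss)) {
      stop("lines without marker rows: ",
           paste(utils::head(miss, 10L), collapse = ", "))
    }
    G_line <- genomic_relationship(markers, center = g_center,
                                   scale_mode = g_scale_mode)
  }
  if (any(c("A", "AE") %in% terms)) {
    if (is.null(pedigree)) missing_input("a pedigree", "A")
    A_all <- additive_relationship(pedigree)
    miss <- setdiff(unique(line), rownames(A_all))
    if (length(miss)) {
      stop("lines absent from the pedigree: ",
           paste(utils::head(miss, 10L), collapse = ", "))
    }
    A_line <- A_all[unique(line), unique(line), drop = FALSE]
  }

  for (tm in terms) {
    if (tm == "E") {
      Z <- ind_factor(site)
      kernels$E <- tcrossprod(Z); factors$E <- Z
    } else if (tm == "L") {
      Z <- ind_factor(line)
      kernels$L <- tcrossprod(Z); factors$L <- Z
    } else if (tm == "W") {
      if (is.null(env_covariates)) missing_input("an env covariable table", "W")
      miss <- setdiff(unique(site), rownames(env_covariates))
      if (length(miss)) {
        stop("sites absent from the covariable table: ",
             paste(miss, collapse = ", "))
      }
      Om <- env_kernel(env_covariates, standardize = standardize_env)
      kernels$W <- expand_to_observations(Om, site)
      factors$W <- level_factor(Om, site)
    } else if (tm == "G") {
      kernels$G <- expand_to_observations(G_line, line)
      factors$G <- level_factor(G_line, line)
    } else if (tm == "A") {
      kernels$A <- expand_to_observations(A_line, line)
      factors$A <- level_factor(A_line, line)
    } else if (tm %in% c("GE", "AE")) {
      Kl <- if (tm == "GE") G_line else A_line
      Kobs <- expand_to_observations(Kl, line)
      Eobs <- kernels$E
      if (is.null(Eobs)) Eobs <- tcrossprod(ind_factor(site))
      kernels[[tm]] <- interaction_kernel(Kobs, Eobs)
      ## site-blocked factor: Phi Phi' = K[l_r, l_s] * 1[site_r = site_s]
      Pl <- level_factor(Kl, line)
      sl <- unique(site)
      Phi <- matrix(0, n, ncol(Pl) * length(sl))
      for (si in seq_along(sl)) {
        rows <- which(site == sl[si])
        cols <- (si - 1L) * ncol(Pl) + seq_len(ncol(Pl))
        Phi[rows, cols] <- Pl[rows, , drop = FALSE]
      }
      factors[[tm]] <- Phi
    }
  }

  structure(list(kernels = kernels, obs = pheno, model = model,
                 factors = factors),
            class = "kernel_set")
}

#' Assemble a kernel set from explicit observation-level kernels
#'
#' Lower-level companion of [build_kernel_set()] for custom covariance
#' structures: wraps named observation-level kernels and an observation
#' table into a `"kernel_set"` ready for [fit_rnm()]. Kernels are checked
#' for symmetry and conformity with the observation count.
#'
#' @param kernels named list of n_obs x n_obs symmetric matrices.
#' @param obs observation table (one row per record; a `y` column is used
#'   as the default response).
#' @param model label for the set (default from the kernel names).
#' @return a `"kernel_set"`.
#' @export
kernel_set <- function(kernels, obs, model = paste(names(kernels),
                                                   collapse = "+")) {
  stopifnot(is.list(kernels), length(kernels) >= 1,
            !is.null(names(kernels)), all(nzchar(names(kernels))))
  obs <- as.data.frame(obs)
  for (nm in names(kernels)) {
    K <- kernels[[nm]]
    if (!is.matrix(K) || nrow(K) != ncol(K) || nrow(K) != nrow(obs)) {
      stop("kernel '", nm, "' must be square of dimension nrow(obs)")
    }
    if (!isSymmetric(unname(K), tol = 1e-8)) {
      stop("kernel '", nm, "' is not symmetric")
    }
    kernels[[nm]] <- unname(K)
  }
  structure(list(kernels = kernels, obs = obs, model = model,
                 factors = NULL),
            class = "kernel_set")
}

#' @export
print.kernel_set <- function(x, ...) {
  cat("Kernel set for model", x$model, "\n")
  cat("  observations:", nrow(x$obs), " sites:",
      length(unique(x$obs$site)), " lines:",
      length(unique(x$obs$line)), "\n")
  cat("  kernels:", paste(names(x$kernels), collapse = ", "),
      "+ residual\n")
  invisible(x)
}

#' Symmetry / positive-semidefiniteness check for a kernel
#'
#' @param K square matrix.
#' @param tol relative eigenvalue tolerance: smallest eigenvalue must be
#'   at least `-tol * largest`.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
check_kernel <- function(K, tol = 1e-8) {
  if (!isSymmetric(unname(K), tol = 1e-8)) stop("kernel is not symmetric")
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev), 1e-300)) {
    stop("kernel is not PSD (min eigenvalue ", format(min(ev)), ")")
  }
  invisible(TRUE)
}
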