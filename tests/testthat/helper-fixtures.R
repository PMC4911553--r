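## Small shared fixtures, all built in code.

small_met <- function(seed = 101, n_lines = 60, n_sites = 3,
                      n_markers = 150,
                      vc = c(E = 2, w = 0.5, g = 0.8, a = 0.4,
                             gE = 0.3, aE = 0.15, eps = 1)) {
  simulate_met(sim_config(n_lines = n_lines, n_markers = n_markers,
                          n_sites = n_sites, variance_components = vc,
                          seed = seed))
}

## naive elementwise oracles used against the kernel builders
loop_gmat <- function(X, center = TRUE) {
  if (center) X <- sweep(X, 2, colMeans(X), "-")
  n <- nrow(X); p <- ncol(X)
  G <- matrix(0, n, n)
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      G[j, k] <- sum(X[j, ] * X[k, ]) / p
    }
  }
  dimnames(G) <- list(rownames(X), rownames(X))
  G
}

loop_env <- function(W) {
  Ws <- scale(W)
  s <- nrow(W); Q <- ncol(W)
  Om <- matrix(0, s, s)
  for (i in seq_len(s)) {
    for (k in seq_len(s)) {
      Om[i, k] <- sum(Ws[i, ] * Ws[k, ]) / Q
    }
  }
  dimnames(Om) <- list(rownames(W), rownames(W))
  Om
}

loop_expand <- function(K, map) {
  n <- length(map)
  out <- matrix(0, n, n)
  for (r in seq_len(n)) {
    for (s in seq_len(n)) {
      out[r, s] <- K[map[r], map[s]]
    }
  }
  out
}

## tabular-method additive relationship, written independently of the
## package implementation (assumes parents precede offspring)
tabular_A <- function(ped) {
  ids <- as.character(ped$id)
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  f <- match(as.character(ped$parent1), ids)
  m <- match(as.character(ped$parent2), ids)
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      if (i == j) {
        A[i, i] <- 1 + 0.5 * (if (!is.na(f[i]) && !is.na(m[i]))
          A[f[i], m[i]] else 0)
      } else {
        v <- 0
        if (!is.na(f[i])) v <- v + A[j, f[i]]
        if (!is.na(m[i])) v <- v + A[j, m[i]]
        A[i, j] <- A[j, i] <- 0.5 * v
      }
    }
  }
  A
}
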