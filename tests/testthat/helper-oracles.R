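# Brute-force oracles, kept deliberately independent of the package's
# computational paths (dense inverses and determinants, explicit path
# walks) so they can validate the factorization-based implementations.

# Shared root-to-tip path length for every tip pair, by walking each tip's
# ancestor chain; independent of ape::vcv.
bf_phylo_cov <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  parent_of <- integer(max(tree$edge))
  len_of <- numeric(max(tree$edge))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  len_of[tree$edge[, 2]] <- tree$edge.length
  chain <- function(tip) {
    nodes <- integer(0)
    v <- tip
    while (v != root) {
      nodes <- c(nodes, v)
      v <- parent_of[v]
    }
    nodes
  }
  chains <- lapply(seq_len(n), chain)
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    shared <- intersect(chains[[i]], chains[[j]])
    V[i, j] <- sum(len_of[shared])
  }
  V
}

# Dense MVN log density with explicit inverse and determinant.
bf_mvn_loglik <- function(y, V, mu, sigma2) {
  n <- length(y)
  S <- sigma2 * V
  r <- y - mu
  as.numeric(-n / 2 * log(2 * pi) - 0.5 * determinant(S)$modulus -
               0.5 * t(r) %*% solve(S) %*% r)
}

# Dense GLS normal equations: beta = (W' V^-1 W)^-1 W' V^-1 y.
bf_gls_beta <- function(y, x, V) {
  W <- cbind(1, x)
  Vi <- solve(V)
  as.numeric(solve(t(W) %*% Vi %*% W, t(W) %*% Vi %*% y))
}

# Profile log-likelihood of the lambda model at one lambda, dense algebra.
bf_lambda_profile <- function(y, V, lam) {
  Vl <- V * lam
  diag(Vl) <- diag(V)
  n <- length(y)
  Vi <- solve(Vl)
  one <- rep(1, n)
  mu <- as.numeric((t(one) %*% Vi %*% y) / (t(one) %*% Vi %*% one))
  s2 <- as.numeric(t(y - mu) %*% Vi %*% (y - mu)) / n
  bf_mvn_loglik(y, Vl, mu, s2)
}

# Grid-search argmax of the lambda profile likelihood.
bf_lambda_grid <- function(y, V, n_grid = 1001) {
  grid <- seq(0, 1, length.out = n_grid)
  ll <- vapply(grid, function(l) bf_lambda_profile(y, V, l), numeric(1))
  list(lambda = grid[which.max(ll)], loglik = max(ll))
}

# Direct per-entry evaluation of the OU covariance formula.
bf_ou_cov <- function(S, T_depth, alpha) {
  out <- S
  for (i in seq_len(nrow(S))) for (j in seq_len(ncol(S))) {
    s <- if (i == j) T_depth else S[i, j]
    out[i, j] <- exp(-2 * alpha * (T_depth - s)) *
      (1 - exp(-2 * alpha * s)) / (2 * alpha)
  }
  out
}

# Small fixed trees used across tests.
tree_3tip <- function() read_newick("((a:1,b:1):1,c:2);")
tree_star <- function(T_depth = 2, n = 4) {
  read_newick(paste0("(", paste0(letters[1:n], ":", T_depth,
                                 collapse = ","), ");"))
}
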