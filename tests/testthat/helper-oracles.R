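# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: covariance by explicit path enumeration, GLS by
# explicit matrix inversion, densities by determinant + inverse.

# shared root-to-MRCA path length for every tip pair, by walking parent
# pointers (independent of vcv / vcv_bm)
brute_vcv <- function(tree) {
  n <- ape::Ntip(tree)
  root <- n + 1L
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(v) {
    nodes <- v
    while (v != root) {
      v <- parent[v]
      nodes <- c(nodes, v)
    }
    nodes
  }
  depth_of <- function(v) {
    d <- 0
    while (v != root) {
      d <- d + elen[v]
      v <- parent[v]
    }
    d
  }
  V <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      common <- intersect(path_to_root(i), path_to_root(j))
      V[i, j] <- max(vapply(common, depth_of, numeric(1)))
    }
  }
  dimnames(V) <- list(tree$tip.label, tree$tip.label)
  V
}

# GLS by explicit inversion (no Cholesky whitening)
brute_gls <- function(y, X, V) {
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  e <- y - X %*% beta
  n <- length(y)
  s2 <- drop(t(e) %*% Vi %*% e) / n
  ll <- -n / 2 * log(2 * pi) - n / 2 * log(s2) -
    0.5 * as.numeric(determinant(V)$modulus) - n / 2
  list(beta = drop(beta), sigma2 = s2, loglik = ll)
}

# MVN log-density by determinant + explicit inverse
brute_mvn <- function(y, mean, V) {
  n <- length(y)
  d <- y - mean
  -0.5 * n * log(2 * pi) - 0.5 * as.numeric(determinant(V)$modulus) -
    0.5 * drop(t(d) %*% solve(V) %*% d)
}

# deterministic random ultrametric tree
rand_tree <- function(n, seed) {
  set.seed(seed)
  ape::rcoal(n)
}

# standard synthetic study used by several files
default_study <- function(seed = 1, ...) {
  simulate_study(simulation_config(seed = seed, ...))
}

# specimen table -> size scores + predictors, matched to the tree
prep_analysis <- function(sim) {
  d <- sim$specimens
  d$size <- size_axis(d)$scores$size
  d$log10_body <- log10(d$body_length_mm)
  d
}
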