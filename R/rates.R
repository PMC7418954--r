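#' Phylogenetically independent contrasts
#'
#' Standardized contrasts via Felsenstein pruning ([ape::pic()]), with
#' polytomies resolved to zero-length edges first (with a warning). Under
#' Brownian motion the n - 1 contrasts are i.i.d. `N(0, sigma2)`, so their
#' mean square is the ML rate estimate.
#'
#' @param y Trait values named by tip label (or in tip order).
#' @param tree [ape::phylo] object.
#' @return Numeric vector of n - 1 standardized contrasts.
#' @export
pic_contrasts <- function(y, tree) {
  if (!ape::is.binary(tree)) {
    warn("tree has polytomies; resolving to zero-length edges")
    tree <- ape::multi2di(tree)
  }
  if (!is.null(names(y))) y <- y[tree$tip.label]
  if (length(y) != ape::Ntip(tree)) abort("y must have one value per tip")
  names(y) <- tree$tip.label
  contrasts <- ape::pic(y, tree)
  if (any(!is.finite(contrasts))) {
    abort("non-finite contrast (zero-length terminal pair with unequal values?)")
  }
  contrasts
}

.assert_monophyletic <- function(tree, tips, label = "clade") {
  tips <- intersect(tree$tip.label, tips)
  if (length(tips) < 2) abort(paste0(label, " needs at least 2 tips in tree"))
  mrca <- ape::getMRCA(tree, tips)
  desc <- ape::extract.clade(tree, mrca)$tip.label
  if (!setequal(desc, tips)) {
    abort(paste0(label, " is not monophyletic in the tree"))
  }
  invisible(tips)
}

#' Clade-wise Brownian-motion rate
#'
#' ML rate for a monophyletic clade: the clade subtree is extracted and
#' the mean squared standardized contrast within it is returned
#' (trait-units squared per My).
#'
#' @param y Trait values named by tip label.
#' @param tree [ape::phylo] object containing the clade.
#' @param tips Tip labels of the clade (must be monophyletic, >= 3 tips).
#' @return Scalar rate estimate.
#' @export
clade_rate <- function(y, tree, tips) {
  if (length(intersect(tips, tree$tip.label)) < 3) {
    abort("clade_rate needs at least 3 clade tips")
  }
  .assert_monophyletic(tree, tips)
  sub <- ape::keep.tip(tree, intersect(tree$tip.label, tips))
  if (is.null(names(y))) names(y) <- tree$tip.label
  mean(pic_contrasts(y[sub$tip.label], sub)^2)
}

#' Permutation test of a clade rate ratio
#'
#' Tests whether clade A's Brownian-motion rate exceeds clade B's. The
#' observed statistic is the ratio of mean squared contrasts. The null is
#' built by pooling the two clades' squared standardized contrasts —
#' exchangeable under a common rate — and reassigning them to clades at
#' the observed counts; the one-tailed P (ratio > 1) uses the add-one
#' correction `(#extreme + 1) / (n_perm + 1)`. The ratio is invariant to
#' rescaling `y`.
#'
#' @param y Trait values named by tip label.
#' @param tree [ape::phylo] object.
#' @param tips_a,tips_b Tip labels of the two disjoint monophyletic clades.
#' @param n_perm Number of permutations (default 10000; warns below 999).
#' @param seed RNG seed (mandatory).
#' @param n_draws Posterior draws per clade rate to attach (see
#'   [rate_posterior()]); 0 to skip.
#' @return Object of class `rate_result`: `sigma2_a`, `sigma2_b`, `ratio`,
#'   `P`, permuted ratios, and posterior draws.
#' @export
rate_ratio_test <- function(y, tree, tips_a, tips_b, n_perm = 10000, seed,
                            n_draws = 0) {
  if (length(intersect(tips_a, tips_b))) abort("clades must be disjoint")
  if (n_perm < 999) warn("fewer than 999 permutations; P resolution is coarse")
  if (is.null(names(y))) names(y) <- tree$tip.label
  sub_a <- ape::keep.tip(tree, .assert_monophyletic(tree, tips_a, "clade A"))
  sub_b <- ape::keep.tip(tree, .assert_monophyletic(tree, tips_b, "clade B"))
  ua2 <- pic_contrasts(y[sub_a$tip.label], sub_a)^2
  ub2 <- pic_contrasts(y[sub_b$tip.label], sub_b)^2
  sigma2_a <- mean(ua2)
  sigma2_b <- mean(ub2)
  ratio <- sigma2_a / sigma2_b
  pool <- c(ua2, ub2)
  m_a <- length(ua2)
  m <- length(pool)
  old <- .Random.seed_safe()
  set.seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(m, m_a)
    mean(pool[idx]) / mean(pool[-idx])
  }, numeric(1))
  P <- (sum(perm >= ratio) + 1) / (n_perm + 1)
  draws_a <- if (n_draws > 0) {
    rate_posterior(y, tree, tips_a, n_draws = n_draws, seed = seed + 1)
  }
  draws_b <- if (n_draws > 0) {
    rate_posterior(y, tree, tips_b, n_draws = n_draws, seed = seed + 2)
  }
  structure(
    list(
      sigma2_a = sigma2_a, sigma2_b = sigma2_b, ratio = ratio, P = P,
      n_contrasts = c(a = m_a, b = length(ub2)),
      perm_ratios = perm, n_perm = n_perm, seed = seed,
      posterior_a = draws_a, posterior_b = draws_b
    ),
    class = "rate_result"
  )
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf(
    "BM rate ratio: %.3f (sigma2_a = %.4g, sigma2_b = %.4g)\n",
    x$ratio, x$sigma2_a, x$sigma2_b
  ))
  cat(sprintf(
    "  one-tailed permutation P (ratio > 1) = %.4g  [%d permutations]\n",
    x$P, x$n_perm
  ))
  invisible(x)
}

#' @rdname rate_ratio_test
#' @param x A `rate_result`.
#' @param ... Unused.
#' @export
tidy.rate_result <- function(x, ...) {
  tibble(
    clade = c("a", "b"),
    sigma2 = c(x$sigma2_a, x$sigma2_b),
    n_contrasts = unname(x$n_contrasts)
  )
}

#' @rdname rate_ratio_test
#' @export
glance.rate_result <- function(x, ...) {
  tibble(
    ratio = x$ratio, p.value = x$P, n_perm = x$n_perm,
    sigma2_a = x$sigma2_a, sigma2_b = x$sigma2_b
  )
}

#' Posterior draws of a clade's Brownian-motion rate
#'
#' Under the i.i.d.-contrast likelihood with the Jeffreys prior
#' `1 / sigma2`, the posterior of the rate is scaled inverse chi-squared
#' with m degrees of freedom and scale equal to the ML rate (m = number of
#' contrasts); draws are sampled directly as `m * s2 / chisq_m`. The
#' posterior mean is `s2 * m / (m - 2)`.
#'
#' @inheritParams clade_rate
#' @param n_draws Number of posterior draws.
#' @param seed RNG seed.
#' @return Numeric vector of rate draws.
#' @export
rate_posterior <- function(y, tree, tips, n_draws = 10000, seed) {
  if (is.null(names(y))) names(y) <- tree$tip.label
  sub <- ape::keep.tip(tree, .assert_monophyletic(tree, tips))
  u2 <- pic_contrasts(y[sub$tip.label], sub)^2
  m <- length(u2)
  s2 <- mean(u2)
  old <- .Random.seed_safe()
  set.seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  m * s2 / rchisq(n_draws, df = m)
}

#' Rate comparison of two traits on the same tree (paired design)
#'
#' Compares the Brownian-motion rate of trait A to trait B measured on the
#' same tips and in comparable units (e.g. log10 larynx dimension vs log10
#' body length, both mm). The statistic is the ratio of mean squared
#' contrasts; the null swaps the two traits' squared contrasts within each
#' contrast pair (the node-level pairing makes this exact under exchange-
#' ability), one-tailed for ratio > 1.
#'
#' @param trait_a,trait_b Trait vectors named by tip label.
#' @param tree [ape::phylo] object.
#' @param tips Optional subset of tips (monophyletic clade); default all.
#' @param n_perm Number of sign-swap permutations.
#' @param seed RNG seed.
#' @return List with `ratio`, `P`, `rate_a`, `rate_b`, `n_contrasts`.
#' @export
trait_vs_body_rate <- function(trait_a, trait_b, tree, tips = NULL,
                               n_perm = 10000, seed) {
  if (!is.null(tips)) {
    keep <- intersect(tree$tip.label, tips)
    if (length(keep) >= 3 && length(keep) < ape::Ntip(tree)) {
      .assert_monophyletic(tree, keep)
      tree <- ape::keep.tip(tree, keep)
    }
  }
  if (is.null(names(trait_a)) || is.null(names(trait_b))) {
    abort("traits must be named by tip label")
  }
  scale_gap <- abs(log10(stats::sd(trait_a) / stats::sd(trait_b)))
  if (is.finite(scale_gap) && scale_gap > 3) {
    warn("traits differ in scale by more than 10^3; check units")
  }
  ua2 <- pic_contrasts(trait_a[tree$tip.label], tree)^2
  ub2 <- pic_contrasts(trait_b[tree$tip.label], tree)^2
  rate_a <- mean(ua2)
  rate_b <- mean(ub2)
  ratio <- rate_a / rate_b
  m <- length(ua2)
  old <- .Random.seed_safe()
  set.seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  perm <- vapply(seq_len(n_perm), function(i) {
    swap <- runif(m) < 0.5
    a <- ifelse(swap, ub2, ua2)
    b <- ifelse(swap, ua2, ub2)
    mean(a) / mean(b)
  }, numeric(1))
  P <- (sum(perm >= ratio) + 1) / (n_perm + 1)
  list(
    ratio = ratio, P = P, rate_a = rate_a, rate_b = rate_b,
    n_contrasts = m, n_perm = n_perm, seed = seed
  )
}

#' Ancestral states under (rate-rescaled) Brownian motion
#'
#' GLS/pruning ancestral estimates for every internal node. With
#' heterogeneous rates, each branch is first stretched by its rate
#' (`edge_rates`), which turns the multiple-rate model into standard BM on
#' a rescaled tree; node heights reported for plotting come from the
#' *original* tree so the phenogram stays in My.
#'
#' @param y Trait values named by tip label.
#' @param tree [ape::phylo] object.
#' @param edge_rates Optional positive vector, one rate per edge (rows of
#'   `tree$edge`); default all 1 (homogeneous BM).
#' @return Object of class `ancestral_states`: tibble `nodes` with
#'   `node`, `height` (My from root), `value`, `is_tip`, plus the tree.
#' @export
ancestral_states <- function(y, tree, edge_rates = NULL) {
  tree <- stats::reorder(tree, "cladewise")
  n <- ape::Ntip(tree)
  if (is.null(names(y))) names(y) <- tree$tip.label
  y <- y[tree$tip.label]
  E <- nrow(tree$edge)
  if (is.null(edge_rates)) edge_rates <- rep(1, E)
  if (length(edge_rates) != E || any(edge_rates <= 0)) {
    abort("edge_rates must be positive, one per edge")
  }
  scaled <- tree
  scaled$edge.length <- tree$edge.length * edge_rates
  # full node-node shared-path covariance on the rescaled tree
  heights_s <- node_heights(scaled)
  n_nodes <- n + tree$Nnode
  anc_sets <- .ancestor_sets(tree)
  root <- n + 1L
  internal <- setdiff(seq_len(n_nodes), seq_len(n))
  Vtt <- vcv_bm(scaled)
  Cat <- matrix(0, length(internal), n)
  for (k in seq_along(internal)) {
    a_set <- anc_sets[[internal[k]]]
    for (i in seq_len(n)) {
      common <- intersect(a_set, anc_sets[[i]])
      Cat[k, i] <- max(heights_s[common])
    }
  }
  U <- chol(Vtt)
  one_w <- backsolve(U, rep(1, n), transpose = TRUE)
  y_w <- backsolve(U, y, transpose = TRUE)
  mu <- sum(one_w * y_w) / sum(one_w^2)
  resid_w <- y_w - mu * one_w
  Cat_w <- t(backsolve(U, t(Cat), transpose = TRUE))
  vals <- drop(Cat_w %*% resid_w) + mu
  heights <- node_heights(tree)
  nodes <- tibble(
    node = c(seq_len(n), internal),
    label = c(tree$tip.label, rep(NA_character_, length(internal))),
    height = heights[c(seq_len(n), internal)],
    value = c(unname(y), vals),
    is_tip = c(rep(TRUE, n), rep(FALSE, length(internal)))
  )
  structure(
    list(nodes = nodes, tree = tree, edge_rates = edge_rates),
    class = "ancestral_states"
  )
}

# per-node ancestor sets (self included), node indices
.ancestor_sets <- function(tree) {
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  root <- ape::Ntip(tree) + 1L
  parent <- integer(n_nodes)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  lapply(seq_len(n_nodes), function(v) {
    path <- v
    while (v != root) {
      v <- parent[v]
      path <- c(path, v)
    }
    path
  })
}

#' @export
print.ancestral_states <- function(x, ...) {
  cat(sprintf(
    "Ancestral states for %d tips / %d internal nodes (root value %.3f)\n",
    sum(x$nodes$is_tip), sum(!x$nodes$is_tip),
    x$nodes$value[x$nodes$node == ape::Ntip(x$tree) + 1]
  ))
  invisible(x)
}

#' Per-edge rates from clade assignments
#'
#' Builds the `edge_rates` vector for [ancestral_states()] from clade-wise
#' rate estimates: every edge inside a clade (and its stem) gets the
#' clade's rate; remaining edges get the pooled rate.
#'
#' @param tree [ape::phylo] object.
#' @param clade_tips Named list of tip-label vectors, one per clade.
#' @param rates Named numeric vector of rates, same names as `clade_tips`.
#' @param default Rate for edges in no listed clade.
#' @return Numeric vector, one rate per edge.
#' @export
clade_edge_rates <- function(tree, clade_tips, rates, default = mean(rates)) {
  tree <- stats::reorder(tree, "cladewise")
  out <- rep(default, nrow(tree$edge))
  for (nm in names(clade_tips)) {
    tips <- intersect(tree$tip.label, clade_tips[[nm]])
    mrca <- ape::getMRCA(tree, tips)
    clade_nodes <- c(mrca, .descendants(tree, mrca))
    out[tree$edge[, 2] %in% clade_nodes] <- rates[[nm]]
  }
  out
}

.descendants <- function(tree, node) {
  E <- tree$edge
  out <- integer(0)
  frontier <- node
  while (length(frontier)) {
    kids <- E[E[, 1] %in% frontier, 2]
    out <- c(out, kids)
    frontier <- kids[kids > ape::Ntip(tree)]
  }
  out
}
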