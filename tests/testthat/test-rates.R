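test_that("pic contrasts match hand calculations and flag bad input", {
  tr <- read_tree("(A:1,B:1);")
  expect_equal(abs(unname(pic_contrasts(c(A = 0, B = 2), tr))), sqrt(2),
    tolerance = 1e-10
  )
  tr2 <- rand_tree(10, seed = 1)
  expect_equal(
    unname(pic_contrasts(setNames(rep(3, 10), tr2$tip.label), tr2)),
    rep(0, 9)
  )
  # sampling check: mean squared contrast near the generating rate
  tr3 <- rand_tree(20, seed = 2)
  u2 <- vapply(1:300, function(i) {
    mean(pic_contrasts(simulate_bm(tr3, 1.7, 0, seed = 10 + i), tr3)^2)
  }, numeric(1))
  expect_equal(mean(u2), 1.7, tolerance = 3 * sd(u2) / sqrt(300) / 1.7 + 0.02)
})

test_that("clade_rate scales like a variance per unit time", {
  sim <- default_study(seed = 3)
  tips_p <- sim$specimens$species[sim$specimens$clade == "primate"]
  y <- setNames(rnorm(55), sim$tree$tip.label)
  r1 <- clade_rate(y, sim$tree, tips_p)
  expect_equal(clade_rate(2 * y, sim$tree, tips_p), 4 * r1, tolerance = 1e-10)
  stretched <- sim$tree
  stretched$edge.length <- stretched$edge.length * 2
  expect_equal(clade_rate(y, stretched, tips_p), r1 / 2, tolerance = 1e-10)
  # a non-monophyletic tip set is rejected
  mixed <- c(tips_p[1:5], sim$specimens$species[sim$specimens$clade == "carnivoran"][1:3])
  expect_error(clade_rate(y, sim$tree, mixed), "monophyletic")
})

test_that("clade_rate is close to unbiased under Brownian motion", {
  tr <- rand_tree(30, seed = 4)
  tips <- tr$tip.label
  est <- vapply(1:300, function(i) {
    clade_rate(simulate_bm(tr, 1, 0, seed = 100 + i), tr, tips)
  }, numeric(1))
  expect_equal(mean(est), 1, tolerance = 0.05)
})

test_that("rate_ratio_test recovers an injected rate contrast and ignores scale", {
  sim <- default_study(seed = 5)
  tree <- sim$tree
  tips_p <- grep("^Primate", tree$tip.label, value = TRUE)
  tips_c <- grep("^Carnivoran", tree$tip.label, value = TRUE)
  ratios <- vapply(1:150, function(i) {
    yp <- simulate_bm(ape::keep.tip(tree, tips_p), 4, 0, seed = 200 + i)
    yc <- simulate_bm(ape::keep.tip(tree, tips_c), 1, 0, seed = 500 + i)
    y <- c(yp, yc)[tree$tip.label]
    rt <- suppressWarnings(
      rate_ratio_test(y, tree, tips_p, tips_c, n_perm = 199, seed = i)
    )
    rt$ratio
  }, numeric(1))
  expect_gte(median(ratios), 3)
  expect_lte(median(ratios), 5.3)

  y <- setNames(simulate_bm(tree, 1, 0, seed = 9), tree$tip.label)
  a <- suppressWarnings(rate_ratio_test(y, tree, tips_p, tips_c, n_perm = 499, seed = 1))
  b <- suppressWarnings(rate_ratio_test(y * 37, tree, tips_p, tips_c, n_perm = 499, seed = 1))
  expect_equal(a$ratio, b$ratio, tolerance = 1e-10)
  expect_equal(a$P, b$P)
  expect_error(
    suppressWarnings(
      rate_ratio_test(y, tree, tips_p, c(tips_p[1], tips_c), n_perm = 999, seed = 1)
    ),
    "disjoint"
  )
  expect_warning(
    rate_ratio_test(y, tree, tips_p, tips_c, n_perm = 99, seed = 1),
    "999"
  )
})

test_that("rate_posterior matches the scaled inverse chi-squared analytically", {
  sim <- default_study(seed = 6)
  tree <- sim$tree
  tips_p <- grep("^Primate", tree$tip.label, value = TRUE)
  y <- setNames(simulate_bm(tree, 1, 0, seed = 10), tree$tip.label)
  m <- length(tips_p) - 1
  s2 <- clade_rate(y, tree, tips_p)
  draws <- rate_posterior(y, tree, tips_p, n_draws = 10000, seed = 3)
  expect_equal(mean(draws), s2 * m / (m - 2), tolerance = 0.05)
  # KS distance against the analytic density: sigma2 ~ m s2 / chisq_m
  ks <- suppressWarnings(
    ks.test(draws, function(q) 1 - pchisq(m * s2 / q, df = m))
  )
  expect_lt(unname(ks$statistic), 0.02)
  d2 <- rate_posterior(y, tree, tips_p, n_draws = 10000, seed = 4)
  expect_lt(abs(mean(draws) - mean(d2)) / mean(draws), 0.01)
})

test_that("trait_vs_body_rate is null at identity and powered for real contrasts", {
  sim <- default_study(seed = 7)
  tree <- sim$tree
  y <- setNames(simulate_bm(tree, 1, 0, seed = 20), tree$tip.label)
  same <- trait_vs_body_rate(y, y, tree, n_perm = 499, seed = 1)
  expect_equal(same$ratio, 1, tolerance = 1e-12)
  expect_gt(same$P, 0.4)

  tips_p <- grep("^Primate", tree$tip.label, value = TRUE)
  sub <- ape::keep.tip(tree, tips_p)
  power <- vapply(1:100, function(i) {
    b <- simulate_bm(sub, 1, 0, seed = 30 + i)
    set.seed(700 + i)
    a <- b + rnorm(length(b), 0, sd(b)) # extra iid variation, equal marginal var
    trait_vs_body_rate(a, b, sub, n_perm = 199, seed = i)$P < 0.05
  }, logical(1))
  expect_gte(mean(power), 0.8)
  expect_warning(
    trait_vs_body_rate(y * 1e4, y, tree, n_perm = 99, seed = 1),
    "scale"
  )
})

test_that("ancestral states interpolate correctly in closed-form cases", {
  tr <- read_tree("(A:1,B:1);")
  a <- ancestral_states(c(A = 0, B = 2), tr)
  expect_equal(a$nodes$value[a$nodes$node == 3], 1)
  # inflating one tip's branch rate hands the root to the other tip
  heavy <- ancestral_states(c(A = 0, B = 2), tr,
    edge_rates = c(1e8, 1)[order(tr$edge[, 2])]
  )
  root_val <- heavy$nodes$value[heavy$nodes$node == 3]
  expect_equal(root_val, 2, tolerance = 1e-3)
})

test_that("equal-rates ancestral states match an independent pruning oracle", {
  for (s in 1:10) {
    tr <- rand_tree(15, seed = 50 + s)
    y <- simulate_bm(tr, 0.8, 1, seed = 60 + s)
    ours <- ancestral_states(y, tr)
    oracle <- phytools::fastAnc(tr, y)
    got <- ours$nodes$value[!ours$nodes$is_tip]
    expect_equal(got, as.numeric(oracle), tolerance = 1e-8)
    expect_equal(
      ours$nodes$value[ours$nodes$is_tip],
      unname(y[tr$tip.label])
    )
  }
})

test_that("clade_edge_rates paints clades and stems", {
  sim <- default_study(seed = 8)
  tree <- ape::reorder.phylo(sim$tree, "cladewise")
  tips <- split(sim$specimens$species, sim$specimens$clade)
  er <- clade_edge_rates(tree, tips, rates = c(primate = 2, carnivoran = 1))
  expect_equal(length(er), nrow(tree$edge))
  term_prim <- match(match(tips$primate, tree$tip.label), tree$edge[, 2])
  expect_true(all(er[term_prim] == 2))
  term_carn <- match(match(tips$carnivoran, tree$tip.label), tree$edge[, 2])
  expect_true(all(er[term_carn] == 1))
})
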