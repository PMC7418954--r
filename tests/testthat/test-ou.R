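test_that("edge regimes paint downstream edges until the next shift", {
  tr <- read_tree("((A:1,B:1):1,(C:1,D:1):1);")
  tr <- ape::reorder.phylo(tr, "cladewise")
  reg0 <- edge_regimes(tr)
  expect_equal(reg0, rep(1L, 6))
  # shift on the first cherry's stem propagates to A and B edges
  stem_ab <- which(tr$edge[, 2] == ape::getMRCA(tr, c("A", "B")))
  reg <- edge_regimes(tr, stem_ab)
  desc <- which(tr$edge[, 1] == tr$edge[stem_ab, 2])
  expect_equal(reg[stem_ab], 2L)
  expect_equal(reg[desc], c(2L, 2L))
  expect_equal(sum(reg == 1L), 3)
})

test_that("single-regime OU at tiny alpha recovers the Brownian likelihood", {
  tr <- rand_tree(15, seed = 1)
  y <- simulate_bm(tr, 0.7, 1, seed = 2)
  ou <- ou_regime_fit(y, tr, alpha = 1e-9)
  bm <- gls_fit(as.numeric(y), matrix(1, 15), vcv_bm(tr))
  expect_equal(ou$loglik, bm$loglik, tolerance = 1e-4)
  expect_equal(unname(ou$theta[1]), unname(bm$coefficients[1]), tolerance = 1e-4)
})

test_that("huge alpha pins each regime's optimum to its tips' values", {
  tr <- read_tree("((A:1,B:1):1,(C:1,D:1):1);")
  tr <- ape::reorder.phylo(tr, "cladewise")
  y <- c(A = -2.1, B = -1.9, C = 5.2, D = 4.8)
  sh <- which(tr$edge[, 2] == ape::getMRCA(tr, c("C", "D")))
  m <- ou_regime_fit(y, tr, shifts = sh, alpha = 500)
  expect_equal(sort(unname(m$theta)), c(-2, 5), tolerance = 1e-3)
})

test_that("the reported likelihood is the exact density at the Hansen moments", {
  for (s in 1:10) {
    tr <- rand_tree(12, seed = 100 + s)
    y <- simulate_bm(tr, 1, 0, seed = 200 + s)
    sh <- sample(nrow(tr$edge), 1)
    m <- tryCatch(
      suppressWarnings(ou_regime_fit(y, tr, shifts = sh)),
      error = function(e) NULL
    )
    if (is.null(m)) next # a tipless-regime draw; covered by its own error test
    mo <- ou_model_moments(m)
    expect_equal(m$loglik, loglik_mvn(m$y, mo$mean, mo$cov), tolerance = 1e-8)
  }
  tr <- rand_tree(12, seed = 1)
  expect_error(
    ou_regime_fit(simulate_bm(tr, 1, 0, seed = 1), tr,
      shifts = seq_len(nrow(tr$edge))
    ),
    "no tips"
  )
})

test_that("strong two-regime simulations recover the optimum ordering", {
  n_rep <- 60
  ok <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    tr <- rand_tree(16, seed = 300 + i)
    tr$edge.length <- tr$edge.length * 50 / tree_depth(tr)
    alpha <- 0.08
    sigma2 <- 0.02
    stat_sd <- sqrt(sigma2 / (2 * alpha))
    # paint a mid-sized clade with an optimum 5 stationary SDs away
    tr <- ape::reorder.phylo(tr, "cladewise")
    sizes <- vapply(seq_len(nrow(tr$edge)), function(e) {
      nd <- tr$edge[e, 2]
      if (nd <= 16) 1L else ape::Ntip(ape::extract.clade(tr, nd))
    }, integer(1))
    cand <- which(sizes >= 4 & sizes <= 8)
    sh <- cand[1]
    y <- simulate_ou_shifts(tr, sh, alpha, sigma2,
      theta = c(0, 5 * stat_sd), seed = 400 + i
    )
    m <- suppressWarnings(ou_regime_fit(y, tr, shifts = sh))
    ok[i] <- m$theta[2] > m$theta[1]
  }
  expect_equal(mean(ok), 1)
})

test_that("detect_shifts is deterministic and quiet on pure Brownian data", {
  tr <- simulate_tree(24, depth = 60, seed = 7)
  y <- simulate_bm(tr, 0.01, 0, seed = 8)
  d1 <- detect_shifts(y, tr, max_shifts = 3)
  d2 <- detect_shifts(y, tr, max_shifts = 3)
  expect_identical(d1$shifts, d2$shifts)
  expect_identical(d1$criterion, d2$criterion)
  expect_error(detect_shifts(y, tr, max_shifts = 10), "n/5")

  false_pos <- vapply(1:80, function(i) {
    tri <- simulate_tree(24, depth = 60, seed = 900 + i)
    yi <- simulate_bm(tri, 0.01, 0, seed = 950 + i)
    length(detect_shifts(yi, tri, max_shifts = 3)$shifts) > 0
  }, logical(1))
  expect_lte(mean(false_pos), 0.1)
})

test_that("detect_shifts recovers a strong injected clade shift", {
  n_rep <- 80
  hit <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    tr <- simulate_tree(30, depth = 60, seed = 1300 + i)
    tr <- ape::reorder.phylo(tr, "cladewise")
    alpha <- 0.15
    sigma2 <- 0.02
    stat_sd <- sqrt(sigma2 / (2 * alpha))
    heights <- node_heights(tr)
    sizes <- vapply(seq_len(nrow(tr$edge)), function(e) {
      nd <- tr$edge[e, 2]
      if (nd <= 30) 1L else ape::Ntip(ape::extract.clade(tr, nd))
    }, integer(1))
    cand <- which(sizes >= 5 & sizes <= 8)
    if (!length(cand)) next
    # the oldest suitable clade, so tips have had time to reach the optimum
    sh <- cand[which.min(heights[tr$edge[cand, 1]])]
    y <- simulate_ou_shifts(tr, sh, alpha, sigma2,
      theta = c(0, 5 * stat_sd), seed = 1400 + i
    )
    det <- detect_shifts(y, tr, max_shifts = 3)
    allowed <- c(sh, laryngevol:::.adjacent_edges(tr, sh))
    hit[i] <- any(det$shifts %in% allowed)
  }
  expect_gte(mean(hit), 0.9)
})

test_that("snr behaves like an effect size", {
  tr <- rand_tree(14, seed = 17)
  y <- simulate_bm(tr, 1, 0, seed = 18)
  m0 <- suppressWarnings(ou_regime_fit(y, tr))
  expect_equal(snr(m0), 0)
  tr <- ape::reorder.phylo(tr, "cladewise")
  internal <- which(tr$edge[, 2] > 14)
  m <- suppressWarnings(ou_regime_fit(y, tr, shifts = internal[2], alpha = 0.5))
  base <- snr(m)
  expect_gt(base, 0)
  # equal optima -> zero signal
  m_eq <- m
  m_eq$theta[] <- 1.3
  expect_equal(snr(m_eq), 0, tolerance = 1e-10)
  # doubling the optimum gap doubles it; quadrupling sigma2 halves it
  m2 <- m
  m2$theta <- m$theta + c(0, diff(m$theta))
  expect_equal(snr(m2) / base, 2, tolerance = 1e-8)
  m4 <- m
  m4$sigma2 <- m$sigma2 * 4
  expect_equal(snr(m4) / base, 0.5, tolerance = 1e-8)
})

test_that("bootstrap support is near 100 in the noiseless limit and seed-stable", {
  tr <- rand_tree(20, seed = 21)
  tr$edge.length <- tr$edge.length * 50 / tree_depth(tr)
  tr <- ape::reorder.phylo(tr, "cladewise")
  sizes <- vapply(seq_len(nrow(tr$edge)), function(e) {
    nd <- tr$edge[e, 2]
    if (nd <= 20) 1L else ape::Ntip(ape::extract.clade(tr, nd))
  }, integer(1))
  sh <- which(sizes >= 5 & sizes <= 9)[1]
  y <- simulate_ou_shifts(tr, sh, 0.1, 0.02, theta = c(0, 3), seed = 22)
  m <- detect_shifts(y, tr, max_shifts = 2)
  expect_true(length(m$shifts) >= 1)
  # near-noiseless model: shifts recovered in essentially every replicate
  m_clean <- m
  m_clean$sigma2 <- 1e-8
  s_clean <- shift_support(m_clean, B = 50, seed = 1)
  expect_true(all(s_clean$support >= 98))
  # two seeds agree within 10 points on the real model
  s1 <- shift_support(m, B = 60, seed = 11)
  s2 <- shift_support(m, B = 60, seed = 12)
  expect_true(all(abs(s1$support - s2$support) < 10))
  expect_warning(shift_support(m, B = 20, seed = 1), "50")
})

test_that("support for an arbitrary shift imposed on Brownian data is low", {
  tr <- rand_tree(20, seed = 31)
  tr$edge.length <- tr$edge.length * 50 / tree_depth(tr)
  tr <- ape::reorder.phylo(tr, "cladewise")
  y <- simulate_bm(tr, 0.02, 0, seed = 32)
  internal <- which(tr$edge[, 2] > 20)
  m <- suppressWarnings(ou_regime_fit(y, tr, shifts = internal[3]))
  s <- shift_support(m, B = 50, seed = 5)
  expect_lt(unname(s$support[1]), 20)
})
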