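test_that("generators are pure functions of (config, seed)", {
  cfg <- simulation_config(seed = 77)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$specimens, s2$specimens)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  expect_identical(s1$landmarks, s2$landmarks)
  t1 <- simulate_tree(10, seed = 5)
  t2 <- simulate_tree(10, seed = 5)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_error(simulation_config(), "seed")
})

test_that("simulate_tree produces ultrametric trees at the requested depth", {
  cherry <- simulate_tree(2, depth = 3, seed = 1)
  expect_equal(unname(node_heights(cherry)[1:2]), c(3, 3))
  big <- simulate_tree(55, depth = 79, seed = 2)
  expect_equal(unname(node_heights(big)[1:55]), rep(79, 55), tolerance = 1e-9)
})

test_that("simulate_bm has the Brownian variance structure", {
  tr <- read_tree("(A:2,B:2);")
  expect_equal(
    unname(simulate_bm(tr, 0, 5, seed = 1)), c(5, 5)
  )
  diffs <- vapply(1:4000, function(i) {
    v <- simulate_bm(tr, 1.3, 0, seed = i)
    v[["A"]] - v[["B"]]
  }, numeric(1))
  expect_equal(var(diffs), 2 * 1.3 * 2, tolerance = 0.05 * 2 * 1.3 * 2 + 0.15)

  tr5 <- rand_tree(5, seed = 3)
  sims <- vapply(1:3000, function(i) {
    as.numeric(simulate_bm(tr5, 0.9, 0, seed = 10000 + i))
  }, numeric(5))
  emp <- cov(t(sims))
  expect_equal(emp, 0.9 * unname(vcv_bm(tr5)), tolerance = 0.1)
})

test_that("simulate_ou_shifts matches OU limits", {
  # huge alpha: tips sit at their regime's optimum
  tr <- read_tree("(A:10,(B:5,C:5):5);")
  tr <- ape::reorder.phylo(tr, "cladewise")
  sh <- which(tr$edge[, 2] == ape::getMRCA(tr, c("B", "C")))
  y <- simulate_ou_shifts(tr, sh, alpha = 100, sigma2 = 0.01,
    theta = c(-1, 2), seed = 4
  )
  expect_equal(unname(y["A"]), -1, tolerance = 0.01)
  expect_equal(unname(y[c("B", "C")]), c(2, 2), tolerance = 0.01)

  # long isolated edge reaches the stationary variance sigma2 / (2 alpha)
  lone <- read_tree("(A:200,B:200);")
  tips <- vapply(1:3000, function(i) {
    simulate_ou_shifts(lone, integer(0), 0.05, 0.4, 0, seed = 100 + i)[["A"]]
  }, numeric(1))
  expect_equal(var(tips), 0.4 / (2 * 0.05), tolerance = 0.3)

  # alpha -> 0 converges in distribution to BM
  short <- read_tree("(A:3,B:3);")
  ou_draws <- vapply(1:3000, function(i) {
    simulate_ou_shifts(short, integer(0), 1e-7, 1, 0, seed = 200 + i)[["A"]]
  }, numeric(1))
  bm_draws <- vapply(1:3000, function(i) {
    simulate_bm(short, 1, 0, seed = 5200 + i)[["A"]]
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ou_draws, bm_draws))
  expect_lt(unname(ks$statistic), 0.04)
})

test_that("noiseless allometry returns the generating slope exactly", {
  cfg <- simulation_config(
    seed = 11, lambda_resid = 0,
    sigma2_resid = c(primate = 1e-12, carnivoran = 1e-12)
  )
  tp <- simulate_tree(10, depth = 65, seed = 1, prefix = "P")
  tc <- simulate_tree(10, depth = 55, seed = 2, prefix = "C")
  tree <- graft_trees(tp, tc, 79)
  clades <- ifelse(grepl("^P", tree$tip.label), "primate", "carnivoran")
  allo <- simulate_allometry(tree, clades, cfg, seed = 3)
  d <- dplyr::mutate(allo, log10_body = log10_body_length)
  fit <- pgls(size ~ log10_body + clade, d, tree)
  expect_equal(unname(fit$coefficients[["log10_body"]]), 4.71, tolerance = 1e-5)
  expect_equal(
    abs(unname(fit$coefficients[[3]])), 1.05,
    tolerance = 1e-5
  )
})

test_that("relabeling the clades negates the fitted intercept difference", {
  cfg <- simulation_config(seed = 12)
  tp <- simulate_tree(12, depth = 65, seed = 4, prefix = "P")
  tc <- simulate_tree(12, depth = 55, seed = 5, prefix = "C")
  tree <- graft_trees(tp, tc, 79)
  clades <- ifelse(grepl("^P", tree$tip.label), "primate", "carnivoran")
  a1 <- simulate_allometry(tree, clades, cfg, seed = 6)
  d1 <- dplyr::mutate(a1, log10_body = log10_body_length)
  d2 <- dplyr::mutate(d1, clade = ifelse(clade == "primate", "carnivoran", "primate"))
  f1 <- pgls(size ~ log10_body + clade, d1, tree)
  f2 <- pgls(size ~ log10_body + clade, d2, tree)
  expect_equal(unname(f1$coefficients[[3]]), -unname(f2$coefficients[[3]]),
    tolerance = 1e-6
  )
})

test_that("landmark generation controls the size-axis variance share", {
  sizes <- setNames(seq(-1.5, 1.5, length.out = 30), paste0("s", 1:30))
  cfg0 <- simulation_config(seed = 13, landmark_noise_cv = 0)
  lm0 <- simulate_landmarks(sizes, cfg0, seed = 14)
  ax0 <- size_axis(landmark_distances(lm0))
  expect_equal(ax0$variance_explained, 1, tolerance = 1e-10)

  sim <- default_study(seed = 15)
  ax <- size_axis(sim$specimens)
  expect_gt(ax$variance_explained, 0.9)

  # size score hitting linear scale 1 reproduces the template distances
  s_unit <- -cfg0$scale_intercept / cfg0$scale_per_size
  lm1 <- simulate_landmarks(c(u = s_unit), cfg0, seed = 16)
  got <- landmark_distances(lm1)
  want <- landmark_distances(landmark_template())
  expect_equal(
    as.numeric(got[, measurement_names()]),
    as.numeric(want[, measurement_names()]),
    tolerance = 1e-10
  )
})

test_that("f0 generation matches its regression model", {
  sizes <- setNames(rnorm(30), paste0("s", 1:30))
  cfg0 <- simulation_config(seed = 17, f0_noise_sd = 0)
  f0 <- simulate_f0(sizes, cfg0, seed = 18)
  expect_equal(suppressWarnings(ols_r2(log10(f0$mean_f0_hz), sizes)), 1)

  # null slope: the pGLS t on size is non-significant at about the nominal rate
  cfg_null <- simulation_config(seed = 19, f0_slope = 0)
  sig <- vapply(1:100, function(i) {
    tr <- rand_tree(26, seed = 3000 + i)
    tr$edge.length <- tr$edge.length * 65 / tree_depth(tr)
    sz <- setNames(as.numeric(scale(simulate_bm(tr, 1, 0, seed = 3300 + i))), tr$tip.label)
    f <- simulate_f0(sz, cfg_null, seed = 3600 + i)
    d <- tibble::tibble(
      species = tr$tip.label, clade = "x",
      size = unname(sz), mean_f0_hz = f$mean_f0_hz
    )
    fit <- suppressMessages(f0_allometry(d, tr))
    fit$p.value[[".size"]] < 0.05
  }, logical(1))
  expect_lt(mean(sig), 0.13)
})

test_that("written studies round-trip through the file readers", {
  sim <- default_study(seed = 20)
  dir <- tempfile("study")
  paths <- write_study(sim, dir)
  expect_true(all(file.exists(paths)))
  spec <- suppressMessages(read_specimen_table(paths[["specimens"]]))
  tree <- read_tree(paths[["tree"]])
  expect_equal(nrow(spec), 55)
  expect_equal(ape::Ntip(tree), 55)
  ax_disk <- size_axis(spec)
  ax_mem <- size_axis(sim$specimens)
  expect_equal(ax_disk$variance_explained, ax_mem$variance_explained,
    tolerance = 1e-6
  )
  unlink(dir, recursive = TRUE)
})
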