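test_that("loglik_mvn is the exact multivariate normal log-density", {
  expect_equal(
    loglik_mvn(0, 0, matrix(1)),
    -0.5 * log(2 * pi)
  )
  # diagonal covariance = sum of univariate log-densities
  set.seed(1)
  y <- rnorm(5)
  v <- runif(5, 0.5, 2)
  expect_equal(
    loglik_mvn(y, rep(0, 5), diag(v)),
    sum(dnorm(y, 0, sqrt(v), log = TRUE))
  )
  # random 6-dim instance vs determinant + explicit inverse
  set.seed(2)
  A <- matrix(rnorm(36), 6)
  V <- crossprod(A) + diag(6)
  mu <- rnorm(6)
  y6 <- rnorm(6)
  expect_equal(loglik_mvn(y6, mu, V), brute_mvn(y6, mu, V), tolerance = 1e-10)
  expect_error(loglik_mvn(y6, mu, -V), "positive definite")
})

test_that("gls_fit equals whitened OLS and brute-force GLS on random instances", {
  set.seed(3)
  for (i in 1:100) {
    n <- sample(6:20, 1)
    p <- sample(1:3, 1)
    X <- cbind(1, matrix(rnorm(n * p), n))
    A <- matrix(rnorm(n * n), n)
    V <- crossprod(A) / n + diag(n)
    y <- rnorm(n)
    fit <- gls_fit(y, X, V)
    oracle <- brute_gls(y, X, V)
    expect_equal(unname(fit$coefficients), unname(oracle$beta), tolerance = 1e-8)
    expect_equal(fit$sigma2, oracle$sigma2, tolerance = 1e-8)
    expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-8)
  }
})

test_that("gls_fit with identity covariance reduces to OLS", {
  set.seed(4)
  x <- rnorm(15)
  y <- 1 + 2 * x + rnorm(15)
  fit <- gls_fit(y, cbind(1, x), diag(15))
  ols <- lm(y ~ x)
  expect_equal(unname(fit$coefficients), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(unname(fit$t), unname(summary(ols)$coefficients[, "t value"]),
    tolerance = 1e-10
  )
  # two points, intercept only -> mean
  fit2 <- gls_fit(c(1, 3), cbind(c(1, 1), deparse.level = 0), diag(2))
  expect_equal(unname(fit2$coefficients), 2)
  expect_error(
    gls_fit(y, cbind(1, x, x2 = x), diag(15)),
    "collinear"
  )
})

test_that("whitened residuals are orthogonal to the whitened design", {
  set.seed(5)
  tr <- rand_tree(20, seed = 5)
  V <- vcv_bm(tr)
  x <- rnorm(20)
  y <- 2 + x + drop(crossprod(chol(V), rnorm(20)))
  X <- cbind(1, x)
  fit <- gls_fit(y, X, V)
  g <- t(X) %*% solve(V) %*% fit$residuals
  expect_true(max(abs(g)) / max(abs(y)) < 1e-8)
})

test_that("lambda profile likelihood peaks where it should", {
  # independent noise -> lambda near 0; pure BM -> lambda near 1
  n_rep <- 100
  hit0 <- hit1 <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    tr <- rand_tree(30, seed = 1000 + i)
    tr$edge.length <- tr$edge.length / tree_depth(tr)
    d <- tibble::tibble(species = tr$tip.label)
    set.seed(2000 + i)
    d$y0 <- rnorm(30)
    d$ybm <- as.numeric(simulate_bm(tr, 1, 0, seed = 3000 + i))
    f0 <- pgls(y0 ~ 1, d, tr)
    f1 <- pgls(ybm ~ 1, d, tr)
    hit0[i] <- f0$lambda < 0.1
    hit1[i] <- f1$lambda > 0.9
  }
  expect_gte(mean(hit0), 0.9)
  expect_gte(mean(hit1), 0.9)
})

test_that("profile likelihood at the ML lambda dominates fixed values", {
  sim <- default_study(seed = 6)
  d <- prep_analysis(sim)
  fit <- pgls(size ~ log10_body, d, sim$tree)
  for (lam in c(0, 0.5, 1)) {
    fixed <- pgls(size ~ log10_body, d, sim$tree, lambda = lam)
    expect_gte(fit$loglik + 1e-8, fixed$loglik)
  }
  expect_true(fit$lambda >= 0 && fit$lambda <= 1)
  expect_error(pgls(size ~ log10_body, d, sim$tree, lambda = 2), "lambda")
})

test_that("residual_trait returns raw-scale lambda-ML residuals in tip order", {
  tr <- rand_tree(15, seed = 7)
  x <- setNames(rnorm(15), tr$tip.label)
  # exactly linear response -> all residuals 0
  y_lin <- 3 + 2 * x
  expect_equal(
    unname(residual_trait(y_lin, x, tr)), rep(0, 15),
    tolerance = 1e-8
  )
  # BM noise -> GLS-weighted mean of residuals is 0
  y <- 1 + x + simulate_bm(tr, 0.5, 0, seed = 8)[tr$tip.label]
  r <- residual_trait(y, x, tr)
  expect_equal(names(r), tr$tip.label)
})

test_that("residual_trait separates clades by the injected grade offset", {
  offs <- vapply(1:40, function(i) {
    cfg <- simulation_config(seed = 5000 + i)
    tp <- simulate_tree(26, depth = 65, seed = cfg$seed + 11, prefix = "P")
    tc <- simulate_tree(29, depth = 55, seed = cfg$seed + 12, prefix = "C")
    tree <- graft_trees(tp, tc, 79)
    clades <- ifelse(grepl("^P", tree$tip.label), "primate", "carnivoran")
    allo <- simulate_allometry(tree, clades, cfg, seed = cfg$seed + 20)
    r <- residual_trait(
      setNames(allo$size, allo$species),
      setNames(allo$log10_body_length, allo$species), tree
    )
    mean(r[allo$clade == "primate"]) - mean(r[allo$clade == "carnivoran"])
  }, numeric(1))
  expect_equal(mean(offs), 1.05, tolerance = 0.1)
})

test_that("covariate models drop missing rows and flag collinearity", {
  sim <- default_study(seed = 10)
  d <- prep_analysis(sim)
  d$age_miss <- d$age_at_death_y
  d$age_miss[1:5] <- NA
  expect_message(
    fit <- covariate_model(d, sim$tree, "age_miss",
      response = "size", predictor = "log10_body"
    ),
    "5 species"
  )
  expect_equal(fit$n, 50)
  expect_equal(nrow(tidy(fit)), 4) # intercept, x, z, x:z
  d$dup <- d$log10_body
  expect_error(
    covariate_model(d, sim$tree, "dup",
      response = "size", predictor = "log10_body"
    ),
    "collinear"
  )
  d$const <- 1
  expect_error(
    covariate_model(d, sim$tree, "const",
      response = "size", predictor = "log10_body"
    ),
    "constant"
  )
})

test_that("an unrelated covariate is significant at roughly the nominal rate", {
  n_rep <- 150
  sig <- vapply(seq_len(n_rep), function(i) {
    tr <- rand_tree(40, seed = 8000 + i)
    tr$edge.length <- tr$edge.length / tree_depth(tr)
    x <- simulate_bm(tr, 1, 0, seed = 8300 + i)
    y <- 2 * x + simulate_bm(tr, 0.5, 0, seed = 8600 + i)
    set.seed(8900 + i)
    d <- tibble::tibble(
      species = tr$tip.label, y = as.numeric(y),
      x = as.numeric(x), z = rnorm(40)
    )
    fit <- covariate_model(d, tr, "z", response = "y", predictor = "x")
    tidy(fit)$p.value[3] < 0.05
  }, logical(1))
  expect_lt(mean(sig), 0.13)
})

test_that("tidy and glance expose the fit in broom shape", {
  sim <- default_study(seed = 11)
  d <- prep_analysis(sim)
  fit <- pgls(size ~ log10_body, d, sim$tree)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  gl <- glance(fit)
  expect_equal(gl$nobs, 55)
  expect_true(gl$lambda >= 0 && gl$lambda <= 1)
})
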