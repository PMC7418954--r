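#' Exact multivariate normal log-density
#'
#' The likelihood primitive behind every model fit in the package; kept
#' exported so likelihood code can be oracle-checked directly.
#'
#' @param y Observation vector.
#' @param mean Mean vector (recycled if scalar).
#' @param V Positive-definite covariance matrix.
#' @return Scalar log-density.
#' @export
loglik_mvn <- function(y, mean, V) {
  n <- length(y)
  if (length(mean) == 1) mean <- rep(mean, n)
  stopifnot(length(mean) == n, is.matrix(V), all(dim(V) == n))
  U <- tryCatch(chol(V), error = function(e) {
    abort("covariance matrix is not positive definite")
  })
  z <- backsolve(U, y - mean, transpose = TRUE)
  -0.5 * n * log(2 * pi) - sum(log(diag(U))) - 0.5 * sum(z^2)
}

# Core GLS engine: Cholesky whitening, ML sigma^2, Wald t statistics.
# sigma2 (reported) is the ML estimate e'V^-1 e / n; standard errors use
# the unbiased RSS/(n - p) so t and P follow the conventional t_{n-p}
# reference distribution.
.gls_core <- function(y, X, V) {
  n <- length(y)
  p <- ncol(X)
  if (n <= p) abort("need more observations than parameters")
  U <- tryCatch(chol(V), error = function(e) {
    abort("covariance matrix is not positive definite")
  })
  yw <- backsolve(U, y, transpose = TRUE)
  Xw <- backsolve(U, X, transpose = TRUE)
  qr_x <- qr(Xw)
  if (qr_x$rank < p) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):p]]
    abort(paste0(
      "design is singular; collinear column(s): ",
      paste(bad, collapse = ", ")
    ))
  }
  beta <- qr.coef(qr_x, yw)
  fitted <- drop(X %*% beta)
  resid_raw <- y - fitted
  ew <- yw - drop(Xw %*% beta)
  rss <- sum(ew^2)
  sigma2_ml <- rss / n
  sigma2_ub <- rss / (n - p)
  logdetV <- 2 * sum(log(diag(U)))
  loglik <- -0.5 * n * log(2 * pi) - 0.5 * n * log(sigma2_ml) -
    0.5 * logdetV - 0.5 * n
  XtX_inv <- chol2inv(qr.R(qr_x))[order(qr_x$pivot), order(qr_x$pivot), drop = FALSE]
  se <- sqrt(sigma2_ub * diag(XtX_inv))
  tval <- beta / se
  pval <- 2 * pt(abs(tval), df = n - p, lower.tail = FALSE)
  # restricted likelihood (used only as an alternative lambda-profile
  # objective; reported fits and model comparisons stay ML)
  loglik_reml <- -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(sigma2_ub) +
    logdetV + determinant(crossprod(Xw))$modulus + (n - p))
  list(
    loglik_reml = as.numeric(loglik_reml),
    coefficients = setNames(beta, colnames(X)),
    se = setNames(se, colnames(X)),
    t = setNames(tval, colnames(X)),
    p.value = setNames(pval, colnames(X)),
    sigma2 = sigma2_ml, sigma2_unbiased = sigma2_ub,
    loglik = loglik, rss_whitened = rss, logdetV = logdetV,
    fitted = fitted, residuals = resid_raw,
    n = n, p = p, df.residual = n - p, vcov_unscaled = XtX_inv
  )
}

#' Generalized least squares with a fixed covariance
#'
#' Fits `y = X beta + e`, `e ~ N(0, sigma2 V)`, by Cholesky whitening.
#' With `V = I` this reduces to ordinary least squares. `sigma2` is the
#' maximum-likelihood estimate; t statistics use the unbiased residual
#' variance and `n - p` degrees of freedom.
#'
#' @param y Response vector.
#' @param X Design matrix (include an intercept column yourself).
#' @param V Positive-definite error covariance (up to scale).
#' @return An object of class `gls_fit`.
#' @export
gls_fit <- function(y, X, V) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  out <- .gls_core(y, X, V)
  out$lambda <- NA_real_
  structure(out, class = c("gls_fit"))
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' Fits a linear model whose residual covariance is the Brownian-motion
#' tree covariance with off-diagonals scaled by Pagel's lambda. Lambda is
#' estimated by maximizing the ML profile likelihood over `[0, 1]`
#' (golden-section search, tolerance 1e-6, with both boundaries checked);
#' fixed values may be supplied instead. Estimation is ML, not REML,
#' so log-likelihoods of nested mean structures are comparable.
#'
#' @param formula Model formula, e.g. `size ~ log10(body_length_mm)`.
#' @param data Data frame with one row per species and a `species` column
#'   matching the tree tips (extra tips/rows are dropped via
#'   [match_taxa()]).
#' @param tree [ape::phylo] with branch lengths.
#' @param lambda `"ML"` (default), `"REML"`, or a fixed value in `[0, 1]`.
#'   `"REML"` profiles lambda on the restricted likelihood — less biased
#'   for the variance structure and the default inside [pancova()]'s F
#'   tests — while all reported log-likelihoods remain ML so nested mean
#'   structures stay comparable.
#' @param species_col Name of the species column.
#' @return Object of class `pgls_fit`: coefficients, `lambda`, `sigma2`
#'   (ML), `loglik`, t and P per coefficient, raw-scale `residuals` in tip
#'   order, and the matched data/tree.
#' @examples
#' sim <- simulate_study(simulation_config(seed = 1))
#' fit <- pgls(size ~ log10(body_length_mm), sim$specimens, sim$tree)
#' tidy(fit)
#' @export
pgls <- function(formula, data, tree, lambda = "ML", species_col = "species") {
  m <- match_taxa(tree, data, species_col = species_col, quiet = TRUE)
  data <- m$data
  tree <- m$tree
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.pass)
  keep <- stats::complete.cases(mf)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    data <- data[keep, , drop = FALSE]
    tree <- ape::keep.tip(tree, data[[species_col]])
    mf <- mf[keep, , drop = FALSE]
    inform(sprintf("dropped %d rows with missing model variables", n_dropped))
  }
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  V0 <- vcv_bm(tree)
  n <- length(y)
  if (n <= ncol(X) + 1) abort("too few species for lambda estimation")
  obj_field <- if (identical(lambda, "REML")) "loglik_reml" else "loglik"
  profile <- function(lam) .gls_core(y, X, apply_lambda(V0, lam))[[obj_field]]
  if (identical(lambda, "ML") || identical(lambda, "REML")) {
    opt <- optimize(profile, c(0, 1), maximum = TRUE, tol = 1e-6)
    cands <- c(opt$maximum, 0, 1)
    lls <- c(opt$objective, profile(0), profile(1))
    lam_hat <- cands[which.max(lls)]
    lambda_estimated <- TRUE
  } else {
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1) {
      abort("lambda must be 'ML', 'REML', or a value in [0, 1]")
    }
    lam_hat <- lambda
    lambda_estimated <- FALSE
  }
  out <- .gls_core(y, X, apply_lambda(V0, lam_hat))
  out$lambda <- lam_hat
  out$lambda_estimated <- lambda_estimated
  out$formula <- formula
  out$tree <- tree
  out$data <- data
  out$species <- data[[species_col]]
  out$n_dropped <- n_dropped
  names(out$residuals) <- data[[species_col]]
  structure(out, class = c("pgls_fit", "gls_fit"))
}

#' @export
print.gls_fit <- function(x, ...) {
  if (inherits(x, "pgls_fit")) {
    cat(sprintf(
      "pGLS fit (n = %d, lambda = %.4g%s)\n", x$n, x$lambda,
      if (isTRUE(x$lambda_estimated)) ", ML" else ", fixed"
    ))
  } else {
    cat(sprintf("GLS fit (n = %d)\n", x$n))
  }
  cm <- cbind(
    estimate = x$coefficients, se = x$se,
    t = x$t, p = x$p.value
  )
  print(round(cm, 4))
  cat(sprintf(
    "sigma2 (ML) = %.4g   loglik = %.3f\n", x$sigma2, x$loglik
  ))
  invisible(x)
}

#' @rdname pgls
#' @param x,object A fitted `gls_fit` / `pgls_fit`.
#' @param ... Unused.
#' @export
tidy.gls_fit <- function(x, ...) {
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    statistic = unname(x$t),
    p.value = unname(x$p.value)
  )
}

#' @rdname pgls
#' @export
glance.gls_fit <- function(x, ...) {
  tibble(
    nobs = x$n, df.residual = x$df.residual,
    lambda = x$lambda, sigma2 = x$sigma2,
    logLik = x$loglik,
    AIC = -2 * x$loglik + 2 * (x$p + 1 + if (isTRUE(x$lambda_estimated)) 1 else 0)
  )
}

#' @export
residuals.gls_fit <- function(object, ...) object$residuals

#' @export
coef.gls_fit <- function(object, ...) object$coefficients

#' @export
logLik.gls_fit <- function(object, ...) {
  structure(object$loglik,
    df = object$p + 1, nobs = object$n,
    class = "logLik"
  )
}

#' Residual trait from a phylogenetic regression
#'
#' "Relative larynx size": raw-scale residuals of the lambda-ML pGLS of a
#' trait on a predictor, in tip order. These residuals are the working
#' trait for shift detection, rate comparison and the phenogram.
#'
#' @param y Response vector in tip order (or named by tip labels).
#' @param x Predictor vector, same order.
#' @param tree [ape::phylo] object.
#' @return Named numeric vector of residuals (tip order).
#' @export
residual_trait <- function(y, x, tree) {
  tips <- tree$tip.label
  if (!is.null(names(y))) y <- y[tips]
  if (!is.null(names(x))) x <- x[tips]
  df <- tibble(species = tips, .y = as.numeric(y), .x = as.numeric(x))
  fit <- pgls(.y ~ .x, df, tree)
  res <- fit$residuals
  res[tips]
}

#' Covariate pGLS models for larynx size
#'
#' Fits `size ~ predictor + covariate + predictor:covariate` by
#' lambda-ML pGLS, dropping rows where the covariate is missing (listwise
#' deletion, count reported). Used to check that grade-shift results are
#' robust to specimen sex, relative age at death, and sexual size
#' dimorphism.
#'
#' @param data Specimen tibble with `species`, the response and predictor
#'   columns, and the covariate.
#' @param tree [ape::phylo] object.
#' @param covariate Covariate column name (string). A derived covariate
#'   can be added to `data` first (e.g. relative age).
#' @param response,predictor Column names of response and predictor.
#' @return A `pgls_fit`; the covariate main-effect and interaction rows of
#'   `tidy()` are the test of interest.
#' @export
covariate_model <- function(data, tree, covariate, response = "size",
                            predictor = "log10_body_length") {
  data <- as_tibble(data)
  for (col in c(response, predictor, covariate)) {
    if (!col %in% names(data)) abort(paste0("no column '", col, "' in data"))
  }
  keep <- !is.na(data[[covariate]])
  if (is.character(data[[covariate]])) keep <- keep & data[[covariate]] != "unknown"
  dropped <- sum(!keep)
  sub <- data[keep, , drop = FALSE]
  z <- sub[[covariate]]
  if (length(unique(z)) < 2) {
    abort(paste0("covariate '", covariate, "' is constant after subsetting"))
  }
  if (dropped > 0) {
    inform(sprintf(
      "covariate_model(%s): %d species with missing covariate dropped (n = %d)",
      covariate, dropped, nrow(sub)
    ))
  }
  f <- stats::as.formula(paste0(
    response, " ~ ", predictor, " * ", covariate
  ))
  pgls(f, sub, tree)
}
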