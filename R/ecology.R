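#' Acoustic allometry: fundamental frequency against larynx size
#'
#' lambda-ML pGLS of log10 mean F0 on larynx-size scores, optionally
#' within one clade. Species without usable F0 are dropped and named in a
#' message (mirroring the exclusion of species with too few measurable
#' calls).
#'
#' @param data Tibble with `species`, `clade`, `size` and `mean_f0_hz`.
#' @param tree [ape::phylo] object.
#' @param clade Optional clade to subset to (`"primate"` /
#'   `"carnivoran"`); default uses all species.
#' @param size_col,f0_col Column names.
#' @return A `pgls_fit` of `log10(F0) ~ size`.
#' @export
f0_allometry <- function(data, tree, clade = NULL, size_col = "size",
                         f0_col = "mean_f0_hz") {
  data <- as_tibble(data)
  for (col in c("species", size_col, f0_col)) {
    if (!col %in% names(data)) abort(paste0("no column '", col, "' in data"))
  }
  if (!is.null(clade)) data <- data[data$clade == clade, , drop = FALSE]
  excluded <- data$species[is.na(data[[f0_col]]) | data[[f0_col]] <= 0]
  if (length(excluded)) {
    inform(paste0(
      "excluded (no usable F0): ", paste(excluded, collapse = ", ")
    ))
    data <- data[!data$species %in% excluded, , drop = FALSE]
  }
  if (nrow(data) < 10) abort("need at least 10 species with F0 after matching")
  data$log10_f0 <- log10(data[[f0_col]])
  data$.size <- data[[size_col]]
  pgls(log10_f0 ~ .size, data, tree)
}

#' Cross-clade comparison of F0 allometric slopes
#'
#' pANCOVA slopes test of `log10(F0) ~ size` between clades.
#'
#' @inheritParams f0_allometry
#' @return A `pancova_result`.
#' @export
f0_slope_comparison <- function(data, tree, size_col = "size",
                                f0_col = "mean_f0_hz") {
  data <- as_tibble(data)
  data <- data[!is.na(data[[f0_col]]) & data[[f0_col]] > 0, , drop = FALSE]
  data$log10_f0 <- log10(data[[f0_col]])
  data$.size <- data[[size_col]]
  pancova(data, tree,
    response = "log10_f0", predictor = ".size",
    group = "clade", hypothesis = "slopes"
  )
}

#' Ordinary (non-phylogenetic) R-squared
#'
#' Coefficient of determination of `lm(y ~ x)` — used for comparing which
#' acoustic summary (mean, maximum, minimum or range of F0) tracks larynx
#' size best, deliberately without phylogenetic correction.
#'
#' @param y,x Numeric vectors (>= 3 complete pairs).
#' @return Scalar R-squared.
#' @export
ols_r2 <- function(y, x) {
  ok <- is.finite(y) & is.finite(x)
  y <- y[ok]
  x <- x[ok]
  if (length(y) < 3) abort("need at least 3 complete pairs")
  if (stats::sd(x) == 0) abort("x is constant; R2 undefined")
  summary(stats::lm(y ~ x))$r.squared
}

#' Mann-Whitney U test
#'
#' Exact U statistic for the first sample (`U_a = sum of ranks of a minus
#' n_a (n_a + 1) / 2`, midranks for ties; `U_a + U_b = n_a n_b` always).
#' P is by exact enumeration for small tie-free samples and the
#' tie-corrected normal approximation otherwise (two-sided).
#'
#' @param a,b Numeric vectors.
#' @return List with `U` (first group), `U_b`, `P`, `n`.
#' @export
mann_whitney <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (!length(a) || !length(b)) abort("both samples must be non-empty")
  n_a <- length(a)
  n_b <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  U_b <- n_a * n_b - U
  ties <- any(duplicated(c(a, b)))
  if (!ties && n_a <= 20 && n_b <= 20) {
    P <- stats::wilcox.test(a, b, exact = TRUE)$p.value
  } else {
    mu <- n_a * n_b / 2
    tie_tab <- table(c(a, b))
    n <- n_a + n_b
    sig2 <- n_a * n_b / 12 *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
    P <- 2 * stats::pnorm(-abs(z))
  }
  list(U = U, U_b = U_b, P = P, n = c(a = n_a, b = n_b))
}

#' Spearman rank correlation
#'
#' Rank correlation with midranks for ties; P from the t approximation
#' `t = r sqrt((n - 2) / (1 - r^2))` on n - 2 df (two-sided). Invariant to
#' monotone transforms of either input.
#'
#' @param a,b Numeric vectors (>= 4 complete pairs).
#' @return List with `r`, `P`, `n`.
#' @export
spearman_cor <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]
  b <- b[ok]
  n <- length(a)
  if (n < 4) abort("need at least 4 complete pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    abort("constant vector; rank correlation undefined")
  }
  r <- stats::cor(rank(a), rank(b))
  P <- if (abs(r) >= 1) {
    0
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(abs(tval), df = n - 2, lower.tail = FALSE)
  }
  list(r = r, P = P, n = n)
}

#' Location and dispersion of group sizes
#'
#' Returns the median plus two dispersion variants: the unscaled median
#' absolute deviation about the median, and the mean absolute deviation
#' about the mean. Both are reported because "median absolute deviation"
#' is used ambiguously across the comparative literature and the two can
#' differ wildly for skewed group-size data; neither is privileged here.
#'
#' @param values Numeric vector (>= 2 values).
#' @return List with `median`, `mad_median`, `mad_mean`, `n`.
#' @export
group_dispersion <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) abort("need at least 2 values")
  list(
    median = stats::median(values),
    mad_median = stats::median(abs(values - stats::median(values))),
    mad_mean = mean(abs(values - mean(values))),
    n = length(values)
  )
}

#' Assemble a mean group size from field descriptions
#'
#' Encodes the standard cleaning rules for heterogeneous group-size
#' sources: an explicitly stated mean wins; species described as solitary
#' get 1; a breeding-pair social unit gets 2; otherwise the midpoint of
#' the reported minimum-maximum range.
#'
#' @param min,max Reported range bounds (NA if absent).
#' @param mean Explicitly stated mean (NA if absent).
#' @param sociality Optional description: `"solitary"`, `"pair"`, or
#'   anything else / NA.
#' @return Scalar mean group size.
#' @export
assign_group_size <- function(min = NA, max = NA, mean = NA, sociality = NA) {
  if (!is.na(mean)) {
    return(mean)
  }
  if (!is.na(sociality)) {
    if (sociality == "solitary") {
      return(1)
    }
    if (sociality == "pair") {
      return(2)
    }
  }
  if (!is.na(min) && !is.na(max)) {
    return((min + max) / 2)
  }
  abort("cannot assign group size: no mean, sociality rule, or range")
}
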