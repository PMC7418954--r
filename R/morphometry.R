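#' Interlandmark distances from a 14-landmark configuration
#'
#' Converts 3-D laryngeal landmark coordinates into the 10 canonical
#' measurements (see [measurement_names()]). Landmarks follow the standard
#' numbering: 1-4 midsagittal cricoid (ventral basal, ventral apical,
#' dorsal basal, dorsal apical), 5-6 lateral basal cricoid, 7-9 ventral
#' thyroid (basal, apical, midpoint), 10-11 lateral dorsal thyroid,
#' 12-13 right/left arytenoid vocal processes, 14 hyoid apex. Vocal fold
#' length is the mean of the 9-12 and 9-13 distances.
#'
#' @param landmarks Either a 14 x 3 numeric matrix (rows = landmarks 1-14,
#'   columns x/y/z, mm), or a data frame with columns `landmark`
#'   (integer 1-14), `x`, `y`, `z`, and optionally `species` for many
#'   specimens at once.
#' @param tol Two landmarks closer than `tol` (mm) trigger a warning
#'   (coincident points usually indicate a digitization slip).
#' @return A one-row tibble of the 10 measurements, with a `species`
#'   column when the input carries one.
#' @examples
#' lm <- landmark_template() * 20
#' landmark_distances(lm)
#' @export
landmark_distances <- function(landmarks, tol = 1e-8) {
  if (is.data.frame(landmarks)) {
    df <- as_tibble(landmarks)
    req <- c("landmark", "x", "y", "z")
    if (!all(req %in% names(df))) {
      abort("landmark data frame needs columns landmark, x, y, z")
    }
    if ("species" %in% names(df)) {
      out <- df |>
        group_by(.data$species) |>
        group_modify(~ landmark_distances(.lm_matrix(.x), tol = tol)) |>
        ungroup()
      return(out)
    }
    landmarks <- .lm_matrix(df)
  }
  if (!is.matrix(landmarks) || ncol(landmarks) != 3) {
    abort("landmarks must be a 14 x 3 matrix")
  }
  if (nrow(landmarks) != 14) {
    abort(sprintf("expected 14 landmarks, got %d", nrow(landmarks)))
  }
  if (anyNA(landmarks) || any(!is.finite(landmarks))) {
    bad <- which(apply(landmarks, 1, function(r) anyNA(r) || any(!is.finite(r))))
    abort(paste0(
      "missing/non-finite coordinates for landmark(s): ",
      paste(bad, collapse = ", ")
    ))
  }
  dmat <- as.matrix(stats::dist(landmarks))
  off <- dmat[upper.tri(dmat)]
  if (any(off < tol)) {
    warn("some landmarks are (near-)coincident")
  }
  pairs <- .measurement_pairs()
  vals <- map_dbl(names(pairs), function(nm) {
    if (nm == "vocal_fold_length") {
      (dmat[9, 12] + dmat[9, 13]) / 2
    } else {
      p <- pairs[[nm]]
      dmat[p[1], p[2]]
    }
  })
  as_tibble(as.list(setNames(vals, names(pairs))))
}

.lm_matrix <- function(df) {
  df <- df[order(df$landmark), ]
  if (!identical(as.integer(df$landmark), 1:14)) {
    missing_lm <- setdiff(1:14, df$landmark)
    abort(paste0(
      "landmark set incomplete; missing landmark(s): ",
      paste(missing_lm, collapse = ", ")
    ))
  }
  as.matrix(df[, c("x", "y", "z")])
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean,
#' computed on raw (not log) values — the convention used for ranking
#' measurement variability across species.
#'
#' @param x Numeric vector, at least two values, positive mean.
#' @param na.rm Drop missing values first.
#' @return Scalar CV.
#' @export
cv <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) < 2) abort("cv needs at least 2 values")
  m <- mean(x)
  if (!is.finite(m) || m <= 0) abort("cv needs a positive mean")
  stats::sd(x) / m
}

#' The "larynx size" principal-component axis
#'
#' Runs a correlation-matrix PCA on the log10 measurements and keeps the
#' leading component as a single size axis. Loadings are standardized
#' (eigenvector times the square root of the eigenvalue, i.e. the scale in
#' which a loading is the correlation between component and variable), and
#' the axis is sign-oriented so the mean loading is positive — larger
#' scores mean larger larynges. Scores are standardized to unit variance by
#' default; all downstream regressions use these scores, so slope
#' magnitudes are tied to this convention.
#'
#' @param data Data frame with one row per species: a species column plus
#'   the 10 measurement columns (raw mm by default).
#' @param measurements Character vector of measurement column names.
#' @param log10 Log10-transform the columns first (set `FALSE` if the
#'   table already holds log10 values).
#' @param scores `"standardized"` (unit variance, default) or `"raw"`
#'   (eigenvector-projection scale, variance = eigenvalue) — the
#'   alternative convention kept switchable for reconciliation of slope
#'   magnitudes.
#' @return An object of class `size_axis`: list with `scores` (tibble
#'   `species`, `size`), `loadings`, `variance_explained`, `correlations`,
#'   `eigenvalues`, `cv` (per-measurement raw-value CV).
#' @examples
#' dat <- simulate_study(simulation_config(seed = 1))$specimens
#' ax <- size_axis(dat)
#' ax$variance_explained
#' @export
size_axis <- function(data, measurements = measurement_names(),
                      log10 = TRUE, scores = c("standardized", "raw")) {
  scores <- match.arg(scores)
  data <- as_tibble(data)
  missing_cols <- setdiff(measurements, names(data))
  if (length(missing_cols)) {
    abort(paste0("missing measurement columns: ", paste(missing_cols, collapse = ", ")))
  }
  X_raw <- as.matrix(data[, measurements])
  if (nrow(X_raw) < 3) abort("size_axis needs at least 3 species")
  if (anyNA(X_raw)) abort("measurement table has missing cells")
  X <- if (log10) log10(X_raw) else X_raw
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    abort(paste0(
      "constant column(s), correlation undefined: ",
      paste(measurements[sds == 0], collapse = ", ")
    ))
  }
  R <- stats::cor(X)
  eig <- eigen(R, symmetric = TRUE)
  v1 <- eig$vectors[, 1]
  loadings <- v1 * sqrt(eig$values[1])
  if (mean(loadings) < 0) {
    loadings <- -loadings
    v1 <- -v1
  }
  Z <- scale(X) # unit-variance columns
  raw_scores <- drop(Z %*% v1)
  sc <- if (scores == "standardized") {
    as.vector(scale(raw_scores))
  } else {
    raw_scores - mean(raw_scores)
  }
  species <- if ("species" %in% names(data)) data$species else paste0("sp", seq_len(nrow(data)))
  structure(
    list(
      scores = tibble(species = species, size = sc),
      loadings = setNames(loadings, measurements),
      variance_explained = eig$values[1] / length(measurements),
      eigenvalues = eig$values,
      correlations = setNames(drop(stats::cor(sc, X)), measurements),
      cv = setNames(apply(X_raw, 2, cv), measurements),
      score_convention = scores
    ),
    class = "size_axis"
  )
}

#' @export
print.size_axis <- function(x, ...) {
  cat(sprintf(
    "Larynx size axis: PC1 of %d log10 measurements across %d species\n",
    length(x$loadings), nrow(x$scores)
  ))
  cat(sprintf(
    "  variance explained: %.1f%%   mean loading: %.3f (SD %.3f)\n",
    100 * x$variance_explained, mean(x$loadings), stats::sd(x$loadings)
  ))
  invisible(x)
}

#' @rdname size_axis
#' @param x A `size_axis` object.
#' @param ... Unused.
#' @export
tidy.size_axis <- function(x, ...) {
  tibble(
    measurement = names(x$loadings),
    cv = unname(x$cv),
    loading = unname(x$loadings),
    correlation = unname(x$correlations)
  ) |>
    arrange(desc(.data$cv))
}

#' @rdname size_axis
#' @export
glance.size_axis <- function(x, ...) {
  tibble(
    n_species = nrow(x$scores),
    variance_explained = x$variance_explained,
    mean_loading = mean(x$loadings),
    sd_loading = stats::sd(x$loadings)
  )
}

#' @export
autoplot.size_axis <- function(object, ...) {
  td <- tidy(object)
  td$measurement <- factor(td$measurement, levels = rev(td$measurement))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$loading, y = .data$measurement)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(
      x = "standardized loading on larynx size (PC1)", y = NULL,
      title = sprintf(
        "PC1 explains %.0f%% of measurement variation",
        100 * object$variance_explained
      )
    ) +
    ggplot2::theme_minimal()
}
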