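#' Allometry scatter plot with clade regression lines
#'
#' log10 body size against larynx-size scores, coloured by clade, with
#' the common-slope pGLS fit drawn per clade (the visual of an allometric
#' grade shift).
#'
#' @param data Tibble with `size`, a log10 body-size column and `clade`.
#' @param fit Optional `pancova_result` (intercepts hypothesis) whose full
#'   model supplies the lines; omitted lines fall back to per-clade OLS.
#' @param predictor Name of the log10 body-size column.
#' @return A ggplot object.
#' @export
plot_allometry <- function(data, fit = NULL, predictor = "log10_body") {
  p <- ggplot2::ggplot(
    data,
    ggplot2::aes(
      x = .data[[predictor]], y = .data$size,
      colour = .data$clade
    )
  ) +
    ggplot2::geom_point(size = 2)
  if (!is.null(fit) && inherits(fit, "pancova_result")) {
    cf <- fit$model_full$coefficients
    slope <- cf[[2]]
    groups <- levels(factor(data$clade))
    ints <- cf[[1]] + c(0, cf[-(1:2)])
    lines <- tibble(
      clade = groups,
      intercept = ints[seq_along(groups)], slope = slope
    )
    p <- p + ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(
        intercept = .data$intercept, slope = .data$slope,
        colour = .data$clade
      )
    )
  } else {
    p <- p + ggplot2::geom_smooth(
      method = "lm", formula = y ~ x, se = FALSE
    )
  }
  p + ggplot2::labs(
    x = "log10 body size", y = "larynx size (PC1 score)"
  ) +
    ggplot2::theme_minimal()
}

#' Phenogram of ancestral trait diversification
#'
#' Divergence time against (reconstructed) trait value: each edge of the
#' phylogeny is a segment from parent to child in (height, value) space.
#'
#' @param anc An `ancestral_states` object.
#' @param clades Optional named vector mapping tip label to clade for
#'   colouring; internal edges take the clade of their descendants (mixed
#'   ancestry falls back to "stem").
#' @return A ggplot object.
#' @export
plot_phenogram <- function(anc, clades = NULL) {
  tree <- anc$tree
  nodes <- anc$nodes
  idx <- match(tree$edge[, 2], nodes$node)
  par_idx <- match(tree$edge[, 1], nodes$node)
  seg <- tibble(
    x = nodes$height[par_idx], y = nodes$value[par_idx],
    xend = nodes$height[idx], yend = nodes$value[idx]
  )
  if (!is.null(clades)) {
    tip_clade <- clades[tree$tip.label]
    node_clade <- character(max(tree$edge))
    node_clade[seq_along(tree$tip.label)] <- tip_clade
    for (e in rev(seq_len(nrow(tree$edge)))) { # postorder-ish fill
      ch <- tree$edge[e, 2]
      pa <- tree$edge[e, 1]
      if (node_clade[pa] == "") {
        node_clade[pa] <- node_clade[ch]
      } else if (node_clade[pa] != node_clade[ch]) {
        node_clade[pa] <- "stem"
      }
    }
    seg$clade <- node_clade[tree$edge[, 2]]
  }
  p <- ggplot2::ggplot(seg)
  if (!is.null(clades)) {
    p <- p + ggplot2::geom_segment(ggplot2::aes(
      x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend,
      colour = .data$clade
    ))
  } else {
    p <- p + ggplot2::geom_segment(ggplot2::aes(
      x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend
    ))
  }
  p + ggplot2::labs(
    x = "time from root (My)", y = "residual larynx size"
  ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ancestral_states <- function(object, ...) plot_phenogram(object, ...)

#' @export
autoplot.rate_result <- function(object, ...) {
  if (is.null(object$posterior_a)) {
    abort("rate_result has no posterior draws; rerun with n_draws > 0")
  }
  df <- bind_rows(
    tibble(clade = "a", rate = object$posterior_a),
    tibble(clade = "b", rate = object$posterior_b)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rate, fill = .data$clade)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::labs(
      x = "Brownian-motion rate (trait units² / My)", y = "density",
      title = sprintf(
        "rate ratio %.2f, permutation P = %.3g", object$ratio, object$P
      )
    ) +
    ggplot2::theme_minimal()
}
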