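#' Configuration for a full pipeline run
#'
#' Collects inputs and analysis switches for [run_all()]. Inputs are
#' either in-memory objects (`specimens` + `tree`, e.g. from
#' [simulate_study()]) or file paths (`specimen_csv` plus one joined tree
#' or two clade trees grafted at `root_age`).
#'
#' @param specimens Specimen tibble (schema of [specimen_dictionary()]).
#' @param tree [ape::phylo], already joined.
#' @param specimen_csv,tree_file,tree_file2 File-based alternatives; with
#'   two tree files the clade trees are grafted at `root_age`.
#' @param root_age Root age (My) used when grafting two clade trees.
#' @param predictor `"body_length"` (default) or `"body_mass"` — the
#'   body-size proxy; the mass variant is the same pipeline with
#'   `log10(body_mass_g)` as predictor.
#' @param covariates Run the covariate pGLS models.
#' @param ou Run OU shift detection.
#' @param max_shifts Maximum shifts for [detect_shifts()].
#' @param bootstrap_B Parametric-bootstrap replicates for shift support
#'   (0 skips the bootstrap).
#' @param rates Run the rate comparisons.
#' @param acoustics Run F0 and social-group analyses.
#' @param n_perm Permutations for rate tests.
#' @param n_draws Posterior draws per clade rate.
#' @param seed Mandatory seed governing every stochastic stage.
#' @param score_convention Passed to [size_axis()].
#' @return List of class `run_config`.
#' @export
run_config <- function(specimens = NULL, tree = NULL, specimen_csv = NULL,
                       tree_file = NULL, tree_file2 = NULL, root_age = 79,
                       predictor = c("body_length", "body_mass"),
                       covariates = TRUE, ou = TRUE, max_shifts = 3,
                       bootstrap_B = 0, rates = TRUE, acoustics = TRUE,
                       n_perm = 1999, n_draws = 2000, seed,
                       score_convention = "standardized") {
  if (missing(seed)) abort("run_config requires an explicit seed")
  predictor <- match.arg(predictor)
  cfg <- structure(as.list(environment()), class = "run_config")
  validate_config(cfg)
}

#' @rdname run_config
#' @param config A `run_config` to check.
#' @export
validate_config <- function(config) {
  if (!inherits(config, "run_config")) abort("not a run_config")
  has_mem <- !is.null(config$specimens) && !is.null(config$tree)
  has_files <- !is.null(config$specimen_csv) && !is.null(config$tree_file)
  if (!has_mem && !has_files) {
    abort("provide specimens + tree, or specimen_csv + tree_file")
  }
  for (f in c(config$specimen_csv, config$tree_file, config$tree_file2)) {
    if (!is.null(f) && !file.exists(f)) abort(paste0("file not found: ", f))
  }
  if (!is.numeric(config$seed)) abort("seed must be numeric")
  config
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full comparative analysis
#'
#' Executes the standard analysis order: size axis from the measurement
#' table, lambda-ML pGLS allometry, pANCOVA (slopes then intercepts),
#' covariate models, grade magnitude from matched pairs, OU shift
#' detection (with optional bootstrap support) and its tip-level pANCOVA
#' confirmation, clade rate comparison with posterior draws, larynx-vs-
#' body rate comparison, ancestral states for the phenogram, and the
#' F0 / social-group analyses. Any stage failure aborts with the stage
#' name. Reruns with the same config are deterministic.
#'
#' @param config A [run_config()].
#' @return List of class `larynx_report`; see [report_json()] for the
#'   machine-readable serialization.
#' @examples
#' sim <- simulate_study(simulation_config(seed = 1))
#' rep <- run_all(run_config(
#'   specimens = sim$specimens, tree = sim$tree,
#'   ou = FALSE, rates = FALSE, covariates = FALSE, acoustics = FALSE,
#'   seed = 1
#' ))
#' names(rep$results)
#' @export
run_all <- function(config) {
  config <- validate_config(config)
  res <- list()
  prov <- list(
    seed = config$seed, timestamp = NA_character_,
    package_version = as.character(utils::packageVersion("laryngevol"))
  )

  dat <- .stage("load", {
    specimens <- if (!is.null(config$specimens)) {
      validate_specimen_table(config$specimens)
    } else {
      read_specimen_table(config$specimen_csv)
    }
    tree <- if (!is.null(config$tree)) {
      validate_tree(config$tree)
    } else if (!is.null(config$tree_file2)) {
      graft_trees(
        read_tree(config$tree_file), read_tree(config$tree_file2),
        root_age = config$root_age
      )
    } else {
      read_tree(config$tree_file)
    }
    m <- match_taxa(tree, specimens, quiet = TRUE)
    list(specimens = m$data, tree = m$tree)
  })
  specimens <- dat$specimens
  tree <- dat$tree

  axis <- .stage("size_axis", {
    size_axis(specimens, scores = config$score_convention)
  })
  res$size_axis <- axis
  d <- specimens
  d$size <- axis$scores$size
  pred_col <- if (config$predictor == "body_length") {
    "body_length_mm"
  } else {
    "body_mass_g"
  }
  d$log10_body <- log10(d[[pred_col]])

  res$allometry <- .stage("pgls_allometry", {
    pgls(size ~ log10_body, d, tree)
  })
  d$residual <- unname(res$allometry$residuals[d$species])

  res$pancova_slopes <- .stage("pancova_slopes", {
    pancova(d, tree,
      response = "size", predictor = "log10_body",
      group = "clade", hypothesis = "slopes"
    )
  })
  res$pancova_intercepts <- .stage("pancova_intercepts", {
    pancova(d, tree,
      response = "size", predictor = "log10_body",
      group = "clade", hypothesis = "intercepts"
    )
  })
  res$grade_magnitude <- .stage("grade_magnitude", {
    if (all(measurement_names() %in% names(d))) grade_magnitude(d) else NULL
  })

  if (config$covariates) {
    res$covariates <- .stage("covariate_models", {
      out <- list()
      if ("specimen_sex" %in% names(d)) {
        out$specimen_sex <- covariate_model(
          d, tree, "specimen_sex",
          response = "size", predictor = "log10_body"
        )
      }
      if (all(c("age_at_death_y", "max_lifespan_y") %in% names(d))) {
        d$relative_age <- d$age_at_death_y / d$max_lifespan_y
        out$relative_age <- covariate_model(
          d, tree, "relative_age",
          response = "size", predictor = "log10_body"
        )
      }
      if (all(c("male_mass_g", "female_mass_g") %in% names(d))) {
        d$ssd <- log10(d$male_mass_g) / log10(d$female_mass_g)
        out$ssd <- covariate_model(
          d, tree, "ssd",
          response = "size", predictor = "log10_body"
        )
        if ("specimen_sex" %in% names(d)) {
          d$ss_x_ssd <- ifelse(d$specimen_sex == "M", d$ssd,
            ifelse(d$specimen_sex == "F", 0, NA)
          )
          out$ss_x_ssd <- covariate_model(
            d, tree, "ss_x_ssd",
            response = "size", predictor = "log10_body"
          )
        }
      }
      out
    })
  }

  resid_vec <- setNames(d$residual, d$species)
  clade_tips <- split(d$species, d$clade)

  if (config$ou) {
    res$shifts <- .stage("detect_shifts", {
      m <- detect_shifts(resid_vec, tree, max_shifts = config$max_shifts)
      if (config$bootstrap_B > 0 && length(m$shifts)) {
        m <- shift_support(m, B = config$bootstrap_B, seed = config$seed)
      }
      m
    })
    res$snr <- snr(res$shifts)
    if (length(res$shifts$shifts)) {
      res$pancova_regimes <- .stage("pancova_regimes", {
        pancova(d, tree,
          response = "size", predictor = "log10_body",
          hypothesis = "regimes", regimes = res$shifts
        )
      })
    }
  }

  if (config$rates) {
    res$rate_test <- .stage("rate_ratio", {
      rate_ratio_test(resid_vec, tree,
        tips_a = clade_tips$primate, tips_b = clade_tips$carnivoran,
        n_perm = config$n_perm, seed = config$seed,
        n_draws = config$n_draws
      )
    })
    if ("crico_thyroid_distance" %in% names(d)) {
      lar <- setNames(log10(d$crico_thyroid_distance), d$species)
      bod <- setNames(d$log10_body, d$species)
      res$larynx_vs_body <- .stage("larynx_vs_body_rate", {
        list(
          overall = trait_vs_body_rate(lar, bod, tree,
            n_perm = config$n_perm, seed = config$seed + 1
          ),
          primate = trait_vs_body_rate(lar, bod, tree,
            tips = clade_tips$primate,
            n_perm = config$n_perm, seed = config$seed + 2
          ),
          carnivoran = trait_vs_body_rate(lar, bod, tree,
            tips = clade_tips$carnivoran,
            n_perm = config$n_perm, seed = config$seed + 3
          )
        )
      })
    }
    res$phenogram <- .stage("ancestral_states", {
      er <- clade_edge_rates(
        tree, clade_tips,
        rates = c(
          primate = res$rate_test$sigma2_a,
          carnivoran = res$rate_test$sigma2_b
        )
      )
      ancestral_states(resid_vec, tree, edge_rates = er)
    })
  }

  if (config$acoustics && "mean_f0_hz" %in% names(d)) {
    res$f0 <- .stage("f0_allometry", {
      list(
        primate = f0_allometry(d, tree, clade = "primate"),
        carnivoran = f0_allometry(d, tree, clade = "carnivoran"),
        slope_comparison = f0_slope_comparison(d, tree),
        ols_r2_mean = ols_r2(d$size, log10(d$mean_f0_hz))
      )
    })
    if ("group_size" %in% names(d)) {
      res$social <- .stage("social_groups", {
        g <- split(d$group_size, d$clade)
        list(
          mann_whitney = mann_whitney(g$primate, g$carnivoran),
          dispersion = lapply(g, group_dispersion),
          spearman = c(
            lapply(
              split(d, d$clade),
              function(s) spearman_cor(s$size, s$group_size)
            ),
            list(overall = spearman_cor(d$size, d$group_size))
          )
        )
      })
    }
  }

  structure(
    list(
      results = res, data = d, tree = tree, config = config,
      provenance = prov
    ),
    class = "larynx_report"
  )
}

#' @export
print.larynx_report <- function(x, ...) {
  r <- x$results
  cat("Larynx-size comparative analysis report\n")
  cat(sprintf(
    "  %d species; PC1 variance explained %.1f%%\n",
    nrow(x$data), 100 * r$size_axis$variance_explained
  ))
  if (!is.null(r$allometry)) {
    cat(sprintf(
      "  allometry: slope %.3f, lambda %.3f\n",
      r$allometry$coefficients[["log10_body"]], r$allometry$lambda
    ))
  }
  if (!is.null(r$pancova_intercepts)) {
    cat(sprintf(
      "  grade shift (intercepts): F(%d,%d) = %.3f, P = %.2g\n",
      r$pancova_intercepts$df_num, r$pancova_intercepts$df_den,
      r$pancova_intercepts$F, r$pancova_intercepts$P
    ))
  }
  if (!is.null(r$shifts)) {
    cat(sprintf(
      "  OU shifts detected: %d (snr %.2f)\n",
      length(r$shifts$shifts), r$snr
    ))
  }
  if (!is.null(r$rate_test)) {
    cat(sprintf(
      "  clade rate ratio: %.2f (P = %.3g)\n",
      r$rate_test$ratio, r$rate_test$P
    ))
  }
  invisible(x)
}

#' Serialize a report to machine-readable JSON
#'
#' Writes a stable, versioned summary of every computed statistic together
#' with the seed and package version that produced it. Reruns with the
#' same config produce identical JSON.
#'
#' @param report A `larynx_report`.
#' @param path Output file; `NULL` returns the JSON string.
#' @return The JSON string, invisibly when written to a file.
#' @export
report_json <- function(report, path = NULL) {
  r <- report$results
  out <- list(
    schema_version = "1.0",
    provenance = report$provenance,
    n_species = nrow(report$data),
    size_axis = list(
      variance_explained = r$size_axis$variance_explained,
      mean_loading = mean(r$size_axis$loadings),
      loadings = as.list(r$size_axis$loadings),
      cv = as.list(r$size_axis$cv)
    )
  )
  if (!is.null(r$allometry)) {
    out$allometry <- list(
      slope = unname(r$allometry$coefficients[["log10_body"]]),
      lambda = r$allometry$lambda, sigma2 = r$allometry$sigma2,
      loglik = r$allometry$loglik
    )
  }
  for (nm in c("pancova_slopes", "pancova_intercepts", "pancova_regimes")) {
    if (!is.null(r[[nm]])) {
      out[[nm]] <- list(
        F = r[[nm]]$F, df_num = r[[nm]]$df_num,
        df_den = r[[nm]]$df_den, P = r[[nm]]$P
      )
    }
  }
  if (!is.null(r$grade_magnitude)) {
    out$grade_magnitude <- list(
      mean_ratio = r$grade_magnitude$mean_ratio,
      sd_ratio = r$grade_magnitude$sd_ratio,
      range = r$grade_magnitude$range_ratio,
      n_pairs = r$grade_magnitude$n_pairs
    )
  }
  if (!is.null(r$shifts)) {
    out$ou_shifts <- list(
      n_shifts = length(r$shifts$shifts),
      shift_edges = r$shifts$shifts,
      theta = as.list(r$shifts$theta),
      alpha = r$shifts$alpha, sigma2 = r$shifts$sigma2,
      snr = r$snr,
      support = as.list(r$shifts$support %||% list())
    )
  }
  if (!is.null(r$rate_test)) {
    out$rate_comparison <- list(
      ratio = r$rate_test$ratio, P = r$rate_test$P,
      sigma2_primate = r$rate_test$sigma2_a,
      sigma2_carnivoran = r$rate_test$sigma2_b,
      n_perm = r$rate_test$n_perm
    )
  }
  if (!is.null(r$larynx_vs_body)) {
    out$larynx_vs_body <- lapply(r$larynx_vs_body, function(z) {
      list(ratio = z$ratio, P = z$P)
    })
  }
  if (!is.null(r$f0)) {
    out$f0 <- list(
      slope_primate = unname(r$f0$primate$coefficients[[".size"]]),
      slope_carnivoran = unname(r$f0$carnivoran$coefficients[[".size"]]),
      t_primate = unname(r$f0$primate$t[[".size"]]),
      t_carnivoran = unname(r$f0$carnivoran$t[[".size"]]),
      slope_comparison_P = r$f0$slope_comparison$P,
      ols_r2_mean = r$f0$ols_r2_mean
    )
  }
  if (!is.null(r$social)) {
    out$social <- list(
      mann_whitney_U = r$social$mann_whitney$U,
      mann_whitney_P = r$social$mann_whitney$P,
      median_primate = r$social$dispersion$primate$median,
      median_carnivoran = r$social$dispersion$carnivoran$median,
      spearman_overall = r$social$spearman$overall$r
    )
  }
  json <- jsonlite::toJSON(out,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}
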