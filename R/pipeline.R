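# One-call pipeline: generate/load -> binarize -> inject nonresponse ->
# impute -> score (means + Rasch) -> reliability -> subgroups -> regression,
# with an optional on-disk report bundle and a reproducibility manifest.

#' Build a validated pipeline configuration
#'
#' Exactly one of `input_paths` (paths to the four delimited tables) or
#' `synthetic` (a [synthetic_config()]) must be supplied. A seed is required
#' whenever any stochastic stage is active (synthetic generation or
#' imputation); the synthetic config's own seed governs generation.
#'
#' @param synthetic A [synthetic_config()], or `NULL`.
#' @param input_paths Named list with `patients`, `providers`, `charts`,
#'   `registry` CSV paths, or `NULL`.
#' @param catalog A `phc_catalog`, a catalogue file path, or `NULL` for the
#'   bundled default.
#' @param impute Run multiple imputation (default `TRUE`).
#' @param m,cycles Imputation settings (defaults 10 and 10).
#' @param quadrature_nodes Gauss-Hermite node count for Rasch fits.
#' @param subgroup_covariates Patient covariates for subgroup summaries.
#' @param cluster Cluster-label column (default `"town"`).
#' @param regression_weights `NULL` or `"response_rate"`.
#' @param seed Integer seed for the imputation stage.
#' @param out_dir Optional output directory for the report bundle.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, input_paths = NULL,
                            catalog = NULL, impute = TRUE, m = 10,
                            cycles = 10, quadrature_nodes = 21,
                            subgroup_covariates = c("gender", "age_band",
                                                    "marriage", "education",
                                                    "income_quintile",
                                                    "insurance",
                                                    "disease_group"),
                            cluster = "town",
                            regression_weights = NULL,
                            seed = NULL, out_dir = NULL) {
  if (is.null(synthetic) == is.null(input_paths)) {
    stop("supply exactly one of `synthetic` or `input_paths`",
         call. = FALSE)
  }
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "synthetic_config"))
  if (!is.null(input_paths)) {
    need <- c("patients", "providers", "charts", "registry")
    if (!all(need %in% names(input_paths))) {
      stop("input_paths needs: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
  }
  if (is.null(seed)) {
    if (!is.null(synthetic)) seed <- synthetic$seed
    else if (impute) {
      stop("a seed is required when imputation is active", call. = FALSE)
    } else seed <- 0L
  }
  structure(
    list(synthetic = synthetic, input_paths = input_paths,
         catalog = catalog, impute = impute, m = m, cycles = cycles,
         quadrature_nodes = quadrature_nodes,
         subgroup_covariates = subgroup_covariates, cluster = cluster,
         regression_weights = regression_weights,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config")
}

resolve_catalog <- function(catalog) {
  if (is.null(catalog)) return(default_catalog())
  if (inherits(catalog, "phc_catalog")) return(catalog)
  load_catalog(catalog)
}

load_input_tables <- function(paths) {
  tabs <- lapply(paths[c("patients", "providers", "charts", "registry")],
                 function(p) readr::read_csv(p, show_col_types = FALSE))
  if (!"dm_registry_followups_per_year" %in% names(tabs$patients)) {
    tabs$patients <- dplyr::left_join(
      tabs$patients, registry_indicators(tabs$registry), by = "patient_id")
  }
  tabs
}

binarize_sources <- function(tables, catalog) {
  list(
    patients = binarize(
      tables$patients,
      catalog[catalog$source %in% c("patient survey", "registry"), ],
      unit_level = "patient", id_col = "patient_id"),
    providers = binarize(
      tables$providers,
      catalog[catalog$source == "provider survey", ],
      unit_level = "provider", id_col = "provider_id"),
    charts = binarize(
      tables$charts,
      catalog[catalog$source == "chart abstraction", ],
      unit_level = "chart", id_col = "chart_id")
  )
}

pooled_rasch_instrument <- function(completed_list, sub_domain, n_nodes) {
  fits <- lapply(completed_list, function(im) {
    rasch_scores(restrict_subdomain(im, sub_domain), n_nodes = n_nodes)
  })
  est <- purrr::map_dbl(fits, ~ mean(.x$score, na.rm = TRUE))
  va <- purrr::map_dbl(fits, ~ stats::var(.x$score, na.rm = TRUE) /
                         sum(!is.na(.x$score)))
  pooled <- pool_estimates(est, va)
  list(scores = fits[[1]], fit = attr(fits[[1]], "fit"), pooled = pooled)
}

#' Run the full quality-scoring pipeline
#'
#' Executes generate/load -> binarize -> (optional nonresponse injection for
#' synthetic inputs) -> reliability (pre-imputation) -> imputation ->
#' mean-based and Rasch-based scoring with Rubin pooling across imputations
#' -> subgroup summaries -> provider-competence regressions, and returns a
#' report bundle. With `out_dir` set, score tables, fit JSONs, subgroup and
#' regression tables and a run manifest (config hash, seed, versions) are
#' written as UTF-8 CSV/JSON; identical config + seed yields an identical
#' bundle.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `phc_report`: `tables`, `matrices`, `reliability`,
#'   `imputation`, `scores` (per-unit), `aggregate` (all 13 sub-domains +
#'   domain totals), `rasch` (per-instrument fits/scores), `subgroups`,
#'   `regression` (models 1-3), `manifest`.
#' @export
run_phc_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  catalog <- resolve_catalog(config$catalog)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  tables <- stage("input", {
    if (!is.null(config$synthetic)) generate_tables(config$synthetic, catalog)
    else load_input_tables(config$input_paths)
  })
  mats <- stage("binarize", binarize_sources(tables, catalog))

  if (!is.null(config$synthetic) && config$synthetic$missing_rate > 0) {
    sc <- config$synthetic
    mats$patients <- inject_missingness(mats$patients, sc, tables$patients,
                                        seed = sc$seed + 50L)
    mats$providers <- inject_missingness(mats$providers, sc,
                                         tables$providers,
                                         seed = sc$seed + 51L)
    mats$charts <- inject_missingness(mats$charts, sc, tables$charts,
                                      seed = sc$seed + 52L)
  }

  reliability <- stage("reliability", dplyr::bind_rows(
    domain_reliability(mats$patients, c("PHC system", "user experience")),
    domain_reliability(
      restrict_subdomain(mats$providers, "provider competence"),
      "clinical care") |>
      dplyr::mutate(domain = "provider competence")
  ))

  imp <- NULL
  cov_cols <- c("gender", "age_band", "education", "disease_group")
  completed <- list(patients = list(mats$patients),
                    providers = list(mats$providers),
                    charts = list(mats$charts))
  if (config$impute) {
    imp <- stage("impute", list(
      patients = mice_impute(
        mats$patients,
        covariates = tables$patients[intersect(cov_cols,
                                               names(tables$patients))],
        m = config$m, cycles = config$cycles, seed = config$seed + 100L),
      providers = mice_impute(
        mats$providers,
        covariates = tables$providers[intersect(c("facility_level", "gender"),
                                                names(tables$providers))],
        m = config$m, cycles = config$cycles, seed = config$seed + 101L),
      charts = mice_impute(
        mats$charts,
        covariates = tables$charts[intersect(c("facility_level",
                                               "disease_group"),
                                             names(tables$charts))],
        m = config$m, cycles = config$cycles, seed = config$seed + 102L)))
    completed <- lapply(imp, function(x) x$completed)
  }

  # mean-scored sub-domains + domain totals, pooled over imputations
  scores <- stage("score", score_quality(completed$patients[[1]]))
  pooled_means <- stage("score", {
    if (config$impute) pool_scores(imp$patients) else {
      agg <- summarize_quality(scores)
      tibble::tibble(measure = agg$measure, estimate = agg$mean_score,
                     total_var = NA_real_, ci_low = NA_real_,
                     ci_high = NA_real_)
    }
  })

  # Rasch instruments
  rasch <- stage("rasch", list(
    `provider competence` = pooled_rasch_instrument(
      completed$providers, "provider competence", config$quadrature_nodes),
    assessment = pooled_rasch_instrument(
      completed$charts, "assessment", config$quadrature_nodes),
    diagnosis = pooled_rasch_instrument(
      completed$charts, "diagnosis", config$quadrature_nodes),
    treatment = pooled_rasch_instrument(
      completed$charts, "treatment", config$quadrature_nodes)))

  aggregate <- stage("aggregate", {
    rasch_rows <- purrr::imap_dfr(rasch, function(r, nm) {
      tibble::tibble(measure = nm, estimate = r$pooled$estimate,
                     total_var = r$pooled$total_var,
                     ci_low = NA_real_, ci_high = NA_real_)
    })
    out <- dplyr::bind_rows(pooled_means, rasch_rows)
    out$domain <- ifelse(out$measure %in% phc_subdomains(),
                         subdomain_to_domain(out$measure), out$measure)
    out$favourable <- favourable(out$estimate)
    out
  })

  # subgroup summaries on patient-level scores (score columns joined with
  # patient covariates and cluster labels)
  subgroups <- stage("subgroups", {
    sdat <- dplyr::left_join(
      scores,
      dplyr::rename(tables$patients, unit_id = "patient_id"),
      by = "unit_id")
    covs <- intersect(config$subgroup_covariates, names(sdat))
    score_cols <- intersect(c("PHC system", "user experience"), names(scores))
    purrr::map_dfr(score_cols, function(scl) {
      purrr::map_dfr(covs, function(cv) {
        out <- subgroup_means(sdat, scl, cv, cluster = config$cluster)
        out$score <- scl
        out
      })
    })
  })

  regression <- stage("regression", {
    comp <- rasch$`provider competence`$scores$score
    comp <- pmin(pmax(comp, 1e-6), 1 - 1e-6)
    lapply(c("model1", "model2", "model3"), function(mid) {
      fit_provider_regression(tables$providers, comp, model_id = mid,
                              cluster = config$cluster,
                              weights = config$regression_weights)
    }) |> stats::setNames(c("model1", "model2", "model3"))
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("phcquality")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    n_patients = nrow(tables$patients),
    n_providers = nrow(tables$providers),
    n_charts = nrow(tables$charts),
    imputed = config$impute, m = if (config$impute) config$m else 0
  )

  report <- structure(
    list(tables = tables, matrices = mats, reliability = reliability,
         imputation = imp, scores = scores, aggregate = aggregate,
         rasch = rasch, subgroups = subgroups, regression = regression,
         manifest = manifest),
    class = "phc_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.phc_report <- function(x, ...) {
  cat(sprintf(
    "<phc_report> %d patients, %d providers, %d charts; %d measures\n",
    x$manifest$n_patients, x$manifest$n_providers, x$manifest$n_charts,
    nrow(x$aggregate)))
  print(x$aggregate[, c("measure", "domain", "estimate", "favourable")],
        n = Inf)
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits per-unit scores, the aggregate score table, reliability, subgroup
#' and regression tables as headered UTF-8 CSVs (missing cells as empty
#' fields), the Rasch fits as JSON, and `manifest.json`.
#'
#' @param report A `phc_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  readr::write_csv(report$scores, p("patient_scores.csv"), na = "")
  readr::write_csv(report$aggregate, p("aggregate_scores.csv"), na = "")
  readr::write_csv(report$reliability, p("reliability.csv"), na = "")
  readr::write_csv(report$subgroups, p("subgroups.csv"), na = "")
  reg <- purrr::imap_dfr(report$regression, function(r, nm) {
    dplyr::mutate(tidy(r), model_id = nm)
  })
  readr::write_csv(reg, p("regression.csv"), na = "")
  for (nm in names(report$rasch)) {
    write_rasch_fit(report$rasch[[nm]]$fit,
                    p(paste0("rasch_", gsub(" ", "_", nm), ".json")))
  }
  jsonlite::write_json(report$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
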