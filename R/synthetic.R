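# Synthetic linked tables: patients, providers, chart abstractions and a
# follow-up registry, with the statistical structure the scoring pipeline
# assumes. Everything is driven by one validated config and one integer seed.
#
# Seed splitting: each table draws under set.seed(seed + offset) with fixed
# offsets (patients +1, providers +2, charts +3, registry +4, missingness +5,
# standalone Rasch responses +6), so any table can be regenerated on its own.

seed_offsets <- c(patients = 1L, providers = 2L, charts = 3L,
                  registry = 4L, missingness = 5L, rasch = 6L)

check_marginal <- function(p, name) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("covariate marginal '", name,
         "' must be non-negative and sum to 1 (got sum ", sum(p), ")",
         call. = FALSE)
  }
  invisible(p)
}

normalise <- function(p) p / sum(p)

#' Default covariate marginals of the synthetic population
#'
#' Categorical distributions for the patient, provider and chart covariates.
#' Printed sample characteristics (region shares, gender, facility mix,
#' disease mix) are used directly; distributions the sample table does not
#' print (age bands, marriage, education, income quintiles, insurance) are
#' fixed at values realistic for rural chronic-disease patients and are
#' documented in the methods vignette.
#'
#' @return Named list of named probability vectors.
#' @export
default_covariate_marginals <- function() {
  list(
    region = c("Hubei" = 0.310, "Henan" = 0.344, "Shanxi" = 0.346),
    gender = c(female = 0.624, male = 0.376),
    age_band = c("<50" = 0.06, "50-60" = 0.22, "60-70" = 0.40, ">=70" = 0.32),
    marriage = c(married = 0.84, unmarried = 0.16),
    education = c("primary or below" = 0.55, "middle school" = 0.30,
                  "high school or above" = 0.15),
    income_quintile = stats::setNames(rep(0.2, 5), paste0("Q", 1:5)),
    insurance = c(NCMS = 0.60, URRBMI = 0.30, UEBMI = 0.06, URBMI = 0.04),
    disease_group = c(hypertension = 0.665, diabetes = 0.131,
                      comorbidity = 0.204),
    provider_region = normalise(c("Hubei" = 0.396, "Henan" = 0.429,
                                  "Shanxi" = 0.174)),
    provider_facility = normalise(c("village clinic" = 0.537,
                                    "township health centre" = 0.321,
                                    "county hospital" = 0.141)),
    provider_gender = c(female = 0.486, male = 0.514),
    chart_facility = c("township health centre" = 0.221,
                       "county hospital" = 0.779),
    chart_disease = normalise(c(hypertension = 0.386, diabetes = 0.360,
                                comorbidity = 0.255))
  )
}

#' Default per-indicator endorsement probabilities
#'
#' One probability per mean-scored sub-domain (applied to each of its
#' indicators), set to the aggregate sub-domain quality levels the framework
#' study reports, so that default synthetic runs live in the same score
#' regime as real rural-China PHC data.
#'
#' @return Named numeric vector over the nine mean-scored sub-domains.
#' @export
default_indicator_probs <- function() {
  c("accessibility" = 0.781, "comprehensiveness" = 0.887,
    "continuity" = 0.489, "coordination" = 0.714,
    "disease management" = 0.777, "shared decision-making" = 0.657,
    "family-centeredness" = 0.382, "information sharing" = 0.933,
    "respect for patient preferences" = 0.936)
}

#' Default Rasch item difficulties per instrument
#'
#' Difficulty vectors (logit scale) for the provider-competence vignette and
#' the three chart-abstraction instruments. Magnitudes are fixed so that
#' test-characteristic-curve scores under a standard-normal ability land in
#' the regimes observed for these instruments (competence low, chart
#' sub-domains favourable).
#'
#' @return Named list of numeric vectors.
#' @export
default_item_difficulties <- function() {
  list(
    "provider competence" = seq(0.2, 2.2, length.out = 12),
    "assessment" = seq(-2.2, -0.4, length.out = 6),
    "diagnosis" = seq(-2.1, -0.3, length.out = 6),
    "treatment" = seq(-1.7, 0.1, length.out = 6)
  )
}

#' Build a validated synthetic-data configuration
#'
#' @param n_patients,n_providers,n_charts Table sizes; defaults are the
#'   analysed sample sizes (1355 patients, 333 providers, 2203 charts).
#' @param cluster_sizes List with `counties`, `towns_per_county`,
#'   `villages_per_town`; default 3 x 3 x 5 (nine towns, the clustering level
#'   used for standard errors).
#' @param indicator_probs Named endorsement probability per mean-scored
#'   sub-domain (scalar each), see [default_indicator_probs()].
#' @param item_difficulties Named list of difficulty vectors per Rasch
#'   instrument, see [default_item_difficulties()].
#' @param covariate_effects Named list of additive ability shifts (logit
#'   scale): `provider_facility` and `chart_facility` entries map facility
#'   levels to shifts of the latent ability theta.
#' @param covariate_marginals See [default_covariate_marginals()].
#' @param missing_rate Fraction of observed cells to mask, in `[0, 1)`.
#' @param missing_mechanism `"MCAR"` or `"MAR"`.
#' @param mar_covariate,mar_rates For MAR: a fully observed covariate and a
#'   named per-level masking rate.
#' @param latent_loading Loading of the shared per-patient latent quality
#'   factor on the logit scale (default 0.8). Survey indicators are drawn as
#'   `Bernoulli(plogis(a_i + loading * u_j))` with `u_j ~ N(0, 1)` and the
#'   intercept calibrated so each indicator's marginal endorsement stays at
#'   its configured probability; the factor induces the within-scale
#'   correlation that summative reliability and imputation rely on. Set 0
#'   for independent indicators.
#' @param registry_rate Mean follow-up visits per patient-year (Poisson);
#'   ignored for the follow-up-frequency indicator, whose count is calibrated
#'   to the disease-management endorsement probability.
#' @param response_rates Facility-level provider response rates, used as
#'   optional regression weights downstream.
#' @param seed Integer master seed; all randomness flows from it.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 1355,
                             n_providers = 333,
                             n_charts = 2203,
                             cluster_sizes = list(counties = 3,
                                                  towns_per_county = 3,
                                                  villages_per_town = 5),
                             indicator_probs = default_indicator_probs(),
                             item_difficulties = default_item_difficulties(),
                             covariate_effects = list(
                               provider_facility = c(
                                 "village clinic" = 0,
                                 "township health centre" = 0.4,
                                 "county hospital" = 0.6),
                               chart_facility = c(
                                 "township health centre" = 0,
                                 "county hospital" = 0.2)),
                             covariate_marginals = default_covariate_marginals(),
                             latent_loading = 0.8,
                             missing_rate = 0.05,
                             missing_mechanism = c("MCAR", "MAR"),
                             mar_covariate = "gender",
                             mar_rates = c(female = 0.03, male = 0.08),
                             registry_rate = 4.2,
                             response_rates = c(
                               "village clinic" = 0.899,
                               "township health centre" = 0.842,
                               "county hospital" = 0.940),
                             seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  stopifnot(n_patients >= 1, n_providers >= 1, n_charts >= 1)
  cs <- cluster_sizes
  if (any(unlist(cs) < 1)) {
    stop("cluster sizes must be positive", call. = FALSE)
  }
  if (any(indicator_probs < 0 | indicator_probs > 1)) {
    stop("indicator endorsement probabilities must lie in [0, 1]",
         call. = FALSE)
  }
  if (!all(vapply(item_difficulties, function(b) all(is.finite(b)),
                  logical(1)))) {
    stop("item difficulties must be finite", call. = FALSE)
  }
  for (nm in names(covariate_marginals)) {
    check_marginal(covariate_marginals[[nm]], nm)
  }
  if (latent_loading < 0) {
    stop("latent_loading must be non-negative", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  }
  if (any(mar_rates < 0 | mar_rates >= 1)) {
    stop("MAR rates must lie in [0, 1)", call. = FALSE)
  }
  seed <- as.integer(seed)
  structure(
    list(n_patients = as.integer(n_patients),
         n_providers = as.integer(n_providers),
         n_charts = as.integer(n_charts),
         cluster_sizes = cs,
         indicator_probs = indicator_probs,
         item_difficulties = item_difficulties,
         covariate_effects = covariate_effects,
         covariate_marginals = covariate_marginals,
         latent_loading = latent_loading,
         missing_rate = missing_rate,
         missing_mechanism = missing_mechanism,
         mar_covariate = mar_covariate,
         mar_rates = mar_rates,
         registry_rate = registry_rate,
         response_rates = response_rates,
         seed = seed),
    class = "synthetic_config"
  )
}

# Cluster frame: counties A/B/C mapped to regions, towns nested in counties,
# villages nested in towns. County-level facilities take the county-seat town
# (the county's first town) as their cluster label.
cluster_frame <- function(config) {
  cs <- config$cluster_sizes
  counties <- names(config$covariate_marginals$region)
  counties <- counties[seq_len(cs$counties)]
  towns <- unlist(lapply(counties, function(co)
    paste0(co, "_town", seq_len(cs$towns_per_county))))
  villages <- unlist(lapply(towns, function(tw)
    paste0(tw, "_v", seq_len(cs$villages_per_town))))
  list(counties = counties, towns = towns, villages = villages,
       town_county = rep(counties, each = cs$towns_per_county),
       village_town = rep(towns, each = cs$villages_per_town))
}

draw_cat <- function(n, marginal) {
  sample(names(marginal), n, replace = TRUE, prob = marginal)
}

# Poisson rate with P(X >= k) = p, for the registry follow-up count.
poisson_rate_for_tail <- function(p, k = 4) {
  stats::uniroot(function(l) stats::ppois(k - 1, l, lower.tail = FALSE) - p,
                 interval = c(1e-6, 60))$root
}

# Intercept a such that E[plogis(a + loading * U)] = p for U ~ N(0,1),
# by Gauss-Hermite quadrature + root finding. Keeps each indicator's
# marginal endorsement probability exactly at the configured value while a
# shared latent factor induces within-scale correlation.
calibrate_latent_intercept <- function(p, loading) {
  if (loading == 0 || p %in% c(0, 1)) return(stats::qlogis(p))
  gh <- gauss_hermite_normal(21)
  stats::uniroot(function(a)
    sum(gh$weights * stats::plogis(a + loading * gh$nodes)) - p,
    interval = c(-40, 40))$root
}

#' Generate the synthetic patient-survey table
#'
#' Draws `n_patients` records: nested county/town/village cluster labels,
#' covariates from the configured marginals, one raw-response column per
#' patient-survey indicator of `catalog` (0/1 for identity rules, category
#' labels for set rules) and a registry follow-up count
#' (`dm_registry_followups_per_year`) calibrated so the binarized
#' follow-up-frequency indicator has the configured disease-management
#' endorsement probability. Deterministic given `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @param catalog Indicator catalogue; default [default_catalog()].
#' @return A tibble, one row per patient.
#' @export
generate_patients <- function(config, catalog = default_catalog()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + seed_offsets[["patients"]])
  n <- config$n_patients
  cf <- cluster_frame(config)
  m <- config$covariate_marginals

  county <- draw_cat(n, m$region[cf$counties] / sum(m$region[cf$counties]))
  town <- vapply(county, function(co)
    sample(cf$towns[cf$town_county == co], 1), character(1))
  village <- vapply(town, function(tw)
    sample(cf$villages[cf$village_town == tw], 1), character(1))

  out <- tibble::tibble(
    patient_id = sprintf("pat_%05d", seq_len(n)),
    county = county, town = unname(town), village = unname(village),
    gender = draw_cat(n, m$gender),
    age_band = draw_cat(n, m$age_band),
    marriage = draw_cat(n, m$marriage),
    education = draw_cat(n, m$education),
    income_quintile = draw_cat(n, m$income_quintile),
    insurance = draw_cat(n, m$insurance),
    disease_group = draw_cat(n, m$disease_group)
  )

  cat_pat <- catalog[catalog$source %in% c("patient survey", "registry"), ]
  lam <- config$latent_loading
  u_latent <- stats::rnorm(n)
  for (i in seq_len(nrow(cat_pat))) {
    id <- cat_pat$indicator_id[i]
    p <- config$indicator_probs[[cat_pat$sub_domain[i]]]
    if (is.null(p)) p <- 0.5
    p_unit <- stats::plogis(calibrate_latent_intercept(p, lam) +
                              lam * u_latent)
    out[[id]] <- switch(
      cat_pat$rule_type[i],
      identity = stats::rbinom(n, 1, p_unit),
      set = {
        # endorsement category with prob p; remainder split "no"/"don't know"
        u <- stats::runif(n)
        ifelse(u < p_unit, "yes", ifelse(u < p_unit + 0.7 * (1 - p_unit),
                                         "no", "don't know"))
      },
      threshold = {
        # registry counts stay marginal Poisson, independent of the factor
        pr <- poisson_rate_for_tail(p, k = as.numeric(cat_pat$rule_arg[i]))
        stats::rpois(n, pr)
      })
  }
  out
}

# Bernoulli draws from the one-parameter logistic model, shared by the
# exported seeded wrapper and the internal table generators (which run inside
# an already-seeded stream).
draw_rasch <- function(difficulties, abilities) {
  eta <- outer(abilities, difficulties, "-")
  p <- stats::plogis(eta)
  y <- matrix(stats::rbinom(length(p), 1, p), nrow = length(abilities))
  colnames(y) <- names(difficulties)
  y
}

#' Generate dichotomous responses from the Rasch model
#'
#' Each response is Bernoulli with probability
#' `exp(theta_j - b_i) / (1 + exp(theta_j - b_i))`: persons differ only in
#' ability theta, items only in difficulty b.
#'
#' @param config A [synthetic_config()] (supplies the seed).
#' @param difficulties Numeric difficulty vector (logit scale).
#' @param abilities Numeric ability vector (logit scale).
#' @param seed Seed for this draw; default `config$seed + 6`.
#' @return Integer 0/1 matrix, persons x items.
#' @export
generate_rasch_responses <- function(config, difficulties, abilities,
                                     seed = config$seed +
                                       seed_offsets[["rasch"]]) {
  if (!all(is.finite(difficulties)) || !all(is.finite(abilities))) {
    stop("difficulties and abilities must be finite", call. = FALSE)
  }
  if (length(difficulties) < 1 || length(abilities) < 1) {
    stop("empty difficulty or ability vector", call. = FALSE)
  }
  set.seed(seed)
  draw_rasch(difficulties, abilities)
}

#' Generate the synthetic provider-survey table
#'
#' Providers are clustered by town (county-hospital staff carry their county
#' seat's town label), with the configured facility mix. Clinical-knowledge
#' vignette responses follow the Rasch model with ability
#' `theta ~ N(0, 1)` plus the configured facility shift; workplace-correlated
#' education and employment covariates mirror the strong rural
#' facility-education gradient.
#'
#' @inheritParams generate_patients
#' @return A tibble, one row per provider (includes latent `theta_true`).
#' @export
generate_providers <- function(config, catalog = default_catalog()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + seed_offsets[["providers"]])
  n <- config$n_providers
  cf <- cluster_frame(config)
  m <- config$covariate_marginals

  county <- draw_cat(n, m$provider_region[cf$counties] /
                       sum(m$provider_region[cf$counties]))
  facility <- draw_cat(n, m$provider_facility)
  town <- vapply(seq_len(n), function(i) {
    tw <- cf$towns[cf$town_county == county[i]]
    if (facility[i] == "county hospital") tw[1] else sample(tw, 1)
  }, character(1))

  p_college <- c("village clinic" = 0.25, "township health centre" = 0.92,
                 "county hospital" = 1.00)[facility]
  p_perm <- c("village clinic" = 0.20, "township health centre" = 0.70,
              "county hospital" = 0.90)[facility]
  p_exam <- c("village clinic" = 0.30, "township health centre" = 0.70,
              "county hospital" = 0.90)[facility]
  p_title <- c("village clinic" = 0.35, "township health centre" = 0.60,
               "county hospital" = 0.80)[facility]

  eff <- config$covariate_effects$provider_facility
  theta <- stats::rnorm(n) + unname(eff[facility])

  out <- tibble::tibble(
    provider_id = sprintf("prov_%04d", seq_len(n)),
    county = county, town = unname(town),
    facility_level = facility,
    gender = draw_cat(n, m$provider_gender),
    education = ifelse(stats::runif(n) < p_college, "college or above",
                       "high school or below"),
    permanent_post = stats::rbinom(n, 1, p_perm),
    passed_licensing_exam = stats::rbinom(n, 1, p_exam),
    job_title = stats::rbinom(n, 1, p_title),
    administrative_role = stats::rbinom(n, 1, 0.2),
    job_satisfaction = ifelse(stats::rbinom(n, 1, 0.7) == 1,
                              "satisfied", "not satisfied"),
    theta_true = theta
  )
  b <- config$item_difficulties[["provider competence"]]
  ids <- catalog$indicator_id[catalog$sub_domain == "provider competence"]
  stopifnot(length(b) == length(ids))
  y <- draw_rasch(stats::setNames(b, ids), theta)
  dplyr::bind_cols(out, tibble::as_tibble(y))
}

#' Generate the synthetic chart-abstraction table
#'
#' Inpatient records exist only at township health centres and county
#' hospitals (village clinics provide no inpatient services). Checklist
#' responses for the assessment, diagnosis and treatment item sets follow the
#' Rasch model with a shared per-chart ability.
#'
#' @inheritParams generate_patients
#' @return A tibble, one row per chart (includes latent `theta_true`).
#' @export
generate_charts <- function(config, catalog = default_catalog()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + seed_offsets[["charts"]])
  n <- config$n_charts
  cf <- cluster_frame(config)
  m <- config$covariate_marginals

  county <- draw_cat(n, m$region[cf$counties] / sum(m$region[cf$counties]))
  facility <- draw_cat(n, m$chart_facility)
  town <- vapply(seq_len(n), function(i) {
    tw <- cf$towns[cf$town_county == county[i]]
    if (facility[i] == "county hospital") tw[1] else sample(tw, 1)
  }, character(1))
  eff <- config$covariate_effects$chart_facility
  theta <- stats::rnorm(n) + unname(eff[facility])

  out <- tibble::tibble(
    chart_id = sprintf("chart_%05d", seq_len(n)),
    county = county, town = unname(town),
    facility_level = facility,
    disease_group = draw_cat(n, m$chart_disease),
    theta_true = theta
  )
  for (sub in c("assessment", "diagnosis", "treatment")) {
    b <- config$item_difficulties[[sub]]
    ids <- catalog$indicator_id[catalog$sub_domain == sub]
    stopifnot(length(b) == length(ids))
    out <- dplyr::bind_cols(
      out, tibble::as_tibble(draw_rasch(stats::setNames(b, ids), theta)))
  }
  out
}

#' Generate the synthetic follow-up registry
#'
#' One row per follow-up visit, consistent with each patient's
#' `dm_registry_followups_per_year` count: visit dates strictly increasing
#' within the observation year, with a blood-pressure (hypertension) or
#' glycated-haemoglobin (diabetes) measurement per visit; comorbid patients
#' carry both.
#'
#' @param config A [synthetic_config()].
#' @param patients Output of [generate_patients()].
#' @return A tibble with columns `patient_id`, `visit_date`, `measure`,
#'   `value`.
#' @export
generate_registry <- function(config, patients) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + seed_offsets[["registry"]])
  counts <- patients$dm_registry_followups_per_year
  idx <- rep(seq_len(nrow(patients)), counts)
  n_vis <- length(idx)
  day <- unlist(lapply(counts[counts > 0], function(k)
    sort(sample.int(365, k))))
  disease <- patients$disease_group[idx]
  measure <- ifelse(disease == "diabetes", "hba1c", "systolic_bp")
  value <- ifelse(measure == "hba1c",
                  stats::rnorm(n_vis, 7.2, 1.1),
                  stats::rnorm(n_vis, 141, 16))
  reg <- tibble::tibble(
    patient_id = patients$patient_id[idx],
    visit_date = as.Date("2022-01-01") + day - 1,
    measure = measure,
    value = round(value, 1)
  )
  # comorbid patients get both measurements per visit
  com <- reg[disease == "comorbidity", ]
  if (nrow(com) > 0) {
    com$measure <- "hba1c"
    com$value <- round(stats::rnorm(nrow(com), 7.2, 1.1), 1)
    reg <- dplyr::bind_rows(reg, com)
  }
  dplyr::arrange(reg, .data$patient_id, .data$visit_date, .data$measure)
}

#' Derive per-patient registry indicators
#'
#' Computes follow-up visits per calendar year of observation per patient
#' (distinct visit dates / years observed), the raw value behind the
#' follow-up-frequency indicator.
#'
#' @param registry Output of [generate_registry()] or a table with
#'   `patient_id` and `visit_date`.
#' @return Tibble with `patient_id` and `dm_registry_followups_per_year`.
#' @export
registry_indicators <- function(registry) {
  registry |>
    dplyr::distinct(.data$patient_id, .data$visit_date) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      dm_registry_followups_per_year =
        dplyr::n() / max(1, dplyr::n_distinct(format(.data$visit_date, "%Y"))),
      .groups = "drop")
}

#' Inject item nonresponse into an indicator matrix
#'
#' Masks observed cells under MCAR (independent Bernoulli at
#' `config$missing_rate`) or MAR (per-unit rate determined by a fully
#' observed covariate, `config$mar_covariate` / `config$mar_rates`). The
#' pre-masking values are retained in the `truth` attribute so imputation can
#' be scored against them.
#'
#' @param matrix An [indicator_matrix()].
#' @param config A [synthetic_config()].
#' @param covariates Data frame aligned with the matrix rows (needed for
#'   MAR), containing `config$mar_covariate`.
#' @param seed Seed; default `config$seed + 5`.
#' @return An `indicator_matrix` with masked cells and `truth` set.
#' @export
inject_missingness <- function(matrix, config, covariates = NULL,
                               seed = config$seed +
                                 seed_offsets[["missingness"]]) {
  stopifnot(inherits(matrix, "indicator_matrix"))
  if (config$missing_rate >= 1) {
    stop("missing_rate must be < 1", call. = FALSE)
  }
  if (config$missing_rate == 0 && config$missing_mechanism == "MCAR") {
    return(matrix)
  }
  set.seed(seed)
  vals <- matrix$values
  if (config$missing_mechanism == "MCAR") {
    rate <- matrix(config$missing_rate, nrow(vals), ncol(vals))
  } else {
    if (is.null(covariates) ||
        !config$mar_covariate %in% names(covariates)) {
      stop("MAR masking needs a covariates table containing '",
           config$mar_covariate, "'", call. = FALSE)
    }
    lev <- as.character(covariates[[config$mar_covariate]])
    if (anyNA(lev)) {
      stop("MAR covariate must be fully observed", call. = FALSE)
    }
    r <- config$mar_rates[lev]
    if (anyNA(r)) {
      stop("mar_rates missing level(s): ",
           paste(setdiff(unique(lev), names(config$mar_rates)),
                 collapse = ", "), call. = FALSE)
    }
    rate <- matrix(r, nrow(vals), ncol(vals))
  }
  mask <- matrix(stats::runif(length(vals)) < rate,
                 nrow(vals), ncol(vals)) & !is.na(vals)
  truth <- if (is.null(matrix$truth)) matrix$values else matrix$truth
  vals[mask] <- NA_real_
  indicator_matrix(vals, matrix$mapping, unit_ids = matrix$unit_ids,
                   unit_level = matrix$unit_level, truth = truth)
}

#' Generate all four linked synthetic tables
#'
#' @param config A [synthetic_config()].
#' @param catalog Indicator catalogue.
#' @return List with `patients`, `providers`, `charts`, `registry` tibbles.
#' @export
generate_tables <- function(config, catalog = default_catalog()) {
  patients <- generate_patients(config, catalog)
  list(
    patients = patients,
    providers = generate_providers(config, catalog),
    charts = generate_charts(config, catalog),
    registry = generate_registry(config, patients)
  )
}
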