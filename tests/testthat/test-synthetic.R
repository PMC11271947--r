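test_that("generation is deterministic given the seed and config", {
  cfg <- small_config(seed = 7)
  t1 <- generate_tables(cfg)
  t2 <- generate_tables(cfg)
  expect_identical(t1, t2)
  t3 <- generate_patients(small_config(seed = 8))
  expect_false(identical(t1$patients, t3))
})

test_that("degenerate endorsement probabilities saturate the indicators", {
  probs <- default_indicator_probs()
  probs[] <- 1
  cfg <- small_config(indicator_probs = probs)
  pats <- generate_patients(cfg)
  im <- binarize(pats, patient_catalog(), "patient", id_col = "patient_id")
  ident <- patient_catalog()$indicator_id[
    patient_catalog()$rule_type == "identity"]
  expect_true(all(im$values[, ident] == 1))
})

test_that("sampled endorsement rates match the configured probability", {
  cfg <- synthetic_config(n_patients = 5000, seed = 13)
  pats <- generate_patients(cfg)
  p <- 0.887  # comprehensiveness indicators
  tol <- 3 * sqrt(p * (1 - p) / 5000)
  expect_lt(abs(mean(pats$comp_health_education) - p), tol)
  # latent-factor marginal calibration holds for a low-probability scale too
  p2 <- 0.382
  expect_lt(abs(mean(pats$fam_history_inquired) - p2),
            3 * sqrt(p2 * (1 - p2) / 5000))
})

test_that("covariate marginals are recovered at large n", {
  cfg <- synthetic_config(n_patients = 10000, seed = 5)
  pats <- generate_patients(cfg)
  for (cv in c("gender", "age_band", "disease_group", "insurance")) {
    marg <- cfg$covariate_marginals[[if (cv == "gender") "gender" else cv]]
    tab <- table(factor(pats[[cv]], levels = names(marg)))
    expect_gt(stats::chisq.test(tab, p = marg)$p.value, 0.01)
  }
})

test_that("invalid configurations are rejected", {
  probs <- default_indicator_probs()
  probs[1] <- 1.4
  expect_error(small_config(indicator_probs = probs), "\\[0, 1\\]")
  expect_error(small_config(missing_rate = 1), "missing_rate")
  expect_error(small_config(cluster_sizes = list(counties = 0,
                                                 towns_per_county = 3,
                                                 villages_per_town = 5)),
               "positive")
  bad_marg <- default_covariate_marginals()
  bad_marg$gender <- c(female = 0.7, male = 0.2)
  expect_error(small_config(covariate_marginals = bad_marg), "sum to 1")
})

test_that("rasch response generation follows the one-parameter model", {
  cfg <- small_config(seed = 2)
  # theta == b gives endorsement 0.5
  y <- generate_rasch_responses(cfg, difficulties = rep(0.7, 10),
                                abilities = rep(0.7, 1000))
  expect_lt(abs(mean(y) - 0.5), 3 * sqrt(0.25 / 10000))
  # extreme easiness saturates
  y1 <- generate_rasch_responses(cfg, difficulties = rep(-30, 3),
                                 abilities = rnorm(50))
  expect_true(all(y1 == 1))
  # theta ~ N(0,1), b = 0: mean response matches the Gauss-Hermite value
  set.seed(99)
  th <- rnorm(10000)
  y2 <- generate_rasch_responses(cfg, difficulties = 0, abilities = th)
  target <- grid_integrate(function(t) plogis(t))
  expect_lt(abs(mean(y2) - target), 3 * sd(plogis(th)) / sqrt(10000) + 0.01)
  expect_error(generate_rasch_responses(cfg, Inf, 0), "finite")
})

test_that("cluster labels are nested counties > towns > villages", {
  cfg <- small_config()
  pats <- generate_patients(cfg)
  expect_true(all(startsWith(pats$town, pats$county)))
  expect_true(all(startsWith(pats$village, pats$town)))
  expect_equal(length(unique(pats$town)), 9)
  charts <- generate_charts(cfg)
  expect_false(any(charts$facility_level == "village clinic"))
})

test_that("registry visits are consistent and strictly increasing per patient", {
  cfg <- small_config(seed = 21)
  pats <- generate_patients(cfg)
  reg <- generate_registry(cfg, pats)
  derived <- registry_indicators(reg)
  joined <- dplyr::inner_join(
    derived, pats[, c("patient_id", "dm_registry_followups_per_year")],
    by = "patient_id", suffix = c("_reg", "_pat"))
  expect_equal(joined$dm_registry_followups_per_year_reg,
               joined$dm_registry_followups_per_year_pat)
  by_pat <- split(reg$visit_date[reg$measure != "hba1c" |
                                   !duplicated(paste(reg$patient_id,
                                                     reg$visit_date))],
                  reg$patient_id[reg$measure != "hba1c" |
                                   !duplicated(paste(reg$patient_id,
                                                     reg$visit_date))])
  expect_true(all(vapply(by_pat, function(d)
    all(diff(sort(unique(d))) > 0), logical(1))))
})

test_that("MCAR masking hits its target rate and preserves the truth", {
  set.seed(4)
  vals <- matrix(rbinom(10000, 1, 0.6), 1000, 10)
  im <- toy_matrix(vals)
  cfg <- small_config(missing_rate = 0.2)
  masked <- inject_missingness(im, cfg)
  frac <- mean(is.na(masked$values))
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / 10000))
  expect_identical(masked$truth, im$values)
  obs <- !is.na(masked$values)
  expect_identical(masked$values[obs], im$values[obs])
  # rate 0 is the identity
  expect_identical(inject_missingness(im, small_config(missing_rate = 0)),
                   im)
})

test_that("MAR masking rates vary with the keyed covariate as configured", {
  set.seed(9)
  n <- 4000
  vals <- matrix(rbinom(n * 5, 1, 0.5), n, 5)
  im <- toy_matrix(vals)
  covs <- tibble::tibble(gender = sample(c("female", "male"), n, TRUE))
  cfg <- small_config(missing_mechanism = "MAR",
                      mar_rates = c(female = 0.1, male = 0.3))
  masked <- inject_missingness(im, cfg, covariates = covs)
  for (lv in c("female", "male")) {
    rows <- covs$gender == lv
    target <- cfg$mar_rates[[lv]]
    frac <- mean(is.na(masked$values[rows, ]))
    expect_lt(abs(frac - target),
              3 * sqrt(target * (1 - target) / sum(rows * 5)))
  }
  expect_error(inject_missingness(im, cfg), "covariates")
})
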