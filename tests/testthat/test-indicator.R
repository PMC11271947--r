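test_that("the bundled default catalogue loads with all 13 sub-domains", {
  cat <- default_catalog()
  expect_setequal(unique(cat$sub_domain), phc_subdomains())
  expect_setequal(unique(cat$domain), names(phc_domains()))
  path <- system.file("extdata", "default_catalog.yaml",
                      package = "phcquality")
  expect_true(nzchar(path))
  from_yaml <- load_catalog(path)
  expect_equal(as.data.frame(from_yaml)[order(from_yaml$indicator_id), ],
               as.data.frame(cat)[order(cat$indicator_id), ],
               ignore_attr = TRUE)
})

test_that("catalogue validation rejects malformed entries", {
  base <- tibble::tibble(indicator_id = c("a", "b"),
                         sub_domain = "continuity",
                         source = "patient survey", rule_type = "identity")
  expect_s3_class(load_catalog(base), "phc_catalog")
  bad_sub <- base
  bad_sub$sub_domain <- c("continuity", "safety")
  expect_error(load_catalog(bad_sub), "safety")
  dup <- base
  dup$indicator_id <- c("a", "a")
  expect_error(load_catalog(dup), "duplicate")
  bad_src <- base
  bad_src$source <- "hospital billing"
  expect_error(load_catalog(bad_src), "source")
})

test_that("binarization rules map raw values as defined", {
  cat <- load_catalog(tibble::tibble(
    indicator_id = c("thr", "mem", "idn"),
    sub_domain = c("disease management", "information sharing",
                   "accessibility"),
    source = c("registry", "patient survey", "patient survey"),
    rule_type = c("threshold", "set", "identity"),
    rule_arg = c("4", "yes", NA), rule_dir = c("ge", NA, NA)))
  rec <- tibble::tibble(
    patient_id = as.character(1:4),
    thr = c(3, 4, 5, NA),
    mem = c("yes", "no", "don't know", NA),
    idn = c(1, 0, NA, 1))
  im <- binarize(rec, cat, "patient")
  expect_equal(unname(im$values[, "thr"]), c(0, 1, 1, NA))
  expect_equal(unname(im$values[, "mem"]), c(1, 0, 0, NA))
  expect_equal(unname(im$values[, "idn"]), c(1, 0, NA, 1))
  # missing raw values become masked cells, never 0
  expect_true(is.na(im$values[4, "thr"]))
  # rule referencing an absent field errors by default
  expect_error(binarize(rec[, 1:3], cat, "patient"), "absent")
  # ... but can be kept as an all-missing column
  im2 <- binarize(rec[, 1:3], cat, "patient", allow_absent = TRUE)
  expect_true(all(is.na(im2$values[, "idn"])))
  expect_equal(ncol(im2$values), 3)
})

test_that("generated data round-trips to the configured endorsement rates", {
  cfg <- synthetic_config(n_patients = 4000, seed = 31)
  pats <- generate_patients(cfg)
  im <- binarize(pats, patient_catalog(), "patient", id_col = "patient_id")
  agg <- summarize_quality(score_quality(im))
  for (sd in names(default_indicator_probs())) {
    p <- default_indicator_probs()[[sd]]
    got <- agg$mean_score[agg$measure == sd]
    # binomial tolerance on the sub-domain mean (items correlated via the
    # latent factor, so allow 3x the independent-item bound)
    expect_lt(abs(got - p), 3 * 3 * sqrt(p * (1 - p) / 4000))
  }
})

test_that("indicator matrices serialize losslessly through text files", {
  cfg <- small_config(missing_rate = 0.1, seed = 3)
  pats <- generate_patients(cfg)
  im <- inject_missingness(
    binarize(pats, patient_catalog(), "patient", id_col = "patient_id"),
    cfg)
  path <- file.path(withr::local_tempdir(), "im.csv")
  write_indicator_matrix(im, path)
  back <- read_indicator_matrix(path)
  expect_equal(back$values, im$values)
  expect_equal(back$mapping$sub_domain, im$mapping$sub_domain)
  expect_equal(back$unit_ids, im$unit_ids)
})

test_that("non-binary raw values under an identity rule are rejected", {
  cat <- load_catalog(tibble::tibble(
    indicator_id = "x", sub_domain = "accessibility",
    source = "patient survey", rule_type = "identity"))
  rec <- tibble::tibble(patient_id = "1", x = 2)
  expect_error(binarize(rec, cat, "patient"), "non-binary")
})
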