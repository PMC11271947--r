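sim_clustered_scores <- function(n = 1350, G = 9, means = c(a = 0.75, b = 0.70),
                                 cluster_sd = 0.02, unit_sd = 0.15,
                                 seed = 1) {
  set.seed(seed)
  cl <- sample(paste0("town", seq_len(G)), n, TRUE)
  cl_eff <- stats::setNames(rnorm(G, 0, cluster_sd), paste0("town", seq_len(G)))
  grp <- sample(names(means), n, TRUE)
  tibble::tibble(
    score = means[grp] + cl_eff[cl] + rnorm(n, 0, unit_sd),
    group = grp, town = cl)
}

test_that("cluster-robust SEs match a hand-computed CR1 sandwich", {
  d <- sim_clustered_scores(n = 200, seed = 3)
  sm <- subgroup_means(d, "score", "group", ref = "a")
  # hand CR1 for the cell mean of group a: G/(G-1) * sum_g (sum residuals)^2 / n^2
  for (lv in c("a", "b")) {
    y <- d$score[d$group == lv]
    cl <- d$town[d$group == lv]
    n <- length(y)
    u <- y - mean(y)
    G <- length(unique(d$town))
    meat <- sum(tapply(u, cl, sum)^2)
    se_hand <- sqrt(G / (G - 1) * meat / n^2)
    expect_equal(sm$se[sm$level == lv], se_hand, tolerance = 1e-10)
  }
  expect_true(all(sm$ci_low <= sm$mean & sm$mean <= sm$ci_high))
})

test_that("clustering collapses to the heteroskedasticity-robust case", {
  set.seed(6)
  d <- tibble::tibble(score = rnorm(60, 0.7, 0.1),
                      group = sample(c("a", "b"), 60, TRUE),
                      town = as.character(1:60))  # one unit per cluster
  fit <- lm(score ~ group, d)
  V_cl <- sandwich::vcovCL(fit, cluster = d$town, type = "HC0",
                           cadjust = FALSE)
  V_hc <- sandwich::vcovHC(fit, type = "HC0")
  expect_equal(V_cl, V_hc, tolerance = 1e-12)
  tst <- subgroup_test(d, "score", "group", levels = c("a", "b"))
  se_hc1 <- sqrt(60 / 59 * V_hc[2, 2])
  expect_equal(tst$se, se_hc1, tolerance = 1e-10)
})

test_that("degenerate levels are flagged and empty levels omitted", {
  d <- tibble::tibble(score = rep(0.8, 10),
                      group = rep(c("a", "b"), each = 5),
                      town = c(rep("t1", 5), paste0("t", 2:6)))
  sm <- suppressWarnings(subgroup_means(d, "score", "group", ref = "a"))
  expect_true(sm$degenerate[sm$level == "a"])  # single cluster
  expect_equal(sm$mean[sm$level == "a"], 0.8)
  d2 <- d
  d2$group <- factor(d2$group, levels = c("a", "b", "c"))
  expect_message(suppressWarnings(
    subgroup_means(d2, "score", "group", ref = "a")), "no observations")
  tst <- subgroup_test(d, "score", "group", levels = c("a", "b"))
  expect_false(is.na(tst$reason))
})

test_that("identical score vectors in both groups give p = 1", {
  d <- tibble::tibble(
    score = rep(c(0.2, 0.5, 0.9), 6),
    group = rep(c("a", "b"), each = 9),
    town = rep(paste0("t", 1:3), 6))
  tst <- subgroup_test(d, "score", "group", levels = c("a", "b"))
  expect_equal(tst$diff, 0)
  expect_equal(tst$p_value, 1)
})

test_that("the cluster-robust test has power against a 0.05 difference", {
  hits <- vapply(1:20, function(r) {
    d <- sim_clustered_scores(n = 1350, means = c(a = 0.75, b = 0.70),
                              seed = 500 + r)
    subgroup_test(d, "score", "group", levels = c("a", "b"))$p_value < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.8)
})

test_that("subgroup mean estimates cover the truth across replicates", {
  means <- c(a = 0.75, b = 0.70)
  cover <- vapply(1:50, function(r) {
    d <- sim_clustered_scores(seed = 900 + r)
    sm <- subgroup_means(d, "score", "group", ref = "a")
    all(abs(sm$mean[match(names(means), sm$level)] - means) <=
          1.1e-9 + (sm$ci_high - sm$ci_low)[match(names(means),
                                                  sm$level)] / 2)
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("provider regression recovers structure and handles degeneracies", {
  cfg <- synthetic_config(n_providers = 400, seed = 19)
  prov <- generate_providers(cfg)
  # constant response: intercept = log(constant), slopes 0
  reg0 <- suppressWarnings(
    fit_provider_regression(prov, rep(0.4, nrow(prov)),
                            model_id = "model1"))
  expect_equal(reg0$terms$estimate[1], log(0.4), tolerance = 1e-12)
  expect_equal(reg0$terms$estimate[-1], c(0, 0), tolerance = 1e-10)

  # multiplying competence by c shifts only the intercept by log(c)
  comp <- pmin(pmax(plogis(prov$theta_true - 1), 0.01), 0.99)
  r1 <- fit_provider_regression(prov, comp, model_id = "model2")
  r2 <- fit_provider_regression(prov, comp * 0.5, model_id = "model2")
  expect_equal(r2$terms$estimate[1] - r1$terms$estimate[1], log(0.5),
               tolerance = 1e-10)
  expect_equal(r2$terms$estimate[-1], r1$terms$estimate[-1],
               tolerance = 1e-10)

  # exact collinearity: dropped term with warning, remaining terms stable
  prov2 <- prov
  prov2$education <- ifelse(prov2$facility_level == "village clinic",
                            "high school or below", "college or above")
  expect_warning(
    r3 <- fit_provider_regression(prov2, comp, model_id = "model2"),
    "collinear")
  expect_true(length(r3$dropped_terms) >= 1)
  expect_true(all(is.finite(r3$terms$estimate)))

  # response-rate weighting and models 1-3 run
  for (mid in c("model1", "model2", "model3")) {
    r <- fit_provider_regression(prov, comp, model_id = mid,
                                 weights = "response_rate")
    expect_true(r$weighted)
    expect_s3_class(tidy(r), "tbl_df")
  }
  expect_error(fit_provider_regression(prov, rep(1.2, nrow(prov))),
               "strictly in")
})

test_that("workplace effects are recovered within cluster-robust CIs", {
  eff <- c("village clinic" = 0, "township health centre" = 0.20,
           "county hospital" = 0.26)
  cover <- vapply(1:50, function(r) {
    set.seed(1200 + r)
    n <- 2000
    towns <- paste0("t", 1:9)
    town <- sample(towns, n, TRUE)
    cl_eff <- stats::setNames(rnorm(9, 0, 0.05), towns)
    fac <- sample(names(eff), n, TRUE, prob = c(0.5, 0.3, 0.2))
    logc <- log(0.30) + eff[fac] + cl_eff[town] + rnorm(n, 0, 0.2)
    prov <- tibble::tibble(provider_id = as.character(1:n), town = town,
                           facility_level = fac)
    reg <- fit_provider_regression(prov, exp(logc), model_id = "model1")
    tt <- reg$terms[grepl("facility", reg$terms$term), ]
    all(tt$ci_low <= c(0.20, 0.26) & c(0.20, 0.26) <= tt$ci_high)
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("joint Wald tests reject under signal, not under the null", {
  d <- sim_clustered_scores(n = 2000, means = c(a = 0.9, b = 0.7),
                            cluster_sd = 0.01, seed = 4)
  jt <- subgroup_joint_test(d, "score", "group")
  expect_lt(jt$p_value, 0.001)
})
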