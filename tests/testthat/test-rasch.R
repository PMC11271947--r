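test_that("rasch_prob matches the logistic closed form and logit identity", {
  expect_equal(rasch_prob(0, 0), 0.5)
  expect_equal(rasch_prob(1, 0), 0.7310586, tolerance = 1e-6)
  expect_equal(rasch_prob(0, 2), 0.1192029, tolerance = 1e-6)
  th <- seq(-5, 5, by = 0.5)
  b <- rev(th)
  expect_equal(qlogis(rasch_prob(th, b)), th - b, tolerance = 1e-9)
  expect_error(rasch_prob(Inf, 0), "finite")
})

sim_rasch <- function(n, b, seed) {
  set.seed(seed)
  th <- rnorm(n)
  y <- matrix(rbinom(n * length(b), 1,
                     plogis(outer(th, b, "-"))), n, length(b))
  colnames(y) <- paste0("it", seq_along(b))
  y
}

test_that("MML recovers generating difficulties at n = 2000", {
  b_true <- seq(-2, 2, length.out = 10)
  y <- sim_rasch(2000, b_true, seed = 101)
  fit <- fit_rasch_mml(y)
  expect_true(fit$convergence$converged)
  expect_gt(cor(fit$difficulties, b_true), 0.98)
  expect_lt(sqrt(mean((fit$difficulties - b_true)^2)), 0.15)
  # EM ascent: marginal log-likelihood non-decreasing over iterations
  expect_true(all(diff(fit$ll_trace) > -1e-8))
  # stored log-likelihood equals re-evaluation on the training data
  expect_equal(marginal_loglik(fit, y), fit$log_likelihood,
               tolerance = 1e-8)
})

test_that("estimates agree with a brute-force grid-search oracle", {
  y <- sim_rasch(150, c(-0.7, 0.9), seed = 55)
  fit <- fit_rasch_mml(y, tol = 1e-9)
  oracle <- grid_search_two_items(y)
  expect_lt(max(abs(unname(fit$difficulties) - oracle)), 1e-3)
})

test_that("column swaps relabel difficulties and degenerate items drop", {
  y <- sim_rasch(300, c(-1, 0, 1), seed = 77)
  fit <- fit_rasch_mml(y)
  ys <- y[, c(2, 1, 3)]
  fits <- fit_rasch_mml(ys)
  expect_equal(unname(fits$difficulties[c("it2", "it1", "it3")]),
               unname(fit$difficulties[c("it2", "it1", "it3")]),
               tolerance = 1e-9)
  # all-1 item is dropped with reason, not fitted at -Inf
  y2 <- cbind(y, all_one = 1)
  fit2 <- fit_rasch_mml(y2)
  expect_equal(fit2$dropped_items$item_id, "all_one")
  expect_match(fit2$dropped_items$reason, "zero variance")
  expect_true(all(is.finite(fit2$difficulties)))
  expect_error(fit_rasch_mml(matrix(1, 10, 3)), "unidentifiable")
})

test_that("parameter recovery improves with sample size", {
  b_true <- c(-1.5, -0.5, 0.5, 1.5)
  rmse <- vapply(c(250, 4000), function(n) {
    errs <- vapply(1:5, function(r) {
      fit <- fit_rasch_mml(sim_rasch(n, b_true, seed = 1000 * n + r))
      sqrt(mean((fit$difficulties - b_true)^2))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_lt(rmse[2], rmse[1])
})

test_that("EAP scoring is deterministic, monotone, and matches integration", {
  y <- sim_rasch(400, c(-1, 0, 1, 2), seed = 31)
  fit <- fit_rasch_mml(y)
  # identical response patterns get identical abilities
  pat <- c(1, 0, 1, 0)
  expect_equal(eap_theta(fit, pat), eap_theta(fit, pat))
  # sum-score sufficiency: EAP strictly increasing in the raw sum score
  pats <- as.matrix(expand.grid(0:1, 0:1, 0:1, 0:1))
  colnames(pats) <- fit$item_ids
  th <- eap_theta(fit, pats)
  agg <- tapply(th, rowSums(pats), range)
  means <- tapply(th, rowSums(pats), mean)
  expect_true(all(diff(means) > 0))
  expect_equal(unname(which.min(th)), which(rowSums(pats) == 0))
  # all-missing pattern is undefined
  expect_true(is.na(eap_theta(fit, rep(NA, 4))))
  # single item b = 0, response 1: EAP equals fine-grid posterior mean
  fit1 <- fit
  fit1$difficulties <- c(it1 = 0)
  fit1$item_ids <- "it1"
  num <- grid_integrate(function(t) t * plogis(t))
  den <- grid_integrate(function(t) plogis(t))
  expect_equal(eap_theta(fit1, matrix(1, 1, 1,
                                      dimnames = list(NULL, "it1"))),
               num / den, tolerance = 1e-6)
})

test_that("ability-to-score mapping is the TCC over the item count", {
  fit <- list(difficulties = c(a = -1, b = 1), item_ids = c("a", "b"))
  class(fit) <- "rasch_fit"
  expect_equal(map_score(fit, 0), 0.5)
  fit1 <- fit
  fit1$difficulties <- c(a = 0)
  expect_equal(map_score(fit1, 0), 0.5)
  fit3 <- fit
  fit3$difficulties <- c(a = 0, b = 0, c = 2)
  expect_equal(map_score(fit3, 0), 0.3730676, tolerance = 1e-6)
  # strictly increasing with limits 0 and 1
  th <- seq(-30, 30, by = 0.5)
  s <- map_score(fit, th)
  expect_true(all(diff(s) > 0))
  expect_lt(s[1], 1e-9)
  expect_gt(s[length(s)], 1 - 1e-9)
})

test_that("the marginal likelihood handles symmetry and empty data", {
  y <- matrix(1, 1, 2, dimnames = list(NULL, c("i1", "i2")))
  fit <- fit_rasch_mml(sim_rasch(200, c(0, 0), seed = 8))
  fit$difficulties <- c(it1 = 0)
  fit$item_ids <- "it1"
  # single unit, single item b = 0, response 1: integral is exactly 1/2
  y1 <- matrix(1, 1, 1, dimnames = list(NULL, "it1"))
  expect_equal(marginal_loglik(fit, y1), log(0.5), tolerance = 1e-9)
  # empty response set: empty product, log-likelihood 0
  expect_equal(marginal_loglik(fit, y1[0, , drop = FALSE]), 0)
  expect_error(marginal_loglik(fit, matrix(0, 1, 3)), "conformable")
})

test_that("missing responses contribute nothing to the likelihood", {
  y <- sim_rasch(120, c(-0.5, 0.5, 1), seed = 66)
  ymiss <- y
  ymiss[1:40, 2] <- NA
  fit <- fit_rasch_mml(ymiss)
  expect_true(fit$convergence$converged)
  # oracle: fine-grid marginal log-likelihood of the masked data
  expect_equal(marginal_loglik(fit, ymiss[1:5, ]),
               loglik_grid_oracle(ymiss[1:5, ], fit$difficulties),
               tolerance = 1e-5)
})
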